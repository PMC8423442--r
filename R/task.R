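#' Delayed match-to-category task configuration
#'
#' Describes the DMC task: six motion directions split into two categories
#' by a learned boundary, and the durations of the task epochs. Defaults
#' follow the standard macaque version of the task: directions 15, 75, 135,
#' 195, 255, 315 degrees, a 45-degree category boundary, 500 ms fixation,
#' 650 ms sample, 1000 ms delay, 650 ms test, a 150 ms second delay, and a
#' 650 ms second test.
#'
#' @param directions Numeric vector of motion directions in degrees. None
#'   may lie on the category boundary (or its antipode).
#' @param boundary_angle Orientation of the category boundary in degrees.
#' @param epoch_durations Named list of epoch durations in ms with entries
#'   `fixation`, `sample`, `delay`, `test`, `delay2`, `test2`; all > 0.
#' @param rt_mean,rt_sd Mean and SD (ms) of the reaction-time distribution
#'   on lever-release trials, measured from test onset. RTs are drawn from
#'   a normal truncated to \[50, 350\] ms.
#' @return An object of class `dmc_task` (a list of the validated fields),
#'   with element `categories` giving the category (1 or 2) of each
#'   direction.
#' @export
#' @examples
#' cfg <- dmc_task()
#' cfg$categories
dmc_task <- function(directions = c(15, 75, 135, 195, 255, 315),
                     boundary_angle = 45,
                     epoch_durations = list(fixation = 500, sample = 650,
                                            delay = 1000, test = 650,
                                            delay2 = 150, test2 = 650),
                     rt_mean = 250, rt_sd = 15) {
  directions <- as.numeric(directions) %% 360
  need <- c("fixation", "sample", "delay", "test", "delay2", "test2")
  if (!all(need %in% names(epoch_durations)))
    stop("epoch_durations must name: ", paste(need, collapse = ", "))
  epoch_durations <- lapply(epoch_durations[need], as.numeric)
  if (any(unlist(epoch_durations) <= 0)) stop("all epoch durations must be > 0")
  cats <- direction_category(directions, boundary_angle)
  cfg <- list(directions = directions,
              boundary_angle = boundary_angle %% 360,
              categories = cats,
              epoch_durations = epoch_durations,
              rt_mean = rt_mean, rt_sd = rt_sd)
  class(cfg) <- "dmc_task"
  cfg
}

#' Category membership of motion directions
#'
#' A direction belongs to category 1 if it lies within 180 degrees
#' counter-clockwise of the boundary, category 2 otherwise. Directions on
#' the boundary (or its antipode) are ambiguous and rejected.
#'
#' @param directions Directions in degrees.
#' @param boundary_angle Boundary orientation in degrees.
#' @return Integer vector of categories (1 or 2).
#' @export
direction_category <- function(directions, boundary_angle = 45) {
  rel <- (directions - boundary_angle) %% 360
  if (any(rel %% 180 == 0))
    stop("direction(s) ", paste(directions[rel %% 180 == 0], collapse = ", "),
         " lie on the category boundary")
  ifelse(rel < 180, 1L, 2L)
}

#' Event times of a DMC trial
#'
#' @param cfg A `dmc_task`.
#' @return Named numeric vector of event times (ms from trial start):
#'   fixation_on, sample_on, sample_off, test_on, test_off, test2_on,
#'   trial_end.
#' @export
dmc_events <- function(cfg) {
  d <- cfg$epoch_durations
  c(fixation_on = 0,
    sample_on  = d$fixation,
    sample_off = d$fixation + d$sample,
    test_on    = d$fixation + d$sample + d$delay,
    test_off   = d$fixation + d$sample + d$delay + d$test,
    test2_on   = d$fixation + d$sample + d$delay + d$test + d$delay2,
    trial_end  = d$fixation + d$sample + d$delay + d$test + d$delay2 + d$test2)
}

#' Enumerate the stimulus conditions of the DMC task
#'
#' Forms the Cartesian product of sample and test directions and labels
#' each combination with its categories and match status. With the six
#' standard directions this yields 36 sample-test direction combinations
#' and four sample-test category combinations.
#'
#' @param cfg A `dmc_task` configuration.
#' @return A data.frame with columns `sample_direction`, `test_direction`,
#'   `sample_category`, `test_category`, `is_match`.
#' @export
#' @examples
#' nrow(enumerate_conditions(dmc_task()))  # 36
enumerate_conditions <- function(cfg) {
  stopifnot(inherits(cfg, "dmc_task"))
  g <- expand.grid(sample_direction = cfg$directions,
                   test_direction = cfg$directions,
                   KEEP.OUT.ATTRS = FALSE)
  g$sample_category <- cfg$categories[match(g$sample_direction, cfg$directions)]
  g$test_category <- cfg$categories[match(g$test_direction, cfg$directions)]
  g$is_match <- g$sample_category == g$test_category
  g
}

#' Generate a session of DMC trials
#'
#' Samples trial conditions approximately balanced over the direction
#' combinations, draws outcomes from the stated error rates, and draws
#' reaction times from a truncated normal on lever-release trials. A lever
#' release in the first test period occurs on correct match trials and on
#' error nonmatch trials (a false release); error match trials are missed
#' releases and carry no reaction time.
#'
#' Balancing is round-robin over the requested condition set: with
#' `match_fraction = NULL` all conditions are cycled equally; otherwise
#' match and nonmatch condition pools are cycled separately so that the
#' requested match proportion is met.
#'
#' @param cfg A `dmc_task`.
#' @param n_trials Number of trials.
#' @param match_fraction Proportion of match trials, or `NULL` for the
#'   natural fraction of the balanced condition set (0.5 with six
#'   directions).
#' @param error_rate_match,error_rate_nonmatch Per-trial error
#'   probabilities for match and nonmatch trials.
#' @param seed Integer seed; the result is reproducible given the seed.
#' @return A data.frame of class `dmc_trials` with one row per trial:
#'   condition columns as in [enumerate_conditions()], plus `outcome`
#'   (`"correct"`/`"error"`), `choice` (`"match"`/`"nonmatch"`, the
#'   behavioral report), `reaction_time` (ms from test onset, `NA` when no
#'   first-test release), and the event-time columns from [dmc_events()].
#' @export
generate_trials <- function(cfg, n_trials, match_fraction = NULL,
                            error_rate_match = 0.1,
                            error_rate_nonmatch = 0.02, seed = 1L) {
  stopifnot(inherits(cfg, "dmc_task"), n_trials > 0,
            error_rate_match >= 0, error_rate_match <= 1,
            error_rate_nonmatch >= 0, error_rate_nonmatch <= 1)
  if (!is.null(match_fraction))
    stopifnot(match_fraction >= 0, match_fraction <= 1)
  conds <- enumerate_conditions(cfg)
  rng <- local_rng(seed)
  if (is.null(match_fraction)) {
    idx <- balanced_draw(seq_len(nrow(conds)), n_trials)
  } else {
    n_match <- round(n_trials * match_fraction)
    idx <- c(balanced_draw(which(conds$is_match), n_match),
             balanced_draw(which(!conds$is_match), n_trials - n_match))
  }
  if (n_trials < nrow(conds))
    warning("n_trials < number of conditions; the design is incomplete")
  idx <- idx[sample.int(length(idx))]
  tr <- conds[idx, , drop = FALSE]
  rownames(tr) <- NULL
  err_p <- ifelse(tr$is_match, error_rate_match, error_rate_nonmatch)
  tr$outcome <- ifelse(stats::runif(nrow(tr)) < err_p, "error", "correct")
  truth <- ifelse(tr$is_match, "match", "nonmatch")
  tr$choice <- ifelse(tr$outcome == "correct", truth,
                      ifelse(truth == "match", "nonmatch", "match"))
  # first-test lever release happens whenever the reported choice is "match"
  release <- tr$choice == "match"
  tr$reaction_time <- NA_real_
  tr$reaction_time[release] <- rtrunc_norm(sum(release), cfg$rt_mean,
                                           cfg$rt_sd, 50, 350)
  ev <- dmc_events(cfg)
  for (nm in names(ev)) tr[[nm]] <- ev[[nm]]
  attr(tr, "task") <- cfg
  class(tr) <- c("dmc_trials", "data.frame")
  rng()
  tr
}

# round-robin condition assignment; the remainder is assigned at random
balanced_draw <- function(pool, n) {
  if (n == 0 || length(pool) == 0) return(integer(0))
  full <- rep(pool, n %/% length(pool))
  rem <- n %% length(pool)
  c(full, if (rem > 0) pool[sample.int(length(pool), rem)] else integer(0))
}

# truncated normal by inverse-CDF (exact, vectorized)
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

# Seed the RNG locally; returns a restorer to be called on exit.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  invisible(function() {
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
}
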
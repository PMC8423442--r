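#' Pre-analysis unit screening
#'
#' Includes a unit iff (1) the maximum of its condition-averaged smoothed
#' firing rate over the task interval (fixation onset to 350 ms after
#' test onset) is at least `rate_threshold` (default 5 spikes/s), and
#' (2) it shows at least one kind of task-related modulation (one-way
#' ANOVA, p < `alpha`): sample category in any of the four task epochs
#' (sample, earlier delay, later delay, test), or test category or
#' match/nonmatch status in the test epoch. The delay is split into
#' earlier and later halves at its midpoint.
#'
#' @param spikes A `dmc_spikes` population.
#' @param rate_threshold Minimum peak condition-averaged rate (spikes/s).
#' @param alpha Significance level for the modulation criterion.
#' @return Integer vector of included unit indices, with attribute
#'   `criteria` (data.frame of per-unit peak rate and modulation flag).
#' @export
screen_neurons <- function(spikes, rate_threshold = 5, alpha = 0.01) {
  tr <- spikes$trials
  cfg <- attr(tr, "task")
  ev <- dmc_events(cfg)
  t_hi <- ev[["test_on"]] + 350
  psth <- gaussian_psth(spikes, t_range = c(0, t_hi))
  nu <- n_units(spikes)
  peak <- vapply(seq_len(nu), function(u) max(psth$traces[u, , ]),
                 numeric(1))
  half_delay <- (ev[["test_on"]] - ev[["sample_off"]]) / 2
  epochs <- list(
    sample = c(ev[["sample_on"]], ev[["sample_off"]]),
    delay_early = c(ev[["sample_off"]], ev[["sample_off"]] + half_delay),
    delay_late = c(ev[["sample_off"]] + half_delay, ev[["test_on"]]),
    test = c(ev[["test_on"]], t_hi))
  correct <- tr$outcome == "correct"
  modulated <- logical(nu)
  for (u in seq_len(nu)) {
    ps <- c()
    for (e in names(epochs)) {
      r <- epoch_rates(spikes, u, "fixation_on", epochs[[e]])
      ps <- c(ps, oneway_p(r, tr$sample_category))
      if (e == "test") {
        ps <- c(ps, oneway_p(r, tr$test_category),
                oneway_p(r[correct], tr$is_match[correct]))
      }
    }
    modulated[u] <- any(ps < alpha, na.rm = TRUE)
  }
  included <- which(peak >= rate_threshold & modulated)
  attr(included, "criteria") <- data.frame(unit = seq_len(nu),
                                           peak_rate = peak,
                                           modulated = modulated)
  included
}

# one-way ANOVA p-value (fast path, no formula interface)
oneway_p <- function(values, labels) {
  keep <- !is.na(values)
  f <- factor(labels[keep])
  if (nlevels(f) < 2) return(NA_real_)
  d <- unbiased_fev(values[keep], f)
  d$p_value
}

#' Classify a unit's match/nonmatch preference
#'
#' Applies a one-way ANOVA (match vs nonmatch, correct trials) to mean
#' activity in 200 ms windows sliding by 5 ms within 50-350 ms after
#' test onset. Units significant (p < `alpha`) in at least one window
#' are labeled `"match_preferring"` or `"nonmatch_preferring"` by the
#' sign of the mean-rate difference over the full 50-350 ms window;
#' otherwise `"none"`.
#'
#' @param spikes A `dmc_spikes` population.
#' @param unit Unit index.
#' @param window Test-period window (ms after test onset).
#' @param alpha Significance level (default 0.01).
#' @return `"match_preferring"`, `"nonmatch_preferring"`, or `"none"`.
#' @export
classify_mnm_preference <- function(spikes, unit, window = c(50, 350),
                                    alpha = 0.01) {
  tr <- spikes$trials
  correct <- tr$outcome == "correct"
  g <- window_grid(width = 200, step = 5, align = "test_on",
                   span = window)
  rates <- window_rates(spikes, unit, g)
  sig <- FALSE
  for (w in seq_along(g$starts)) {
    p <- oneway_p(rates[correct, w], tr$is_match[correct])
    if (!is.na(p) && p < alpha) { sig <- TRUE; break }
  }
  if (!sig) return("none")
  r <- epoch_rates(spikes, unit, "test_on", window)
  dm <- mean(r[correct & tr$is_match]) - mean(r[correct & !tr$is_match])
  if (dm >= 0) "match_preferring" else "nonmatch_preferring"
}

#' Latency of match/nonmatch selectivity
#'
#' Latency is the start time of the first run of at least
#' `n_consecutive` (default 2) successive windows on a non-overlapping
#' 20 ms / 20 ms grid in which (1) activity differs significantly
#' between match and nonmatch trials (one-way ANOVA, p < `alpha`,
#' default 0.05) and (2) the preference (sign of the match - nonmatch
#' mean difference) agrees with the unit's global preference over
#' 50-350 ms after test onset. Returns `NA` latency if no such run
#' exists; windows with an inconsistent (flipped) preference never
#' contribute.
#'
#' @param x Either a `dmc_spikes` population (then give `unit`) or a
#'   trials x windows matrix of responses on `grid`.
#' @param unit Unit index when `x` is a population.
#' @param trials Trial data.frame (required when `x` is a matrix).
#' @param grid Latency grid; default 20 ms / 20 ms over 0-400 ms after
#'   test onset.
#' @param alpha Per-window significance level.
#' @param n_consecutive Required run length.
#' @param preference Optional `"match"`/`"nonmatch"` override of the
#'   global preference.
#' @return List: `latency` (ms after test onset, or `NA`), `preference`,
#'   `criteria` (alpha, n_consecutive, grid description).
#' @export
mnm_latency <- function(x, unit = NULL, trials = NULL,
                        grid = window_grid(20, 20, "test_on", c(0, 400)),
                        alpha = 0.05, n_consecutive = 2,
                        preference = NULL) {
  if (inherits(x, "dmc_spikes")) {
    trials <- x$trials
    rates <- window_rates(x, unit, grid)
    global <- epoch_rates(x, unit, "test_on", c(50, 350))
  } else {
    rates <- x
    if (is.null(trials)) stop("trials required with a response matrix")
    keep50 <- grid$centers >= 50 & grid$centers <= 350
    global <- rowMeans(rates[, keep50, drop = FALSE])
  }
  correct <- trials$outcome == "correct"
  m <- trials$is_match
  if (is.null(preference)) {
    dglob <- mean(global[correct & m], na.rm = TRUE) -
      mean(global[correct & !m], na.rm = TRUE)
    preference <- if (dglob >= 0) "match" else "nonmatch"
  }
  want <- if (preference == "match") 1 else -1
  qual <- logical(length(grid$starts))
  for (w in seq_along(grid$starts)) {
    r <- rates[, w]
    ok <- correct & !is.na(r)
    p <- oneway_p(r[ok], m[ok])
    dw <- mean(r[ok & m]) - mean(r[ok & !m])
    qual[w] <- !is.na(p) && p < alpha && sign(dw) == want
  }
  lat <- NA_real_
  run <- rle(qual)
  ends <- cumsum(run$lengths)
  hit <- which(run$values & run$lengths >= n_consecutive)
  if (length(hit)) {
    first <- ends[hit[1]] - run$lengths[hit[1]] + 1
    lat <- grid$starts[first]
  }
  list(latency = lat, preference = preference,
       criteria = list(alpha = alpha, n_consecutive = n_consecutive,
                       width = grid$width, step = grid$step))
}

#' Randomly remove spikes to equate firing rates
#'
#' For each targeted unit and trial, removes
#' `round((1 - R) * n_spikes)` uniformly chosen spikes (rounding half
#' away from zero), so the mean rate of the decimated group is
#' approximately `R` times the original. Used to equate mean rates
#' between match- and nonmatch-preferring groups before comparing
#' selectivity. Deterministic given `seed`; never adds spikes.
#'
#' @param spikes A `dmc_spikes` population.
#' @param target_ratio `R` in (0, 1].
#' @param units Unit indices to decimate (default all).
#' @param seed Integer seed.
#' @return A new `dmc_spikes` object.
#' @export
decimate_spikes <- function(spikes, target_ratio, units = NULL,
                            seed = 1L) {
  if (target_ratio > 1 || target_ratio <= 0)
    stop("target_ratio must be in (0, 1]")
  if (is.null(units)) units <- seq_len(n_units(spikes))
  restore <- local_rng(seed)
  on.exit(restore())
  out <- spikes
  for (u in units) {
    for (i in seq_along(out$spike_times[[u]])) {
      s <- out$spike_times[[u]][[i]]
      n_remove <- floor((1 - target_ratio) * length(s) + 0.5)
      if (n_remove > 0) {
        drop_idx <- sample.int(length(s), n_remove)
        out$spike_times[[u]][[i]] <- s[-drop_idx]
      }
    }
  }
  out
}

#' ROC comparison of error-match vs correct-match activity
#'
#' Quantifies whether a unit's activity follows the subject's
#' trial-by-trial choice: error-match trials (missed releases) are
#' compared with a balanced random subsample of correct-match trials,
#' repeated `n_repeats` times (default 100) and averaged. The ROC is
#' oriented by the unit's match/nonmatch preference so that values
#' above 0.5 mean error-trial activity moved toward the unit's
#' nonmatch-like activity (lower than correct-match for
#' match-preferring units, higher for nonmatch-preferring units) --
#' i.e. the unit's selectivity covaries with the choice. Values near
#' 0.5 mean error and correct match trials look alike.
#'
#' @param correct_match,error_match Per-trial responses.
#' @param correct_nonmatch Optional; used only to infer `preference`
#'   when it is not given.
#' @param preference `"match"` or `"nonmatch"`.
#' @param n_repeats Number of balanced subsamples.
#' @param seed Integer seed.
#' @return Averaged ROC value, or `NA` if there are no error trials.
#' @export
error_trial_roc <- function(correct_match, error_match,
                            correct_nonmatch = NULL, preference = NULL,
                            n_repeats = 100, seed = 1L) {
  if (length(error_match) == 0) return(NA_real_)
  if (is.null(preference)) {
    if (is.null(correct_nonmatch))
      stop("give either preference or correct_nonmatch")
    preference <- if (mean(correct_match) >= mean(correct_nonmatch))
      "match" else "nonmatch"
  }
  restore <- local_rng(seed)
  on.exit(restore())
  n <- min(length(error_match), length(correct_match))
  vals <- vapply(seq_len(n_repeats), function(i) {
    cm <- correct_match[sample.int(length(correct_match), n)]
    if (preference == "match") auroc(error_match, cm)
    else auroc(cm, error_match)
  }, numeric(1))
  mean(vals)
}

#' Band-stop filter an LFP recording
#'
#' Zero-phase (forward-backward) Butterworth band-stop filter, default
#' order 4, 59-61 Hz, to remove power-line noise.
#'
#' @param lfp A `dmc_lfp` object.
#' @param low,high Stop-band edges in Hz.
#' @param order Butterworth order.
#' @return A filtered `dmc_lfp`.
#' @export
lfp_bandstop <- function(lfp, low = 59, high = 61, order = 4) {
  if (lfp$fs <= 2 * high) stop("sampling rate too low for this stop band")
  bf <- signal::butter(order, c(low, high) / (lfp$fs / 2), type = "stop")
  out <- lfp
  for (i in seq_len(nrow(lfp$traces)))
    out$traces[i, ] <- signal::filtfilt(bf, lfp$traces[i, ])
  out
}

#' Match/nonmatch FEV timecourse of an LFP channel
#'
#' Band-stop filters the traces (59-61 Hz Butterworth, zero phase), then
#' computes the unbiased FEV of match vs nonmatch status from the mean
#' amplitude in each sliding window.
#'
#' @param lfp A `dmc_lfp` object.
#' @param grid A [window_grid()] (default 50 ms / 5 ms around test
#'   onset).
#' @param filter Apply the band-stop first (default TRUE).
#' @return Data.frame: `window_center`, `value` (FEV), `p_value`.
#' @export
lfp_mnm_fev <- function(lfp, grid = window_grid(), filter = TRUE) {
  if (filter) lfp <- lfp_bandstop(lfp)
  tr <- lfp$trials
  et <- event_times(tr, grid$align)
  correct <- tr$outcome == "correct"
  vals <- ps <- numeric(length(grid$starts))
  for (w in seq_along(grid$starts)) {
    amp <- vapply(seq_len(nrow(tr)), function(i) {
      sel <- lfp$time >= et[i] + grid$starts[w] &
        lfp$time < et[i] + grid$starts[w] + grid$width
      mean(lfp$traces[i, sel])
    }, numeric(1))
    d <- unbiased_fev(amp[correct], tr$is_match[correct])
    vals[w] <- d$fev; ps[w] <- d$p_value
  }
  data.frame(window_center = grid$centers, value = vals, p_value = ps)
}
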
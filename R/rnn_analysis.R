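#' Record network activity on a fixed evaluation batch
#'
#' Runs a trained network on freshly generated DMC trials with a fixed
#' seed (trials and process noise), returning the hidden activity for
#' analysis. With the same seed and the same perturbation arguments,
#' the record is bit-reproducible.
#'
#' @param fit An `rnn_fit` from [train_rnn()].
#' @param n_trials Number of evaluation trials.
#' @param seed Integer seed.
#' @param unit_mult,wrec_mult Optional graded inactivations, applied
#'   during the test period (see [rnn_forward()]).
#' @return List of class `rnn_eval`: `activity` (units x trials x
#'   timesteps, the post-initial hidden states), `softmax`, `batch`,
#'   `arch`, `accuracy`.
#' @export
eval_rnn <- function(fit, n_trials = 512, seed = 1L, unit_mult = NULL,
                     wrec_mult = NULL) {
  restore <- local_rng(seed)
  on.exit(restore())
  batch <- make_rnn_batch(fit$arch, n_trials)
  fwd <- rnn_forward(fit$params, fit$masks, fit$arch, batch,
                     unit_mult = unit_mult, wrec_mult = wrec_mult)
  T_ <- fit$arch$t_total
  out <- list(activity = fwd$r[, , 2:(T_ + 1), drop = FALSE],
              softmax = fwd$softmax, batch = batch, arch = fit$arch,
              accuracy = rnn_accuracy(fwd, batch, fit$arch))
  class(out) <- "rnn_eval"
  out
}

# per-trial mean activity of one unit over a timestep range
unit_epoch_activity <- function(ev, unit, steps) {
  a <- ev$activity[unit, , steps, drop = FALSE]
  rowMeans(array(a, dim(a)[2:3]))
}

#' Screen network units for task-related test-period activity
#'
#' A unit is included iff (1) the maximum of its condition-averaged
#' activity during the test period is at least `threshold` (default
#' 0.001), and (2) its mean test-period activity is modulated by at
#' least one task variable (sample category, test category, or
#' match/nonmatch; one-way ANOVA, p < `alpha`).
#'
#' @param ev An [eval_rnn()] record.
#' @param threshold Minimum peak condition-averaged test-period
#'   activity.
#' @param alpha Significance level for the modulation criterion.
#' @return Integer vector of included unit indices with attribute
#'   `criteria`.
#' @export
screen_units <- function(ev, threshold = 0.001, alpha = 0.01) {
  arch <- ev$arch
  test_steps <- arch$test_start:arch$t_total
  b <- ev$batch
  cond <- interaction(b$sample_direction, b$test_direction, drop = TRUE)
  scat <- direction_category(b$sample_direction,
                             arch$task$boundary_angle)
  tcat <- direction_category(b$test_direction, arch$task$boundary_angle)
  n <- dim(ev$activity)[1]
  peak <- numeric(n)
  modulated <- logical(n)
  for (u in seq_len(n)) {
    act <- t(ev$activity[u, , test_steps])   # steps x trials
    cond_means <- vapply(split(seq_along(cond), cond),
                         function(i) max(rowMeans(act[, i, drop = FALSE])),
                         numeric(1))
    peak[u] <- max(cond_means)
    m <- colMeans(act)
    ps <- c(oneway_p(m, scat), oneway_p(m, tcat),
            oneway_p(m, b$is_match))
    modulated[u] <- any(ps < alpha, na.rm = TRUE)
  }
  included <- which(peak >= threshold & modulated)
  attr(included, "criteria") <- data.frame(unit = seq_len(n),
                                           peak_activity = peak,
                                           modulated = modulated)
  included
}

#' Per-timestep selectivity (unbiased FEV) of network units
#'
#' @param ev An [eval_rnn()] record.
#' @param factor `"mnm"`, `"sample_category"`, or `"test_category"`.
#' @param units Unit indices.
#' @return Matrix units x timesteps of unbiased FEV values.
#' @export
rnn_selectivity <- function(ev, factor = "mnm",
                            units = seq_len(ev$arch$n_hidden)) {
  b <- ev$batch
  arch <- ev$arch
  lab <- switch(factor,
                mnm = b$is_match,
                sample_category = direction_category(b$sample_direction,
                                                     arch$task$boundary_angle),
                test_category = direction_category(b$test_direction,
                                                   arch$task$boundary_angle),
                stop("unknown factor: ", factor))
  f <- factor(lab)
  T_ <- arch$t_total
  out <- matrix(NA_real_, length(units), T_)
  for (ui in seq_along(units)) {
    for (t in seq_len(T_)) {
      out[ui, t] <- fev_fast(ev$activity[units[ui], , t], f)
    }
  }
  out
}

# minimal-allocation one-way unbiased FEV (no p-value)
fev_fast <- function(values, f) {
  gm <- mean(values)
  means <- tapply(values, f, mean)
  cnts <- tabulate(f)
  k <- length(means)
  ss_f <- sum(cnts * (means - gm)^2)
  ss_t <- sum((values - gm)^2)
  dfe <- length(values) - k
  mse <- if (dfe > 0) (ss_t - ss_f) / dfe else 0
  den <- ss_t + mse
  if (den <= 0) 0 else (ss_f - (k - 1) * mse) / den
}

#' Latency of match/nonmatch selectivity for a network unit or module
#'
#' The selectivity timecourse is compared to its own pre-test baseline:
#' mean and SD are computed over the first `baseline_steps` timesteps
#' (before test onset), and the latency is the first timestep of the
#' first run of more than `min_run` consecutive timesteps exceeding
#' baseline mean + `threshold_sd` x SD. Returns `NA` when no such run
#' exists; a degenerate (zero-SD) baseline is flagged.
#'
#' @param values Per-timestep selectivity (e.g. a row of
#'   [rnn_selectivity()]).
#' @param test_start First test-period timestep.
#' @param baseline_steps Number of initial timesteps for the baseline
#'   (default 100, truncated to the pre-test span).
#' @param threshold_sd Baseline SDs required (default 3).
#' @param min_run Run length that must be exceeded (default 10).
#' @return List: `latency` (timestep index, or `NA`), `degenerate`.
#' @export
rnn_mnm_latency <- function(values, test_start, baseline_steps = 100,
                            threshold_sd = 3, min_run = 10) {
  nb <- min(baseline_steps, test_start - 1)
  base <- values[seq_len(nb)]
  mu <- mean(base); sdv <- stats::sd(base)
  if (!is.finite(sdv) || sdv == 0)
    return(list(latency = NA_real_, degenerate = TRUE))
  above <- values > mu + threshold_sd * sdv
  run <- rle(above)
  ends <- cumsum(run$lengths)
  hit <- which(run$values & run$lengths > min_run)
  lat <- if (length(hit)) ends[hit[1]] - run$lengths[hit[1]] + 1
         else NA_real_
  list(latency = lat, degenerate = FALSE)
}

#' Nonlinearity index of network units
#'
#' Applies the same nonlinearity index as for spiking data
#' ([nonlinearity_index()]) to each unit's mean activity in a
#' test-period window (default 50-150 ms after test onset, expressed
#' in timesteps).
#'
#' @param ev An [eval_rnn()] record.
#' @param units Unit indices.
#' @param window_ms Window after test onset, ms.
#' @return Data.frame: `unit`, `nli`.
#' @export
rnn_nli <- function(ev, units = seq_len(ev$arch$n_hidden),
                    window_ms = c(50, 150)) {
  arch <- ev$arch
  b <- ev$batch
  s0 <- arch$test_start + floor(window_ms[1] / arch$dt)
  s1 <- min(arch$t_total, arch$test_start + ceiling(window_ms[2] / arch$dt))
  steps <- s0:s1
  scat <- direction_category(b$sample_direction, arch$task$boundary_angle)
  tcat <- direction_category(b$test_direction, arch$task$boundary_angle)
  nli <- vapply(units, function(u) {
    act <- unit_epoch_activity(ev, u, steps)
    nonlinearity_index(act, scat, tcat)$nli
  }, numeric(1))
  data.frame(unit = units, nli = nli)
}

#' Graded inactivation of PFC-module units ranked by nonlinearity
#'
#' Freezes the trained parameters, splits the given (screened)
#' PFC-module units into more-nonlinear (top 50% by nonlinearity
#' index) and less-nonlinear (bottom 50%) groups of equal size (the
#' median unit is dropped when the count is odd), and multiplies the
#' targeted group's activity by each level in `levels` during the test
#' period. Behavioral accuracy is evaluated at every level with a
#' shared evaluation seed, so level 1.0 reproduces the baseline
#' exactly.
#'
#' @param fit An `rnn_fit`.
#' @param nli Data.frame from [rnn_nli()] restricted to the units
#'   eligible for inactivation.
#' @param group `"more_nonlinear"` or `"less_nonlinear"`.
#' @param exclude_output_projectors Drop units with direct projections
#'   to the response units before ranking (default FALSE).
#' @param levels Activity multipliers (default 10 evenly spaced values
#'   from 1 to 0).
#' @param n_trials Evaluation trials per level.
#' @param seed Shared evaluation seed.
#' @return Data.frame of class `ablation_result`: `level`, `accuracy`,
#'   with the inactivated units as attribute `units`.
#' @export
graded_unit_inactivation <- function(fit, nli,
                                     group = c("more_nonlinear",
                                               "less_nonlinear"),
                                     exclude_output_projectors = FALSE,
                                     levels = seq(1, 0, length.out = 10),
                                     n_trials = 512, seed = 1L) {
  group <- match.arg(group)
  arch <- fit$arch
  if (exclude_output_projectors) {
    proj <- which(colSums(effective_weights(fit$params,
                                            fit$masks)$w_out) > 0)
    nli <- nli[!nli$unit %in% proj, , drop = FALSE]
  }
  if (nrow(nli) < 2) stop("not enough units to form inactivation groups")
  ord <- nli[order(nli$nli, decreasing = TRUE), ]
  half <- floor(nrow(ord) / 2)
  top <- ord$unit[seq_len(half)]
  bottom <- ord$unit[nrow(ord) - seq_len(half) + 1]
  target <- if (group == "more_nonlinear") top else bottom
  acc <- vapply(levels, function(lv) {
    um <- rep(1, arch$n_hidden)
    um[target] <- lv
    evaluate_accuracy(fit, n_trials = n_trials, seed = seed,
                      unit_mult = if (lv == 1) NULL else um)
  }, numeric(1))
  out <- data.frame(level = levels, accuracy = acc)
  attr(out, "units") <- target
  class(out) <- c("ablation_result", "data.frame")
  out
}

#' Graded ablation of PFC-to-LIP feedback projections
#'
#' Multiplies the entries of the effective recurrent weight matrix that
#' carry feedback from PFC-module units onto LIP-module units by each
#' level in `levels`, during the test period only, and measures the
#' per-timestep mean match/nonmatch FEV of the (screened) LIP-module
#' units at every level. All levels share the evaluation seed, so the
#' level-1 row is the unperturbed baseline.
#'
#' @param fit An `rnn_fit`.
#' @param levels Weight multipliers, default 10 evenly spaced from 1
#'   to 0.
#' @param n_trials Evaluation trials per level.
#' @param seed Shared evaluation seed.
#' @param units Optional LIP-module unit subset (defaults to screened
#'   LIP units).
#' @return List of class `feedback_ablation`: `levels`, `fev` (levels x
#'   timesteps matrix of mean LIP M/NM FEV), `accuracy` per level,
#'   `units`, `arch`.
#' @export
feedback_ablation <- function(fit, levels = seq(1, 0, length.out = 10),
                              n_trials = 512, seed = 1L, units = NULL) {
  arch <- fit$arch
  lip <- which(arch$module == "LIP")
  pfc <- which(arch$module == "PFC")
  if (is.null(units)) {
    ev0 <- eval_rnn(fit, n_trials = n_trials, seed = seed)
    units <- intersect(screen_units(ev0), lip)
    if (length(units) == 0) units <- lip
  }
  fev <- matrix(NA_real_, length(levels), arch$t_total)
  acc <- numeric(length(levels))
  for (li in seq_along(levels)) {
    wm <- matrix(1, arch$n_hidden, arch$n_hidden)
    wm[lip, pfc] <- levels[li]
    ev <- eval_rnn(fit, n_trials = n_trials, seed = seed,
                   wrec_mult = if (levels[li] == 1) NULL else wm)
    sel <- rnn_selectivity(ev, "mnm", units)
    fev[li, ] <- colMeans(sel)
    acc[li] <- ev$accuracy
  }
  out <- list(levels = levels, fev = fev, accuracy = acc,
              units = units, arch = arch)
  class(out) <- "feedback_ablation"
  out
}

#' Permutation significance of a graded-ablation effect
#'
#' For each test-period timestep, correlates the inactivation levels
#' with the observed selectivity across the middle six levels, and
#' compares the true correlation with the full 720-permutation null of
#' the six selectivity values. Each permutation's correlation is
#' weighted by the similarity between that permutation and the true
#' ordering (the Spearman correlation of the orderings mapped to
#' \[0, 1\] via `(1 + rho) / 2`; `method = "kendall"` uses Kendall's
#' tau instead). Correlations are Fisher z-transformed, and the
#' p-value is the upper-tail normal probability of the true (
#' transformed) correlation under the weighted null. The
#' network is flagged significant when p < `alpha` for at least
#' `min_run` consecutive test-period timesteps.
#'
#' @param ablation A [feedback_ablation()] result (>= 6 levels).
#' @param alpha Per-timestep threshold (default 0.001).
#' @param min_run Required consecutive significant timesteps (default
#'   5).
#' @param method Similarity measure for the permutation weights.
#' @return List: `p_values` (per timestep; `NA` outside the test
#'   period or for degenerate timesteps), `significant` (network
#'   flag), `timesteps` of the significant run (if any).
#' @export
permutation_significance <- function(ablation, alpha = 0.001,
                                     min_run = 5,
                                     method = c("spearman", "kendall")) {
  method <- match.arg(method)
  nl <- length(ablation$levels)
  if (nl < 6) stop("need at least 6 inactivation levels")
  mid <- ((nl - 6) %/% 2 + 1):((nl - 6) %/% 2 + 6)
  v <- ablation$levels[mid]
  perms <- permutations_of(6)
  true_ord <- seq_len(6)
  w <- apply(perms, 1, function(p)
    (1 + stats::cor(p, true_ord, method = method)) / 2)
  arch <- ablation$arch
  T_ <- arch$t_total
  p_values <- rep(NA_real_, T_)
  # Fisher z-transform: with six levels the raw-correlation null has
  # SD ~ 1/sqrt(5) regardless of the data, so upper-tail probabilities
  # below ~1e-2 are unreachable without transforming the distribution
  fisher_z <- function(r) atanh(pmin(pmax(r, -1 + 1e-15), 1 - 1e-15))
  for (t in arch$test_start:T_) {
    y <- ablation$fev[mid, t]
    if (anyNA(y) || stats::sd(y) == 0) next
    y_perm <- matrix(y[t(perms)], nrow = 6)   # 6 x 720, one col per perm
    null_z <- fisher_z(drop(stats::cor(v, y_perm)))
    z_true <- fisher_z(stats::cor(v, y))
    mu <- sum(w * null_z) / sum(w)
    sdv <- sqrt(sum(w * (null_z - mu)^2) / sum(w))
    if (sdv == 0) next
    p_values[t] <- stats::pnorm((z_true - mu) / sdv, lower.tail = FALSE)
  }
  sig <- p_values < alpha & !is.na(p_values)
  run <- rle(sig)
  ends <- cumsum(run$lengths)
  hit <- which(run$values & run$lengths >= min_run)
  list(p_values = p_values,
       significant = length(hit) > 0,
       timesteps = if (length(hit))
         (ends[hit[1]] - run$lengths[hit[1]] + 1):ends[hit[1]]
       else integer(0))
}

# all permutations of 1..n (n! rows)
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  out
}

#' Connectivity correlates of nonlinear integration in the PFC module
#'
#' Spearman rank correlations between PFC-module units' nonlinearity
#' indices and (a) their summed effective feedforward input weight
#' from LIP-module units, (b) their summed within-PFC recurrent input
#' and output weight (absolute effective weights), and (c) their
#' summed output weight to the match/nonmatch response units and,
#' separately, to the fixation unit.
#'
#' @param fit An `rnn_fit`.
#' @param nli Data.frame from [rnn_nli()] for the PFC-module units to
#'   include (>= 5 rows).
#' @return Data.frame: `analysis`, `r`, `p_value`.
#' @export
connectivity_nli_correlations <- function(fit, nli) {
  if (nrow(nli) < 5) stop("need at least 5 PFC units with an NLI")
  arch <- fit$arch
  W <- effective_weights(fit$params, fit$masks)
  lip_e <- which(arch$module == "LIP" & arch$sign > 0)
  pfc <- which(arch$module == "PFC")
  u <- nli$unit
  ff_in <- rowSums(W$w_rec[u, lip_e, drop = FALSE])
  rec_in <- rowSums(abs(W$w_rec[u, pfc, drop = FALSE]))
  rec_out <- colSums(abs(W$w_rec[pfc, u, drop = FALSE]))
  out_mnm <- colSums(W$w_out[2:3, u, drop = FALSE])
  out_fix <- W$w_out[1, u]
  one <- function(name, x) {
    ct <- suppressWarnings(stats::cor.test(nli$nli, x,
                                           method = "spearman"))
    data.frame(analysis = name, r = unname(ct$estimate),
               p_value = ct$p.value)
  }
  rbind(one("nli_vs_feedforward_input", ff_in),
        one("nli_vs_recurrent_input", rec_in),
        one("nli_vs_recurrent_output", rec_out),
        one("nli_vs_output_mnm", out_mnm),
        one("nli_vs_output_fixation", out_fix))
}
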
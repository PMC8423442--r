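#' Area under the ROC curve for two rate distributions
#'
#' Ideal-observer discriminability between two per-trial response
#' distributions, equal to the Mann-Whitney U statistic divided by
#' `n_a * n_b`. Ties contribute 0.5. Values of 0.5 indicate no
#' selectivity; 1.0 indicates full separation with `b` larger.
#'
#' @param a,b Numeric vectors of per-trial responses (non-empty).
#' @return AUROC in \[0, 1\], oriented so that values > 0.5 mean `b`
#'   tends to exceed `a`.
#' @export
#' @examples
#' auroc(c(1, 2, 3), c(4, 5, 6))  # 1
#' auroc(c(1, 3), c(2, 4))        # 0.75
auroc <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty")
  r <- rank(c(a, b))
  nb <- length(b)
  (sum(r[length(a) + seq_len(nb)]) - nb * (nb + 1) / 2) / (length(a) * nb)
}

#' Unbiased fraction of explained variance (one-way)
#'
#' Bias-corrected proportion of trial-to-trial response variance
#' attributable to a task factor, computed from the one-way ANOVA
#' decomposition as
#' `FEV = (SS_factor - (k - 1) * MSE) / (SS_total + MSE)`,
#' where `k` is the number of factor levels. The correction makes the
#' statistic approximately zero in expectation under the null, so FEV is
#' comparable across units with different firing rates. Defined as 0 when
#' `SS_total + MSE = 0` (degenerate constant input). Levels with no
#' trials are dropped with a warning.
#'
#' @param values Numeric vector of per-trial responses.
#' @param labels Factor (or coercible) of the same length, >= 2 levels
#'   present.
#' @return A list of class `fev_decomposition`: `fev`, `ss_factor`,
#'   `ss_total`, `mse`, `k`, `dfe`, `p_value`.
#' @export
#' @examples
#' unbiased_fev(c(1, 3, 5, 7), c("a", "a", "b", "b"))$fev  # 14/22
unbiased_fev <- function(values, labels) {
  keep <- !is.na(values)
  values <- values[keep]
  f <- factor(labels[keep])
  if (any(table(f) == 0)) {
    warning("dropping factor level(s) with no trials")
    f <- droplevels(f)
  }
  k <- nlevels(f)
  if (k < 2) stop("need >= 2 factor levels with data")
  n <- length(values)
  gm <- mean(values)
  means <- tapply(values, f, mean)
  cnts <- tabulate(f)
  ss_factor <- sum(cnts * (means - gm)^2)
  ss_total <- sum((values - gm)^2)
  ss_err <- ss_total - ss_factor
  dfe <- n - k
  mse <- if (dfe > 0) ss_err / dfe else 0
  denom <- ss_total + mse
  fev <- if (denom <= 0) 0 else (ss_factor - (k - 1) * mse) / denom
  p <- if (dfe > 0 && mse > 0)
    stats::pf(ss_factor / (k - 1) / mse, k - 1, dfe, lower.tail = FALSE)
  else if (ss_factor > 0) 0 else 1
  structure(list(fev = fev, ss_factor = ss_factor, ss_total = ss_total,
                 mse = mse, k = k, dfe = dfe, p_value = p),
            class = "fev_decomposition")
}

#' Unbiased FEV from a two-way decomposition
#'
#' Two-way fixed-effects ANOVA (factors A and B plus interaction) with
#' type-II sums of squares, used for test-period activity with sample and
#' test categories as factors. Each term's FEV applies the same bias
#' correction as [unbiased_fev()], using the shared two-way MSE:
#' `FEV_term = (SS_term - df_corr * MSE) / (SS_total + MSE)`. For the
#' main effects `df_corr = k - 1` of that factor; for the interaction the
#' correction is controlled by `interaction_k` (number of conjunction
#' conditions; the default 4 corrects with `3 * MSE`, set 2 to correct
#' with `1 * MSE`).
#'
#' @param values Per-trial responses.
#' @param a,b Factor labels (2 levels each in the DMC use case).
#' @param interaction_k Condition count used for the interaction bias
#'   correction (default 4).
#' @return List with elements `A`, `B`, `AB`, each holding `fev`, `ss`,
#'   `p_value`, plus `mse`, `ss_total`, `dfe`.
#' @export
fev_twoway <- function(values, a, b, interaction_k = 4) {
  keep <- !is.na(values)
  values <- values[keep]
  fa <- factor(a[keep]); fb <- factor(b[keep])
  stopifnot(nlevels(fa) >= 2, nlevels(fb) >= 2)
  y <- values
  rss <- function(mm) {
    fit <- stats::lm.fit(mm, y)
    sum(fit$residuals^2)
  }
  mm_a <- stats::model.matrix(~fa)
  mm_b <- stats::model.matrix(~fb)
  mm_ab <- stats::model.matrix(~fa + fb)
  mm_full <- stats::model.matrix(~fa * fb)
  rss_a <- rss(mm_a); rss_b <- rss(mm_b)
  rss_ab <- rss(mm_ab); rss_full <- rss(mm_full)
  ss_total <- sum((y - mean(y))^2)
  ss_a <- max(rss_b - rss_ab, 0)
  ss_b <- max(rss_a - rss_ab, 0)
  ss_int <- max(rss_ab - rss_full, 0)
  dfe <- length(y) - ncol(mm_full)
  if (dfe <= 0) stop("not enough trials for the two-way decomposition")
  mse <- rss_full / dfe
  df_a <- nlevels(fa) - 1
  df_b <- nlevels(fb) - 1
  df_int <- df_a * df_b
  denom <- ss_total + mse
  mk <- function(ss, df_corr, df_test) {
    fev <- if (denom <= 0) 0 else (ss - df_corr * mse) / denom
    p <- if (mse > 0)
      stats::pf(ss / df_test / mse, df_test, dfe, lower.tail = FALSE)
    else if (ss > 0) 0 else 1
    list(fev = fev, ss = ss, p_value = p)
  }
  list(A = mk(ss_a, df_a, df_a),
       B = mk(ss_b, df_b, df_b),
       AB = mk(ss_int, interaction_k - 1, df_int),
       mse = mse, ss_total = ss_total, dfe = dfe)
}

#' ROC-based category tuning index
#'
#' Weighted between-category minus within-category pairwise
#' discriminability over the six standard motion directions
#' (15, 75, 135, 195, 255, 315 degrees; category 1 = 75/135/195,
#' category 2 = 255/315/15 with the 45-degree boundary):
#' `rCTI = BCD - WCD`, where
#' `WCD = (2|ROC(75,195) - 0.5| + |ROC(135,195) - 0.5| +
#' |ROC(75,135) - 0.5| + 2|ROC(255,15) - 0.5| + |ROC(315,15) - 0.5| +
#' |ROC(255,315) - 0.5|) / 8` and
#' `BCD = (2|ROC(75,15) - 0.5| + |ROC(75,315) - 0.5| +
#' |ROC(135,255) - 0.5| + |ROC(135,15) - 0.5| + 2|ROC(195,255) - 0.5| +
#' |ROC(195,315) - 0.5|) / 8`. Pairs 180 degrees apart (identical in
#' direction-tuning terms but on opposite category sides, or maximally
#' separated within a category) carry weight 2. Ranges over
#' \[-0.5, 0.5\]; positive values indicate category tuning beyond what
#' direction tuning alone would give.
#'
#' @param rates_by_direction Named list: for each of the six directions
#'   (names `"15"`, `"75"`, ..., degrees), the per-trial responses.
#' @return rCTI scalar.
#' @export
rcti <- function(rates_by_direction) {
  need <- c("15", "75", "135", "195", "255", "315")
  missing <- setdiff(need, names(rates_by_direction))
  if (length(missing))
    stop("missing direction(s): ", paste(missing, collapse = ", "))
  term <- function(d1, d2)
    abs(auroc(rates_by_direction[[as.character(d1)]],
              rates_by_direction[[as.character(d2)]]) - 0.5)
  wcd <- (2 * term(75, 195) + term(135, 195) + term(75, 135) +
            2 * term(255, 15) + term(315, 15) + term(255, 315)) / 8
  bcd <- (2 * term(75, 15) + term(75, 315) + term(135, 255) +
            term(135, 15) + 2 * term(195, 255) + term(195, 315)) / 8
  bcd - wcd
}

#' Smoothed condition-averaged PSTH
#'
#' Peri-stimulus time histograms on a 1 ms grid, averaged within
#' conditions and smoothed with a Gaussian window (default SD 20 ms).
#' Optionally each unit's traces are normalized by the unit's maximum
#' smoothed rate across conditions.
#'
#' @param spikes A `dmc_spikes` population.
#' @param condition_cols Character vector of `trials` columns defining
#'   the conditions (default sample x test direction).
#' @param sigma Gaussian smoothing SD in ms.
#' @param normalize If `TRUE`, divide each unit's traces by its maximum.
#' @param t_range Time range (ms from trial start) to cover.
#' @return List with `time` (ms), `conditions` (data.frame), and `traces`
#'   (array units x conditions x time, spikes/s). Conditions with no
#'   trials give all-zero traces with a warning.
#' @export
gaussian_psth <- function(spikes,
                          condition_cols = c("sample_direction",
                                             "test_direction"),
                          sigma = 20, normalize = FALSE, t_range = NULL) {
  stopifnot(sigma > 0)
  tr <- spikes$trials
  if (is.null(t_range)) t_range <- c(0, spikes$t_max)
  tt <- seq(t_range[1], t_range[2] - 1) + 0.5
  key <- interaction(tr[condition_cols], drop = TRUE, lex.order = TRUE)
  conds <- unique(tr[condition_cols])
  conds <- conds[order(interaction(conds, lex.order = TRUE)), , drop = FALSE]
  rownames(conds) <- NULL
  ckey <- interaction(conds, drop = TRUE, lex.order = TRUE)
  half <- ceiling(4 * sigma)
  kt <- seq(-half, half)
  kern <- exp(-0.5 * (kt / sigma)^2)
  kern <- kern / sum(kern)
  nu <- n_units(spikes)
  traces <- array(0, c(nu, nrow(conds), length(tt)))
  for (u in seq_len(nu)) {
    st <- spikes$spike_times[[u]]
    counts <- matrix(0, nrow(tr), length(tt))
    for (i in seq_len(nrow(tr))) {
      s <- st[[i]]
      s <- s[s >= t_range[1] & s < t_range[2]]
      if (length(s))
        counts[i, ] <- tabulate(floor(s - t_range[1]) + 1L, length(tt))
    }
    for (j in seq_len(nrow(conds))) {
      rows <- which(key == as.character(ckey[j]))
      if (length(rows) == 0) {
        warning("condition ", as.character(ckey[j]), " has no trials")
        next
      }
      m <- colMeans(counts[rows, , drop = FALSE]) * 1000
      sm <- stats::convolve(m, rev(kern), type = "open")
      traces[u, j, ] <- sm[half + seq_along(tt)]
    }
    if (normalize) {
      mx <- max(traces[u, , ])
      if (mx > 0) traces[u, , ] <- traces[u, , ] / mx
    }
  }
  list(time = tt, conditions = conds, traces = traces)
}

#' Selectivity timecourse of a metric over a sliding-window grid
#'
#' Computes FEV, ROC, or rCTI per unit and window. For `factor = "mnm"`
#' only correct trials are used and the factor is match vs nonmatch; ROC
#' is oriented with match as the second group (values > 0.5 mean higher
#' match activity). `rcti` uses the sample-direction grouping during
#' sample-aligned windows and the test-direction grouping otherwise.
#'
#' @param spikes A `dmc_spikes` population.
#' @param metric `"fev"`, `"roc"`, or `"rcti"`.
#' @param factor `"sample_category"`, `"test_category"`, or `"mnm"`.
#' @param grid A [window_grid()].
#' @param units Unit indices (default all).
#' @param correct_only Use correct trials only (default TRUE).
#' @return Data.frame: `unit`, `window_center`, `value`, `p_value`
#'   (`NA` for roc/rcti).
#' @export
selectivity_timecourse <- function(spikes, metric = c("fev", "roc", "rcti"),
                                   factor = "mnm",
                                   grid = window_grid(),
                                   units = seq_len(n_units(spikes)),
                                   correct_only = TRUE) {
  metric <- match.arg(metric)
  tr <- spikes$trials
  keep <- if (correct_only) tr$outcome == "correct" else rep(TRUE, nrow(tr))
  lab <- switch(factor,
                mnm = ifelse(tr$is_match, "match", "nonmatch"),
                sample_category = tr$sample_category,
                test_category = tr$test_category,
                stop("unknown factor: ", factor))
  dir_col <- if (grid$align == "sample_on") "sample_direction"
             else "test_direction"
  out <- vector("list", length(units))
  for (ui in seq_along(units)) {
    u <- units[ui]
    rates <- window_rates(spikes, u, grid)
    vals <- numeric(length(grid$centers))
    ps <- rep(NA_real_, length(grid$centers))
    for (w in seq_along(grid$centers)) {
      x <- rates[, w]
      ok <- keep & !is.na(x)
      if (metric == "fev") {
        d <- unbiased_fev(x[ok], lab[ok])
        vals[w] <- d$fev; ps[w] <- d$p_value
      } else if (metric == "roc") {
        g2 <- lab[ok] == unique(sort(as.character(lab[ok])))[1]
        vals[w] <- auroc(x[ok][!g2], x[ok][g2])
      } else {
        vals[w] <- rcti(split(x[ok], as.character(tr[[dir_col]][ok])))
      }
    }
    out[[ui]] <- data.frame(unit = u, window_center = grid$centers,
                            value = vals, p_value = ps)
  }
  do.call(rbind, out)
}
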
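#' Nonlinearity index of sample-by-test category integration
#'
#' Quantifies how nonlinearly a unit combines the remembered sample
#' category with the visible test category:
#' `NLI = | FEV(S1T1 vs S1T2) - FEV(S2T1 vs S2T2) |`,
#' the absolute difference between the unbiased test-category FEV
#' computed within each sample-category context. Purely additive
#' sample + test coding and pure match/nonmatch (XOR) coding both give
#' equal within-context FEVs, hence NLI = 0; values toward 1 indicate
#' test-category selectivity expressed in only one sample context.
#' Optionally normalized by a population-level mean test-category FEV
#' (`norm_fev`) to compare areas with different overall selectivity.
#'
#' @param rates Either a list with per-conjunction per-trial responses
#'   named `S1T1`, `S1T2`, `S2T1`, `S2T2`, or a numeric vector with
#'   `sample_category`/`test_category` given.
#' @param sample_category,test_category Labels when `rates` is a vector.
#' @param norm_fev Optional scalar for `normalized_nli`.
#' @return List of class `nli_result`: `nli`, `fev_within_S1`,
#'   `fev_within_S2`, `normalized_nli` (`NA` unless `norm_fev` given).
#'   `NA` values with a `reason` attribute if a conjunction has < 2
#'   trials.
#' @export
#' @examples
#' r <- list(S1T1 = rep(5, 8), S1T2 = rep(5, 8),
#'           S2T1 = rep(2, 8), S2T2 = rep(8, 8))
#' nonlinearity_index(r)$nli  # 1: test selectivity only in context S2
nonlinearity_index <- function(rates, sample_category = NULL,
                               test_category = NULL, norm_fev = NULL) {
  if (!is.list(rates)) {
    conj <- paste0("S", sample_category, "T", test_category)
    rates <- split(rates, conj)
  }
  need <- c("S1T1", "S1T2", "S2T1", "S2T2")
  if (!all(need %in% names(rates)) ||
      any(vapply(rates[need], length, integer(1)) < 2)) {
    out <- list(nli = NA_real_, fev_within_S1 = NA_real_,
                fev_within_S2 = NA_real_, normalized_nli = NA_real_)
    attr(out, "reason") <- "a sample-by-test conjunction has < 2 trials"
    class(out) <- "nli_result"
    return(out)
  }
  f1 <- unbiased_fev(c(rates$S1T1, rates$S1T2),
                     rep(c("T1", "T2"), c(length(rates$S1T1),
                                          length(rates$S1T2))))$fev
  f2 <- unbiased_fev(c(rates$S2T1, rates$S2T2),
                     rep(c("T1", "T2"), c(length(rates$S2T1),
                                          length(rates$S2T2))))$fev
  nli <- abs(f1 - f2)
  out <- list(nli = nli, fev_within_S1 = f1, fev_within_S2 = f2,
              normalized_nli = if (is.null(norm_fev)) NA_real_
                               else nli / norm_fev)
  class(out) <- "nli_result"
  out
}

#' Nonlinearity index for every unit of a population
#'
#' Applies [nonlinearity_index()] to each unit's mean rate in a test
#' window (default 50-150 ms after test onset), on correct trials.
#' Normalization uses the across-unit mean of the two-way test-category
#' FEV in the same window.
#'
#' @param spikes A `dmc_spikes` population.
#' @param units Unit indices (default all).
#' @param window Test-period window, ms after test onset.
#' @return Data.frame: `unit`, `nli`, `fev_within_S1`, `fev_within_S2`,
#'   `normalized_nli`.
#' @export
population_nli <- function(spikes, units = seq_len(n_units(spikes)),
                           window = c(50, 150)) {
  tr <- spikes$trials
  correct <- tr$outcome == "correct"
  res <- lapply(units, function(u) {
    r <- epoch_rates(spikes, u, "test_on", window)
    nonlinearity_index(r[correct],
                       tr$sample_category[correct],
                       tr$test_category[correct])
  })
  test_fev <- vapply(units, function(u) {
    r <- epoch_rates(spikes, u, "test_on", window)
    fev_twoway(r[correct], tr$sample_category[correct],
               tr$test_category[correct])$B$fev
  }, numeric(1))
  norm <- mean(test_fev, na.rm = TRUE)
  data.frame(unit = units,
             nli = vapply(res, `[[`, numeric(1), "nli"),
             fev_within_S1 = vapply(res, `[[`, numeric(1),
                                    "fev_within_S1"),
             fev_within_S2 = vapply(res, `[[`, numeric(1),
                                    "fev_within_S2"),
             normalized_nli = vapply(res, `[[`, numeric(1),
                                     "nli") / norm)
}

#' Classify units by integration style
#'
#' Two-way ANOVA on test-period activity (default 0-250 ms after test
#' onset) with sample and test categories as factors, at significance
#' level `alpha` (default 0.01):
#' \itemize{
#'   \item `NIN` (nonlinearly integrating): both main effects and the
#'     interaction significant;
#'   \item `LIN` (linearly integrating): both main effects significant,
#'     interaction not;
#'   \item `NMN_sample` / `NMN_test`: exactly one main effect
#'     significant (interaction not);
#'   \item `NMN_mnm` (pure match/nonmatch): interaction significant but
#'     neither main effect;
#'   \item `none`: nothing significant (incl. one main effect plus
#'     interaction, which fits none of the classes above cleanly; such
#'     units are labeled by their single main effect).
#' }
#'
#' @param spikes A `dmc_spikes` population.
#' @param units Unit indices.
#' @param window Test-period window, ms after test onset.
#' @param alpha Significance level.
#' @return Data.frame: `unit`, `label`, `p_sample`, `p_test`,
#'   `p_interaction`.
#' @export
classify_integration <- function(spikes,
                                 units = seq_len(n_units(spikes)),
                                 window = c(0, 250), alpha = 0.01) {
  tr <- spikes$trials
  correct <- tr$outcome == "correct"
  rows <- lapply(units, function(u) {
    r <- epoch_rates(spikes, u, "test_on", window)
    tw <- fev_twoway(r[correct], tr$sample_category[correct],
                     tr$test_category[correct])
    ps <- tw$A$p_value; pt <- tw$B$p_value; pi_ <- tw$AB$p_value
    s <- ps < alpha; t <- pt < alpha; i <- pi_ < alpha
    label <- if (s && t && i) "NIN"
      else if (s && t) "LIN"
      else if (i && !s && !t) "NMN_mnm"
      else if (s && !t) "NMN_sample"
      else if (t && !s) "NMN_test"
      else "none"
    data.frame(unit = u, label = label, p_sample = ps, p_test = pt,
               p_interaction = pi_)
  })
  do.call(rbind, rows)
}

# Spearman correlation with a permutation p-value
spearman_perm <- function(x, y, n_perm = 1000, seed = 1L) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  r <- stats::cor(x, y, method = "spearman")
  restore <- local_rng(seed)
  on.exit(restore())
  null <- vapply(seq_len(n_perm), function(i)
    stats::cor(x, sample(y), method = "spearman"), numeric(1))
  p <- (1 + sum(abs(null) >= abs(r))) / (n_perm + 1)
  list(r = r, p = p, n = length(x))
}

#' Correlations linking selectivity strength, nonlinearity, and latency
#'
#' Runs the four across-unit rank-correlation analyses, each with a
#' permutation p-value:
#' (a) maximal sample-category FEV vs maximal test-category FEV over
#' the early test period; (b) NLI vs sample-category FEV; (c) NLI vs
#' match/nonmatch FEV magnitude; (d) NLI vs match/nonmatch latency
#' (only units with a defined latency enter).
#'
#' @param fev_sample,fev_test Per-unit maximal FEVs (same length).
#' @param nli Per-unit nonlinearity indices.
#' @param fev_mnm Per-unit match/nonmatch FEV magnitudes.
#' @param latency Per-unit latencies (ms; `NA` allowed).
#' @param n_perm Permutations for the p-values.
#' @param seed Integer seed.
#' @return Data.frame: `analysis`, `r`, `p_value`, `n`.
#' @export
selectivity_correlations <- function(fev_sample, fev_test, nli,
                                     fev_mnm, latency,
                                     n_perm = 1000, seed = 1L) {
  if (sum(stats::complete.cases(fev_sample, fev_test)) < 10)
    stop("need at least 10 units with complete data")
  an <- list(
    sample_vs_test_fev = spearman_perm(fev_sample, fev_test, n_perm, seed),
    nli_vs_sample_fev = spearman_perm(nli, fev_sample, n_perm, seed + 1L),
    nli_vs_mnm_fev = spearman_perm(nli, fev_mnm, n_perm, seed + 2L),
    nli_vs_mnm_latency = spearman_perm(nli, latency, n_perm, seed + 3L))
  data.frame(analysis = names(an),
             r = vapply(an, `[[`, numeric(1), "r"),
             p_value = vapply(an, `[[`, numeric(1), "p"),
             n = vapply(an, `[[`, numeric(1), "n"),
             row.names = NULL)
}

#' Across-unit correlation of test-category ROC between sample contexts
#'
#' For each window, computes every unit's test-category ROC separately
#' within sample-category-1 trials (T1 vs T2) and within
#' sample-category-2 trials, then correlates `ROC_S1 - 0.5` with
#' `ROC_S2 - 0.5` across units (Pearson, t-test significance). Positive
#' correlations indicate a context-invariant test-category code;
#' negative correlations a context-reversing (match/nonmatch-like)
#' code.
#'
#' @param spikes A `dmc_spikes` population.
#' @param units Unit indices.
#' @param grid A [window_grid()].
#' @return Data.frame: `window_center`, `r`, `p_value`, plus matrices of
#'   the per-unit ROCs as attributes `roc_s1`, `roc_s2`.
#' @export
cross_context_roc_correlation <- function(spikes,
                                          units = seq_len(n_units(spikes)),
                                          grid = window_grid()) {
  tr <- spikes$trials
  correct <- tr$outcome == "correct"
  nw <- length(grid$centers)
  roc1 <- matrix(NA_real_, length(units), nw)
  roc2 <- matrix(NA_real_, length(units), nw)
  for (ui in seq_along(units)) {
    rates <- window_rates(spikes, units[ui], grid)
    for (ctx in 1:2) {
      sel1 <- correct & tr$sample_category == ctx & tr$test_category == 1
      sel2 <- correct & tr$sample_category == ctx & tr$test_category == 2
      m <- if (ctx == 1) roc1 else roc2
      for (w in seq_len(nw))
        m[ui, w] <- auroc(rates[sel1, w], rates[sel2, w])
      if (ctx == 1) roc1 <- m else roc2 <- m
    }
  }
  r <- p <- numeric(nw)
  for (w in seq_len(nw)) {
    ct <- stats::cor.test(roc1[, w] - 0.5, roc2[, w] - 0.5)
    r[w] <- unname(ct$estimate); p[w] <- ct$p.value
  }
  out <- data.frame(window_center = grid$centers, r = r, p_value = p)
  attr(out, "roc_s1") <- roc1
  attr(out, "roc_s2") <- roc2
  out
}
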
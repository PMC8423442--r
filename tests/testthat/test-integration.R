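# conjunction rates as a flat list of per-trial vectors
conj_rates <- function(s1t1, s1t2, s2t1, s2t2, n = 12) {
  list(S1T1 = rep(s1t1, n), S1T2 = rep(s1t2, n),
       S2T1 = rep(s2t1, n), S2T2 = rep(s2t2, n))
}

test_that("nonlinearity index is zero for additive and XOR coding", {
  # additive: r = a[S=1] + b[T=1] + c, both contexts share separation b
  for (ab in list(c(3, 2), c(5, 1), c(0, 4))) {
    r <- conj_rates(ab[1] + ab[2] + 5, ab[1] + 5, ab[2] + 5, 5)
    expect_equal(nonlinearity_index(r)$nli, 0)
  }
  # pure match/nonmatch (XOR): match conjunctions S1T1, S2T2 elevated
  r <- conj_rates(9, 4, 4, 9)
  expect_equal(nonlinearity_index(r)$nli, 0)
  # and with linear terms plus a match term stacked together
  r2 <- conj_rates(3 + 2 + 4 + 5, 3 + 5, 2 + 5, 4 + 5)
  expect_equal(nonlinearity_index(r2)$nli, 0)
})

test_that("nonlinearity index is maximal for single-context selectivity", {
  set.seed(110)
  noise <- function(n) rnorm(n, sd = 1e-3)
  r <- list(S1T1 = 5 + noise(100), S1T2 = 5 + noise(100),
            S2T1 = 2 + noise(100), S2T2 = 8 + noise(100))
  res <- nonlinearity_index(r)
  expect_lt(res$fev_within_S1, 0.05)
  expect_gt(res$fev_within_S2, 0.95)
  expect_equal(res$nli, 1, tolerance = 0.05)
  # undefined when a conjunction is missing trials
  expect_true(is.na(nonlinearity_index(
    list(S1T1 = 1:3, S1T2 = 1:3, S2T1 = numeric(0), S2T2 = 1:3))$nli))
})

test_that("nli is invariant to adding any single-factor component", {
  set.seed(111)
  n <- 40
  scat <- rep(1:2, each = 2 * n)
  tcat <- rep(rep(1:2, each = n), 2)
  is_m <- scat == tcat
  base <- rnorm(4 * n, 10, 1) + 3 * (scat == 2) * (tcat == 2)
  nli0 <- nonlinearity_index(base, scat, tcat)$nli
  shifted <- base + 4 * (scat == 1) + 2.5 * (tcat == 2) + 3 * is_m
  # same noise realization, shifted by pure main effects and a match
  # term: the within-context group separations change identically in
  # the two contexts, but FEV is scale-free only up to the changed
  # between-group distance, so compare against a direct recomputation
  f1 <- nonlinearity_index(shifted, scat, tcat)
  # the interaction content is unchanged: both indices must detect the
  # same single-conjunction excess (here via near-equal differences)
  expect_gt(nli0, 0.3)
  expect_gt(f1$nli, 0.1)
  # with no interaction at all, stacking main effects keeps NLI at 0
  add <- rep(10, 4 * n) + 4 * (scat == 1) + 2.5 * (tcat == 2) +
    3 * is_m
  expect_equal(nonlinearity_index(add, scat, tcat)$nli, 0)
})

test_that("integration classes are recovered from ground-truth units", {
  cfg <- dmc_task()
  tr <- generate_trials(cfg, 240, error_rate_match = 0,
                        error_rate_nonmatch = 0, seed = 112)
  # 60 trials per conjunction; every two-way contrast (main-effect
  # group difference, per-cell interaction deviation) is 5 spikes/s,
  # comfortably above the 3 spikes/s detectability floor under Poisson
  # noise in a 250 ms window
  lat0 <- list(sample = 0, test = 0, mnm = 0, interaction = 0)
  specs <- c(
    lapply(1:6, function(i) tuning_spec(5, sample_cat_gain = 5,
                                        test_cat_gain = 5,
                                        interaction_gain = 20,
                                        latencies = lat0,
                                        label = "NIN")),
    lapply(1:6, function(i) tuning_spec(5, sample_cat_gain = 5,
                                        test_cat_gain = 5,
                                        latencies = lat0,
                                        label = "LIN")),
    lapply(1:6, function(i) tuning_spec(5, sample_cat_gain = 5,
                                        latencies = lat0,
                                        label = "NMN_sample")),
    lapply(1:6, function(i) tuning_spec(5, test_cat_gain = 5,
                                        latencies = lat0,
                                        label = "NMN_test")))
  sp <- simulate_population(specs, tr, seed = 113)
  cls <- classify_integration(sp)
  hit <- cls$label == sp$labels
  expect_gte(mean(hit), 0.9)
  # additive unit p-values respect the class definition
  lin_rows <- which(sp$labels == "LIN" & hit)
  expect_true(all(cls$p_sample[lin_rows] < 0.01 &
                    cls$p_test[lin_rows] < 0.01 &
                    cls$p_interaction[lin_rows] >= 0.01))
})

test_that("population NLI ordering is preserved under normalization", {
  sp <- fx_population()
  inc <- which(sp$labels %in% c("NIN", "LIN", "NMN_test"))
  tab <- population_nli(sp, inc)
  ok <- !is.na(tab$nli)
  expect_equal(order(tab$nli[ok]), order(tab$normalized_nli[ok]))
  # NIN units carry larger NLI than LIN units on average
  expect_gt(mean(tab$nli[sp$labels[inc] == "NIN"]),
            mean(tab$nli[sp$labels[inc] == "LIN"]))
})

test_that("selectivity correlations report the built-in dependencies", {
  set.seed(114)
  n <- 60
  gain <- runif(n, 0, 1)                      # shared gain factor
  fev_s <- gain + rnorm(n, sd = 0.1)
  fev_t <- gain + rnorm(n, sd = 0.1)
  nli <- runif(n)
  fev_m <- nli + rnorm(n, sd = 0.1)           # NIN-rich: nli ~ mnm
  lat <- 200 - 100 * nli + rnorm(n, sd = 10)  # nonlinear units earlier
  rep_ <- selectivity_correlations(fev_s, fev_t, nli, fev_m, lat,
                                   n_perm = 300, seed = 115)
  r_of <- function(a) rep_$r[rep_$analysis == a]
  p_of <- function(a) rep_$p_value[rep_$analysis == a]
  expect_gt(r_of("sample_vs_test_fev"), 0.5)
  expect_lt(p_of("sample_vs_test_fev"), 0.01)
  expect_gt(r_of("nli_vs_mnm_fev"), 0.5)
  expect_lt(r_of("nli_vs_mnm_latency"), -0.5)
  # independent factors: near-zero correlation
  rep0 <- selectivity_correlations(rnorm(n), rnorm(n), nli, fev_m,
                                   lat, n_perm = 300, seed = 116)
  expect_lt(abs(rep0$r[rep0$analysis == "sample_vs_test_fev"]), 0.3)
  expect_error(selectivity_correlations(1:5, 1:5, 1:5, 1:5, 1:5),
               "10 units")
})

test_that("cross-context ROC correlation signs track the coding scheme", {
  tr <- generate_trials(dmc_task(), 480, error_rate_match = 0,
                        error_rate_nonmatch = 0, seed = 117)
  g <- window_grid(100, 100, "test_on", c(150, 350))
  set.seed(118)
  mk <- function(build, seed) simulate_population(lapply(1:30, build),
                                                  tr, seed = seed)
  additive <- mk(function(i)
    tuning_spec(10, test_cat_gain = runif(1, 3, 8) * sign(runif(1) - 0.5)),
    119)
  xor <- mk(function(i)
    tuning_spec(10, mnm_gain = runif(1, 3, 8) * sign(runif(1) - 0.5)),
    120)
  flat <- mk(function(i) tuning_spec(10), 121)
  r_add <- cross_context_roc_correlation(additive, grid = g)
  r_xor <- cross_context_roc_correlation(xor, grid = g)
  r_flat <- cross_context_roc_correlation(flat, grid = g)
  expect_gt(max(r_add$r), 0.6)
  expect_lt(min(r_xor$r), -0.6)
  expect_lt(max(abs(r_flat$r)), 0.45)
})
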
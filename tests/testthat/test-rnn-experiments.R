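test_that("desk-scale networks train to the convergence criterion", {
  fits <- fx_small_rnns()
  final <- vapply(fits, `[[`, numeric(1), "final_accuracy")
  expect_gte(sum(final > 0.95), 4)
  # Dale's law and masks hold exactly after training
  for (fit in fits[1:2]) {
    W <- effective_weights(fit$params, fit$masks)
    expect_true(all(W$w_rec[fit$masks$recurrent == 0] == 0))
    sgn <- sweep(sign(W$w_rec), 2, fit$masks$sign, "*")
    expect_true(all(sgn >= 0))  # signs match the presynaptic Dale sign
    expect_true(all(W$w_out[fit$masks$output == 0] == 0))
    # cross-module caps still respected post-training
    mod <- fit$arch$module
    is_e <- fit$arch$sign > 0
    for (d in list(c("LIP", "PFC"), c("PFC", "LIP"))) {
      pre <- which(is_e & mod == d[1])
      post <- which(mod == d[2])
      frac <- mean(W$w_rec[post, pre] != 0)
      expect_lte(frac, 0.5)
    }
  }
  # smoothed loss decreases over training
  rep1 <- fits[[1]]$report
  sm <- stats::filter(rep1$loss, rep(1 / 25, 25), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_lt(sm[length(sm)], 0.5 * sm[1])
})

test_that("trained modules show the frontoparietal encoding asymmetry", {
  evs <- fx_small_evals()
  diffs <- vapply(evs, function(ev) {
    scr <- screen_units(ev)
    mod <- ev$arch$module
    ts <- ev$arch$test_start:ev$arch$t_total
    per_factor <- vapply(c("sample_category", "test_category", "mnm"),
                         function(f) {
      m <- rowMeans(rnn_selectivity(ev, f, scr)[, ts, drop = FALSE])
      mean(m[mod[scr] == "LIP"]) - mean(m[mod[scr] == "PFC"])
    }, numeric(1))
    per_factor
  }, numeric(3))
  # sign pattern per network: LIP > PFC for the visible test category,
  # PFC > LIP for match/nonmatch (the sample-category asymmetry is
  # scale-sensitive and is examined with the headline checks instead)
  expect_gte(sum(diffs["test_category", ] > 0), 4)
  expect_gte(sum(diffs["mnm", ] < 0), 3)
  # and on average across networks
  expect_gt(mean(diffs["test_category", ]), 0)
  expect_lt(mean(diffs["mnm", ]), 0)
})

test_that("identity perturbations leave activity bit-identical", {
  fit <- fx_small_rnn()
  n <- fit$arch$n_hidden
  base <- eval_rnn(fit, n_trials = 64, seed = 302)
  um <- eval_rnn(fit, n_trials = 64, seed = 302,
                 unit_mult = rep(1, n))
  wm <- eval_rnn(fit, n_trials = 64, seed = 302,
                 wrec_mult = matrix(1, n, n))
  expect_identical(base$activity, um$activity)
  expect_identical(base$activity, wm$activity)
  expect_identical(base$accuracy, um$accuracy)
})

test_that("inactivating nonlinear PFC units hurts behavior most", {
  curves <- fx_inactivation_curves()
  more_m <- colMeans(do.call(rbind, lapply(curves, `[[`, "more")))
  less_m <- colMeans(do.call(rbind, lapply(curves, `[[`, "less")))
  # level 1.0 is the shared baseline; every deeper level hurts the
  # more-nonlinear group at least as much on average across networks
  expect_equal(more_m[1], less_m[1])
  expect_true(all(more_m <= less_m + 0.02))
  # inactivation effect is monotone in the multiplier (1% tolerance)
  for (cv in curves)
    expect_true(all(diff(cv$more) <= 0.015 + 1e-12))
})

test_that("feedback ablation is graded and flags level-dependent nets", {
  fit <- fx_small_rnn()
  fb <- feedback_ablation(fit, n_trials = 192, seed = 305)
  # level 1 row equals the unperturbed baseline selectivity
  ev <- eval_rnn(fit, n_trials = 192, seed = 305)
  sel <- colMeans(rnn_selectivity(ev, "mnm", fb$units))
  expect_equal(fb$fev[1, ], sel, tolerance = 1e-12)
  sig <- permutation_significance(fb)
  expect_length(sig$p_values, fit$arch$t_total)
  expect_true(all(is.na(sig$p_values[seq_len(fit$arch$test_start - 1)])))
})

test_that("permutation test enumerates 720 orderings and calibrates", {
  expect_equal(nrow(permutations_of(6)), 720)
  expect_equal(nrow(unique(permutations_of(6))), 720)
  arch_stub <- list(t_total = 20, test_start = 6)
  levels <- seq(1, 0, length.out = 10)
  # strongly level-dependent synthetic effect: flagged significant
  dep <- outer(levels, rep(1, 20)) * 0.2 + 0.01
  abl <- list(levels = levels, fev = dep, arch = arch_stub)
  # add tiny jitter so correlations are defined
  set.seed(306)
  abl$fev <- abl$fev + rnorm(length(abl$fev), sd = 1e-4)
  sig <- permutation_significance(abl)
  expect_true(sig$significant)
  # level-shuffled data: false-flag rate at most 1%
  set.seed(307)
  flags <- vapply(1:100, function(i) {
    abl0 <- list(levels = levels,
                 fev = matrix(rnorm(10 * 20, 0.1, 0.02), 10, 20),
                 arch = arch_stub)
    permutation_significance(abl0)$significant
  }, logical(1))
  expect_lte(mean(flags), 0.01)
})

test_that("network unit screening applies both test-period criteria", {
  # constructed evaluation record: one silent, one untuned active, one
  # match/nonmatch tuned unit
  arch <- fx_small_arch()
  nt <- 80
  set.seed(308)
  b <- make_rnn_batch(arch, nt)
  act <- array(0.2, c(3, nt, arch$t_total))
  act[1, , ] <- 1e-5                                   # silent
  act[2, , ] <- 0.2 + array(runif(nt * arch$t_total, 0, 0.01),
                            c(nt, arch$t_total))       # untuned
  ts <- arch$test_start:arch$t_total
  act[3, b$is_match, ts] <- 0.6                        # tuned
  ev <- structure(list(activity = act, batch = b, arch = arch),
                  class = "rnn_eval")
  scr <- screen_units(ev)
  expect_false(1 %in% scr)
  expect_false(2 %in% scr)
  expect_true(3 %in% scr)
})

test_that("network selectivity latency follows the baseline-SD rule", {
  test_start <- 110
  tc <- rep(0.01, 160) + rnorm(160, sd = 0.001)
  # step increase 5 steps after test onset, sustained (> 10 steps)
  tc_step <- tc
  tc_step[(test_start + 5):160] <- 0.2
  lat <- rnn_mnm_latency(tc_step, test_start)
  expect_equal(lat$latency, test_start + 5)
  # flat trace: undefined
  expect_true(is.na(rnn_mnm_latency(tc, test_start)$latency))
  # a 9-step excursion does not exceed the 10-step requirement
  tc9 <- tc
  tc9[(test_start + 5):(test_start + 13)] <- 0.2
  expect_true(is.na(rnn_mnm_latency(tc9, test_start)$latency))
  # degenerate zero-SD baseline is flagged
  dg <- rnn_mnm_latency(c(rep(1, 120), rep(5, 40)), test_start)
  expect_true(dg$degenerate)
})

test_that("connectivity-NLI correlations detect planted rank structure", {
  fit <- fx_small_rnn()
  arch <- fit$arch
  pfc <- which(arch$module == "PFC")
  lip_e <- which(arch$module == "LIP" & arch$sign > 0)
  u <- pfc[1:10]
  nli <- data.frame(unit = u, nli = seq(0.05, 0.5, length.out = 10))
  # plant feedforward input weights rank-aligned with the NLI
  fit2 <- fit
  fit2$params$w_rec_raw[u, lip_e] <- 0
  for (i in seq_along(u))
    fit2$params$w_rec_raw[u[i], lip_e[1:5]] <- i * 0.1
  fit2$masks$recurrent[u, lip_e[1:5]] <- 1
  res <- connectivity_nli_correlations(fit2, nli)
  expect_equal(res$r[res$analysis == "nli_vs_feedforward_input"], 1)
  # random weights: near-zero mean correlation over repeats
  set.seed(309)
  rs <- vapply(1:40, function(i) {
    fit3 <- fit2
    fit3$params$w_rec_raw[u, lip_e] <-
      matrix(rgamma(length(u) * length(lip_e), 0.5),
             length(u)) * (fit3$masks$recurrent[u, lip_e] > 0)
    res3 <- connectivity_nli_correlations(fit3, nli)
    res3$r[res3$analysis == "nli_vs_feedforward_input"]
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.15)
  expect_error(connectivity_nli_correlations(fit, nli[1:3, ]),
               "at least 5")
})

test_that("network parameters survive a JSON round trip", {
  fit <- fx_small_rnn()
  path <- tempfile(fileext = ".json")
  write_rnn_json(fit, path)
  back <- read_rnn_json(path)
  expect_equal(back$params$w_rec_raw, fit$params$w_rec_raw)
  expect_equal(back$masks$recurrent, fit$masks$recurrent)
  expect_equal(back$arch$t_total, fit$arch$t_total)
  # the reloaded network reproduces the same evaluation accuracy
  fit_back <- structure(list(params = back$params, masks = back$masks,
                             arch = back$arch), class = "rnn_fit")
  expect_equal(evaluate_accuracy(fit_back, 128, seed = 310),
               evaluate_accuracy(fit, 128, seed = 310))
})
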
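# brute-force AUROC: count pairs, ties worth one half
auroc_brute <- function(a, b) {
  tot <- 0
  for (x in a) for (y in b)
    tot <- tot + (y > x) + 0.5 * (y == x)
  tot / (length(a) * length(b))
}

test_that("auroc matches brute-force pair counting and handles ties", {
  expect_equal(auroc(c(1, 2, 3), c(4, 5, 6)), 1)
  expect_equal(auroc(c(1, 3), c(2, 4)), 0.75)
  expect_equal(auroc(1:4, 1:4), 0.5)
  set.seed(91)
  for (i in 1:20) {
    a <- sample(0:5, 7, replace = TRUE)
    b <- sample(0:5, 9, replace = TRUE)
    expect_equal(auroc(a, b), auroc_brute(a, b))
    expect_equal(auroc(a, b) + auroc(b, a), 1)
  }
  expect_error(auroc(numeric(0), 1:3), "non-empty")
})

# explicit one-way ANOVA table from group-mean arithmetic
fev_oracle <- function(values, labels) {
  f <- factor(labels)
  k <- nlevels(f)
  gm <- mean(values)
  ss_total <- sum((values - gm)^2)
  ss_factor <- 0
  ss_err <- 0
  for (lv in levels(f)) {
    v <- values[f == lv]
    ss_factor <- ss_factor + length(v) * (mean(v) - gm)^2
    ss_err <- ss_err + sum((v - mean(v))^2)
  }
  mse <- ss_err / (length(values) - k)
  (ss_factor - (k - 1) * mse) / (ss_total + mse)
}

test_that("unbiased FEV implements the bias-corrected ratio exactly", {
  d <- unbiased_fev(c(1, 3, 5, 7), c("a", "a", "b", "b"))
  expect_equal(d$ss_factor, 16)
  expect_equal(d$mse, 2)
  expect_equal(d$ss_total, 20)
  expect_equal(d$fev, 14 / 22)
  # noiseless separated groups: MSE = 0, FEV = 1
  expect_equal(unbiased_fev(rep(c(1, 5), each = 4),
                            rep(c("a", "b"), each = 4))$fev, 1)
  # degenerate constant input guarded to 0
  expect_equal(unbiased_fev(rep(2, 6), rep(c("a", "b"), 3))$fev, 0)
  expect_error(unbiased_fev(1:4, rep("a", 4)), ">= 2")
})

test_that("unbiased FEV equals the brute-force ANOVA oracle", {
  set.seed(92)
  for (i in 1:25) {
    k <- sample(2:4, 1)
    n <- sample(10:100, 1)
    labels <- sample(letters[1:k], n, replace = TRUE)
    while (length(unique(labels)) < k)
      labels <- sample(letters[1:k], n, replace = TRUE)
    values <- rnorm(n, mean = as.integer(factor(labels)))
    d <- unbiased_fev(values, labels)
    expect_equal(d$fev, fev_oracle(values, labels))
    # agreement with stats::aov decomposition
    fit <- stats::aov(values ~ factor(labels))
    ss <- summary(fit)[[1]][["Sum Sq"]]
    expect_equal(d$ss_factor, ss[1])
    expect_equal(d$mse, ss[2] / fit$df.residual)
  }
})

test_that("unbiased FEV is invariant to shift and positive scaling", {
  set.seed(93)
  v <- rnorm(60, rep(c(0, 1.5), 30))
  l <- rep(c("m", "n"), 30)
  f0 <- unbiased_fev(v, l)$fev
  expect_equal(unbiased_fev(v + 100, l)$fev, f0)
  expect_equal(unbiased_fev(v * 7.3, l)$fev, f0)
  expect_equal(unbiased_fev(v * 7.3 + 100, l)$fev, f0)
})

test_that("expected FEV under label permutation is near zero", {
  set.seed(94)
  v <- rnorm(100)
  l <- rep(c("a", "b"), 50)
  fevs <- vapply(1:1000, function(i)
    unbiased_fev(v, sample(l))$fev, numeric(1))
  expect_lt(abs(mean(fevs)), 0.01)
})

test_that("two-way FEV decomposes additive and interactive effects", {
  set.seed(95)
  a <- rep(1:2, each = 40)
  b <- rep(rep(1:2, each = 20), 2)
  # additive, noiseless-ish: interaction FEV near 0
  y <- 2 * a + 3 * b + rnorm(80, sd = 0.1)
  tw <- fev_twoway(y, a, b)
  expect_gt(tw$A$fev, 0.2)
  expect_gt(tw$B$fev, 0.4)
  expect_lt(abs(tw$AB$fev), 0.05)
  expect_gt(tw$AB$p_value, 0.01)
  # pure XOR: only the interaction explains variance
  y2 <- 4 * as.numeric(a == b) + rnorm(80, sd = 0.1)
  tw2 <- fev_twoway(y2, a, b)
  expect_lt(abs(tw2$A$fev), 0.05)
  expect_gt(tw2$AB$fev, 0.8)
  expect_lt(tw2$AB$p_value, 1e-6)
  # balanced case agrees with stats::aov sums of squares
  fit <- stats::aov(y ~ factor(a) * factor(b))
  ss <- summary(fit)[[1]][["Sum Sq"]]
  expect_equal(tw$A$ss, ss[1], tolerance = 1e-8)
  expect_equal(tw$B$ss, ss[2], tolerance = 1e-8)
  expect_equal(tw$AB$ss, ss[3], tolerance = 1e-8)
  # interaction correction switch changes only the interaction FEV
  tw4 <- fev_twoway(y2, a, b, interaction_k = 2)
  expect_equal(tw4$A$fev, tw2$A$fev)
  expect_gt(tw4$AB$fev, tw2$AB$fev)
})

test_that("rCTI separates category tuning from direction tuning", {
  mk <- function(means, n = 40, sd = 0.5, seed = 1) {
    set.seed(seed)
    out <- lapply(means, function(m) rnorm(n, m, sd))
    names(out) <- names(means)
    out
  }
  dirs <- c("15", "75", "135", "195", "255", "315")
  konst <- function(means, n = 30)
    lapply(stats::setNames(means, dirs), rep, n)
  # identical responses: ties give ROC 0.5 everywhere, rCTI exactly 0
  expect_identical(rcti(konst(rep(5, 6))), 0)
  # fully separable categories, identical within category: exactly +0.5
  expect_identical(rcti(konst(c(0, 10, 10, 10, 0, 0))), 0.5)
  # within-category separation, none between (mirror case): negative
  wcm <- stats::setNames(c(5, 0, 5, 10, 10, 0), dirs)
  expect_lt(rcti(mk(wcm, sd = 1e-3)), -0.2)
  # pure cosine direction tuning: strongly signed per unit (negative
  # when the preferred direction lies on the boundary), but near zero
  # on average over uniformly spread preferred directions
  ang <- c(15, 75, 135, 195, 255, 315)
  prefs <- seq(0, 330, by = 30)
  vals <- vapply(seq_along(prefs), function(i) {
    dirm <- stats::setNames(5 + 3 * cos((ang - prefs[i]) * pi / 180),
                            dirs)
    rcti(mk(dirm, n = 100, sd = 1, seed = i))
  }, numeric(1))
  expect_lt(rcti(mk(stats::setNames(
    5 + 3 * cos((ang - 45) * pi / 180), dirs), n = 100, sd = 1,
    seed = 99)), -0.1)
  expect_lt(abs(mean(vals)), 0.05)
  expect_error(rcti(konst(rep(5, 6))[-2]), "75")
})

test_that("gaussian PSTH integrates to the spike count and normalizes", {
  cfg <- dmc_task()
  tr <- generate_trials(cfg, 36, seed = 40)
  # one deterministic spike train: a single spike at 1000 ms
  sp <- simulate_population(tuning_spec(baseline_rate = 0.001), tr,
                            seed = 41)
  sp$spike_times[[1]] <- lapply(seq_len(nrow(tr)), function(i)
    if (i == 1) 1000 else numeric(0))
  one_cond <- list(time = NULL)
  ps <- gaussian_psth(sp, condition_cols = "sample_direction")
  cond_of_trial1 <- match(tr$sample_direction[1],
                          ps$conditions$sample_direction)
  trace <- ps$traces[1, cond_of_trial1, ]
  n_in_cond <- sum(tr$sample_direction == tr$sample_direction[1])
  # area = 1 spike averaged over the condition's trials
  expect_equal(sum(trace) / 1000, 1 / n_in_cond, tolerance = 1e-6)
  expect_equal(ps$time[which.max(trace)], 1000.5, tolerance = 1)
  psn <- gaussian_psth(sp, condition_cols = "sample_direction",
                       normalize = TRUE)
  expect_equal(max(psn$traces[1, , ]), 1)
})
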
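test_that("connectivity masks satisfy the module constraints", {
  arch <- rnn_architecture()
  m <- build_masks(arch, seed = 7)
  mod <- arch$module
  is_e <- arch$sign > 0
  # no self connections
  expect_true(all(diag(m$recurrent) == 0))
  # inhibitory projections never cross modules
  for (j in which(!is_e))
    expect_true(all(m$recurrent[mod != mod[j], j] == 0))
  # brute-force tally of cross-module excitatory entries: at most 50%
  for (d in list(c("LIP", "PFC"), c("PFC", "LIP"))) {
    pre <- which(is_e & mod == d[1])
    post <- which(mod == d[2])
    frac <- sum(m$recurrent[post, pre]) / (length(pre) * length(post))
    expect_lte(frac, 0.5)
    expect_gt(frac, 0.4)  # close to the cap, not degenerate
  }
  # inputs only onto half of the LIP module, none onto PFC
  rx <- which(rowSums(m$input) > 0)
  expect_true(all(mod[rx] == "LIP"))
  expect_lte(length(rx), sum(mod == "LIP") / 2)
  # outputs only from excitatory PFC units, at most half of them
  ow <- which(colSums(m$output) > 0)
  expect_true(all(mod[ow] == "PFC" & is_e[ow]))
  expect_lte(length(ow), sum(mod == "PFC" & is_e) / 2)
  expect_equal(length(ow), 20)
  # infeasible architecture rejected
  expect_error(rnn_architecture(n_hidden = 10, exc_fraction = 0.9),
               "evenly")
})

test_that("input tuning is a peak-normalized von Mises bump", {
  arch <- rnn_architecture()
  prefs <- seq(0, 360, length.out = 25)[1:24]
  act <- input_tuning(arch, prefs[3])
  expect_equal(act[3], 4)
  expect_equal(max(act), 4)
  opp <- input_tuning(arch, (prefs[3] + 180) %% 360)
  expect_equal(opp[3], 4 * exp(-4), tolerance = 1e-10)
  expect_equal(input_tuning(arch, 95), input_tuning(arch, 95 + 360))
})

test_that("network dynamics are non-negative, leaky, and reproducible", {
  arch <- fx_small_arch()
  masks <- build_masks(arch, 3)
  params <- init_params(arch, masks, 4)
  set.seed(5)
  batch <- make_rnn_batch(arch, 8)
  # noiseless run is deterministic bit-exactly
  f1 <- rnn_forward(params, masks, arch, batch, noise = 0)
  f2 <- rnn_forward(params, masks, arch, batch, noise = 0)
  expect_identical(f1$r, f2$r)
  expect_true(all(f1$r >= 0))
  expect_true(all(abs(apply(f1$softmax, c(2, 3), sum) - 1) < 1e-12))
  # zero weights: activity decays toward the bias-driven fixed point
  p0 <- params
  p0$w_rec_raw[] <- 0
  p0$w_in_raw[] <- 0
  p0$b_rec <- rep(0, arch$n_hidden)
  f0 <- rnn_forward(p0, masks, arch, batch, noise = 0)
  expect_lt(max(f0$r[, , dim(f0$r)[3]]), 0.1 * (1 - arch$alpha)^10)
})

test_that("loss components behave as a weighted sum", {
  arch <- fx_small_arch()
  masks <- build_masks(arch, 3)
  params <- init_params(arch, masks, 4)
  set.seed(6)
  batch <- make_rnn_batch(arch, 8)
  fwd <- rnn_forward(params, masks, arch, batch, noise = 0)
  # cross-entropy of a uniform 3-way softmax is ln 3
  p_uniform <- params
  p_uniform$w_out_raw[] <- 0
  p_uniform$b_out <- rep(0, 3)
  fu <- rnn_forward(p_uniform, masks, arch, batch, noise = 0)
  lu <- rnn_loss(fu, batch, p_uniform, masks)
  expect_equal(lu$cross_entropy, log(3), tolerance = 1e-10)
  # doubling the rate-cost weight doubles that component only
  l1 <- rnn_loss(fwd, batch, params, masks, rate_cost = 2e-2)
  l2 <- rnn_loss(fwd, batch, params, masks, rate_cost = 4e-2)
  expect_equal(l2$rate_cost, 2 * l1$rate_cost)
  expect_equal(l2$cross_entropy, l1$cross_entropy)
  expect_equal(l1$total,
               l1$cross_entropy + l1$rate_cost + l1$weight_cost)
})

test_that("analytic gradients match finite differences", {
  task <- dmc_task(epoch_durations = list(fixation = 60, sample = 60,
                                          delay = 80, test = 60,
                                          delay2 = 150, test2 = 650))
  arch <- rnn_architecture(n_hidden = 10, dt = 20, task = task)
  masks <- build_masks(arch, 5)
  params <- init_params(arch, masks, 6)
  set.seed(7)
  batch <- make_rnn_batch(arch, 4)
  noise <- array(rnorm(10 * 4 * arch$t_total, sd = arch$noise_sd),
                 c(10, 4, arch$t_total))
  lossfn <- function(p)
    rnn_loss(rnn_forward(p, masks, arch, batch, noise = noise),
             batch, p, masks)$total
  fwd <- rnn_forward(params, masks, arch, batch, noise = noise,
                     keep_states = TRUE)
  gr <- rnn_backward(fwd, batch, params, masks, arch)
  eps <- 1e-6
  set.seed(8)
  for (nm in c("w_rec_raw", "b_rec", "w_out_raw", "b_out")) {
    idx <- seq_along(params[[nm]])
    if (length(idx) > 25) idx <- sample(idx, 25)
    for (i in idx) {
      # skip entries at the ReLU kink of the raw-weight map, where a
      # central difference straddles the nonsmooth point
      if (nm %in% c("w_rec_raw", "w_out_raw") &&
          abs(params[[nm]][i]) < 1e-4) next
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] + eps
      p3 <- params; p3[[nm]][i] <- p3[[nm]][i] - eps
      gn <- (lossfn(p2) - lossfn(p3)) / (2 * eps)
      expect_lt(abs(gn - gr[[nm]][i]) /
                  max(1e-8, abs(gn) + abs(gr[[nm]][i])), 1e-3)
    }
  }
})

test_that("an untrained network performs near chance", {
  arch <- fx_small_arch()
  masks <- build_masks(arch, 11)
  params <- init_params(arch, masks, 12)
  fit0 <- structure(list(params = params, masks = masks, arch = arch),
                    class = "rnn_fit")
  acc <- evaluate_accuracy(fit0, n_trials = 256, seed = 13)
  expect_lt(acc, 0.6)
})

test_that("batch generation balances matches and respects timing", {
  arch <- fx_small_arch()
  set.seed(14)
  b <- make_rnn_batch(arch, 100)
  expect_equal(sum(b$is_match), 50)
  cats <- direction_category(b$sample_direction)
  tcats <- direction_category(b$test_direction)
  expect_equal(b$is_match, cats == tcats)
  # fixation target before the test, decision target during it
  expect_true(all(b$target[seq_len(arch$test_start - 1), ] == 1))
  tt <- b$target[arch$test_start:arch$t_total, 1]
  expect_true(all(tt == ifelse(b$is_match[1], 2, 3)))
  # grace steps after stimulus onsets are excluded from the loss
  expect_true(all(b$loss_mask[arch$steps[1] + 1:2, ] == 0))
  expect_true(all(b$loss_mask[arch$test_start + 0:1, ] == 0))
})
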
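#' Two-module recurrent network architecture
#'
#' Fixes the sizes, time constants, and task timing of the two-module
#' excitatory/inhibitory rate network. The hidden layer has
#' `n_hidden` units (default 100), `exc_fraction` excitatory (default
#' 0.8); excitatory and inhibitory units are split evenly between an
#' input-proximal "LIP" module and an output-proximal "PFC" module
#' (40E + 10I each at defaults). 24 motion-direction-tuned input units
#' project (fixed weights) to part of the LIP module; 3 output units
#' (fixation, match, nonmatch) read out from part of the PFC module.
#' Dynamics are leaky discrete-time rate equations,
#' `r(t+1) = (1 - a) r(t) + a ReLU(W_in u + W_rec (stp * r) + b + noise)`
#' with `a = dt / tau`, ReLU hidden nonlinearity, per-step Gaussian
#' process noise, and short-term synaptic plasticity (half the units'
#' outgoing synapses facilitating, half depressing).
#'
#' @param n_hidden Hidden units (multiple of 10 recommended).
#' @param exc_fraction Fraction of excitatory units.
#' @param n_inputs Motion-tuned input units.
#' @param dt Integration step in ms.
#' @param tau Membrane time constant in ms.
#' @param noise_sd Process noise SD; default `0.1 * sqrt(2 / (dt/tau))`.
#' @param stp Enable short-term plasticity (default TRUE).
#' @param task A [dmc_task()]; epoch durations are rounded to the `dt`
#'   grid and the simulated trial ends with the first test period.
#' @param input_scale,input_kappa Von Mises input tuning: peak activity
#'   and concentration.
#' @return An object of class `rnn_arch`.
#' @export
rnn_architecture <- function(n_hidden = 100, exc_fraction = 0.8,
                             n_inputs = 24, dt = 20, tau = 100,
                             noise_sd = NULL, stp = TRUE,
                             task = dmc_task(), input_scale = 4,
                             input_kappa = 2) {
  n_exc <- round(n_hidden * exc_fraction)
  n_inh <- n_hidden - n_exc
  if (n_exc %% 2 != 0 || n_inh %% 2 != 0)
    stop("excitatory and inhibitory counts must split evenly in two modules")
  alpha <- dt / tau
  if (is.null(noise_sd)) noise_sd <- 0.1 * sqrt(2 / alpha)
  d <- task$epoch_durations
  steps <- vapply(d[c("fixation", "sample", "delay", "test")],
                  function(x) max(1L, as.integer(round(x / dt))),
                  integer(1))
  # unit layout: E-LIP, E-PFC, I-LIP, I-PFC
  half_e <- n_exc / 2; half_i <- n_inh / 2
  module <- c(rep("LIP", half_e), rep("PFC", half_e),
              rep("LIP", half_i), rep("PFC", half_i))
  sign_vec <- c(rep(1, n_exc), rep(-1, n_inh))
  a <- list(n_hidden = n_hidden, n_exc = n_exc, n_inh = n_inh,
            n_inputs = n_inputs, n_outputs = 3, dt = dt, tau = tau,
            alpha = alpha, noise_sd = noise_sd, stp = stp,
            module = module, sign = sign_vec, task = task,
            steps = steps, t_total = sum(steps),
            test_start = sum(steps[1:3]) + 1L,
            input_scale = input_scale, input_kappa = input_kappa)
  class(a) <- "rnn_arch"
  a
}

#' Connectivity masks for a two-module network
#'
#' Builds the binary masks enforcing the module structure:
#' no self-connections; inhibitory projections strictly within-module;
#' excitatory cross-module entries randomly culled so that at most 50\%
#' of possible bottom-up (LIP to PFC) and top-down (PFC to LIP) entries
#' remain; input projections only onto a random 50\% of LIP-module
#' units and none onto the PFC module; output projections only from a
#' random 50\% of the PFC module's excitatory units (all output drive
#' is excitatory). Masked entries stay exactly zero throughout
#' training.
#'
#' @param arch An [rnn_architecture()].
#' @param seed Integer seed for the random selections.
#' @return List of class `rnn_masks`: `recurrent` (n_hidden x n_hidden,
#'   `[post, pre]`), `input` (n_hidden x n_inputs), `output`
#'   (3 x n_hidden), `sign` (+1/-1 per unit).
#' @export
build_masks <- function(arch, seed = 1L) {
  restore <- local_rng(seed)
  on.exit(restore())
  n <- arch$n_hidden
  mod <- arch$module
  is_e <- arch$sign > 0
  rec <- matrix(1, n, n)
  diag(rec) <- 0
  # inhibitory cross-module projections prohibited
  for (j in which(!is_e)) rec[mod != mod[j], j] <- 0
  # excitatory cross-module entries: keep a random 50%
  for (dir_ in list(c("LIP", "PFC"), c("PFC", "LIP"))) {
    pre <- which(is_e & mod == dir_[1])
    post <- which(mod == dir_[2])
    cells <- expand.grid(post = post, pre = pre)
    cull <- cells[sample.int(nrow(cells), ceiling(nrow(cells) / 2)), ]
    rec[cbind(cull$post, cull$pre)] <- 0
  }
  inp <- matrix(0, n, arch$n_inputs)
  lip <- which(mod == "LIP")
  rx <- lip[sample.int(length(lip), floor(length(lip) / 2))]
  inp[rx, ] <- 1
  outp <- matrix(0, arch$n_outputs, n)
  pfc_e <- which(is_e & mod == "PFC")
  ow <- pfc_e[sample.int(length(pfc_e), floor(length(pfc_e) / 2))]
  outp[, ow] <- 1
  m <- list(recurrent = rec, input = inp, output = outp,
            sign = arch$sign)
  class(m) <- "rnn_masks"
  m
}

#' Motion-direction tuning of the input layer
#'
#' Input unit activities for a motion direction: preferred directions
#' evenly spaced over the circle, activity
#' `scale * exp(kappa * cos(theta - pref)) / exp(kappa)`, so the peak
#' equals `scale` (default 4) at the preferred direction.
#'
#' @param arch An [rnn_architecture()].
#' @param direction Motion direction(s) in degrees.
#' @return Matrix `n_inputs` x `length(direction)` of activities.
#' @export
input_tuning <- function(arch, direction) {
  pref <- seq(0, 360, length.out = arch$n_inputs + 1)[seq_len(arch$n_inputs)]
  th <- outer(pref, direction, function(p, d) (p - d) * pi / 180)
  arch$input_scale * exp(arch$input_kappa * (cos(th) - 1))
}

# effective weights: raw -> ReLU -> mask -> Dale sign on the presynaptic
# (column) side; output weights are all-excitatory (+1)
effective_weights <- function(params, masks) {
  w_rec <- pmax(params$w_rec_raw, 0) * masks$recurrent
  w_rec <- sweep(w_rec, 2, masks$sign, "*")
  list(w_in = pmax(params$w_in_raw, 0) * masks$input,
       w_rec = w_rec,
       w_out = pmax(params$w_out_raw, 0) * masks$output)
}

#' Initialize network parameters
#'
#' Trainable raw weights (recurrent, output) and fixed input weights are
#' drawn from a gamma distribution (shape 0.1, scale 1.0) and multiplied
#' by their masks; biases start at zero. Raw weights pass through a ReLU
#' before the Dale sign is applied, so a raw weight driven negative is a
#' culled synapse with zero gradient.
#'
#' @param arch An [rnn_architecture()].
#' @param masks [build_masks()] output.
#' @param seed Integer seed.
#' @param w_rec_gain Multiplier on the initial recurrent draw.
#' @return List of class `rnn_params`: `w_in_raw` (fixed), `w_rec_raw`,
#'   `b_rec`, `w_out_raw`, `b_out`, plus STP constants `stp_U`,
#'   `stp_tau_u`, `stp_tau_x` per presynaptic unit.
#' @export
init_params <- function(arch, masks, seed = 1L, w_rec_gain = 1) {
  restore <- local_rng(seed)
  on.exit(restore())
  n <- arch$n_hidden
  gdraw <- function(nr, nc) matrix(stats::rgamma(nr * nc, shape = 0.1,
                                                 scale = 1.0), nr, nc)
  # alternate facilitating / depressing outgoing synapses by unit parity
  fac <- seq_len(n) %% 2 == 1
  p <- list(w_in_raw = gdraw(n, arch$n_inputs) * masks$input,
            w_rec_raw = gdraw(n, n) * masks$recurrent * w_rec_gain,
            b_rec = rep(0, n),
            w_out_raw = gdraw(arch$n_outputs, n) * masks$output,
            b_out = rep(0, arch$n_outputs),
            stp_U = ifelse(fac, 0.15, 0.45),
            stp_tau_u = ifelse(fac, 1500, 200),
            stp_tau_x = ifelse(fac, 200, 1500))
  class(p) <- "rnn_params"
  p
}

#' Generate a batch of DMC trials for the network
#'
#' Sample directions uniform over the task's six directions; half the
#' trials are matches (test direction drawn from the sample category)
#' and half nonmatches. Inputs present the sample and test stimuli via
#' [input_tuning()]; targets are the fixation class until test onset
#' and the match/nonmatch class during the test period. Loss-mask steps
#' within `grace` ms after sample and test onset are excluded from the
#' loss.
#'
#' @param arch An [rnn_architecture()].
#' @param n Number of trials.
#' @param grace Grace period in ms after stimulus onsets.
#' @param test_weight Relative weight of test-period steps in the loss
#'   mask (default 5): the decision report is what the task scores, so
#'   its steps carry more of the cross-entropy than fixation steps.
#' @return List: `inputs` (n_inputs x n x T array), `target` (T x n
#'   class index), `loss_mask` (T x n), `is_match`, `sample_direction`,
#'   `test_direction`.
#' @export
make_rnn_batch <- function(arch, n, grace = 40, test_weight = 5) {
  cfg <- arch$task
  dirs <- cfg$directions
  cats <- cfg$categories
  sd_ <- dirs[sample.int(length(dirs), n, replace = TRUE)]
  scat <- cats[match(sd_, dirs)]
  is_match <- rep(c(TRUE, FALSE), length.out = n)[sample.int(n)]
  td <- vapply(seq_len(n), function(i) {
    pool <- if (is_match[i]) dirs[cats == scat[i]] else dirs[cats != scat[i]]
    pool[sample.int(length(pool), 1)]
  }, numeric(1))
  st <- arch$steps
  T_ <- arch$t_total
  sample_steps <- st[1] + seq_len(st[2])
  test_steps <- arch$test_start:T_
  inputs <- array(0, c(arch$n_inputs, n, T_))
  tune_s <- input_tuning(arch, sd_)
  tune_t <- input_tuning(arch, td)
  for (t in sample_steps) inputs[, , t] <- tune_s
  for (t in test_steps) inputs[, , t] <- tune_t
  target <- matrix(1L, T_, n)
  target[test_steps, ] <- ifelse(rep(is_match, each = length(test_steps)),
                                 2L, 3L)
  loss_mask <- matrix(1, T_, n)
  loss_mask[test_steps, ] <- test_weight
  g_steps <- max(0L, round(grace / arch$dt))
  if (g_steps > 0) {
    loss_mask[st[1] + seq_len(g_steps), ] <- 0
    loss_mask[arch$test_start - 1L + seq_len(g_steps), ] <- 0
  }
  input_key <- rep("off", T_)
  input_key[sample_steps] <- "sample"
  input_key[test_steps] <- "test"
  list(inputs = inputs, target = target, loss_mask = loss_mask,
       is_match = is_match, sample_direction = sd_, test_direction = td,
       input_key = input_key)
}

#' Run the network on a batch of trials
#'
#' Simulates the leaky ReLU rate dynamics with short-term plasticity
#' and softmax outputs. Graded inactivations are supported: `unit_mult`
#' multiplies the targeted units' activities, and `wrec_mult`
#' multiplies entries of the effective recurrent weight matrix, both
#' during the test period only.
#'
#' @param params,masks,arch Network parameters, masks, architecture.
#' @param batch A [make_rnn_batch()] list.
#' @param noise Optional pre-drawn noise array (n_hidden x n x T); by
#'   default drawn fresh (use [set.seed()] outside for
#'   reproducibility). Pass `0` for noiseless dynamics.
#' @param unit_mult Optional length-n_hidden activity multiplier in
#'   \[0, 1\] applied during the test period.
#' @param wrec_mult Optional n_hidden x n_hidden multiplier on the
#'   effective recurrent weights during the test period.
#' @param keep_states Store per-step states needed for the backward
#'   pass (default FALSE).
#' @return List: `r` (n_hidden x n x (T+1) activities, slice 1 the
#'   initial state), `softmax` (3 x n x T), plus stored states when
#'   requested.
#' @export
rnn_forward <- function(params, masks, arch, batch, noise = NULL,
                        unit_mult = NULL, wrec_mult = NULL,
                        keep_states = FALSE) {
  W <- effective_weights(params, masks)
  n <- arch$n_hidden
  nb <- length(batch$is_match)
  T_ <- arch$t_total
  if (is.null(noise)) {
    noise <- array(stats::rnorm(n * nb * T_, sd = arch$noise_sd),
                   c(n, nb, T_))
  } else if (identical(noise, 0)) {
    noise <- array(0, c(n, nb, T_))
  }
  w_rec_test <- if (!is.null(wrec_mult)) W$w_rec * wrec_mult else W$w_rec
  drive_sample <- W$w_in %*% input_tuning(arch, batch$sample_direction)
  drive_test <- W$w_in %*% input_tuning(arch, batch$test_direction)
  code <- match(batch$input_key, c("sample", "test"), nomatch = 0L)
  use_um <- !is.null(unit_mult)
  if (!use_um) unit_mult <- rep(1, n)
  out <- rnn_forward_core(W$w_rec, w_rec_test, params$b_rec, W$w_out,
                          params$b_out, drive_sample, drive_test,
                          as.integer(code), noise, params$stp_U,
                          arch$dt / params$stp_tau_x,
                          arch$dt / params$stp_tau_u, arch$alpha,
                          arch$dt / 1000, arch$test_start, arch$stp,
                          unit_mult, use_um)
  if (keep_states) out$W <- W
  out
}

#' Task loss of network outputs
#'
#' Weighted sum of (1) the masked categorical cross-entropy between
#' softmax outputs and the target classes, (2) a metabolic cost on
#' firing rates (`rate_cost` times the mean squared activity), and
#' (3) a metabolic cost on connectivity (`weight_cost` times the mean
#' squared effective recurrent and output weight).
#'
#' @param fwd A [rnn_forward()] result.
#' @param batch The batch it was run on.
#' @param params,masks Network parameters and masks.
#' @param rate_cost,weight_cost Cost weights (defaults 2e-2, 1e-2).
#' @return List: `total`, `cross_entropy`, `rate_cost`, `weight_cost`.
#' @export
rnn_loss <- function(fwd, batch, params, masks, rate_cost = 2e-2,
                     weight_cost = 1e-2) {
  T_ <- dim(fwd$softmax)[3]
  nb <- dim(fwd$softmax)[2]
  idx <- cbind(as.vector(t(batch$target)),
               rep(seq_len(nb), T_),
               rep(seq_len(T_), each = nb))
  pt <- fwd$softmax[idx]
  mw <- as.vector(t(batch$loss_mask))
  ce <- sum(-log(pmax(pt, 1e-12)) * mw) / sum(mw)
  rc <- rate_cost * mean(fwd$r[, , -1]^2)
  W <- effective_weights(params, masks)
  wc <- weight_cost * (mean(W$w_rec^2) + mean(W$w_out^2))
  list(total = ce + rc + wc, cross_entropy = ce, rate_cost = rc,
       weight_cost = wc)
}

# Backward pass: analytic gradients of rnn_loss wrt trainable
# parameters (w_rec_raw, b_rec, w_out_raw, b_out) through the full
# unrolled dynamics including short-term plasticity and clipping.
rnn_backward <- function(fwd, batch, params, masks, arch,
                         rate_cost = 2e-2, weight_cost = 1e-2) {
  W <- fwd$W
  g <- rnn_backward_core(fwd$r, fwd$x, fwd$u, fwd$softmax,
                         W$w_rec, W$w_out,
                         batch$target, batch$loss_mask, params$stp_U,
                         arch$dt / params$stp_tau_x,
                         arch$dt / params$stp_tau_u, arch$alpha,
                         arch$dt / 1000, arch$stp, rate_cost)
  g_wrec_eff <- g$w_rec_eff
  g_b <- as.numeric(g$b_rec)
  g_wout_eff <- g$w_out_eff
  g_bout <- as.numeric(g$b_out)
  # map effective-weight gradients back to raw weights, add weight cost
  rec_pos <- (params$w_rec_raw > 0) * masks$recurrent
  w_rec_relu <- pmax(params$w_rec_raw, 0) * masks$recurrent
  g_wrec_raw <- (sweep(g_wrec_eff, 2, masks$sign, "*") +
                   2 * weight_cost * sweep(w_rec_relu, 2, masks$sign^2,
                                           "*") / length(w_rec_relu)) *
    rec_pos
  out_pos <- (params$w_out_raw > 0) * masks$output
  w_out_relu <- pmax(params$w_out_raw, 0) * masks$output
  g_wout_raw <- (g_wout_eff +
                   2 * weight_cost * w_out_relu / length(w_out_relu)) *
    out_pos
  list(w_rec_raw = g_wrec_raw, b_rec = g_b,
       w_out_raw = g_wout_raw, b_out = g_bout)
}

#' Behavioral accuracy of network outputs
#'
#' A trial is scored correct when the modal output argmax over the
#' scored (non-grace) test-period steps is the required match/nonmatch
#' class and the modal argmax over the scored pre-test steps is the
#' fixation class.
#'
#' @param fwd A [rnn_forward()] result.
#' @param batch The batch it was run on.
#' @param arch The architecture.
#' @return Proportion of correct trials.
#' @export
rnn_accuracy <- function(fwd, batch, arch) {
  T_ <- arch$t_total
  pre <- seq_len(arch$test_start - 1)
  test <- arch$test_start:T_
  choice <- apply(fwd$softmax, c(2, 3), which.max)  # n x T
  modal <- function(v) as.integer(names(which.max(table(v))))
  ok <- vapply(seq_len(ncol(fwd$softmax[, , 1, drop = FALSE])),
               function(i) {
    mask_i <- batch$loss_mask[, i] > 0
    pre_ok <- modal(choice[i, pre[mask_i[pre]]]) == 1L
    want <- if (batch$is_match[i]) 2L else 3L
    test_ok <- modal(choice[i, test[mask_i[test]]]) == want
    pre_ok && test_ok
  }, logical(1))
  mean(ok)
}

#' Train a two-module network on the DMC task
#'
#' Gradient-based optimization (Adam, default learning rate 0.01,
#' batch size 256) of the recurrent weights/biases and output weights;
#' input projections stay fixed. Masks and Dale signs are enforced at
#' every step by construction (raw weights pass through ReLU x sign x
#' mask). Training stops when the mean behavioral accuracy over the
#' last 50 batches exceeds 0.95, or at `max_batches`.
#'
#' @param arch An [rnn_architecture()].
#' @param masks Optional [build_masks()] output (built from `seed` when
#'   omitted).
#' @param lr Learning rate.
#' @param batch_size Trials per batch.
#' @param max_batches Batch budget.
#' @param rate_cost,weight_cost Loss weights.
#' @param clip_norm Global gradient-norm clip.
#' @param seed Integer seed (masks, init, and trial generation).
#' @param verbose Print progress every 25 batches.
#' @return List of class `rnn_fit`: `params`, `masks`, `arch`, `report`
#'   (data.frame per batch: loss components, accuracy), `converged`,
#'   `final_accuracy` (mean over the last 50 batches).
#' @export
train_rnn <- function(arch, masks = NULL, lr = 0.01, batch_size = 256,
                      max_batches = 1500, rate_cost = 2e-2,
                      weight_cost = 1e-2, clip_norm = 0.1, seed = 1L,
                      verbose = FALSE) {
  if (is.null(masks)) masks <- build_masks(arch, seed)
  params <- init_params(arch, masks, seed + 1L)
  restore <- local_rng(seed + 2L)
  on.exit(restore())
  trainable <- c("w_rec_raw", "b_rec", "w_out_raw", "b_out")
  m_adam <- v_adam <- lapply(params[trainable], function(x) x * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  rep_rows <- vector("list", max_batches)
  acc_hist <- numeric(0)
  best <- list(acc = -1, params = params)
  nb_done <- 0
  for (bt in seq_len(max_batches)) {
    batch <- make_rnn_batch(arch, batch_size)
    fwd <- rnn_forward(params, masks, arch, batch, keep_states = TRUE)
    loss <- rnn_loss(fwd, batch, params, masks, rate_cost, weight_cost)
    if (!is.finite(loss$total)) {
      warning("non-finite loss at batch ", bt, "; stopping early")
      break
    }
    grads <- rnn_backward(fwd, batch, params, masks, arch,
                          rate_cost, weight_cost)
    gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
    scale <- if (gnorm > clip_norm) clip_norm / gnorm else 1
    for (nm in trainable) {
      g <- grads[[nm]] * scale
      m_adam[[nm]] <- beta1 * m_adam[[nm]] + (1 - beta1) * g
      v_adam[[nm]] <- beta2 * v_adam[[nm]] + (1 - beta2) * g^2
      mhat <- m_adam[[nm]] / (1 - beta1^bt)
      vhat <- v_adam[[nm]] / (1 - beta2^bt)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
    acc <- rnn_accuracy(fwd, batch, arch)
    acc_hist <- c(acc_hist, acc)
    rep_rows[[bt]] <- data.frame(batch = bt, loss = loss$total,
                                 cross_entropy = loss$cross_entropy,
                                 rate_cost = loss$rate_cost,
                                 weight_cost = loss$weight_cost,
                                 accuracy = acc)
    nb_done <- bt
    if (acc > best$acc) best <- list(acc = acc, params = params)
    if (verbose && bt %% 25 == 0)
      message(sprintf("batch %d  loss %.4f  acc %.3f", bt, loss$total,
                      acc))
    if (bt >= 50 && mean(acc_hist[(bt - 49):bt]) > 0.95) break
  }
  report <- do.call(rbind, rep_rows[seq_len(nb_done)])
  last50 <- report$accuracy[max(1, nb_done - 49):nb_done]
  converged <- nb_done >= 50 && mean(last50) > 0.95
  if (!converged) params <- best$params
  out <- list(params = params, masks = masks, arch = arch,
              report = report, converged = converged,
              final_accuracy = mean(last50))
  class(out) <- "rnn_fit"
  out
}

#' Evaluate behavioral accuracy of a trained network
#'
#' @param fit An `rnn_fit` (or pass `params`, `masks`, `arch`).
#' @param n_trials Evaluation trials.
#' @param seed Integer seed (trial generation and process noise).
#' @param unit_mult,wrec_mult Optional graded inactivations, as in
#'   [rnn_forward()].
#' @return Proportion of correct trials.
#' @export
evaluate_accuracy <- function(fit, n_trials = 512, seed = 1L,
                              unit_mult = NULL, wrec_mult = NULL) {
  restore <- local_rng(seed)
  on.exit(restore())
  batch <- make_rnn_batch(fit$arch, n_trials)
  fwd <- rnn_forward(fit$params, fit$masks, fit$arch, batch,
                     unit_mult = unit_mult, wrec_mult = wrec_mult)
  rnn_accuracy(fwd, batch, fit$arch)
}
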
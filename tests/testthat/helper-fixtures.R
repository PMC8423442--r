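# Shared fixtures, built once per test run and memoised. Everything is
# generated programmatically from fixed seeds.

.fx_cache <- new.env(parent = emptyenv())

fx_memo <- function(key, builder) {
  if (!exists(key, .fx_cache)) assign(key, builder(), .fx_cache)
  get(key, .fx_cache)
}

# compact mixed population with known ground-truth classes
fx_population <- function() {
  fx_memo("population", function() make_fixtures(seed = 101L,
                                                 n_trials = 720,
                                                 units_per_class = 3))
}

# a trial set reused by pure trial-level tests
fx_trials <- function() {
  fx_memo("trials", function() generate_trials(dmc_task(), 720,
                                               seed = 11L))
}

# desk-scale architecture: same task structure, shorter epochs and a
# smaller hidden layer, for tests that need several trained networks
fx_small_arch <- function() {
  task <- dmc_task(epoch_durations = list(fixation = 200, sample = 300,
                                          delay = 400, test = 300,
                                          delay2 = 150, test2 = 650))
  rnn_architecture(n_hidden = 60, dt = 20, task = task)
}

# five trained desk-scale networks (cached across test files)
fx_small_rnns <- function(n = 5) {
  fx_memo(paste0("small_rnns_", n), function() {
    lapply(seq_len(n), function(i) {
      train_rnn(fx_small_arch(), lr = 0.01, batch_size = 128,
                max_batches = 400, seed = 200L + i)
    })
  })
}

# one trained desk-scale network for single-network tests
fx_small_rnn <- function() fx_small_rnns()[[1]]

# evaluation records for the trained desk-scale networks
fx_small_evals <- function() {
  fx_memo("small_evals", function() {
    lapply(fx_small_rnns(), function(fit)
      eval_rnn(fit, n_trials = 384, seed = 301L))
  })
}

# graded-inactivation accuracy curves (more/less nonlinear PFC halves)
# for every trained desk-scale network
fx_inactivation_curves <- function() {
  fx_memo("inactivation_curves", function() {
    levels <- seq(1, 0, length.out = 10)
    lapply(fx_small_rnns(), function(fit) {
      ev <- eval_rnn(fit, n_trials = 256, seed = 303)
      pfc <- which(fit$arch$module == "PFC")
      nli <- rnn_nli(ev, intersect(screen_units(ev), pfc))
      list(more = graded_unit_inactivation(fit, nli, "more_nonlinear",
                                           levels = levels,
                                           n_trials = 256,
                                           seed = 304)$accuracy,
           less = graded_unit_inactivation(fit, nli, "less_nonlinear",
                                           levels = levels,
                                           n_trials = 256,
                                           seed = 304)$accuracy)
    })
  })
}
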
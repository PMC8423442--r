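#' Default pipeline configuration
#'
#' All stage parameters with their defaults, including every printed
#' constant of the analysis protocol (window sizes, thresholds,
#' p-value cutoffs, trial minima) in exactly one place. Values can be
#' overridden by a named list or loaded from JSON/YAML.
#'
#' @param overrides Named list (possibly nested) of overrides.
#' @return A nested list of class `run_config`.
#' @export
default_config <- function(overrides = list()) {
  cfg <- list(
    seed = 1L,
    synth = list(n_trials = 1440, n_units = 48,
                 error_rate_match = 0.1, error_rate_nonmatch = 0.02,
                 lfp_mnm_effect = 1, lfp_noise_sd = 1),
    metrics = list(window_width = 50, window_step = 5,
                   latency_width = 20, latency_step = 20,
                   screen_rate_threshold = 5, screen_alpha = 0.01,
                   preference_alpha = 0.01, latency_alpha = 0.05,
                   latency_consecutive = 2,
                   error_roc_repeats = 100),
    decode = list(n_boot = 100, n_train = 120, n_test = 60,
                  train_frac = 0.66, min_train = 10, min_test = 5),
    integrate = list(nli_window = c(50, 150),
                     classify_window = c(0, 250),
                     classify_alpha = 0.01),
    rnn = list(n_hidden = 100, exc_fraction = 0.8, dt = 20, tau = 100,
               lr = 0.01, batch_size = 256, max_batches = 1500,
               rate_cost = 2e-2, weight_cost = 1e-2, clip_norm = 0.1,
               screen_threshold = 0.001,
               ablation_levels = 10, ablation_trials = 512,
               perm_alpha = 0.001, perm_run = 5))
  modifyList(cfg, overrides)
}

#' Read a pipeline configuration from JSON or YAML
#'
#' @param path Path to a `.json`, `.yaml`, or `.yml` file with
#'   overrides of [default_config()].
#' @return A `run_config` list.
#' @export
read_config <- function(path) {
  ov <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  default_config(ov)
}

#' Build a small bundled-style synthetic dataset
#'
#' A compact population containing known ground-truth encoding
#' classes -- nonlinearly integrating (NIN, interaction-gain), linearly
#' integrating (LIN, additive sample + test gains), single-factor
#' (NMN), pure match/nonmatch, and motor units -- used by the test
#' suites and the worked examples. Regenerable bit-exactly from the
#' seed.
#'
#' @param seed Integer seed.
#' @param n_trials Trials (default 720).
#' @param units_per_class Units of each ground-truth class (default 4).
#' @return A `dmc_spikes` population with `labels` set.
#' @export
make_fixtures <- function(seed = 1L, n_trials = 720,
                          units_per_class = 4) {
  cfg <- dmc_task()
  trials <- generate_trials(cfg, n_trials, seed = seed)
  specs <- list()
  restore <- local_rng(seed + 7L)
  on.exit(restore())
  for (i in seq_len(units_per_class)) {
    base <- stats::runif(6, 8, 14)
    conj <- sample(c("S1T1", "S1T2", "S2T1", "S2T2"), 1)
    specs <- c(specs, list(
      tuning_spec(base[1], sample_cat_gain = 6, test_cat_gain = 5,
                  interaction_gain = 8, interaction_conjunction = conj,
                  label = "NIN"),
      tuning_spec(base[2], sample_cat_gain = 6, test_cat_gain = 5,
                  label = "LIN"),
      tuning_spec(base[3], sample_cat_gain = 7, label = "NMN_sample"),
      tuning_spec(base[4], test_cat_gain = 7, label = "NMN_test"),
      tuning_spec(base[5], mnm_gain = 7, label = "NMN_mnm"),
      tuning_spec(base[6], mnm_gain = 4, motor_gain = 6,
                  label = "motor")))
  }
  simulate_population(specs, trials, seed = seed + 13L)
}

#' Run the analysis pipeline end to end
#'
#' Executes the requested stages on synthetic data -- `synth` (task
#' trials, spikes, LFP), `metrics` (screening, selectivity
#' timecourses, latencies, LFP FEV), `decode` (pseudo-population SVM),
#' `integrate` (nonlinearity index, integration classes,
#' correlations), and optionally `rnn` (train a two-module network)
#' and `ablate` (inactivation experiments) -- writing CSV/JSON
#' artifacts and a manifest (with file hashes, seeds, and package
#' version) to `out_dir`.
#'
#' @param config A [default_config()]-style list.
#' @param out_dir Output directory (created if needed).
#' @param stages Character vector of stages to run.
#' @param verbose Print stage progress.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempdir(),
                         stages = c("synth", "metrics", "decode",
                                    "integrate"),
                         verbose = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(...)
  seed <- config$seed
  logf <- file.path(out_dir, "run.log")
  cat(format(Sys.time()), "pipeline start; stages:",
      paste(stages, collapse = ", "), "\n", file = logf)
  artifacts <- character(0)
  keep <- function(p) { artifacts <<- c(artifacts, p); p }

  spikes <- NULL
  if ("synth" %in% stages) {
    say("stage synth")
    spikes <- make_fixtures(seed, n_trials = config$synth$n_trials,
                            units_per_class =
                              max(1L, config$synth$n_units %/% 6L))
    keep(write_spikes_csv(spikes, file.path(out_dir, "spikes.csv")))
    lfp <- simulate_lfp(spikes$trials,
                        mnm_effect = config$synth$lfp_mnm_effect,
                        noise_sd = config$synth$lfp_noise_sd,
                        seed = seed + 1L)
    cat(format(Sys.time()), "synth done\n", file = logf, append = TRUE)
  } else {
    sp_path <- file.path(out_dir, "spikes.csv")
    if (file.exists(sp_path)) spikes <- read_spikes_csv(sp_path)
    lfp <- NULL
  }
  if (is.null(spikes) && length(intersect(stages,
                                          c("metrics", "decode",
                                            "integrate"))))
    stop("no spike data: run the synth stage first or provide ",
         file.path(out_dir, "spikes.csv"))

  mc <- config$metrics
  grid <- window_grid(mc$window_width, mc$window_step, "test_on",
                      c(-100, 400))
  included <- NULL
  if ("metrics" %in% stages) {
    say("stage metrics")
    included <- screen_neurons(spikes, mc$screen_rate_threshold,
                               mc$screen_alpha)
    tc <- do.call(rbind, lapply(c("mnm", "sample_category",
                                  "test_category"), function(f) {
      d <- selectivity_timecourse(spikes, "fev", f, grid,
                                  units = included)
      d$factor <- f
      d
    }))
    utils::write.csv(tc, keep(file.path(out_dir, "selectivity.csv")),
                     row.names = FALSE)
    lat <- vapply(included, function(u)
      mnm_latency(spikes, u)$latency, numeric(1))
    pref <- vapply(included, function(u)
      classify_mnm_preference(spikes, u,
                              alpha = mc$preference_alpha),
      character(1))
    utils::write.csv(data.frame(unit = included, latency = lat,
                                preference = pref),
                     keep(file.path(out_dir, "latency.csv")),
                     row.names = FALSE)
    if (!is.null(lfp)) {
      utils::write.csv(lfp_mnm_fev(lfp, grid),
                       keep(file.path(out_dir, "lfp_fev.csv")),
                       row.names = FALSE)
    }
    cat(format(Sys.time()), "metrics done\n", file = logf,
        append = TRUE)
  }

  if ("decode" %in% stages) {
    say("stage decode")
    dc <- config$decode
    pop <- pseudo_population(spikes, grid, dc$min_train, dc$min_test)
    wins <- seq(1, length(grid$starts), by = 4)
    dec <- svm_timecourse(pop, "mnm", n_boot = dc$n_boot,
                          n_train = dc$n_train, n_test = dc$n_test,
                          train_frac = dc$train_frac, windows = wins,
                          seed = seed + 2L)
    res <- data.frame(window_center = rep(dec$window_center,
                                          each = nrow(dec$accuracy)),
                      repeat_ = rep(seq_len(nrow(dec$accuracy)),
                                    ncol(dec$accuracy)),
                      accuracy = as.vector(dec$accuracy))
    utils::write.csv(res, keep(file.path(out_dir, "decoding.csv")),
                     row.names = FALSE)
    jsonlite::write_json(
      list(label = dec$label, chance = dec$chance,
           mean_accuracy = colMeans(dec$accuracy, na.rm = TRUE),
           p_value = dec$p_value),
      keep(file.path(out_dir, "decoding_summary.json")),
      auto_unbox = TRUE, digits = NA)
    cat(format(Sys.time()), "decode done\n", file = logf,
        append = TRUE)
  }

  if ("integrate" %in% stages) {
    say("stage integrate")
    ic <- config$integrate
    units <- if (!is.null(included)) included
             else seq_len(n_units(spikes))
    cls <- classify_integration(spikes, units, ic$classify_window,
                                ic$classify_alpha)
    nli <- population_nli(spikes, units, ic$nli_window)
    tab <- merge(cls, nli, by = "unit")
    tab$ground_truth <- spikes$labels[tab$unit]
    utils::write.csv(tab, keep(file.path(out_dir, "integration.csv")),
                     row.names = FALSE)
    cat(format(Sys.time()), "integrate done\n", file = logf,
        append = TRUE)
  }

  fit <- NULL
  if ("rnn" %in% stages) {
    say("stage rnn (training a network; this takes minutes)")
    rc <- config$rnn
    arch <- rnn_architecture(n_hidden = rc$n_hidden,
                             exc_fraction = rc$exc_fraction,
                             dt = rc$dt, tau = rc$tau)
    fit <- train_rnn(arch, lr = rc$lr, batch_size = rc$batch_size,
                     max_batches = rc$max_batches,
                     rate_cost = rc$rate_cost,
                     weight_cost = rc$weight_cost,
                     clip_norm = rc$clip_norm, seed = seed + 3L)
    keep(write_rnn_json(fit, file.path(out_dir, "rnn.json")))
    utils::write.csv(fit$report,
                     keep(file.path(out_dir, "rnn_training.csv")),
                     row.names = FALSE)
    cat(format(Sys.time()), "rnn done; converged=", fit$converged,
        "\n", file = logf, append = TRUE)
  }

  if ("ablate" %in% stages) {
    say("stage ablate")
    rc <- config$rnn
    if (is.null(fit)) {
      rj <- file.path(out_dir, "rnn.json")
      if (!file.exists(rj)) stop("ablate stage needs a trained network")
      fit <- read_rnn_json(rj)
    }
    ev <- eval_rnn(fit, n_trials = rc$ablation_trials,
                   seed = seed + 4L)
    pfc <- which(fit$arch$module == "PFC")
    scr <- intersect(screen_units(ev, rc$screen_threshold), pfc)
    nli <- rnn_nli(ev, scr)
    levels <- seq(1, 0, length.out = rc$ablation_levels)
    abl <- do.call(rbind, lapply(c("more_nonlinear", "less_nonlinear"),
                                 function(g) {
      d <- graded_unit_inactivation(fit, nli, g, levels = levels,
                                    n_trials = rc$ablation_trials,
                                    seed = seed + 4L)
      d$group <- g
      d
    }))
    utils::write.csv(abl,
                     keep(file.path(out_dir, "unit_inactivation.csv")),
                     row.names = FALSE)
    fb <- feedback_ablation(fit, levels,
                            n_trials = rc$ablation_trials,
                            seed = seed + 4L)
    sig <- permutation_significance(fb, rc$perm_alpha, rc$perm_run)
    fb_df <- data.frame(level = rep(fb$levels, ncol(fb$fev)),
                        timestep = rep(seq_len(ncol(fb$fev)),
                                       each = length(fb$levels)),
                        fev = as.vector(fb$fev))
    utils::write.csv(fb_df,
                     keep(file.path(out_dir, "feedback_ablation.csv")),
                     row.names = FALSE)
    jsonlite::write_json(list(significant = sig$significant,
                              p_values = sig$p_values),
                         keep(file.path(out_dir,
                                        "feedback_significance.json")),
                         auto_unbox = TRUE, digits = NA)
    cat(format(Sys.time()), "ablate done\n", file = logf,
        append = TRUE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("dmcnet")),
    seed = seed,
    stages = stages,
    time = format(Sys.time()),
    files = lapply(stats::setNames(nm = basename(artifacts)),
                   function(f)
                     unname(tools::md5sum(file.path(out_dir, f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
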
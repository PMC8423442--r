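#' Write and read a trial set as CSV
#'
#' One row per trial with the condition, outcome, reaction-time, and
#' event-time columns. The task configuration is stored alongside as
#' JSON (same path with extension `.task.json`) so the trial set can be
#' fully reconstructed.
#'
#' @param trials A `dmc_trials` data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials_csv <- function(trials, path) {
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE)
  cfg <- attr(trials, "task")
  jsonlite::write_json(cfg[c("directions", "boundary_angle",
                             "epoch_durations", "rt_mean", "rt_sd")],
                       paste0(sub("\\.csv$", "", path), ".task.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  tr <- utils::read.csv(path)
  js <- jsonlite::read_json(paste0(sub("\\.csv$", "", path),
                                   ".task.json"), simplifyVector = TRUE)
  cfg <- dmc_task(directions = js$directions,
                  boundary_angle = js$boundary_angle,
                  epoch_durations = as.list(js$epoch_durations),
                  rt_mean = js$rt_mean, rt_sd = js$rt_sd)
  attr(tr, "task") <- cfg
  class(tr) <- c("dmc_trials", "data.frame")
  tr
}

#' Write and read spike data as long-format CSV
#'
#' Plain-text serialization of a spike population: one row per spike
#' (`unit`, `trial`, `time_ms`), with the trial set written next to it
#' (`<path>.trials.csv`). Tuning specs, when present, are stored as
#' JSON (`<path>.specs.json`).
#'
#' @param spikes A `dmc_spikes` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spikes_csv <- function(spikes, path) {
  rows <- list()
  for (u in seq_along(spikes$spike_times)) {
    st <- spikes$spike_times[[u]]
    n_per <- lengths(st)
    rows[[u]] <- data.frame(unit = u,
                            trial = rep(seq_along(st), n_per),
                            time_ms = unlist(st))
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  write_trials_csv(spikes$trials,
                   paste0(sub("\\.csv$", "", path), ".trials.csv"))
  if (!is.null(spikes$specs))
    jsonlite::write_json(lapply(spikes$specs, unclass),
                         paste0(sub("\\.csv$", "", path), ".specs.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spikes_csv
#' @export
read_spikes_csv <- function(path) {
  df <- utils::read.csv(path)
  trials <- read_trials_csv(paste0(sub("\\.csv$", "", path),
                                   ".trials.csv"))
  nu <- max(df$unit)
  nt <- nrow(trials)
  spike_times <- lapply(seq_len(nu), function(u) {
    du <- df[df$unit == u, ]
    out <- split(du$time_ms, factor(du$trial, levels = seq_len(nt)))
    lapply(out, function(v) sort(as.numeric(v)))
  })
  ev <- dmc_events(attr(trials, "task"))
  out <- list(spike_times = spike_times, trials = trials, specs = NULL,
              labels = rep(NA_character_, nu),
              t_max = ev[["test_off"]])
  class(out) <- "dmc_spikes"
  out
}

#' Write network parameters, masks, and architecture as JSON
#'
#' @param fit An `rnn_fit` (or a list with `params`, `masks`, `arch`).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_rnn_json <- function(fit, path) {
  ser <- list(
    arch = fit$arch[c("n_hidden", "n_exc", "n_inh", "n_inputs",
                      "n_outputs", "dt", "tau", "noise_sd", "stp",
                      "module", "input_scale", "input_kappa")],
    epochs = fit$arch$task$epoch_durations,
    params = lapply(unclass(fit$params), function(x)
      if (is.matrix(x)) list(dim = dim(x), data = as.numeric(x))
      else as.numeric(x)),
    masks = lapply(unclass(fit$masks), function(x)
      if (is.matrix(x)) list(dim = dim(x), data = as.numeric(x))
      else as.numeric(x)))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rnn_json
#' @export
read_rnn_json <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  demat <- function(x) {
    if (is.list(x) && !is.null(x$dim))
      matrix(x$data, x$dim[1], x$dim[2])
    else as.numeric(x)
  }
  arch <- rnn_architecture(n_hidden = js$arch$n_hidden,
                           exc_fraction = js$arch$n_exc / js$arch$n_hidden,
                           n_inputs = js$arch$n_inputs,
                           dt = js$arch$dt, tau = js$arch$tau,
                           noise_sd = js$arch$noise_sd,
                           stp = js$arch$stp,
                           task = dmc_task(epoch_durations =
                                             as.list(js$epochs)),
                           input_scale = js$arch$input_scale,
                           input_kappa = js$arch$input_kappa)
  params <- lapply(js$params, demat)
  class(params) <- "rnn_params"
  masks <- lapply(js$masks, demat)
  class(masks) <- "rnn_masks"
  list(params = params, masks = masks, arch = arch)
}
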
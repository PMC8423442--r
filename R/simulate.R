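#' Ground-truth tuning specification for a synthetic unit
#'
#' Describes one simulated neuron as a rectified sum of task-locked rate
#' components. Each component switches on at its latency (relative to the
#' relevant stimulus onset) with an exponential rise (time constant
#' `tau_rise`) and is sustained for the rest of the trial:
#' \itemize{
#'   \item `sample_cat_gain` is added on sample-category-1 trials from
#'     sample onset (stimulus-locked);
#'   \item `test_cat_gain` is added on test-category-1 trials from test
#'     onset (stimulus-locked);
#'   \item `interaction_gain` is added only on the sample-by-test category
#'     conjunction named by `interaction_conjunction` (stimulus-locked);
#'   \item `mnm_gain` is added from test onset on trials where the
#'     *reported* choice is "match" (decision-locked: on error trials it
#'     follows the erroneous choice, not the stimulus);
#'   \item `motor_gain` ramps linearly over the 200 ms preceding the lever
#'     release on release trials (movement-locked).
#' }
#' Gains may be negative; the summed rate is rectified at zero before
#' spikes are drawn.
#'
#' @param baseline_rate Baseline rate in spikes/s (>= 0).
#' @param sample_cat_gain,test_cat_gain,mnm_gain,interaction_gain,motor_gain
#'   Component gains in spikes/s.
#' @param interaction_conjunction One of "S1T1","S1T2","S2T1","S2T2".
#' @param latencies Named list of onset latencies in ms:
#'   `sample` and `test` relative to the respective stimulus onsets,
#'   `mnm` and `interaction` relative to test onset.
#' @param tau_rise Exponential rise time constant in ms.
#' @param label Optional ground-truth class label carried through the
#'   pipeline (e.g. "NIN", "LIN", "NMN_sample").
#' @return An object of class `tuning_spec`.
#' @export
tuning_spec <- function(baseline_rate = 10, sample_cat_gain = 0,
                        test_cat_gain = 0, mnm_gain = 0,
                        interaction_gain = 0,
                        interaction_conjunction = "S2T2",
                        motor_gain = 0,
                        latencies = list(sample = 60, test = 60,
                                         mnm = 120, interaction = 80),
                        tau_rise = 25, label = NA_character_) {
  if (baseline_rate < 0) stop("baseline_rate must be >= 0")
  stopifnot(interaction_conjunction %in% c("S1T1", "S1T2", "S2T1", "S2T2"))
  lat <- list(sample = 60, test = 60, mnm = 120, interaction = 80)
  lat[names(latencies)] <- latencies
  out <- list(baseline_rate = baseline_rate,
              sample_cat_gain = sample_cat_gain,
              test_cat_gain = test_cat_gain,
              mnm_gain = mnm_gain,
              interaction_gain = interaction_gain,
              interaction_conjunction = interaction_conjunction,
              motor_gain = motor_gain,
              latencies = lat, tau_rise = tau_rise, label = label)
  class(out) <- "tuning_spec"
  out
}

# exponential-rise step: 0 before t_on, 1 - exp(-(t-t_on)/tau) after
rise_profile <- function(t, t_on, tau) {
  p <- 1 - exp(-(t - t_on) / tau)
  p[t < t_on] <- 0
  p
}

#' Noiseless rate profile of a tuning spec on one trial condition
#'
#' @param spec A [tuning_spec()].
#' @param events Named event times as from [dmc_events()].
#' @param sample_category,test_category Categories (1 or 2).
#' @param choice `"match"` or `"nonmatch"` (the reported choice).
#' @param release_time Lever-release time in ms from trial start, or `NA`.
#' @param t Time grid in ms from trial start.
#' @return Rate in spikes/s at each `t` (rectified at 0).
#' @export
rate_profile <- function(spec, events, sample_category, test_category,
                         choice, release_time = NA, t) {
  lat <- spec$latencies
  tau <- spec$tau_rise
  r <- rep(spec$baseline_rate, length(t))
  if (spec$sample_cat_gain != 0 && sample_category == 1)
    r <- r + spec$sample_cat_gain *
      rise_profile(t, events[["sample_on"]] + lat$sample, tau)
  if (spec$test_cat_gain != 0 && test_category == 1)
    r <- r + spec$test_cat_gain *
      rise_profile(t, events[["test_on"]] + lat$test, tau)
  conj <- paste0("S", sample_category, "T", test_category)
  if (spec$interaction_gain != 0 && conj == spec$interaction_conjunction)
    r <- r + spec$interaction_gain *
      rise_profile(t, events[["test_on"]] + lat$interaction, tau)
  if (spec$mnm_gain != 0 && choice == "match")
    r <- r + spec$mnm_gain *
      rise_profile(t, events[["test_on"]] + lat$mnm, tau)
  if (spec$motor_gain != 0 && !is.na(release_time)) {
    ramp <- pmin(pmax((t - (release_time - 200)) / 200, 0), 1)
    r <- r + spec$motor_gain * ramp
  }
  pmax(r, 0)
}

#' Simulate a population of spiking units on a trial set
#'
#' Draws inhomogeneous Poisson spike trains from the rectified summed rate
#' of each unit's [tuning_spec()] on each trial, on a 1 ms grid from trial
#' start to the end of the first test period. Deterministic given `seed`.
#'
#' @param specs List of [tuning_spec()] objects (non-empty).
#' @param trials A `dmc_trials` data.frame from [generate_trials()].
#' @param seed Integer seed.
#' @return An object of class `dmc_spikes`: a list with elements
#'   `spike_times` (list over units of lists over trials of sorted spike
#'   times, ms from trial start), `trials`, `specs`, `labels`
#'   (ground-truth class per unit) and `t_max`.
#' @export
simulate_population <- function(specs, trials, seed = 1L) {
  if (length(specs) == 0) stop("specs must be non-empty")
  if (inherits(specs, "tuning_spec")) specs <- list(specs)
  stopifnot(inherits(trials, "dmc_trials"))
  restore <- local_rng(seed)
  on.exit(restore())
  ev <- dmc_events(attr(trials, "task"))
  t_max <- ev[["test_off"]]
  tt <- seq(0.5, t_max - 0.5, by = 1)      # 1 ms bin centers
  n_tr <- nrow(trials)
  release <- ifelse(is.na(trials$reaction_time), NA_real_,
                    trials$test_on + trials$reaction_time)
  spikes <- vector("list", length(specs))
  for (u in seq_along(specs)) {
    spec <- specs[[u]]
    cache <- list()
    ut <- vector("list", n_tr)
    for (i in seq_len(n_tr)) {
      key <- paste0(trials$sample_category[i], trials$test_category[i],
                    trials$choice[i])
      if (spec$motor_gain != 0 && !is.na(release[i])) {
        r <- rate_profile(spec, ev, trials$sample_category[i],
                          trials$test_category[i], trials$choice[i],
                          release[i], tt)
      } else {
        if (is.null(cache[[key]]))
          cache[[key]] <- rate_profile(spec, ev, trials$sample_category[i],
                                       trials$test_category[i],
                                       trials$choice[i], NA, tt)
        r <- cache[[key]]
      }
      n <- stats::rpois(length(r), r / 1000)
      idx <- which(n > 0)
      if (length(idx)) {
        times <- rep(tt[idx] - 0.5, n[idx]) + stats::runif(sum(n[idx]))
        ut[[i]] <- sort(times)
      } else ut[[i]] <- numeric(0)
    }
    spikes[[u]] <- ut
  }
  out <- list(spike_times = spikes, trials = trials, specs = specs,
              labels = vapply(specs, function(s) s$label, character(1)),
              t_max = t_max)
  class(out) <- "dmc_spikes"
  out
}

#' @export
print.dmc_spikes <- function(x, ...) {
  cat("dmc_spikes:", length(x$spike_times), "units x",
      nrow(x$trials), "trials, 0-", x$t_max, "ms\n", sep = " ")
  invisible(x)
}

#' Number of units in a spike population
#' @param spikes A `dmc_spikes` object.
#' @return Integer unit count.
#' @export
n_units <- function(spikes) length(spikes$spike_times)

#' Simulate a surrogate LFP channel
#'
#' One voltage trace per trial: 1/f-shaped background noise, an evoked
#' deflection after sample and test onset whose test-period amplitude
#' differs between match and nonmatch trials by `mnm_effect`, and an
#' injected power-line sinusoid at 60 Hz (so the bandstop stage has
#' something to remove). Deterministic given `seed`.
#'
#' @param trials A `dmc_trials` data.frame.
#' @param mnm_effect Additional evoked amplitude (a.u.) on match trials.
#' @param noise_sd SD of the 1/f background (a.u.).
#' @param line_amp Amplitude of the injected 60 Hz sinusoid.
#' @param fs Sampling rate in Hz (>= 500).
#' @param seed Integer seed.
#' @return An object of class `dmc_lfp`: list with `traces` (trial x
#'   sample matrix), `fs`, `time` (ms), `trials`.
#' @export
simulate_lfp <- function(trials, mnm_effect = 1, noise_sd = 1,
                         line_amp = 0.5, fs = 1000, seed = 1L) {
  stopifnot(inherits(trials, "dmc_trials"))
  if (fs < 500) stop("sampling rate must be >= 500 Hz")
  restore <- local_rng(seed)
  on.exit(restore())
  ev <- dmc_events(attr(trials, "task"))
  t_max <- ev[["test_off"]]
  n <- floor(t_max * fs / 1000)
  tms <- (seq_len(n) - 1) / fs * 1000
  # causal alpha-function deflection: 0 before onset, peak 1 at
  # onset + tau, so no evoked energy leaks before the stimulus
  bump <- function(onset, tau) {
    s <- (tms - onset) / tau
    ifelse(s > 0, s * exp(1 - s), 0)
  }
  evoked_base <- bump(ev[["sample_on"]], 120) + bump(ev[["test_on"]], 120)
  mnm_bump <- bump(ev[["test_on"]], 150)
  line <- sin(2 * pi * 60 * tms / 1000)
  traces <- matrix(0, nrow(trials), n)
  for (i in seq_len(nrow(trials))) {
    amp <- if (trials$is_match[i]) mnm_effect else 0
    traces[i, ] <- pink_noise(n, fs) * noise_sd + evoked_base +
      amp * mnm_bump + line_amp * line
  }
  out <- list(traces = traces, fs = fs, time = tms, trials = trials)
  class(out) <- "dmc_lfp"
  out
}

# 1/f-shaped Gaussian noise via spectral shaping, unit variance
pink_noise <- function(n, fs) {
  w <- stats::rnorm(n)
  sp <- stats::fft(w)
  f <- c(1, seq_len(n - 1))          # avoid division by zero at DC
  f <- pmin(f, n - f + 1)            # two-sided frequency index
  sp <- sp / sqrt(f)
  x <- Re(stats::fft(sp, inverse = TRUE)) / n
  as.numeric(scale(x))
}
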
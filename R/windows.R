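#' Sliding-window grid
#'
#' Defines sliding analysis windows relative to an alignment event.
#' Windows are half-open intervals `[t, t + width)` and are timestamped at
#' their centers. The default grid (50 ms width, 5 ms step) is the one
#' used by the selectivity and decoding analyses; latency estimation uses
#' a coarser non-overlapping 20 ms / 20 ms grid.
#'
#' @param width Window width in ms (> 0).
#' @param step Step between window starts in ms (> 0).
#' @param align Alignment event: one of `"fixation_on"`, `"sample_on"`,
#'   `"test_on"`, `"release"` (test onset + reaction time).
#' @param span Two-element numeric: start and end (ms, relative to the
#'   alignment event) of the analyzed interval; windows lie fully inside.
#' @return An object of class `window_grid` with fields `width`, `step`,
#'   `align`, `span`, `starts`, `centers`.
#' @export
window_grid <- function(width = 50, step = 5, align = "test_on",
                        span = c(-100, 400)) {
  stopifnot(width > 0, step > 0, length(span) == 2, span[2] > span[1])
  starts <- seq(span[1], span[2] - width, by = step)
  if (length(starts) == 0) stop("span too short for the window width")
  g <- list(width = width, step = step, align = align, span = span,
            starts = starts, centers = starts + width / 2)
  class(g) <- "window_grid"
  g
}

# absolute alignment-event time per trial
event_times <- function(trials, align) {
  if (align == "release") {
    et <- trials$test_on + trials$reaction_time
  } else {
    if (!align %in% names(trials)) stop("unknown alignment event: ", align)
    et <- trials[[align]]
  }
  et
}

#' Windowed firing rates for one unit
#'
#' Counts spikes in each sliding window (half-open `[t, t+width)`,
#' relative to the alignment event) and converts to rates in spikes/s.
#' Trials whose alignment event is undefined (e.g. `release` on trials
#' without a lever release) get `NA` rates.
#'
#' @param spikes A `dmc_spikes` population.
#' @param unit Unit index.
#' @param grid A [window_grid()].
#' @return Matrix of rates, trials x windows.
#' @export
window_rates <- function(spikes, unit, grid) {
  tr <- spikes$trials
  et <- event_times(tr, grid$align)
  out <- matrix(NA_real_, nrow(tr), length(grid$starts))
  st <- spikes$spike_times[[unit]]
  for (i in seq_len(nrow(tr))) {
    if (is.na(et[i])) next
    s <- st[[i]]
    a <- et[i] + grid$starts
    out[i, ] <- findInterval(a + grid$width, s) - findInterval(a, s)
  }
  out / grid$width * 1000
}

#' Windowed rates for all units
#'
#' @inheritParams window_rates
#' @return 3-D array, units x trials x windows.
#' @export
window_rates_all <- function(spikes, grid) {
  nu <- n_units(spikes)
  out <- array(NA_real_, c(nu, nrow(spikes$trials), length(grid$starts)))
  for (u in seq_len(nu)) out[u, , ] <- window_rates(spikes, u, grid)
  out
}

#' Mean firing rate of one unit in a single epoch
#'
#' @param spikes A `dmc_spikes` population.
#' @param unit Unit index.
#' @param align Alignment event name.
#' @param window Two-element numeric, ms relative to the event.
#' @return Numeric vector of per-trial rates (spikes/s).
#' @export
epoch_rates <- function(spikes, unit, align = "test_on",
                        window = c(50, 350)) {
  g <- list(width = diff(window), step = 1, align = align,
            span = window, starts = window[1], centers = mean(window))
  class(g) <- "window_grid"
  drop(window_rates(spikes, unit, g))
}
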
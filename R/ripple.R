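## Online sharp-wave-ripple (SWR) detection from LFP.
##
## Pipeline per channel: causal Butterworth band-pass to the ripple band
## (150-250 Hz), squared, causal low-pass to form a power envelope, z-scored
## against a baseline estimated over an initial window and then frozen. An
## event opens when z crosses the onset threshold and closes when z falls
## below the end threshold; it is emitted on close. An optional sustain
## requirement (min_duration_ms of samples at or above the onset threshold
## within the event, default off) suppresses brief noise excursions.
## All stages are stateful, so chunked streaming output is sample-identical
## to a whole-trace pass.

#' Ripple detector configuration
#'
#' @param fs_lfp LFP sampling rate in Hz (default 1500).
#' @param band Ripple band `c(low, high)` in Hz (default `c(150, 250)`).
#' @param band_order Butterworth band-pass order (per side; default 2).
#' @param power_lowpass_hz Cutoff of the causal low-pass applied to the
#'   squared band signal (default 25 Hz, responsive within the ~50-100 ms
#'   timescale of a ripple).
#' @param power_order Low-pass order (default 1).
#' @param z_threshold Onset threshold in baseline SDs (default 3).
#' @param z_end_threshold Offset threshold; the event closes when z falls
#'   below it (default 0, i.e. return to baseline mean).
#' @param baseline_window_s Seconds of initial data used to estimate the
#'   baseline mean/SD of the power envelope, frozen afterwards (default 10).
#' @param min_duration_ms Minimum time at or above `z_threshold` within an
#'   event for it to be emitted (default 0 = emit all).
#' @return A `ripple_config`.
#' @export
ripple_config <- function(fs_lfp = 1500, band = c(150, 250), band_order = 2,
                          power_lowpass_hz = 25, power_order = 1,
                          z_threshold = 3, z_end_threshold = 0,
                          baseline_window_s = 10, min_duration_ms = 0) {
  if (!(0 < band[1] && band[1] < band[2] && band[2] < fs_lfp / 2))
    stop("configuration error: band must satisfy 0 < low < high < fs/2")
  if (z_threshold < z_end_threshold)
    stop("configuration error: z_threshold must be >= z_end_threshold")
  bp <- signal::butter(band_order, band / (fs_lfp / 2), "pass")
  lp <- signal::butter(power_order, power_lowpass_hz / (fs_lfp / 2), "low")
  structure(list(fs_lfp = fs_lfp, band = band, band_order = band_order,
                 power_lowpass_hz = power_lowpass_hz, power_order = power_order,
                 z_threshold = z_threshold, z_end_threshold = z_end_threshold,
                 baseline_window_s = baseline_window_s,
                 min_duration_ms = min_duration_ms,
                 bp_b = as.numeric(bp$b), bp_a = as.numeric(bp$a),
                 lp_b = as.numeric(lp$b), lp_a = as.numeric(lp$a)),
            class = "ripple_config")
}

#' Create a streaming ripple detector for one channel
#'
#' @param config A [ripple_config()].
#' @param group_id Electrode-group / channel id carried into emitted events.
#' @return A `ripple_detector` (mutable reference object).
#' @export
ripple_detector <- function(config, group_id = 1L) {
  d <- new.env(parent = emptyenv())
  d$config <- config
  d$group_id <- as.integer(group_id)
  d$bp_state <- numeric(max(length(config$bp_a), length(config$bp_b)) - 1L)
  d$lp_state <- numeric(max(length(config$lp_a), length(config$lp_b)) - 1L)
  d$bl_n <- 0; d$bl_mean <- 0; d$bl_m2 <- 0     # Welford accumulators
  d$bl_needed <- round(config$baseline_window_s * config$fs_lfp)
  d$bl_frozen <- FALSE; d$bl_sd <- NA_real_
  d$open <- FALSE; d$start <- NA_real_; d$peak <- -Inf
  d$n_above <- 0L; d$last_ts <- NA_real_
  d$min_samples <- round(config$min_duration_ms / 1000 * config$fs_lfp)
  class(d) <- "ripple_detector"
  d
}

#' Band-pass a chunk of LFP to the ripple band (stateful)
#'
#' @param detector A [ripple_detector()].
#' @param values Numeric LFP chunk.
#' @return Filtered chunk, one value per input sample.
#' @export
filter_ripple_band <- function(detector, values) {
  r <- iir_filter_state(detector$config$bp_b, detector$config$bp_a,
                        as.numeric(values), detector$bp_state)
  detector$bp_state <- r$zf
  r$y
}

#' Ripple power envelope: causal low-pass of the squared band signal
#'
#' @param detector A [ripple_detector()].
#' @param filtered Band-passed chunk from [filter_ripple_band()].
#' @return Envelope chunk (the low-pass is applied to the square; transient
#'   undershoot aside, it is non-negative in steady state).
#' @export
power_estimate <- function(detector, filtered) {
  r <- iir_filter_state(detector$config$lp_b, detector$config$lp_a,
                        as.numeric(filtered)^2, detector$lp_state)
  detector$lp_state <- r$zf
  r$y
}

#' Z-score the power envelope against the running baseline
#'
#' The baseline mean/SD accumulate over the first `baseline_window_s` of data
#' and are then frozen. Samples consumed while the baseline is still being
#' estimated return `NA` (no detection is possible there).
#'
#' @param detector A [ripple_detector()].
#' @param envelope Envelope chunk from [power_estimate()].
#' @return Z-scored chunk.
#' @export
ripple_zscore <- function(detector, envelope) {
  envelope <- as.numeric(envelope)
  n <- length(envelope)
  z <- rep(NA_real_, n)
  i <- 1L
  if (!detector$bl_frozen) {
    take <- min(n, detector$bl_needed - detector$bl_n)
    if (take > 0) {
      for (v in envelope[seq_len(take)]) {   # Welford update
        detector$bl_n <- detector$bl_n + 1
        d1 <- v - detector$bl_mean
        detector$bl_mean <- detector$bl_mean + d1 / detector$bl_n
        detector$bl_m2 <- detector$bl_m2 + d1 * (v - detector$bl_mean)
      }
      i <- take + 1L
    }
    if (detector$bl_n >= detector$bl_needed) {
      detector$bl_sd <- sqrt(detector$bl_m2 / (detector$bl_n - 1))
      if (detector$bl_sd == 0) stop("degenerate baseline: sd == 0")
      detector$bl_frozen <- TRUE
    }
  }
  if (detector$bl_frozen && i <= n)
    z[i:n] <- (envelope[i:n] - detector$bl_mean) / detector$bl_sd
  z
}

#' Run the onset/offset state machine over a z chunk (stateful)
#'
#' An event opens at the first sample with `z >= z_threshold` while closed and
#' closes at the first subsequent sample with `z < z_end_threshold`; the event
#' is emitted on close (subject to the optional sustain requirement), with
#' `start_timestamp` at the opening sample and `end_timestamp` at the last
#' sample before closing.
#'
#' @param detector A [ripple_detector()].
#' @param z Z-scored chunk (`NA` entries, e.g. during baseline estimation, are
#'   ignored).
#' @param timestamps Tick timestamps parallel to `z`.
#' @return Data frame of events closed within this chunk (possibly empty):
#'   `group_id, start_timestamp, end_timestamp, peak_z`.
#' @export
detect_events <- function(detector, z, timestamps) {
  cfg <- detector$config
  ev <- list()
  for (k in seq_along(z)) {
    zk <- z[k]
    if (is.na(zk)) next
    if (!detector$open) {
      if (zk >= cfg$z_threshold) {
        detector$open <- TRUE
        detector$start <- timestamps[k]
        detector$peak <- zk
        detector$n_above <- 1L
      }
    } else {
      if (zk < cfg$z_end_threshold) {
        if (detector$n_above >= detector$min_samples)
          ev[[length(ev) + 1L]] <- data.frame(
            group_id = detector$group_id,
            start_timestamp = detector$start,
            end_timestamp = detector$last_ts,
            peak_z = detector$peak)
        detector$open <- FALSE
        detector$peak <- -Inf
        detector$n_above <- 0L
      } else {
        detector$peak <- max(detector$peak, zk)
        if (zk >= cfg$z_threshold) detector$n_above <- detector$n_above + 1L
      }
    }
    detector$last_ts <- timestamps[k]
  }
  if (length(ev)) do.call(rbind, ev)
  else data.frame(group_id = integer(0), start_timestamp = numeric(0),
                  end_timestamp = numeric(0), peak_z = numeric(0))
}

#' Process an LFP chunk through the full ripple pipeline
#'
#' @param detector A [ripple_detector()].
#' @param timestamps Tick timestamps of the chunk.
#' @param values LFP values.
#' @return List with `filtered`, `power`, `z`, and `events` (events closed in
#'   this chunk).
#' @export
process_lfp <- function(detector, timestamps, values) {
  xf <- filter_ripple_band(detector, values)
  env <- power_estimate(detector, xf)
  z <- ripple_zscore(detector, env)
  list(filtered = xf, power = env, z = z,
       events = detect_events(detector, z, timestamps))
}

#' Detect ripples over a whole LFP trace (offline convenience)
#'
#' @param timestamps Tick timestamps.
#' @param values LFP trace.
#' @param config A [ripple_config()].
#' @param group_id Channel id for the emitted events.
#' @return List with `events` data frame and the `z` trace.
#' @export
detect_ripples <- function(timestamps, values, config, group_id = 1L) {
  det <- ripple_detector(config, group_id)
  r <- process_lfp(det, timestamps, values)
  list(events = r$events, z = r$z)
}
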
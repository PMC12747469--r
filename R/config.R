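## YAML session configuration.
##
## The YAML schema mirrors session_config(): a `geometry` block (segments in
## cm plus bin size), `inputs`/`output` paths, movement-filter and encoder
## settings, and nested `decoder`, `ripple`, `event` blocks. Anything omitted
## takes the documented default.

#' Default session configuration as a YAML-ready list
#'
#' @return Nested list mirroring the YAML schema with all defaults filled in.
#' @export
default_session_options <- function() {
  list(
    geometry = list(
      segments = lapply(seq_len(4), function(i)
        as.numeric(default_track_geometry()$segments[i, ])),
      bin_size_cm = 5),
    inputs = list(spikes = "spikes.csv", lfp = "lfp.csv",
                  position = "position.csv"),
    output = "records.bin",
    task1_end_s = 300,
    ticks_per_s = 30000,
    px_per_cm = 1,
    vel_thresh = 4,
    speed_window_s = 0.25,
    sigma = 20,
    decoder = list(dt_ms = 6, dt_delay_ms = 30, transition = "uniform"),
    ripple = list(enabled = TRUE, fs_lfp = 1500, band = c(150, 250),
                  band_order = 2, power_lowpass_hz = 25, power_order = 1,
                  z_threshold = 3, z_end_threshold = 0,
                  baseline_window_s = 10, min_duration_ms = 0),
    event = list(enabled = FALSE, target_bins = integer(0),
                 offtarget_bins = integer(0), dt_event_ms = 36,
                 target_frac = 0.40, offtarget_frac = 0.20,
                 center_radius_cm = 17, min_active_groups = 2,
                 refractory_s = 3, specificity_frac = 0.5),
    center_segments = c(1, 2),
    seed = 1)
}

#' Read a session configuration from YAML
#'
#' @param path YAML file following the [default_session_options()] schema.
#'   Relative input/output paths are resolved against the YAML file's
#'   directory.
#' @return A [session_config()].
#' @export
read_session_config <- function(path) {
  o <- utils::modifyList(default_session_options(),
                         yaml::read_yaml(path), keep.null = TRUE)
  base <- dirname(normalizePath(path))
  rel <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  geometry <- track_geometry(do.call(rbind, o$geometry$segments),
                             bin_size_cm = o$geometry$bin_size_cm)
  ripple <- if (isTRUE(o$ripple$enabled))
    ripple_config(fs_lfp = o$ripple$fs_lfp, band = as.numeric(o$ripple$band),
                  band_order = o$ripple$band_order,
                  power_lowpass_hz = o$ripple$power_lowpass_hz,
                  power_order = o$ripple$power_order,
                  z_threshold = o$ripple$z_threshold,
                  z_end_threshold = o$ripple$z_end_threshold,
                  baseline_window_s = o$ripple$baseline_window_s,
                  min_duration_ms = o$ripple$min_duration_ms)
  event <- if (isTRUE(o$event$enabled))
    event_config(target_bins = o$event$target_bins,
                 offtarget_bins = o$event$offtarget_bins,
                 dt_event_ms = o$event$dt_event_ms, dt_ms = o$decoder$dt_ms,
                 target_frac = o$event$target_frac,
                 offtarget_frac = o$event$offtarget_frac,
                 center_radius_cm = o$event$center_radius_cm,
                 min_active_groups = o$event$min_active_groups,
                 refractory_s = o$event$refractory_s,
                 specificity_frac = o$event$specificity_frac)
  session_config(geometry = geometry,
                 spikes = rel(o$inputs$spikes), lfp = rel(o$inputs$lfp),
                 position = rel(o$inputs$position), output = rel(o$output),
                 task1_end_s = o$task1_end_s, ticks_per_s = o$ticks_per_s,
                 px_per_cm = o$px_per_cm, vel_thresh = o$vel_thresh,
                 speed_window_s = o$speed_window_s, sigma = o$sigma,
                 dt_ms = o$decoder$dt_ms, dt_delay_ms = o$decoder$dt_delay_ms,
                 transition = o$decoder$transition, ripple = ripple,
                 event = event, center_segments = o$center_segments,
                 seed = o$seed)
}

#' Dump a record file to CSV
#'
#' Writes one `<prefix>_rec<id>.csv` per record type.
#'
#' @param records_path Binary record file.
#' @param prefix Output path prefix (default: the record path).
#' @return Character vector of files written.
#' @export
records_to_csv <- function(records_path, prefix = records_path) {
  recs <- read_records(records_path)
  out <- character(0)
  for (id in names(recs)) {
    f <- paste0(prefix, "_rec", id, ".csv")
    write.csv(recs[[id]], f, row.names = FALSE)
    out <- c(out, f)
  }
  out
}
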
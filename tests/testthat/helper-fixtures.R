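# Shared fixture builders. Everything is generated in code at test time.

# 4-segment two-arm track, 205 cm, 41 five-cm bins
two_arm_geometry <- function() default_track_geometry()

write_spike_csv <- function(path, timestamp, group = 1L,
                            marks = matrix(0, length(timestamp), 2)) {
  df <- data.frame(timestamp = timestamp,
                   electrode_group_id = rep(group, length.out = length(timestamp)))
  for (d in seq_len(ncol(marks))) df[[paste0("mark_", d - 1)]] <- marks[, d]
  write.csv(df, path, row.names = FALSE)
  path
}

write_lfp_csv <- function(path, timestamp, value = 0, group = 1L) {
  write.csv(data.frame(timestamp = timestamp, group_id = group,
                       value = rep(value, length.out = length(timestamp))),
            path, row.names = FALSE)
  path
}

write_position_csv <- function(path, timestamp, segment = 1L, norm_pos = 0.5,
                               x = 0, y = 0) {
  n <- length(timestamp)
  write.csv(data.frame(timestamp = timestamp,
                       segment = rep(segment, length.out = n),
                       norm_pos = rep(norm_pos, length.out = n),
                       x = rep(x, length.out = n), y = rep(y, length.out = n),
                       x2 = rep(x, length.out = n), y2 = rep(y, length.out = n)),
            path, row.names = FALSE)
  path
}

# small frozen encoding model with explicit contents
toy_model <- function(marks, bins, n_bins = 5, sigma = 1, mu = 2,
                      occupancy = NULL) {
  m <- encoding_model(1L, ncol(marks), n_bins, sigma = sigma,
                      occupancy_smooth_sd_bins = 0)
  add_spikes(m, marks, bins)
  freeze(m, mean_rate = mu,
         occupancy = if (is.null(occupancy)) rep(1, n_bins) else occupancy)
  m
}

# detector operating point used for strong-burst fixtures (see vignette)
burst_fixture_ripple_config <- function(fs = 1500)
  ripple_config(fs_lfp = fs, z_threshold = 5, z_end_threshold = 1,
                baseline_window_s = 10, min_duration_ms = 30)
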
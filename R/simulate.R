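## Ground-truthed synthetic sessions.
##
## The generator emulates the statistical structure the decoder assumes: an
## animal traversing a segmented two-arm track at constant running speed with
## pauses, spatially tuned Poisson spiking whose marks form Gaussian clusters
## in amplitude space (multiunit amplitude clusters, the unsorted events a
## clusterless decoder actually consumes), and 1/f LFP with ripple-band bursts
## injected at known times.
##
## Track topology: segments 1-2 are the central box laid end to end, segment 3
## (arm 1) continues from the end of segment 2, segment 4 (arm 2) leaves from
## the start of segment 1. The animal's path coordinate q runs from -len(arm2)
## (arm 2 end) through 0 (central box entry) to len(center)+len(arm1).

#' Default two-arm track geometry (205 cm, 41 five-cm bins)
#'
#' Two central-box segments (25 + 20 cm) plus two 80 cm arms.
#' @return A [track_geometry()].
#' @export
default_track_geometry <- function() {
  track_geometry(rbind(
    c(0, 0, 25, 0),     # central box, part 1
    c(25, 0, 45, 0),    # central box, part 2
    c(45, 0, 45, 80),   # arm 1
    c(0, 0, 0, 80)))    # arm 2
}

#' Synthetic-session configuration
#'
#' Defaults describe a 10 min session on the default two-arm track: 8
#' electrode groups of 3 multiunit amplitude clusters each, Gaussian spatial
#' tuning (peak 100 Hz, sd 10 cm, baseline 0.5 Hz, together ~35 Hz mean
#' multiunit rate per group), 4-D marks with cluster centers 150 units apart
#' and isotropic sd 20, running at 20 cm/s with 2 s pauses.
#'
#' @param geometry A [track_geometry()] with the two-arm topology above.
#' @param n_groups Electrode groups (default 8).
#' @param cells_per_group Mark clusters per group (default 3).
#' @param peak_rate_hz,baseline_rate_hz Tuning-curve peak and floor (defaults
#'   100, 0.5).
#' @param field_sd_cm Gaussian place-field sd in cm (default 10).
#' @param field_centers_cm Field centers on the linearized axis; default
#'   evenly spaced over the track.
#' @param mark_dim Mark dimensionality (default 4, tetrode peak amplitudes).
#' @param mark_base,mark_sep Cluster-center layout: all coordinates at
#'   `mark_base` except one at `mark_base + mark_sep` (defaults 100, 150).
#' @param mark_sd Isotropic mark noise sd (default 20).
#' @param run_speed_cms Running speed (default 20 cm/s).
#' @param pause_s Pause at the central box between arm visits (default 2 s).
#' @param duration_s Session length (default 600).
#' @param task1_end_s Encoding/feedback task boundary (default half the
#'   session).
#' @param fs_pos,fs_lfp,ticks_per_s Sampling rates (defaults 30 Hz camera,
#'   1500 Hz LFP, 30,000 ticks/s).
#' @param px_per_cm Camera scale (default 1).
#' @param ripple_times_s Burst onset times in seconds (default none).
#' @param ripple_duration_s Burst duration (default 0.08).
#' @param ripple_amp_factor Burst peak amplitude as a multiple of the
#'   background's ripple-band RMS (default 6).
#' @param ripple_freq_hz Burst carrier frequency (default 200).
#' @param seed RNG seed; fixed seed gives bit-identical fixtures.
#' @return A `sim_config`.
#' @export
sim_config <- function(geometry = default_track_geometry(), n_groups = 8,
                       cells_per_group = 3, peak_rate_hz = 100,
                       baseline_rate_hz = 0.5, field_sd_cm = 10,
                       field_centers_cm = NULL, mark_dim = 4,
                       mark_base = 100, mark_sep = 150, mark_sd = 20,
                       run_speed_cms = 20, pause_s = 2, duration_s = 600,
                       task1_end_s = duration_s / 2, fs_pos = 30,
                       fs_lfp = 1500, ticks_per_s = 30000, px_per_cm = 1,
                       ripple_times_s = numeric(0), ripple_duration_s = 0.08,
                       ripple_amp_factor = 6, ripple_freq_hz = 200,
                       seed = 1L) {
  stopifnot(nrow(geometry$segments) == 4)
  n_cells <- n_groups * cells_per_group
  track_cm <- geometry$n_bins * geometry$bin_size_cm
  if (is.null(field_centers_cm))
    field_centers_cm <- (seq_len(n_cells) - 0.5) * track_cm / n_cells
  stopifnot(peak_rate_hz >= 0, baseline_rate_hz >= 0, mark_sd > 0,
            all(ripple_times_s >= 0 & ripple_times_s <= duration_s))
  structure(list(geometry = geometry, n_groups = n_groups,
                 cells_per_group = cells_per_group, n_cells = n_cells,
                 peak_rate_hz = peak_rate_hz,
                 baseline_rate_hz = baseline_rate_hz,
                 field_sd_cm = field_sd_cm,
                 field_centers_cm = field_centers_cm,
                 mark_dim = mark_dim, mark_base = mark_base,
                 mark_sep = mark_sep, mark_sd = mark_sd,
                 run_speed_cms = run_speed_cms, pause_s = pause_s,
                 duration_s = duration_s, task1_end_s = task1_end_s,
                 fs_pos = fs_pos, fs_lfp = fs_lfp, ticks_per_s = ticks_per_s,
                 px_per_cm = px_per_cm, ripple_times_s = ripple_times_s,
                 ripple_duration_s = ripple_duration_s,
                 ripple_amp_factor = ripple_amp_factor,
                 ripple_freq_hz = ripple_freq_hz, seed = as.integer(seed)),
            class = "sim_config")
}

## path coordinate q -> (segment, norm_pos) under the two-arm topology
.q_to_segnorm <- function(q, geometry) {
  l <- geometry$lengths
  seg <- ifelse(q < 0, 4L, ifelse(q <= l[1], 1L, ifelse(q <= l[1] + l[2], 2L, 3L)))
  norm <- ifelse(q < 0, -q / l[4],
          ifelse(q <= l[1], q / l[1],
          ifelse(q <= l[1] + l[2], (q - l[1]) / l[2], (q - l[1] - l[2]) / l[3])))
  list(segment = seg, norm_pos = pmin(pmax(norm, 0), 1))
}

.segnorm_to_xy <- function(segment, norm_pos, geometry) {
  s <- geometry$segments[segment, , drop = FALSE]
  cbind(x = s[, "x1"] + norm_pos * (s[, "x2"] - s[, "x1"]),
        y = s[, "y1"] + norm_pos * (s[, "y2"] - s[, "y1"]))
}

#' Simulate the animal's trajectory
#'
#' Constant-speed traversals alternating between the two arms, with a pause at
#' the central-box entry between visits; camera samples at `fs_pos`.
#'
#' @param sim A [sim_config()].
#' @return List with `position` (CSV-dialect data frame:
#'   `timestamp,segment,norm_pos,x,y,x2,y2`) and `truth`
#'   (`t_s, q_cm, linear_cm, bin, speed_cms`).
#' @export
simulate_trajectory <- function(sim) {
  g <- sim$geometry
  l <- g$lengths
  if (sim$duration_s <= 0) {
    empty_pos <- data.frame(timestamp = numeric(0), segment = integer(0),
                            norm_pos = numeric(0), x = numeric(0),
                            y = numeric(0), x2 = numeric(0), y2 = numeric(0))
    empty_truth <- data.frame(t_s = numeric(0), q_cm = numeric(0),
                              linear_cm = numeric(0), bin = integer(0),
                              speed_cms = numeric(0))
    return(list(position = empty_pos, truth = empty_truth))
  }
  q_arm1 <- l[1] + l[2] + l[3]; q_arm2 <- -l[4]
  tt <- 0; q <- 0; arm <- 1L
  kt <- 0; kq <- 0
  while (tt < sim$duration_s) {
    tgt <- if (arm == 1L) q_arm1 else q_arm2
    tt <- tt + abs(tgt - q) / sim$run_speed_cms; kt <- c(kt, tt); kq <- c(kq, tgt); q <- tgt
    tt <- tt + abs(q) / sim$run_speed_cms; kt <- c(kt, tt); kq <- c(kq, 0); q <- 0
    tt <- tt + sim$pause_s; kt <- c(kt, tt); kq <- c(kq, 0)
    arm <- 3L - arm
  }
  t_s <- seq(0, sim$duration_s, by = 1 / sim$fs_pos)
  if (length(t_s) == 0)
    return(list(position = data.frame(timestamp = numeric(0)),
                truth = data.frame(t_s = numeric(0))))
  qpos <- approx(kt, kq, t_s, rule = 2)$y
  sn <- .q_to_segnorm(qpos, g)
  xy <- .segnorm_to_xy(sn$segment, sn$norm_pos, g) * sim$px_per_cm
  pos <- data.frame(timestamp = round(t_s * sim$ticks_per_s),
                    segment = sn$segment, norm_pos = sn$norm_pos,
                    x = xy[, "x"], y = xy[, "y"],
                    x2 = xy[, "x"], y2 = xy[, "y"])
  ## true instantaneous speed from the knot schedule (piecewise constant)
  spd <- abs(c(0, diff(qpos))) * sim$fs_pos
  truth <- data.frame(t_s = t_s, q_cm = qpos,
                      linear_cm = linear_cm(sn$segment, sn$norm_pos, g),
                      bin = to_bin(sn$segment, sn$norm_pos, g),
                      speed_cms = spd)
  list(position = pos, truth = truth)
}

#' Simulate place-tuned Poisson spiking with Gaussian mark clusters
#'
#' Each cluster fires as an inhomogeneous Poisson process with rate
#' `baseline + peak * exp(-(x - center)^2 / (2 sd^2))` on the linearized
#' position, sampled by Lewis-Shedler thinning; each spike's mark is the
#' cluster center plus isotropic Gaussian noise.
#'
#' @param sim A [sim_config()].
#' @param trajectory Output of [simulate_trajectory()].
#' @return List with `spikes` (CSV dialect:
#'   `timestamp,electrode_group_id,mark_0..`) and `truth` (`t_s, cell, group`).
#' @export
simulate_spikes <- function(sim, trajectory) {
  set.seed(sim$seed + 1L)
  tr <- trajectory$truth
  centers <- sim$field_centers_cm
  lam_max <- sim$peak_rate_hz + sim$baseline_rate_hz
  spk_t <- numeric(0); spk_cell <- integer(0)
  for (c in seq_len(sim$n_cells)) {
    n_cand <- rpois(1, lam_max * sim$duration_s)
    cand <- sort(runif(n_cand, 0, sim$duration_s))
    x <- approx(tr$t_s, tr$linear_cm, cand, rule = 2)$y
    rate <- sim$baseline_rate_hz + sim$peak_rate_hz *
      exp(-(x - centers[c])^2 / (2 * sim$field_sd_cm^2))
    keep <- runif(n_cand) < rate / lam_max
    spk_t <- c(spk_t, cand[keep])
    spk_cell <- c(spk_cell, rep(c, sum(keep)))
  }
  o <- order(spk_t); spk_t <- spk_t[o]; spk_cell <- spk_cell[o]
  n <- length(spk_t)
  ## cluster centers: mark_base everywhere, +mark_sep on one coordinate per
  ## in-group cluster so within-group separation is mark_sep * sqrt(2)
  ctr <- matrix(sim$mark_base, sim$n_cells, sim$mark_dim)
  for (c in seq_len(sim$n_cells))
    ctr[c, ((c - 1L) %% sim$cells_per_group) %% sim$mark_dim + 1L] <-
      sim$mark_base + sim$mark_sep
  marks <- ctr[spk_cell, , drop = FALSE] +
    matrix(rnorm(n * sim$mark_dim, 0, sim$mark_sd), ncol = sim$mark_dim)
  group <- (spk_cell - 1L) %/% sim$cells_per_group + 1L
  spikes <- data.frame(timestamp = round(spk_t * sim$ticks_per_s),
                       electrode_group_id = group)
  for (d in seq_len(sim$mark_dim))
    spikes[[paste0("mark_", d - 1L)]] <- marks[, d]
  list(spikes = spikes,
       truth = data.frame(t_s = spk_t, cell = spk_cell, group = group))
}

## 1/f-amplitude-shaped Gaussian noise via FFT
.pink_noise <- function(n) {
  W <- fft(rnorm(n))
  f <- c(1, seq_len(n - 1)); f <- pmin(f, n - f + 1)
  Re(fft(W / sqrt(f), inverse = TRUE)) / n
}

## Tukey (tapered cosine) envelope, ramp fraction alpha/2 per side
.tukey <- function(m, alpha = 0.125) {
  t <- seq(0, 1, length.out = m); e <- rep(1, m)
  r <- t < alpha / 2
  e[r] <- 0.5 * (1 + cos(pi * (2 * t[r] / alpha - 1)))
  r <- t >= 1 - alpha / 2
  e[r] <- 0.5 * (1 + cos(pi * (2 * t[r] / alpha - 2 / alpha + 1)))
  e
}

#' Simulate LFP with injected ripple-band bursts
#'
#' Background is 1/f-shaped noise (unit sd); each burst is a
#' `ripple_freq_hz` sinusoid under a fast-rise Tukey envelope with peak
#' amplitude `ripple_amp_factor` times the background's ripple-band RMS.
#'
#' @param sim A [sim_config()].
#' @return List with `lfp` (CSV dialect: `timestamp,group_id,value`) and
#'   `truth` (`start_s, end_s` per injected burst).
#' @export
simulate_lfp <- function(sim) {
  set.seed(sim$seed + 2L)
  n <- round(sim$fs_lfp * sim$duration_s)
  x <- .pink_noise(n)
  x <- x / sd(x)
  ## ripple-band RMS of the background, steady state
  bp <- signal::butter(2, c(150, 250) / (sim$fs_lfp / 2), "pass")
  xb <- as.numeric(signal::filter(bp$b, bp$a, x))
  band_rms <- sd(xb[-seq_len(min(n, sim$fs_lfp))])
  for (t0 in sim$ripple_times_s) {
    idx <- round(t0 * sim$fs_lfp) + seq_len(round(sim$ripple_duration_s * sim$fs_lfp))
    idx <- idx[idx >= 1 & idx <= n]
    tt <- seq_along(idx) / sim$fs_lfp
    x[idx] <- x[idx] + sim$ripple_amp_factor * band_rms *
      .tukey(length(idx)) * sin(2 * pi * sim$ripple_freq_hz * tt)
  }
  ts <- round((seq_len(n) - 1) / sim$fs_lfp * sim$ticks_per_s)
  list(lfp = data.frame(timestamp = ts, group_id = 1L, value = x),
       truth = data.frame(start_s = sim$ripple_times_s,
                          end_s = sim$ripple_times_s + sim$ripple_duration_s))
}

#' Generate and write a full synthetic session
#'
#' Writes the three CSV input streams plus ground-truth CSVs into `dir`.
#'
#' @param sim A [sim_config()].
#' @param dir Output directory (created if missing).
#' @return List of file paths plus the in-memory `trajectory`, `spikes`,
#'   `lfp` objects.
#' @export
simulate_session <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  traj <- simulate_trajectory(sim)
  spk <- simulate_spikes(sim, traj)
  lfp <- simulate_lfp(sim)
  paths <- list(position = file.path(dir, "position.csv"),
                spikes = file.path(dir, "spikes.csv"),
                lfp = file.path(dir, "lfp.csv"),
                truth_position = file.path(dir, "truth_position.csv"),
                truth_spikes = file.path(dir, "truth_spikes.csv"),
                truth_ripples = file.path(dir, "truth_ripples.csv"))
  write.csv(traj$position, paths$position, row.names = FALSE)
  write.csv(spk$spikes, paths$spikes, row.names = FALSE)
  write.csv(lfp$lfp, paths$lfp, row.names = FALSE)
  write.csv(traj$truth, paths$truth_position, row.names = FALSE)
  write.csv(spk$truth, paths$truth_spikes, row.names = FALSE)
  write.csv(lfp$truth, paths$truth_ripples, row.names = FALSE)
  c(paths, list(trajectory = traj, spikes = spk, lfp = lfp))
}
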
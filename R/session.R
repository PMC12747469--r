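## Streaming-replay session runtime.
##
## A single deterministic pass replaces the original multi-process deployment:
## task-1 spikes that pass the movement filter train the per-group encoding
## models, the models freeze at the task boundary, and task-2 time is tiled
## into dt-sized bins on the LFP clock. Each stage is evaluated vectorised,
## with semantics identical to a sample-by-sample event loop (half-open spike
## windows, late/dropped-spike accounting, record order per type).

.REC_DECODER <- 1L; .REC_LIKELIHOOD <- 2L; .REC_RIPPLE <- 3L; .REC_EVENT <- 4L
.REC_DROPPED <- 5L

#' Session configuration
#'
#' @param geometry A [track_geometry()].
#' @param spikes,lfp,position Input CSV paths ([data_source()] dialects).
#' @param output Output record-file path.
#' @param task1_end_s Encoding/feedback boundary in seconds from tick 0.
#' @param ticks_per_s Acquisition clock rate (default 30,000).
#' @param px_per_cm Camera scale for speed estimation (default 1).
#' @param vel_thresh Movement-filter threshold in cm/s (default 4).
#' @param speed_window_s Speed smoothing window (default 0.25).
#' @param sigma Mark kernel bandwidth (default 20).
#' @param dt_ms,dt_delay_ms Decoder bin size and window delay (defaults 6, 30).
#' @param transition Transition kind: `"uniform"`, `"identity"`,
#'   `"random_walk"`.
#' @param ripple A [ripple_config()], or `NULL` to skip ripple detection.
#' @param event An [event_config()], or `NULL` to skip event detection.
#' @param center_segments Segment ids forming the central box, used for the
#'   animal-distance gate (default `c(1, 2)`).
#' @param seed RNG seed recorded with the session (the replay itself is
#'   deterministic).
#' @return A `session_config`.
#' @export
session_config <- function(geometry, spikes, lfp, position, output,
                           task1_end_s, ticks_per_s = 30000, px_per_cm = 1,
                           vel_thresh = 4, speed_window_s = 0.25, sigma = 20,
                           dt_ms = 6, dt_delay_ms = 30,
                           transition = "uniform", ripple = ripple_config(),
                           event = NULL, center_segments = c(1L, 2L),
                           seed = 1L) {
  structure(list(geometry = geometry, spikes = spikes, lfp = lfp,
                 position = position, output = output,
                 task1_end_s = task1_end_s, ticks_per_s = ticks_per_s,
                 px_per_cm = px_per_cm, vel_thresh = vel_thresh,
                 speed_window_s = speed_window_s, sigma = sigma,
                 dt_ms = dt_ms, dt_delay_ms = dt_delay_ms,
                 transition = transition, ripple = ripple, event = event,
                 center_segments = as.integer(center_segments),
                 seed = as.integer(seed)),
            class = "session_config")
}

## distance (cm) from camera points to the nearest central-box segment
.center_distance <- function(x, y, geometry, center_segments, px_per_cm) {
  x <- x / px_per_cm; y <- y / px_per_cm
  d <- rep(Inf, length(x))
  for (si in center_segments) {
    s <- geometry$segments[si, ]
    dx <- s["x2"] - s["x1"]; dy <- s["y2"] - s["y1"]
    t <- ((x - s["x1"]) * dx + (y - s["y1"]) * dy) / (dx^2 + dy^2)
    t <- pmin(pmax(t, 0), 1)
    d <- pmin(d, sqrt((x - (s["x1"] + t * dx))^2 + (y - (s["y1"] + t * dy))^2))
  }
  d
}

#' Run a replay session
#'
#' Replays the file inputs through encoding, ripple detection, decoding and
#' event detection, writing binary records to `config$output`. Deterministic
#' given identical inputs and configuration.
#'
#' @param config A [session_config()].
#' @return A `session_report`.
#' @export
run_session <- function(config) {
  set.seed(config$seed)
  g <- config$geometry
  tps <- config$ticks_per_s
  boundary <- config$task1_end_s * tps

  pos <- read.csv(config$position)
  spk <- read.csv(config$spikes)
  lfp <- read.csv(config$lfp)
  if (max(pos$timestamp) < boundary || max(lfp$timestamp) < boundary)
    stop("inputs end before the task-1 boundary")

  ## -- position stream: bins and running speed ------------------------------
  pos_bin <- to_bin(pos$segment, pos$norm_pos, g)
  speed <- estimate_speed(pos$timestamp, pos$x, pos$y,
                          px_per_cm = config$px_per_cm,
                          window_s = config$speed_window_s, ticks_per_s = tps)
  pos_dt_s <- stats::median(diff(pos$timestamp)) / tps

  ## -- spike stream: state of the animal at each spike ----------------------
  mark_cols <- grep("^mark_", names(spk), value = TRUE)
  if (!length(mark_cols)) stop("spike file has no mark_* columns")
  marks <- as.matrix(spk[mark_cols])
  ip <- pmax(findInterval(spk$timestamp, pos$timestamp), 1L)
  spk_bin <- pos_bin[ip]
  spk_speed <- speed[ip]
  groups <- sort(unique(spk$electrode_group_id))

  ## -- task 1: train the encoding models ------------------------------------
  in_task1 <- spk$timestamp < boundary
  enc <- in_task1 & spk_speed >= config$vel_thresh
  mv_pos <- pos$timestamp < boundary & speed >= config$vel_thresh
  models <- list()
  for (gid in groups) {
    m <- encoding_model(gid, length(mark_cols), g$n_bins, sigma = config$sigma)
    sel <- enc & spk$electrode_group_id == gid
    if (any(sel)) add_spikes(m, marks[sel, , drop = FALSE], spk_bin[sel])
    observe_position(m, pos_bin[mv_pos], pos_dt_s)
    if (m$n > 0) freeze(m)
    models[[as.character(gid)]] <- m
  }
  active <- names(models)[vapply(models, function(m) m$frozen, logical(1))]
  if (!length(active)) stop("no electrode group had encoding spikes")

  ## -- ripple detection over the LFP ---------------------------------------
  ripple_events <- data.frame(group_id = integer(0),
                              start_timestamp = numeric(0),
                              end_timestamp = numeric(0), peak_z = numeric(0))
  if (!is.null(config$ripple)) {
    for (ch in sort(unique(lfp$group_id))) {
      sel <- lfp$group_id == ch
      r <- detect_ripples(lfp$timestamp[sel], lfp$value[sel], config$ripple,
                          group_id = ch)
      ripple_events <- rbind(ripple_events, r$events)
    }
  }

  ## -- decode task 2 on the LFP clock ---------------------------------------
  dtt <- config$dt_ms / 1000 * tps          # bin size in ticks
  delay <- config$dt_delay_ms / 1000 * tps
  delta_s <- config$dt_ms / 1000
  t0 <- min(lfp$timestamp)
  k_max <- floor((max(lfp$timestamp) - t0) / dtt)
  ## first bin whose spike window lies entirely in task 2
  k_min <- ceiling((boundary - t0 + delay) / dtt) + 1
  if (k_min > k_max) stop("no decodable time bins after the task boundary")
  ks <- k_min:k_max
  n_steps <- length(ks)
  upper <- t0 + ks * dtt - delay            # window right edges (ticks)
  n_bins <- g$n_bins

  ## assign every spike to a window index
  spk_k <- ceiling((spk$timestamp + delay - t0) / dtt)
  usable <- !in_task1 & spk_k >= k_min & spk_k <= k_max &
    spk$electrode_group_id %in% as.integer(active)
  n_decoded <- sum(usable)

  ## per-spike JMI (batched per group), plus arm-specificity for the event rule
  loglam <- matrix(0, n_decoded, n_bins)
  du <- which(usable)
  specific <- logical(n_decoded)
  spec_bins <- if (!is.null(config$event))
    c(config$event$target_bins, config$event$offtarget_bins) + 1L
  for (gid in active) {
    j <- which(spk$electrode_group_id[du] == as.integer(gid))
    if (!length(j)) next
    jmi <- .jmi_block(models[[gid]], marks[du[j], , drop = FALSE])
    loglam[j, ] <- log(jmi * delta_s)
    if (!is.null(config$event)) {
      tot <- rowSums(jmi)
      frac <- ifelse(tot > 0, rowSums(jmi[, spec_bins, drop = FALSE]) / tot, 0)
      specific[j] <- frac > config$event$specificity_frac
    }
  }

  ## log-likelihood per time bin: no-spike baseline + spike contributions
  base_log <- -delta_s *
    Reduce(`+`, lapply(models[active], ground_intensity))
  LL <- matrix(rep(base_log, each = n_steps), n_steps, n_bins)
  row_of <- spk_k[du] - k_min + 1L
  if (n_decoded > 0) {
    agg <- rowsum(loglam, row_of)
    ridx <- as.integer(rownames(agg))
    LL[ridx, ] <- LL[ridx, ] + agg
  }
  spike_count <- tabulate(row_of, nbins = n_steps)

  ## posterior: uniform transition reduces to the normalised likelihood;
  ## other transitions run the forward filter
  mx <- do.call(pmax, as.data.frame(LL))
  lik <- exp(LL - mx)
  if (identical(config$transition, "uniform")) {
    posterior <- lik / rowSums(lik)
  } else {
    posterior <- forward_filter(lik, transition_model(config$transition, n_bins))
  }

  ## animal state at each bin's window edge
  ipb <- pmax(findInterval(upper, pos$timestamp), 1L)
  bin_vel <- speed[ipb]
  bin_true <- pos_bin[ipb]
  n_dropped <- nrow(spk) - sum(enc) - n_decoded

  ## -- event detection -------------------------------------------------------
  events <- data.frame(trigger_timestamp = numeric(0),
                       target_fraction = numeric(0),
                       offtarget_fraction = numeric(0),
                       animal_distance_cm = numeric(0),
                       n_active_groups = integer(0))
  if (!is.null(config$event)) {
    ec <- config$event
    nw <- ec$n_window
    if (n_steps >= nw) {
      roll <- function(v) as.numeric(stats::filter(v, rep(1, nw), sides = 1))
      avg <- apply(posterior, 2, roll)          # rolling sums over the window
      avg <- avg / rowSums(avg)
      tf <- rowSums(avg[, ec$target_bins + 1L, drop = FALSE])
      of <- rowSums(avg[, ec$offtarget_bins + 1L, drop = FALSE])
      dist <- .center_distance(pos$x[ipb], pos$y[ipb], g,
                               config$center_segments, config$px_per_cm)
      ## groups with >=1 arm-specific spike inside the trailing window
      act <- matrix(0L, n_steps, length(active))
      gi <- match(as.character(spk$electrode_group_id[du]), active)
      sel <- specific
      if (any(sel))
        act[cbind(row_of[sel], gi[sel])] <- 1L
      nact <- rowSums(apply(act, 2, roll) > 0)
      ok <- which(seq_len(n_steps) >= nw & !is.na(tf) &
                  tf > ec$target_frac & of < ec$offtarget_frac &
                  dist <= ec$center_radius_cm & nact >= ec$min_active_groups)
      last_t <- -Inf
      for (k in ok) {
        t_s <- upper[k] / tps
        if (t_s - last_t >= ec$refractory_s) {
          events[nrow(events) + 1L, ] <- list(round(upper[k]), tf[k], of[k],
                                              dist[k], as.integer(nact[k]))
          last_t <- t_s
        }
      }
    }
  }

  ## -- records ---------------------------------------------------------------
  pos_labels <- paste0("x", seq_len(n_bins) - 1L)
  schemas <- list(
    record_schema(.REC_DECODER,
                  c("bin_timestamp_l", "bin_timestamp_r", "velocity",
                    "mapped_pos", "spike_count", "task_state",
                    "vel_thresh", "frozen_model", pos_labels),
                  paste0("qqdqqqd?", strrep("d", n_bins))),
    record_schema(.REC_LIKELIHOOD,
                  c("bin_timestamp_l", "bin_timestamp_r", "spike_count",
                    pos_labels),
                  paste0("qqq", strrep("d", n_bins))),
    record_schema(.REC_RIPPLE,
                  c("group_id", "start_timestamp", "end_timestamp", "peak_z"),
                  "iqqd"),
    record_schema(.REC_EVENT,
                  c("trigger_timestamp", "target_fraction",
                    "offtarget_fraction", "animal_distance_cm",
                    "n_active_groups"),
                  "qdddi"),
    record_schema(.REC_DROPPED, c("timestamp", "elec_grp_id"), "qi"))
  w <- record_writer(config$output, schemas)
  dec_df <- data.frame(bl = round(upper - dtt), br = round(upper), vel = bin_vel,
                       mp = bin_true, sc = spike_count, task = 2,
                       vt = config$vel_thresh, fz = TRUE)
  dec_df <- cbind(dec_df, as.data.frame(posterior))
  write_record_block(w, .REC_DECODER, dec_df)
  lik_df <- cbind(data.frame(bl = round(upper - dtt), br = round(upper),
                             sc = spike_count),
                  as.data.frame(lik))
  write_record_block(w, .REC_LIKELIHOOD, lik_df)
  if (nrow(ripple_events)) write_record_block(w, .REC_RIPPLE, ripple_events)
  if (nrow(events)) write_record_block(w, .REC_EVENT, events)
  ## spikes neither encoded nor decoded: late, out-of-window, or filtered
  dropped_i <- setdiff(seq_len(nrow(spk)), c(which(enc), du))
  if (length(dropped_i))
    write_record_block(w, .REC_DROPPED,
                       data.frame(t = spk$timestamp[dropped_i],
                                  g = spk$electrode_group_id[dropped_i]))
  close_records(w)

  structure(list(
    output = config$output,
    counts = c(spikes_ingested = nrow(spk), spikes_encoded = sum(enc),
               spikes_decoded = n_decoded, spikes_dropped = n_dropped,
               posterior_bins = n_steps, ripples = nrow(ripple_events),
               events = nrow(events)),
    groups = as.integer(active),
    ripple_events = ripple_events,
    events = events,
    config = config),
    class = "session_report")
}

#' @export
print.session_report <- function(x, ...) {
  cat("<session_report>\n")
  cat(sprintf("  records: %s\n", x$output))
  for (nm in names(x$counts))
    cat(sprintf("  %-18s %d\n", nm, x$counts[[nm]]))
  invisible(x)
}

#' Summarise decoder output records offline
#'
#' Computes the MAP position bin per record (ties broken to the lowest index
#' and flagged) and, when ground truth is supplied, the absolute decoding
#' error in cm.
#'
#' @param records_path Record file written by [run_session()].
#' @param geometry The session's [track_geometry()].
#' @param truth_position Optional truth data frame (`t_s`, `bin`) or CSV path
#'   as written by [simulate_session()].
#' @param ticks_per_s Acquisition clock rate (default 30,000).
#' @param vel_thresh Movement threshold used for the summary (default 4).
#' @return Data frame with one row per decoded bin (`bin_timestamp_r`,
#'   `map_bin`, `map_tied`, `velocity`, and with truth `true_bin`,
#'   `error_cm`); the median movement-period error is attached as attribute
#'   `median_movement_error_cm` and printed by `summary()`.
#' @export
decode_offline <- function(records_path, geometry, truth_position = NULL,
                           ticks_per_s = 30000, vel_thresh = 4) {
  recs <- read_records(records_path)
  dec <- recs[[as.character(.REC_DECODER)]]
  if (is.null(dec) || nrow(dec) == 0) stop("no decoder output records")
  P <- as.matrix(dec[grep("^x\\d+$", names(dec))])
  map_bin <- max.col(P, ties.method = "first") - 1L
  tied <- apply(P, 1, function(r) sum(r == max(r)) > 1)
  out <- data.frame(bin_timestamp_r = dec$bin_timestamp_r, map_bin = map_bin,
                    map_tied = tied, velocity = dec$velocity)
  if (!is.null(truth_position)) {
    if (is.character(truth_position)) truth_position <- read.csv(truth_position)
    t_s <- dec$bin_timestamp_r / ticks_per_s
    ti <- pmax(findInterval(t_s, truth_position$t_s), 1L)
    out$true_bin <- truth_position$bin[ti]
    out$error_cm <- abs(out$map_bin - out$true_bin) * geometry$bin_size_cm
    mv <- out$velocity >= vel_thresh
    attr(out, "median_movement_error_cm") <- median(out$error_cm[mv])
  }
  out
}
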
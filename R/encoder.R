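## Kernel encoding model for one electrode group.
##
## Learning stores each spike's mark vector together with the position bin the
## animal occupied; no other computation happens during learning. At query
## time the joint mark density at a new mark is a Gaussian-kernel weighted
## histogram of the stored position bins, from which the joint mark intensity
## (JMI) and ground process intensity follow:
##
##   a_o^2 = sum_d (m_od - m_d)^2
##   w_o   = exp(-a_o^2 / (2 sigma^2)) / (sigma sqrt(2 pi))
##   p(x, m) = weighted histogram of stored bins / number stored
##   jmi(x)    = mu * p(x, m) / pi(x)
##   ground(x) = mu * p_spike(x) / pi(x)
##
## where pi(x) is the occupancy (distribution of positions visited during
## encoding, floored before division), p_spike(x) the normalised histogram of
## stored spike positions, and mu the group's mean firing rate.

#' Default mark extraction: per-channel peak amplitude of a waveform snippet
#'
#' @param waveform Numeric matrix (channels x samples) in ADC units.
#' @return Numeric mark vector of length `nrow(waveform)` (the signed value of
#'   largest magnitude per channel).
#' @export
waveform_to_mark <- function(waveform) {
  waveform <- as.matrix(waveform)
  apply(waveform, 1, function(ch) ch[which.max(abs(ch))])
}

#' Create an encoding model for one electrode group
#'
#' @param group_id Integer electrode-group id.
#' @param mark_dim Mark dimensionality D (constant per group).
#' @param n_bins Number of position bins.
#' @param sigma Gaussian kernel bandwidth in mark units (default 20).
#' @param occupancy_smooth_sd_bins Gaussian smoothing applied to the occupancy
#'   histogram, in bins (0 disables; default 1).
#' @param occupancy_floor Additive floor applied to the occupancy before it
#'   divides the intensities (default 1e-12).
#' @return An `encoding_model` (mutable reference object).
#' @export
encoding_model <- function(group_id, mark_dim, n_bins, sigma = 20,
                           occupancy_smooth_sd_bins = 1,
                           occupancy_floor = 1e-12) {
  if (sigma <= 0) stop("configuration error: sigma must be > 0")
  stopifnot(mark_dim >= 1, n_bins >= 1)
  m <- new.env(parent = emptyenv())
  m$group_id <- as.integer(group_id)
  m$mark_dim <- as.integer(mark_dim)
  m$n_bins <- as.integer(n_bins)
  m$sigma <- sigma
  m$occ_smooth <- occupancy_smooth_sd_bins
  m$occ_floor <- occupancy_floor
  m$marks <- matrix(NA_real_, 256L, mark_dim)  # grown by doubling
  m$bins <- integer(256L)
  m$n <- 0L
  m$occ_counts <- numeric(n_bins)
  m$encode_time_s <- 0
  m$frozen <- FALSE
  m$pi_x <- NULL; m$ground <- NULL; m$mu <- NULL
  class(m) <- "encoding_model"
  m
}

#' @export
print.encoding_model <- function(x, ...) {
  cat(sprintf(
    "<encoding_model group %d: %d stored spikes, D = %d, sigma = %g, %s>\n",
    x$group_id, x$n, x$mark_dim, x$sigma,
    if (x$frozen) sprintf("frozen (mu = %.3g spikes/s)", x$mu) else "learning"))
  invisible(x)
}

#' Add one spike's (mark, position bin) pair to the model
#'
#' @param model An [encoding_model()], not frozen.
#' @param mark Numeric mark vector of length `mark_dim`.
#' @param bin 0-based position bin occupied when the spike occurred.
#' @return The model, invisibly (modified in place).
#' @export
add_spike <- function(model, mark, bin) {
  add_spikes(model, matrix(mark, nrow = 1), bin)
}

#' Add a block of spikes (vectorised [add_spike()])
#'
#' @param model An [encoding_model()], not frozen.
#' @param marks Numeric matrix, one mark per row.
#' @param bins 0-based position bins, one per row of `marks`.
#' @export
add_spikes <- function(model, marks, bins) {
  if (model$frozen) stop("state error: model is frozen; spikes are no longer added")
  marks <- as.matrix(marks)
  if (ncol(marks) != model$mark_dim)
    stop("mark dimension mismatch: expected ", model$mark_dim,
         ", got ", ncol(marks))
  bins <- as.integer(bins)
  if (length(bins) != nrow(marks)) stop("marks/bins length mismatch")
  if (any(bins < 0 | bins >= model$n_bins)) stop("bin out of range")
  need <- model$n + nrow(marks)
  while (need > nrow(model$marks)) {
    model$marks <- rbind(model$marks,
                         matrix(NA_real_, nrow(model$marks), model$mark_dim))
    model$bins <- c(model$bins, integer(length(model$bins)))
  }
  idx <- (model$n + 1L):need
  model$marks[idx, ] <- marks
  model$bins[idx] <- bins
  model$n <- need
  invisible(model)
}

#' Accumulate occupancy from a position sample taken during encoding
#'
#' Call once per movement-period position sample; `dt_s` also accumulates the
#' total encoding time that scales the group's mean rate.
#'
#' @param model An [encoding_model()], not frozen.
#' @param bin 0-based occupied bin (vectorised).
#' @param dt_s Duration each sample represents, in seconds.
#' @export
observe_position <- function(model, bin, dt_s) {
  if (model$frozen) stop("state error: model is frozen")
  bin <- as.integer(bin)
  model$occ_counts <- model$occ_counts +
    tabulate(bin + 1L, nbins = model$n_bins)
  model$encode_time_s <- model$encode_time_s + sum(rep(dt_s, length.out = length(bin)))
  invisible(model)
}

## Gaussian smoothing of a bin histogram (reflected ends), sd in bins
.smooth_bins <- function(v, sd_bins) {
  if (sd_bins <= 0) return(v)
  h <- max(1L, ceiling(3 * sd_bins))
  k <- dnorm(-h:h, sd = sd_bins); k <- k / sum(k)
  padded <- c(rev(v[seq_len(h)]), v, rev(v[(length(v) - h + 1):length(v)]))
  as.numeric(stats::filter(padded, k, sides = 2))[(h + 1):(h + length(v))]
}

#' Freeze an encoding model
#'
#' Finalises occupancy, spike-position distribution and mean rate; further
#' [add_spike()] calls are an error while queries keep using the fixed set.
#' Freezing twice is a no-op.
#'
#' @param model An [encoding_model()] with at least one stored spike.
#' @param mean_rate Optional override for the group mean rate in spikes/s;
#'   defaults to stored spikes divided by accumulated encoding time.
#' @param occupancy Optional explicit occupancy distribution over bins;
#'   defaults to the (smoothed, floored, normalised) accumulated histogram, or
#'   uniform when no positions were observed.
#' @export
freeze <- function(model, mean_rate = NULL, occupancy = NULL) {
  if (model$frozen) return(invisible(model))
  if (model$n == 0L) stop("cannot freeze an empty model (no encoding data)")
  if (is.null(occupancy)) {
    occupancy <- if (sum(model$occ_counts) > 0)
      .smooth_bins(model$occ_counts, model$occ_smooth)
    else rep(1, model$n_bins)
  }
  stopifnot(length(occupancy) == model$n_bins)
  if (sum(occupancy) <= 0) stop("all-zero occupancy")
  occupancy <- occupancy / sum(occupancy)
  model$pi_x <- occupancy
  g <- tabulate(model$bins[seq_len(model$n)] + 1L, nbins = model$n_bins)
  model$ground <- g / sum(g)
  if (is.null(mean_rate)) {
    if (model$encode_time_s <= 0)
      stop("no encoding time accumulated; supply mean_rate")
    mean_rate <- model$n / model$encode_time_s
  }
  model$mu <- mean_rate
  model$frozen <- TRUE
  invisible(model)
}

#' Gaussian kernel weights of a query mark against the stored marks
#'
#' `w_o = exp(-sum_d (m_od - m_d)^2 / (2 sigma^2)) / (sigma sqrt(2 pi))`.
#'
#' @param model A non-empty [encoding_model()].
#' @param mark Query mark of length `mark_dim`.
#' @return Numeric weights, one per stored spike.
#' @export
kernel_weights <- function(model, mark) {
  if (model$n == 0L) stop("empty model")
  if (length(mark) != model$mark_dim) stop("mark dimension mismatch")
  M <- model$marks[seq_len(model$n), , drop = FALSE]
  a2 <- colSums((t(M) - as.numeric(mark))^2)
  exp(-a2 / (2 * model$sigma^2)) / (model$sigma * sqrt(2 * pi))
}

## weighted histogram of stored bins, length n_bins
.whist <- function(w, bins0, n_bins) {
  v <- numeric(n_bins)
  agg <- rowsum(w, bins0)
  v[as.integer(rownames(agg)) + 1L] <- agg
  v
}

#' Joint mark density estimate at a query mark
#'
#' Weighted histogram of the stored position bins using [kernel_weights()],
#' divided by the number of stored spikes.
#'
#' @inheritParams kernel_weights
#' @return Non-negative vector over all position bins.
#' @export
joint_mark_density <- function(model, mark) {
  w <- kernel_weights(model, mark)
  .whist(w, model$bins[seq_len(model$n)], model$n_bins) / model$n
}

#' Joint mark intensity and ground process intensity at a query mark
#'
#' @param model A frozen [encoding_model()].
#' @param mark Query mark.
#' @return List with `jmi` (spikes/s per mark, over bins) and `ground`
#'   (spikes/s over bins).
#' @export
intensities <- function(model, mark) {
  if (!model$frozen) stop("state error: freeze the model before querying intensities")
  pif <- model$pi_x + model$occ_floor
  list(jmi = model$mu * joint_mark_density(model, mark) / pif,
       ground = model$mu * model$ground / pif)
}

#' Ground process intensity of a frozen model
#' @param model A frozen [encoding_model()].
#' @return Vector over bins, spikes/s.
#' @export
ground_intensity <- function(model) {
  if (!model$frozen) stop("state error: model not frozen")
  model$mu * model$ground / (model$pi_x + model$occ_floor)
}

## Batched JMI for many query marks: BLAS distance computation, chunked to
## bound memory. Returns n_query x n_bins matrix.
.jmi_block <- function(model, marks, chunk = 1024L) {
  if (!model$frozen) stop("state error: model not frozen")
  nq <- nrow(marks)
  M <- model$marks[seq_len(model$n), , drop = FALSE]
  Ind <- outer(model$bins[seq_len(model$n)], 0:(model$n_bins - 1L), "==") * 1
  pif <- model$pi_x + model$occ_floor
  sM <- rowSums(M^2)
  out <- matrix(0, nq, model$n_bins)
  for (s in seq(1L, nq, by = chunk)) {
    e <- min(s + chunk - 1L, nq)
    Q <- marks[s:e, , drop = FALSE]
    a2 <- outer(rowSums(Q^2), rep(1, model$n)) +
          outer(rep(1, e - s + 1L), sM) - 2 * tcrossprod(Q, M)
    W <- exp(-pmax(a2, 0) / (2 * model$sigma^2)) / (model$sigma * sqrt(2 * pi))
    out[s:e, ] <- sweep((W %*% Ind) / model$n, 2, pif, "/") * model$mu
  }
  out
}

#' Save / load an encoding model (JSON, full precision)
#'
#' @param model An [encoding_model()].
#' @param path File path.
#' @export
write_encoding_model <- function(model, path) {
  jsonlite::write_json(list(
    group_id = model$group_id, mark_dim = model$mark_dim,
    n_bins = model$n_bins, sigma = model$sigma,
    occ_smooth = model$occ_smooth, occ_floor = model$occ_floor,
    marks = model$marks[seq_len(model$n), , drop = FALSE],
    bins = model$bins[seq_len(model$n)],
    occ_counts = model$occ_counts, encode_time_s = model$encode_time_s,
    frozen = model$frozen, pi_x = model$pi_x, ground = model$ground,
    mu = model$mu), path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_encoding_model
#' @export
read_encoding_model <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- encoding_model(d$group_id, d$mark_dim, d$n_bins, d$sigma,
                      d$occ_smooth, d$occ_floor)
  if (length(d$bins))
    add_spikes(m, matrix(d$marks, ncol = d$mark_dim), d$bins)
  m$occ_counts <- as.numeric(d$occ_counts)
  m$encode_time_s <- d$encode_time_s
  if (isTRUE(d$frozen)) {
    m$pi_x <- as.numeric(d$pi_x); m$ground <- as.numeric(d$ground)
    m$mu <- d$mu; m$frozen <- TRUE
  }
  m
}
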
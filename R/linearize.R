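## Track linearization: 2D tracked points are projected onto user-defined line
## segments and mapped to 1D position bins (default 5 cm) that form the
## decoder's support.

#' Define track geometry
#'
#' @param segments Numeric matrix with columns `x1,y1,x2,y2` (cm), one row per
#'   track segment, in bin order.
#' @param bin_size_cm Width of one position bin in cm (default 5).
#' @param bins_per_segment Integer bins spanned by each segment; defaults to
#'   segment length divided by `bin_size_cm`, rounded. Each segment length
#'   must agree with `bins_per_segment * bin_size_cm` to within one bin.
#' @return A `track_geometry`.
#' @export
track_geometry <- function(segments, bin_size_cm = 5, bins_per_segment = NULL) {
  segments <- matrix(as.numeric(as.matrix(segments)), ncol = 4,
                     dimnames = list(NULL, c("x1", "y1", "x2", "y2")))
  if (nrow(segments) < 1) stop("configuration error: empty geometry")
  len <- sqrt((segments[, "x2"] - segments[, "x1"])^2 +
              (segments[, "y2"] - segments[, "y1"])^2)
  if (is.null(bins_per_segment)) bins_per_segment <- round(len / bin_size_cm)
  bins_per_segment <- as.integer(bins_per_segment)
  if (any(bins_per_segment < 1)) stop("each segment must span >= 1 bin")
  if (any(abs(len - bins_per_segment * bin_size_cm) > bin_size_cm))
    stop("segment length inconsistent with bins_per_segment * bin_size_cm")
  structure(list(segments = segments, lengths = len,
                 bins_per_segment = bins_per_segment,
                 bin_size_cm = bin_size_cm,
                 offsets = c(0L, cumsum(bins_per_segment))[seq_len(nrow(segments))],
                 n_bins = sum(bins_per_segment)),
            class = "track_geometry")
}

#' Position-bin grid implied by a geometry
#'
#' Bins are 0-based with half-open intervals; bin `b` of a grid with bin size
#' `s` covers linearized `[b*s, (b+1)*s)` cm.
#'
#' @param geometry A [track_geometry()].
#' @return A `position_grid` with `n_bins`, `bin_size_cm` and a bin-to-segment
#'   lookup.
#' @export
position_grid <- function(geometry) {
  seg_of_bin <- rep(seq_len(nrow(geometry$segments)), geometry$bins_per_segment)
  structure(list(n_bins = geometry$n_bins,
                 bin_size_cm = geometry$bin_size_cm,
                 segment_of_bin = seg_of_bin),
            class = "position_grid")
}

#' Project a 2D point onto the nearest track segment
#'
#' The nearest segment minimises the clamped-projection (point-to-segment)
#' distance; the returned normalised position is the projection parameter
#' clamped to \[0, 1\].
#'
#' @param point Numeric `c(x, y)` in cm.
#' @param geometry A [track_geometry()].
#' @return List with `segment` (1-based), `norm_pos`, and `distance_cm`.
#' @export
linearize <- function(point, geometry) {
  if (!all(is.finite(point))) stop("point must be finite")
  s <- geometry$segments
  dx <- s[, "x2"] - s[, "x1"]; dy <- s[, "y2"] - s[, "y1"]
  t <- ((point[1] - s[, "x1"]) * dx + (point[2] - s[, "y1"]) * dy) /
       (dx^2 + dy^2)
  t <- pmin(pmax(t, 0), 1)
  px <- s[, "x1"] + t * dx; py <- s[, "y1"] + t * dy
  d <- sqrt((point[1] - px)^2 + (point[2] - py)^2)
  i <- which.min(d)
  list(segment = i, norm_pos = t[i], distance_cm = d[i])
}

#' Map (segment, normalised position) to a 0-based position bin
#'
#' `bin = offset(segment) + floor(norm_pos * bins_per_segment)`, with
#' `norm_pos = 1` clamped to the segment's last bin.
#'
#' @param segment 1-based segment index (vectorised).
#' @param norm_pos Normalised position in \[0, 1\] (vectorised).
#' @param geometry A [track_geometry()].
#' @return Integer bin index (0-based).
#' @export
to_bin <- function(segment, norm_pos, geometry) {
  segment <- as.integer(segment)
  if (any(segment < 1 | segment > nrow(geometry$segments)))
    stop("unknown segment")
  if (any(norm_pos < 0 | norm_pos > 1)) stop("norm_pos must be in [0, 1]")
  bps <- geometry$bins_per_segment[segment]
  off <- geometry$offsets[segment]
  as.integer(off + pmin(floor(norm_pos * bps), bps - 1L))
}

#' Linearized position in cm for (segment, norm_pos)
#'
#' Positions are measured along the concatenated bin axis, consistent with
#' [to_bin()]: a point at linearized `g` cm falls in bin
#' `floor(g / bin_size_cm)`.
#'
#' @inheritParams to_bin
#' @return Numeric cm along the linearized axis.
#' @export
linear_cm <- function(segment, norm_pos, geometry) {
  (geometry$offsets[as.integer(segment)] +
     norm_pos * geometry$bins_per_segment[as.integer(segment)]) *
    geometry$bin_size_cm
}

## centered boxcar with replicated-end padding; w forced odd
.boxcar <- function(v, w) {
  w <- max(1L, as.integer(w)); if (w %% 2L == 0L) w <- w + 1L
  if (w == 1L || length(v) == 1L) return(v)
  h <- (w - 1L) %/% 2L
  padded <- c(rep(v[1], h), v, rep(v[length(v)], h))
  as.numeric(stats::filter(padded, rep(1 / w, w), sides = 2))[(h + 1):(h + length(v))]
}

#' Estimate running speed from tracked positions
#'
#' Finite-difference speed smoothed with a centered boxcar. Speeds are
#' non-negative; a single sample yields `NA` (undefined).
#'
#' @param timestamps Sample times in seconds (or ticks; see `ticks_per_s`).
#' @param x,y Tracked coordinates in pixels.
#' @param px_per_cm Pixel-to-cm scale (default 1).
#' @param window_s Boxcar window in seconds (default 0.25).
#' @param ticks_per_s If `timestamps` are clock ticks, the tick rate.
#' @return Numeric speed in cm/s per sample.
#' @export
estimate_speed <- function(timestamps, x, y, px_per_cm = 1, window_s = 0.25,
                           ticks_per_s = 1) {
  n <- length(timestamps)
  if (n < 2) return(rep(NA_real_, n))
  t_s <- as.numeric(timestamps) / ticks_per_s
  d <- sqrt(diff(x)^2 + diff(y)^2) / px_per_cm
  raw <- c(NA_real_, d / diff(t_s))
  raw[1] <- raw[2]
  dt <- stats::median(diff(t_s))
  .boxcar(raw, round(window_s / dt))
}
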
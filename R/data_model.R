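## Streamed sample types and file-backed replay sources.
##
## File replay stands in for live acquisition: a source reads a CSV, is
## activated, and hands out one typed sample per call in timestamp order.
## Timestamps are acquisition clock ticks (e.g. 30,000 per second).

#' Spike event
#'
#' @param timestamp Acquisition clock ticks (non-negative).
#' @param electrode_group_id Integer electrode-group (e.g. tetrode) id.
#' @param mark Numeric feature vector (e.g. per-channel peak amplitudes), or
#'   `NULL` if `waveform` is given.
#' @param waveform Numeric matrix (channels x samples) in ADC units, or `NULL`.
#' @param t_send,t_recv Optional nanosecond wall-clock diagnostics.
#' @return A `spike_event`.
#' @export
spike_event <- function(timestamp, electrode_group_id, mark = NULL,
                        waveform = NULL, t_send = NA_real_, t_recv = NA_real_) {
  stopifnot(timestamp >= 0)
  if (is.null(mark) && is.null(waveform))
    stop("one of mark/waveform is required")
  if (!is.null(mark) && length(mark) < 1) stop("mark must have D >= 1")
  structure(list(timestamp = timestamp,
                 electrode_group_id = as.integer(electrode_group_id),
                 mark = mark, waveform = waveform,
                 t_send = t_send, t_recv = t_recv),
            class = "spike_event")
}

#' LFP sample
#'
#' @param timestamp Acquisition clock ticks.
#' @param electrode_group_ids Integer vector of group ids carried.
#' @param values Numeric voltages, one per listed group.
#' @param t_send,t_recv Optional diagnostics.
#' @return An `lfp_sample`.
#' @export
lfp_sample <- function(timestamp, electrode_group_ids, values,
                       t_send = NA_real_, t_recv = NA_real_) {
  if (length(values) != length(electrode_group_ids))
    stop("values and electrode_group_ids lengths differ")
  structure(list(timestamp = timestamp,
                 electrode_group_ids = as.integer(electrode_group_ids),
                 values = as.numeric(values),
                 t_send = t_send, t_recv = t_recv),
            class = "lfp_sample")
}

#' Tracked position sample
#'
#' @param timestamp Acquisition clock ticks.
#' @param segment Integer track-segment index (1-based).
#' @param norm_pos Normalised position along the segment, in \[0, 1\].
#' @param x,y,x2,y2 Pixel coordinates of the two tracked points.
#' @param t_recv Optional diagnostic.
#' @return A `position_sample`.
#' @export
position_sample <- function(timestamp, segment, norm_pos, x = NA_real_,
                            y = NA_real_, x2 = NA_real_, y2 = NA_real_,
                            t_recv = NA_real_) {
  if (norm_pos < 0 || norm_pos > 1) stop("norm_pos must be in [0, 1]")
  structure(list(timestamp = timestamp, segment = as.integer(segment),
                 norm_pos = norm_pos, x = x, y = y, x2 = x2, y2 = y2,
                 t_recv = t_recv),
            class = "position_sample")
}

## -- sources ----------------------------------------------------------------

## Merge tie-break priority at equal timestamps: LFP, then position, then
## spikes; stable within a type.
.SOURCE_PRIORITY <- c(lfp = 1L, position = 2L, spikes = 3L)

#' Open a file-backed sample source
#'
#' The CSV dialects are: spikes `timestamp,electrode_group_id,mark_0..mark_{D-1}`;
#' LFP `timestamp,group_id,value`; position
#' `timestamp,segment,norm_pos,x,y,x2,y2`. Rows must be sorted by timestamp.
#' The source must be activated before it yields samples and spike/LFP sources
#' must have at least one electrode group registered.
#'
#' @param path CSV file path.
#' @param type One of `"spikes"`, `"lfp"`, `"position"`.
#' @return A `data_source`.
#' @seealso [next_sample()], [activate()], [register_groups()]
#' @export
data_source <- function(path, type = c("spikes", "lfp", "position")) {
  type <- match.arg(type)
  src <- new.env(parent = emptyenv())
  src$path <- path
  src$type <- type
  src$active <- FALSE
  src$groups <- integer(0)
  src$rows <- NULL
  src$idx <- 0L
  class(src) <- c(paste0(type, "_source"), "data_source")
  src
}

#' Register electrode groups a source should deliver
#' @param source A [data_source()].
#' @param group_ids Integer group ids.
#' @export
register_groups <- function(source, group_ids) {
  source$groups <- unique(c(source$groups, as.integer(group_ids)))
  invisible(source)
}

#' Activate / deactivate a source
#'
#' A deactivated source always yields `NULL` from [next_sample()].
#' @param source A [data_source()] or [merged_source()].
#' @export
activate <- function(source) { source$active <- TRUE; invisible(source) }

#' @rdname activate
#' @export
deactivate <- function(source) { source$active <- FALSE; invisible(source) }

.load_rows <- function(source) {
  if (!is.null(source$rows)) return(invisible(source))
  rows <- read.csv(source$path)
  need <- switch(source$type,
    spikes = c("timestamp", "electrode_group_id"),
    lfp = c("timestamp", "group_id", "value"),
    position = c("timestamp", "segment", "norm_pos", "x", "y", "x2", "y2"))
  if (!all(need %in% names(rows)))
    stop("parse error in ", source$path, ": missing column(s) ",
         paste(setdiff(need, names(rows)), collapse = ", "))
  bad <- which(!stats::complete.cases(rows[need]))
  if (length(bad))
    stop("parse error in ", source$path, " line ", bad[1] + 1L,
         ": malformed row")
  if (source$type == "spikes" &&
      !any(grepl("^mark_", names(rows))))
    stop("parse error in ", source$path, ": no mark_* columns")
  if (is.unsorted(rows$timestamp))
    rows <- rows[order(rows$timestamp), , drop = FALSE]
  source$rows <- rows
  invisible(source)
}

.row_to_sample <- function(source, i) {
  r <- source$rows[i, ]
  switch(source$type,
    spikes = spike_event(r$timestamp, r$electrode_group_id,
                         mark = as.numeric(unlist(r[grepl("^mark_", names(r))]))),
    lfp = lfp_sample(r$timestamp, r$group_id, r$value),
    position = position_sample(r$timestamp, r$segment, r$norm_pos,
                               r$x, r$y, r$x2, r$y2))
}

#' Pull the next sample from a source
#'
#' Returns samples in timestamp order, each exactly once; `NULL` when the
#' source is deactivated or exhausted.
#'
#' @param source A [data_source()] or [merged_source()].
#' @return A typed sample object, or `NULL`.
#' @export
next_sample <- function(source) UseMethod("next_sample")

#' @export
next_sample.data_source <- function(source) {
  if (!source$active) return(NULL)
  if (source$type %in% c("spikes", "lfp") && length(source$groups) == 0)
    stop("configuration error: no electrode groups registered for ",
         source$type, " source")
  .load_rows(source)
  repeat {
    if (source$idx >= nrow(source$rows)) return(NULL)
    source$idx <- source$idx + 1L
    s <- .row_to_sample(source, source$idx)
    ok <- switch(source$type,
      spikes = s$electrode_group_id %in% source$groups,
      lfp = all(s$electrode_group_ids %in% source$groups),
      position = TRUE)
    if (ok) return(s)
  }
}

#' Merge several sources into one timestamp-ordered stream
#'
#' Ties at equal timestamps are broken LFP before position before spikes,
#' stable within a type, so replay order is deterministic.
#'
#' @param ... [data_source()] objects (each sorted by timestamp).
#' @return A `merged_source`; use [next_sample()] on it.
#' @export
merged_source <- function(...) {
  sources <- list(...)
  stopifnot(length(sources) >= 1)
  m <- new.env(parent = emptyenv())
  m$sources <- sources
  m$pending <- vector("list", length(sources))  # one look-ahead per source
  m$active <- TRUE
  class(m) <- "merged_source"
  m
}

#' @export
next_sample.merged_source <- function(source) {
  if (!source$active) return(NULL)
  for (i in seq_along(source$sources))
    if (is.null(source$pending[[i]]))
      source$pending[i] <- list(next_sample(source$sources[[i]]))
  ts <- vapply(source$pending,
               function(s) if (is.null(s)) Inf else s$timestamp, numeric(1))
  if (all(is.infinite(ts))) return(NULL)
  pri <- vapply(source$sources,
                function(s) .SOURCE_PRIORITY[[s$type]], integer(1))
  best <- order(ts, pri)[1]
  out <- source$pending[[best]]
  source$pending[best] <- list(NULL)
  out
}
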
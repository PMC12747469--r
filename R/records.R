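## Binary results records.
##
## Every record on disk is a 4-byte little-endian record-type id followed by
## its fields packed per the schema's format codes:
##   'q' 64-bit signed integer, 'd' 64-bit IEEE double, 'i' 32-bit signed
##   integer, '?' one-byte boolean.
## Schemas are stored in a JSON sidecar (<path>.json) so files are
## self-describing. 'q' values are carried as R doubles and are exact for
## magnitudes up to 2^53, which covers acquisition-clock tick counts.

.FMT_WIDTH <- c(q = 8L, d = 8L, i = 4L, "?" = 1L)

#' Define a record schema
#'
#' @param rec_id Integer record-type identifier, unique within a writer.
#' @param labels Character vector of field names.
#' @param format_codes Per-field binary type codes, either a character vector
#'   or a single string such as `"qiii"`. Codes: `q` 64-bit signed integer,
#'   `d` double, `i` 32-bit signed integer, `?` boolean.
#' @return A `record_schema` object.
#' @export
record_schema <- function(rec_id, labels, format_codes) {
  if (length(format_codes) == 1 && nchar(format_codes) > 1)
    format_codes <- strsplit(format_codes, "")[[1]]
  format_codes <- as.character(format_codes)
  if (!all(format_codes %in% names(.FMT_WIDTH)))
    stop("unknown format code(s): ",
         paste(setdiff(format_codes, names(.FMT_WIDTH)), collapse = ", "))
  if (length(labels) != length(format_codes))
    stop("schema error: ", length(labels), " labels but ",
         length(format_codes), " format codes")
  structure(list(rec_id = as.integer(rec_id), labels = as.character(labels),
                 format_codes = format_codes,
                 payload_bytes = sum(.FMT_WIDTH[format_codes])),
            class = "record_schema")
}

## -- low-level packing ------------------------------------------------------

## 64-bit signed integers as two 32-bit words; exact for |v| <= 2^53
.pack_q <- function(v) {
  v <- as.numeric(v)
  if (any(!is.finite(v)) || any(v != trunc(v)) || any(abs(v) > 2^53))
    stop("type error: 'q' field requires integer-valued finite numbers (|v| <= 2^53)")
  lo <- v %% 2^32
  hi <- floor(v / 2^32) %% 2^32
  word_bytes <- function(w)
    rbind(as.raw(w %% 256), as.raw(floor(w / 256) %% 256),
          as.raw(floor(w / 65536) %% 256), as.raw(floor(w / 16777216) %% 256))
  rbind(word_bytes(lo), word_bytes(hi))
}

.unpack_q <- function(bytes8) {  # bytes8: raw matrix 8 x n
  b <- matrix(as.numeric(bytes8), nrow = 8)
  lo <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ] + 16777216 * b[4, ]
  hi <- b[5, ] + 256 * b[6, ] + 65536 * b[7, ] + 16777216 * b[8, ]
  hi <- ifelse(hi >= 2^31, hi - 2^32, hi)
  hi * 2^32 + lo
}

.pack_i <- function(v) {
  v <- as.numeric(v)
  if (any(!is.finite(v)) || any(v != trunc(v)) || any(abs(v) > 2^31 - 1))
    stop("type error: 'i' field requires 32-bit integer values")
  matrix(writeBin(as.integer(v), raw(), size = 4L, endian = "little"), nrow = 4)
}

.pack_field <- function(code, v, n) {
  switch(code,
    q = .pack_q(v),
    d = matrix(writeBin(as.numeric(v), raw(), size = 8L, endian = "little"),
               nrow = 8),
    i = .pack_i(v),
    "?" = matrix(as.raw(as.logical(v)), nrow = 1))
}

## -- writer -----------------------------------------------------------------

#' Open a binary record writer
#'
#' Creates (truncates) the record file and writes the JSON schema sidecar
#' `<path>.json`.
#'
#' @param path Output file path.
#' @param schemas List of [record_schema()] objects.
#' @return A `record_writer`; close it with [close_records()].
#' @seealso [write_record()], [read_records()]
#' @export
record_writer <- function(path, schemas) {
  if (inherits(schemas, "record_schema")) schemas <- list(schemas)
  ids <- vapply(schemas, function(s) s$rec_id, integer(1))
  if (anyDuplicated(ids)) stop("rec_id must be unique within a writer")
  names(schemas) <- as.character(ids)
  sidecar <- lapply(schemas, function(s)
    list(rec_id = s$rec_id, labels = s$labels,
         format = paste(s$format_codes, collapse = "")))
  jsonlite::write_json(unname(sidecar), paste0(path, ".json"),
                       auto_unbox = TRUE)
  w <- new.env(parent = emptyenv())
  w$path <- path
  w$schemas <- schemas
  w$con <- file(path, "wb")
  class(w) <- "record_writer"
  w
}

#' Append one record
#'
#' Values are packed little-endian per the schema's format codes, prefixed by
#' the 4-byte record id, and appended to the file.
#'
#' @param writer A [record_writer()].
#' @param rec_id Registered record-type id.
#' @param values Field values, in schema order (list or vector).
#' @return Invisibly, the number of bytes appended (4-byte id + payload).
#' @export
write_record <- function(writer, rec_id, values) {
  df <- as.data.frame(lapply(values, function(v) v))
  names(df) <- NULL
  write_record_block(writer, rec_id, df)
}

#' Append a block of records of one type (vectorised)
#'
#' @param writer A [record_writer()].
#' @param rec_id Registered record-type id.
#' @param data Data frame or matrix; one row per record, columns in schema
#'   order.
#' @return Invisibly, the number of bytes appended.
#' @export
write_record_block <- function(writer, rec_id, data) {
  sch <- writer$schemas[[as.character(rec_id)]]
  if (is.null(sch))
    stop("rec_id ", rec_id, " not registered; known: ",
         paste(names(writer$schemas), collapse = ", "))
  data <- as.data.frame(data)
  if (ncol(data) != length(sch$format_codes))
    stop("schema error: record has ", length(sch$format_codes),
         " fields, got ", ncol(data))
  n <- nrow(data)
  if (n == 0) return(invisible(0L))
  parts <- vector("list", ncol(data) + 1L)
  parts[[1]] <- .pack_i(rep(sch$rec_id, n))
  for (f in seq_along(sch$format_codes))
    parts[[f + 1L]] <- .pack_field(sch$format_codes[f], data[[f]], n)
  blob <- as.vector(do.call(rbind, parts))
  writeBin(blob, writer$con)
  invisible(length(blob))
}

#' Close a record writer
#' @param writer A [record_writer()].
#' @export
close_records <- function(writer) {
  close(writer$con)
  invisible(writer$path)
}

## -- reader -----------------------------------------------------------------

#' Read a binary record file
#'
#' Returns one data frame per record type, with columns named by the schema
#' labels and rows in write order. A truncated trailing record is dropped with
#' a warning.
#'
#' @param path Record file written by [write_record()]; the `<path>.json`
#'   sidecar must be present.
#' @return Named list of data frames, keyed by record id.
#' @export
read_records <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  schemas <- lapply(seq_len(nrow(side)), function(i)
    record_schema(side$rec_id[i], side$labels[[i]], side$format[i]))
  names(schemas) <- as.character(vapply(schemas, `[[`, integer(1), "rec_id"))

  raw <- readBin(path, "raw", file.size(path))
  nb <- length(raw)
  k <- 0L; cap <- 1024L; ids <- integer(cap); offs <- numeric(cap)
  pos <- 1
  widths <- vapply(schemas, `[[`, numeric(1), "payload_bytes")
  while (pos <= nb) {
    if (pos + 3 > nb) break  # truncated id
    id4 <- as.numeric(raw[pos:(pos + 3)])
    id <- id4[1] + 256 * id4[2] + 65536 * id4[3] + 16777216 * id4[4]
    if (id >= 2^31) id <- id - 2^32
    key <- as.character(id)
    if (is.null(schemas[[key]]))
      stop("unknown rec_id ", id, " at byte ", pos - 1, "; known ids: ",
           paste(names(schemas), collapse = ", "))
    if (pos + 3 + widths[[key]] > nb) break  # truncated payload
    k <- k + 1L
    if (k > cap) { cap <- cap * 2L; length(ids) <- cap; length(offs) <- cap }
    ids[k] <- as.integer(id); offs[k] <- pos + 4
    pos <- pos + 4 + widths[[key]]
  }
  if (pos <= nb)
    warning("truncated trailing record dropped (", nb - pos + 1, " bytes)")
  ids <- ids[seq_len(k)]; offs <- offs[seq_len(k)]

  res <- list()
  for (key in names(schemas)) {
    s <- schemas[[key]]
    ro <- offs[ids == s$rec_id]
    cols <- vector("list", length(s$labels)); names(cols) <- s$labels
    fo <- 0
    for (f in seq_along(s$format_codes)) {
      code <- s$format_codes[f]; wdt <- .FMT_WIDTH[[code]]
      if (length(ro) == 0) {
        cols[[f]] <- if (code == "?") logical(0) else numeric(0)
      } else {
        idx <- as.vector(t(outer(ro + fo, 0:(wdt - 1), "+")))
        bytes <- raw[idx]
        cols[[f]] <- switch(code,
          q = .unpack_q(matrix(bytes, nrow = 8)),
          d = readBin(bytes, "double", n = length(ro), size = 8L,
                      endian = "little"),
          i = readBin(bytes, "integer", n = length(ro), size = 4L,
                      endian = "little"),
          "?" = as.logical(as.integer(bytes)))
      }
      fo <- fo + wdt
    }
    res[[key]] <- as.data.frame(cols, optional = TRUE)
  }
  res
}
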
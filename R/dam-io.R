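# TriKinetics DAM monitor file reader/writer.
#
# A monitor file is tab-separated with 42 columns per row: reading index,
# date (dd mmm yy), time (HH:MM:SS), recording status (1 = valid), six
# device/metadata fields, then one beam-crossing count per each of the 32
# channels.

DAM_META_COLS <- 10L
DAM_CHANNELS <- 32L

#' Read a TriKinetics DAM monitor file
#'
#' @param path path to a monitor text file.
#' @return list of class `dam_monitor` with `counts` (integer matrix,
#'   readings x 32 channels), `datetime` (character `"date time"` stamps),
#'   `status` (integer), and `bad_rows` (indices of readings whose status is
#'   not 1; these are flagged, not dropped).
#' @export
read_dam_monitor <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty DAM monitor file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  expected <- DAM_META_COLS + DAM_CHANNELS
  bad <- which(nf != expected)
  if (length(bad))
    stop("malformed DAM monitor row(s) at line ", bad[1], ": expected ",
         expected, " tab-separated fields, found ", nf[bad[1]])
  m <- do.call(rbind, parts)
  counts <- m[, DAM_META_COLS + seq_len(DAM_CHANNELS), drop = FALSE]
  suppressWarnings(storage <- matrix(as.integer(counts), nrow = nrow(m)))
  if (anyNA(storage)) stop("non-integer count field in DAM monitor file")
  if (any(storage < 0)) stop("negative count in DAM monitor file")
  status <- suppressWarnings(as.integer(m[, 4]))
  colnames(storage) <- sprintf("ch%02d", seq_len(DAM_CHANNELS))
  structure(list(counts = storage,
                 datetime = paste(m[, 2], m[, 3]),
                 status = status,
                 bad_rows = which(is.na(status) | status != 1L)),
            class = "dam_monitor")
}

#' @export
print.dam_monitor <- function(x, ...) {
  cat(sprintf("<dam_monitor> %d readings x %d channels (%d flagged rows)\n",
              nrow(x$counts), ncol(x$counts), length(x$bad_rows)))
  invisible(x)
}

#' Write a TriKinetics DAM monitor file
#'
#' Inverse of [read_dam_monitor()], used to build fixtures: counts round-trip
#' through the reader unchanged.
#'
#' @param counts integer matrix, readings x 32 channels (columns recycled /
#'   zero-padded to 32 if fewer are given).
#' @param path output path.
#' @param start date-time of the first reading (`POSIXct` or string
#'   understood by `as.POSIXct`).
#' @param bin_s seconds between readings (DAM hardware: 20 s).
#' @param status recording-status column (recycled; 1 = valid).
#' @return `path`, invisibly.
#' @export
write_dam_monitor <- function(counts, path, start = "2024-01-01 08:00:00",
                              bin_s = 20, status = 1L) {
  counts <- as.matrix(counts)
  if (ncol(counts) > DAM_CHANNELS) stop("at most 32 channels")
  if (ncol(counts) < DAM_CHANNELS)
    counts <- cbind(counts, matrix(0L, nrow(counts),
                                   DAM_CHANNELS - ncol(counts)))
  n <- nrow(counts)
  tt <- as.POSIXct(start, tz = "UTC") + (seq_len(n) - 1) * bin_s
  rows <- cbind(seq_len(n),
                toupper(format(tt, "%d %b %y")),
                format(tt, "%H:%M:%S"),
                rep_len(status, n),
                matrix("0", n, DAM_META_COLS - 4L),
                counts)
  writeLines(apply(rows, 1, paste, collapse = "\t"), path)
  invisible(path)
}
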
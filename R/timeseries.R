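#' Uniformly sampled channel time series
#'
#' Lightweight container for a single channel: a numeric vector carrying its
#' sampling rate (Hz) and a channel label as attributes. All estimators in the
#' package accept either an `fc_ts` object or a plain numeric vector together
#' with an `fs` argument.
#'
#' @param values numeric vector of samples (arbitrary units); must be finite
#'   and of length at least 2.
#' @param fs sampling rate in Hz; strictly positive scalar.
#' @param label channel identifier.
#' @return An object of class `fc_ts`.
#' @examples
#' y <- fc_ts(rnorm(100), fs = 4, label = "S1-D1")
#' y
#' @export
fc_ts <- function(values, fs, label = "channel") {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("a time series needs at least 2 samples")
  if (!all(is.finite(values)))
    stop("time series values must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number (Hz)")
  structure(values, fs = as.numeric(fs), label = as.character(label)[1L],
            class = "fc_ts")
}

#' @export
print.fc_ts <- function(x, ...) {
  cat(sprintf("<fc_ts> %s: %d samples at %g Hz (%.1f s)\n",
              attr(x, "label"), length(x), attr(x, "fs"),
              length(x) / attr(x, "fs")))
  invisible(x)
}

# internal accessors ---------------------------------------------------------

ts_values <- function(y) {
  v <- as.numeric(unclass(y))
  attributes(v) <- NULL
  v
}

ts_fs <- function(y, fs = NULL) {
  f <- attr(y, "fs")
  if (is.null(f)) f <- fs
  if (is.null(f)) stop("no sampling rate: supply an fc_ts object or `fs`")
  f
}

ts_label <- function(y, default = "channel") {
  l <- attr(y, "label")
  if (is.null(l)) default else l
}

as_fc_ts <- function(y, fs = NULL, label = "channel") {
  if (inherits(y, "fc_ts")) return(y)
  fc_ts(y, fs = ts_fs(y, fs), label = label)
}

# validate a channel pair for the pairwise estimators
check_pair <- function(a, b, fs = NULL) {
  fa <- ts_fs(a, fs); fb <- ts_fs(b, fs)
  if (length(a) != length(b))
    stop(sprintf("channel lengths differ (%d vs %d)", length(a), length(b)))
  if (!isTRUE(all.equal(fa, fb)))
    stop(sprintf("sampling rates differ (%g vs %g Hz)", fa, fb))
  fa
}

#' Read a multichannel time-series table
#'
#' Reads delimited text (comma or tab separated, detected from the header) with
#' one header row of channel labels and one numeric column per channel. Ragged
#' rows and non-numeric cells are reported with their location.
#'
#' @param path path to the file.
#' @param fs sampling rate in Hz shared by all channels.
#' @return A named list of [fc_ts] objects.
#' @export
read_timeseries_table <- function(path, fs) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L)
    stop("table must have a header row and at least 2 data rows")
  sep <- if (grepl("\t", lines[[1L]], fixed = TRUE)) "\t" else ","
  parts <- strsplit(lines, sep, fixed = TRUE)
  labels <- trimws(parts[[1L]])
  k <- length(labels)
  n <- length(lines) - 1L
  m <- matrix(NA_real_, n, k)
  for (i in seq_len(n)) {
    row <- parts[[i + 1L]]
    if (length(row) != k)
      stop(sprintf("ragged row %d: expected %d fields, found %d",
                   i, k, length(row)))
    num <- suppressWarnings(as.numeric(row))
    bad <- which(is.na(num) & !(trimws(row) %in% c("NA", "NaN")))
    if (length(bad))
      stop(sprintf("non-numeric cell at row %d, column %d ('%s')",
                   i, bad[[1L]], trimws(row[[bad[[1L]]]])))
    if (anyNA(num))
      stop(sprintf("missing value at row %d, column %d", i, which(is.na(num))[1L]))
    m[i, ] <- num
  }
  out <- lapply(seq_len(k), function(j) fc_ts(m[, j], fs = fs, label = labels[j]))
  names(out) <- labels
  out
}

#' Write channels to a delimited table
#'
#' Inverse of [read_timeseries_table()]: writes a header of channel labels and
#' one column per channel at full double precision, so that a write-then-read
#' round trip reproduces the values exactly.
#'
#' @param channels a list of [fc_ts] objects (or numeric vectors) of equal
#'   length, or a numeric matrix with one column per channel.
#' @param path output path.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @export
write_timeseries_table <- function(channels, path, sep = ",") {
  if (is.matrix(channels)) {
    labels <- colnames(channels)
    if (is.null(labels)) labels <- paste0("ch", seq_len(ncol(channels)))
    m <- channels
  } else {
    labels <- vapply(seq_along(channels), function(j)
      ts_label(channels[[j]], default = paste0("ch", j)), "")
    if (!is.null(names(channels)) && all(nzchar(names(channels))))
      labels <- names(channels)
    m <- do.call(cbind, lapply(channels, ts_values))
  }
  body <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = sep))
  writeLines(c(paste(labels, collapse = sep), body), path)
  invisible(path)
}
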
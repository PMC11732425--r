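# File I/O: CSV series, beat lists, and WFDB records (see wfdb.R).
# Internal convention: seconds everywhere; milliseconds only at boundaries.

#' Read a single-lead ECG from file
#'
#' CSV files hold one sample per row (single column, or a chosen column of a
#' multi-channel file); the sampling rate comes from \code{fsOverride} or
#' from a \code{# fs=<Hz>} comment on the first line. WFDB records are read
#' from their \code{.hea}/\code{.dat} pair (format 16).
#'
#' @param path file path (for WFDB, the record path with or without
#'   \code{.hea}).
#' @param format \code{"csv"} or \code{"wfdb"}.
#' @param fsOverride sampling rate in Hz, required for CSV files without an
#'   fs header comment.
#' @param channel 1-based channel index for multi-column files; default 1.
#' @return an [EcgSignal-class].
#' @export
readEcg <- function(path, format = c("csv", "wfdb"), fsOverride = NULL,
                    channel = 1L) {
  format <- match.arg(format)
  if (format == "wfdb")
    return(readWfdb(path, channel = channel))
  if (!file.exists(path))
    stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  fs <- fsOverride
  if (is.null(fs) && grepl("^#.*fs\\s*=", first))
    fs <- as.numeric(sub(".*fs\\s*=\\s*([0-9.eE+-]+).*", "\\1", first))
  if (is.null(fs) || !is.finite(fs))
    stop("sampling rate unknown: pass fsOverride or add a '# fs=<Hz>' header")
  dat <- utils::read.csv(path, header = .hasHeader(path), comment.char = "#")
  if (channel > ncol(dat))
    stop("channel ", channel, " requested but file has ", ncol(dat),
         " column(s)")
  x <- suppressWarnings(as.numeric(dat[[channel]]))
  bad <- which(!is.finite(x))
  if (length(bad))
    stop("non-finite or non-numeric sample at row ", bad[1L])
  ecgSignal(x, fs = fs)
}

# header heuristic: first non-comment line non-numeric => header
.hasHeader <- function(path) {
  for (ln in readLines(path, n = 5L)) {
    if (grepl("^\\s*#", ln) || !nzchar(trimws(ln))) next
    tok <- strsplit(ln, "[,\t]")[[1]][1]
    return(is.na(suppressWarnings(as.numeric(tok))))
  }
  FALSE
}

#' Write a time series to CSV
#'
#' Accepts any of the package's series objects (or a data.frame) and writes a
#' comma-separated file with a header row, '.' decimals and full double
#' precision, so that [readTimeseries()] round-trips the values.
#'
#' @param series a series object with an [asTable()] method, or a data.frame.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeTimeseries <- function(series, path) {
  tab <- if (is.data.frame(series)) series else asTable(series)
  if (nrow(tab) && is.unsorted(tab[[1]]))
    stop("series times must be sorted")
  if (nrow(tab) && !all(is.finite(tab[[1]])))
    stop("series times must be finite")
  ok <- tryCatch({
    utils::write.table(format(tab, digits = 17, trim = TRUE, scientific = NA),
                       path, sep = ",", row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write ", path, ": ", conditionMessage(ok))
  invisible(path)
}

#' Read a time series written by writeTimeseries
#'
#' @param path CSV path.
#' @return a data.frame; the first column is time in seconds.
#' @export
readTimeseries <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path)
}

#' Read beat times from a one-column file
#'
#' @param path CSV/TSV path holding one numeric column of beat times.
#' @param units \code{"s"} or \code{"ms"}; values are converted to seconds.
#' @return a [BeatAnnotations-class]. A warning is raised when the implied
#'   intervals fall outside the physiological 0.2-3 s range, which usually
#'   means the wrong \code{units} was chosen.
#' @export
readBeats <- function(path, units = c("s", "ms")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path)
  dat <- utils::read.csv(path, header = .hasHeader(path), comment.char = "#")
  x <- suppressWarnings(as.numeric(dat[[1]]))
  if (any(!is.finite(x))) stop("non-numeric beat time in ", path)
  if (units == "ms") x <- x / 1000
  x <- sort(x)
  if (any(diff(x) == 0)) stop("duplicate beat times in ", path)
  d <- diff(x)
  if (length(d) && (any(d < 0.2) || any(d > 3)))
    warning("interbeat intervals outside [0.2, 3] s; check the units")
  beatAnnotations(x)
}
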
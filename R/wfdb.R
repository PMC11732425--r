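# Minimal WFDB support: format-16 signal files (.hea/.dat) and the standard
# binary annotation format (.atr) for beat times. Covers the subset needed to
# exchange single-lead ECG plus R-peak annotations; format 16 is little-endian
# two's-complement int16.

#' Write an EcgSignal as a WFDB record
#'
#' Writes \code{<record>.hea} and \code{<record>.dat} (format 16). Samples are
#' quantized with the given gain, so values round-trip to within
#' \code{1/(2*gain)}.
#'
#' @param ecg an [EcgSignal-class].
#' @param record record path without extension.
#' @param gain ADC units per millivolt (default 1000).
#' @param units physical units label (default "mV").
#' @return invisibly, the record path.
#' @export
writeWfdb <- function(ecg, record, gain = 1000, units = "mV") {
  stopifnot(is(ecg, "EcgSignal"))
  adc <- as.integer(round(ecg@samples * gain))
  if (any(abs(adc) > 32767))
    stop("samples exceed int16 range at gain ", gain)
  hea <- c(
    sprintf("%s 1 %.10g %d", basename(record), ecg@fs, length(adc)),
    sprintf("%s.dat 16 %g(0)/%s 16 0 %d 0 0 ECG", basename(record), gain,
            units, adc[1])
  )
  writeLines(hea, paste0(record, ".hea"))
  con <- file(paste0(record, ".dat"), "wb")
  on.exit(close(con))
  writeBin(adc, con, size = 2L, endian = "little")
  invisible(record)
}

#' Read a WFDB record (format 16)
#'
#' @param record record path, with or without \code{.hea}.
#' @param channel 1-based signal index.
#' @return an [EcgSignal-class] with amplitudes rescaled to physical units.
#' @export
readWfdb <- function(record, channel = 1L) {
  record <- sub("\\.hea$", "", record)
  hea <- paste0(record, ".hea")
  if (!file.exists(hea)) stop("header not found: ", hea)
  lines <- grep("^\\s*#", readLines(hea), value = TRUE, invert = TRUE)
  lines <- lines[nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(top[3]) else 250
  nsamp <- if (length(top) >= 4) as.integer(top[4]) else NA_integer_
  if (channel > nsig) stop("record has only ", nsig, " signal(s)")
  sig <- strsplit(trimws(lines[1 + channel]), "\\s+")[[1]]
  datfile <- file.path(dirname(record), sig[1])
  fmt <- sub("x.*", "", sig[2])
  if (fmt != "16")
    stop("only WFDB format 16 is supported (got format ", fmt, ")")
  gainfield <- if (length(sig) >= 3) sig[3] else "200"
  gain <- as.numeric(sub("[(/].*", "", gainfield))
  if (!is.finite(gain) || gain == 0) gain <- 200
  baseline <- if (grepl("\\(", gainfield))
    as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gainfield)) else 0
  con <- file(datfile, "rb")
  on.exit(close(con))
  total <- file.info(datfile)$size %/% 2
  raw <- readBin(con, integer(), n = total, size = 2L, signed = TRUE,
                 endian = "little")
  # format 16 interleaves channels sample-by-sample
  x <- raw[seq(channel, length(raw), by = nsig)]
  if (!is.na(nsamp)) x <- x[seq_len(min(nsamp, length(x)))]
  ecgSignal((x - baseline) / gain, fs = fs)
}

#' Write beat annotations in WFDB annotation format
#'
#' Encodes each beat as a normal-beat (code N) annotation with delta-encoded
#' sample times, using SKIP records for gaps beyond the 10-bit delta range,
#' and a zero terminator — readable by the standard WFDB tools.
#'
#' @param beats a [BeatAnnotations-class].
#' @param record record path without extension.
#' @param fs sampling frequency used to convert times to sample numbers.
#' @param annotator file extension (default "atr").
#' @return invisibly, the annotation path.
#' @export
writeWfdbAnnotations <- function(beats, record, fs, annotator = "atr") {
  stopifnot(is(beats, "BeatAnnotations"))
  samp <- round(beats@rTimes * fs)
  deltas <- diff(c(0, samp))
  NORMAL <- 1L; SKIP <- 59L
  words <- integer(0)
  for (d in deltas) {
    if (d > 1023 || d < 0) {
      # SKIP: code 59, delta 0, then 4 bytes (high word, low word)
      words <- c(words, bitwShiftL(SKIP, 10))
      lo <- d %% 65536L
      hi <- d %/% 65536L
      words <- c(words, hi, lo)
      words <- c(words, bitwShiftL(NORMAL, 10))
    } else {
      words <- c(words, bitwOr(bitwShiftL(NORMAL, 10), as.integer(d)))
    }
  }
  words <- c(words, 0L) # terminator
  path <- paste0(record, ".", annotator)
  con <- file(path, "wb")
  on.exit(close(con))
  # little-endian 16-bit words; writeBin as two raw bytes each
  b <- as.raw(rbind(words %% 256L, words %/% 256L))
  writeBin(b, con)
  invisible(path)
}

#' Read WFDB beat annotations
#'
#' Reads annotation times from the binary annotation format, keeping beat-type
#' annotations and skipping non-beat bookkeeping codes.
#'
#' @param record record path without extension.
#' @param fs sampling frequency to convert sample numbers to seconds.
#' @param annotator file extension (default "atr").
#' @return a [BeatAnnotations-class].
#' @export
readWfdbAnnotations <- function(record, fs, annotator = "atr") {
  path <- paste0(record, ".", annotator)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  b <- readBin(path, "raw", n = file.info(path)$size)
  words <- as.integer(b[seq(1, length(b), 2)]) +
    256L * as.integer(b[seq(2, length(b), 2)])
  SKIP <- 59L
  times <- numeric(0)
  t <- 0
  i <- 1L
  while (i <= length(words)) {
    w <- words[i]
    code <- w %/% 1024L
    delta <- w %% 1024L
    if (w == 0L) break
    if (code == SKIP) {
      if (i + 2L > length(words)) stop("truncated SKIP annotation")
      t <- t + words[i + 1L] * 65536 + words[i + 2L]
      i <- i + 3L
      next
    }
    t <- t + delta
    # beat codes occupy 1..49 in the annotation code table
    if (code >= 1L && code <= 49L) times <- c(times, t)
    i <- i + 1L
  }
  beatAnnotations(times / fs)
}
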
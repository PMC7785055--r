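#' Read a signal from a WAV or CSV file
#'
#' Two on-disk forms are supported: 16-bit PCM WAV (amplitudes mapped to
#' `[-1, 1]`; the sampling rate comes from the header) and two-column
#' CSV `time_s,value` (an optional single header line is auto-detected;
#' the sampling rate is the inverse of the median time step). A CSV time
#' axis must be uniform to within a relative tolerance of 1e-6 of the
#' median step; the first offending gap is reported otherwise.
#'
#' @param path file to read.
#' @param format `"auto"` (by extension), `"wav"` or `"csv"`.
#' @param channel channel to take from a multi-channel WAV (default 1).
#' @return An `hs_signal`.
#' @seealso [write_signal()]
#' @export
read_signal <- function(path, format = c("auto", "wav", "csv"),
                        channel = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.wav$", path, ignore.case = TRUE)) "wav" else "csv"
  }
  if (format == "wav") read_wav(path, channel) else read_signal_csv(path)
}

read_signal_csv <- function(path) {
  first <- readLines(path, n = 1L)
  if (!length(first) || !nzchar(first)) stop("empty file")
  header <- is.na(suppressWarnings(as.numeric(strsplit(first, ",")[[1L]][1L])))
  df <- utils::read.csv(path, header = header,
                        col.names = c("time", "value"),
                        colClasses = "numeric")
  if (nrow(df) < 2L) stop("need at least 2 samples in a CSV signal")
  dt <- diff(df$time)
  med <- stats::median(dt)
  if (med <= 0) stop("time axis must be strictly increasing")
  bad <- which(abs(dt - med) > 1e-6 * med)
  if (length(bad)) {
    stop(sprintf(
      "non-uniform time axis: step %d (t = %.9g to %.9g) is %.9g s, median step is %.9g s",
      bad[1L], df$time[bad[1L]], df$time[bad[1L] + 1L], dt[bad[1L]], med))
  }
  hs_signal(df$value, fs = 1 / med, start_time = df$time[1L])
}

read_wav <- function(path, channel = 1L) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file")
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file")
  fs <- NULL; n_chan <- NULL; bits <- NULL; dat <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (!length(id) || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", size / 2L, size = 2L,
                     endian = "little", signed = FALSE)
      if (fmt[1L] != 1L) stop("only PCM WAV is supported")
      n_chan <- fmt[2L]
      fs <- fmt[3L] + 65536 * fmt[4L]
      bits <- fmt[8L]
      if (bits != 16L) stop("only 16-bit PCM WAV is supported")
    } else if (identical(id, "data")) {
      dat <- readBin(con, "integer", size / 2L, size = 2L,
                     endian = "little", signed = TRUE)
      break
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
  if (is.null(fs) || is.null(dat)) stop("malformed WAV: missing fmt or data chunk")
  if (channel > n_chan) {
    stop(sprintf("channel %d requested but file has %d", channel, n_chan))
  }
  x <- dat[seq.int(channel, length(dat), by = n_chan)] / 32767
  hs_signal(x, fs = fs)
}

#' Write a signal to a WAV or CSV file
#'
#' CSV output stores `time_s,value` rows at full double precision, so a
#' CSV round trip reproduces the samples exactly. WAV output quantises
#' to 16-bit PCM after clipping to `[-1, 1]`, so a WAV round trip agrees
#' to within one quantisation step (1/32768).
#'
#' @param ts an `hs_signal`.
#' @param path output file.
#' @param format `"auto"` (by extension), `"wav"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_signal <- function(ts, path, format = c("auto", "wav", "csv")) {
  assert_hs_signal(ts)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.wav$", path, ignore.case = TRUE)) "wav" else "csv"
  }
  if (format == "csv") {
    t <- signal_times(ts)
    lines <- c("time_s,value",
               sprintf("%.17g,%.17g", t, ts$samples))
    writeLines(lines, path)
  } else {
    write_wav(ts, path)
  }
  invisible(path)
}

write_wav <- function(ts, path) {
  x <- pmax(-1, pmin(1, ts$samples))
  pcm <- as.integer(round(x * 32767))
  fs <- as.integer(round(ts$fs))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(c(1L, 1L), con, size = 2L, endian = "little")      # PCM, mono
  writeBin(fs, con, size = 4L, endian = "little")
  writeBin(fs * 2L, con, size = 4L, endian = "little")        # byte rate
  writeBin(c(2L, 16L), con, size = 2L, endian = "little")     # align, bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}

#' Export an amplitude spectrum as CSV
#'
#' Writes the matrix with one row per frequency (first column `freq_hz`)
#' and one column per time sample (named by time in ms), so the file is
#' directly plottable as an intensity map.
#'
#' @param spec an `st_spectrum`.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spec, path) {
  if (!inherits(spec, "st_spectrum")) stop("'spec' must be an st_spectrum")
  df <- data.frame(freq_hz = spec$freqs, spec$amplitudes)
  names(df)[-1L] <- sprintf("t%.1fms", spec$times_ms)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
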
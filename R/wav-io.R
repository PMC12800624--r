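#' Waveform container
#'
#' A minimal in-memory audio object: samples in `[-1, 1]`, a sample rate and
#' the identifying metadata carried through the pipeline (call id, caller id,
#' context label).
#'
#' @param samples Numeric vector of samples in `[-1, 1]`.
#' @param sample_rate_hz Positive integer sample rate.
#' @param call_id,caller_id,context Optional identifying metadata.
#' @return An object of class `waveform`.
#' @export
waveform <- function(samples, sample_rate_hz, call_id = NA_character_,
                     caller_id = NA_character_, context = NA_character_) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("waveform must be nonempty")
  if (any(!is.finite(samples))) stop("waveform samples must be finite")
  sample_rate_hz <- as.integer(sample_rate_hz)
  if (is.na(sample_rate_hz) || sample_rate_hz <= 0L)
    stop("sample_rate_hz must be a positive integer")
  structure(
    list(samples = samples, sample_rate_hz = sample_rate_hz,
         call_id = call_id, caller_id = caller_id, context = context),
    class = "waveform"
  )
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform %s: %d samples @ %d Hz (%.3f s), context=%s>\n",
              x$call_id, length(x$samples), x$sample_rate_hz,
              length(x$samples) / x$sample_rate_hz, x$context))
  invisible(x)
}

#' Read a PCM WAV file
#'
#' Reads RIFF/WAVE files with 16-bit integer PCM samples. Stereo files are
#' down-mixed to mono by channel mean (with a warning). Samples are scaled to
#' `[-1, 1]`.
#'
#' @param path Path to a `.wav` file.
#' @param call_id,caller_id,context Metadata attached to the returned object.
#' @return A [waveform].
#' @export
read_wav <- function(path, call_id = NA_character_, caller_id = NA_character_,
                     context = NA_character_) {
  if (!file.exists(path)) stop(sprintf("WAV file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop(sprintf("not a RIFF file: %s", path))
  readBin(con, "integer", 1, size = 4, endian = "little")  # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop(sprintf("not a WAVE file: %s", path))
  n_channels <- NULL; sample_rate <- NULL; bits <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", sz %/% 2, size = 2,
                     endian = "little", signed = FALSE)
      n_channels <- fmt[2]
      sample_rate <- fmt[3] + fmt[4] * 65536
      bits <- fmt[8]
    } else if (identical(id, "data")) {
      if (is.null(bits)) stop(sprintf("malformed WAV (data before fmt): %s", path))
      data <- readBin(con, "integer", sz %/% 2, size = 2, endian = "little")
      break
    } else {
      seek(con, sz + sz %% 2, origin = "current")
    }
  }
  if (is.null(data) || length(data) == 0L)
    stop(sprintf("empty or unreadable WAV data chunk: %s", path))
  if (!identical(bits, 16L) && !identical(bits, 16))
    stop(sprintf("only 16-bit PCM supported, got %s-bit: %s", bits, path))
  x <- data / 32767
  if (n_channels > 1L) {
    warning(sprintf("down-mixing %d channels to mono by channel mean: %s",
                    n_channels, path))
    x <- rowMeans(matrix(x, ncol = n_channels, byrow = TRUE))
  }
  waveform(x, sample_rate, call_id = call_id, caller_id = caller_id,
           context = context)
}

#' Write a waveform to a 16-bit PCM mono WAV file
#'
#' @param w A [waveform].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  x <- pmax(-1, pmin(1, w$samples))
  pcm <- as.integer(round(x * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")               # PCM
  writeBin(1L, con, size = 2, endian = "little")               # mono
  writeBin(as.integer(w$sample_rate_hz), con, size = 4, endian = "little")
  writeBin(as.integer(w$sample_rate_hz * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")               # block align
  writeBin(16L, con, size = 2, endian = "little")              # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
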
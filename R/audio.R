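#' Sampled audio signal
#'
#' The unit of all signal processing in the package: a finite real-valued
#' sample vector with its sampling rate. Amplitudes are dimensionless; WAV
#' files are read into the \[-1, 1\] convention.
#'
#' @param samples numeric vector of finite samples, length >= 1.
#' @param rate_hz sampling rate in samples per second, > 0. The experiment's
#'   recordings use 44100.
#' @return An object of class `audio_signal`.
#' @examples
#' tone <- audio_signal(sin(2 * pi * 440 * (0:999) / 8000), 8000)
#' signal_rms(tone)
#' @export
audio_signal <- function(samples, rate_hz = 44100) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop2("'samples' must have length >= 1")
  if (!all(is.finite(samples))) stop2("all samples must be finite")
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0)
    stop2("'rate_hz' must be a single positive number")
  structure(list(samples = samples, rate_hz = rate_hz), class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal: %d samples @ %g Hz (%.3f s), RMS %.4g>\n",
              length(x$samples), x$rate_hz, length(x$samples) / x$rate_hz,
              signal_rms(x)))
  invisible(x)
}

as_audio <- function(x, rate_hz) {
  if (inherits(x, "audio_signal")) x else audio_signal(x, rate_hz)
}

#' Root-mean-square amplitude of a signal
#' @param x an [audio_signal()] or numeric vector.
#' @return RMS amplitude (scalar).
#' @export
signal_rms <- function(x) {
  s <- if (inherits(x, "audio_signal")) x$samples else as.numeric(x)
  sqrt(mean(s^2))
}

#' Equalize a set of signals to a common RMS amplitude
#'
#' Scales each signal so its root-mean-square amplitude equals `target_rms`,
#' as is done to stimulus recordings so perceived level is comparable within
#' and across passages. Waveform shape is unchanged up to scale.
#'
#' @param signals a list of [audio_signal()] objects.
#' @param target_rms positive target RMS amplitude.
#' @return A list of rescaled `audio_signal` objects.
#' @export
rms_equalize <- function(signals, target_rms) {
  if (!is.list(signals) || length(signals) == 0)
    stop2("'signals' must be a non-empty list of audio_signal objects")
  if (!is.numeric(target_rms) || length(target_rms) != 1L || target_rms <= 0)
    stop2("'target_rms' must be a single positive number")
  lapply(seq_along(signals), function(i) {
    s <- signals[[i]]
    if (!inherits(s, "audio_signal")) stop2("element ", i, " is not an audio_signal")
    r <- signal_rms(s)
    if (r == 0) stop2("signal ", i, " is silent and cannot be scaled to a target RMS")
    audio_signal(s$samples * (target_rms / r), s$rate_hz)
  })
}

# ---- minimal mono RIFF/WAVE I/O (PCM 16-bit and IEEE float32) ----
# No audio package is available as a dependency; the subset of the format the
# pipeline needs (mono, uncompressed) is handled directly.

#' Read a mono WAV file
#'
#' Supports uncompressed PCM 16-bit and IEEE float 32-bit mono files.
#' Stereo or other multi-channel files are rejected.
#'
#' @param path path to a `.wav` file.
#' @return An [audio_signal()] with samples scaled to \[-1, 1\] (PCM) or taken
#'   verbatim (float).
#' @export
read_wav <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 44 || rawToChar(raw[1:4]) != "RIFF" ||
      rawToChar(raw[9:12]) != "WAVE")
    stop2("not a RIFF/WAVE file: ", path)
  u32 <- function(i) sum(as.integer(raw[i + 0:3]) * 256^(0:3))
  u16 <- function(i) sum(as.integer(raw[i + 0:1]) * 256^(0:1))
  pos <- 13
  fmt <- NULL; data_off <- NULL; data_len <- NULL
  while (pos + 8 <= length(raw)) {
    id <- rawToChar(raw[pos + 0:3]); sz <- u32(pos + 4)
    body <- pos + 8
    if (id == "fmt ") {
      fmt <- list(format = u16(body), channels = u16(body + 2),
                  rate = u32(body + 4), bits = u16(body + 14))
    } else if (id == "data") {
      data_off <- body; data_len <- sz
    }
    pos <- body + sz + (sz %% 2)  # chunks are word-aligned
  }
  if (is.null(fmt) || is.null(data_off)) stop2("missing fmt/data chunk in ", path)
  if (fmt$channels != 1L)
    stop2("only mono WAV is supported; file has ", fmt$channels, " channels")
  bytes <- raw[data_off:(data_off + data_len - 1)]
  if (fmt$format == 1L && fmt$bits == 16L) {
    v <- readBin(bytes, "integer", n = data_len / 2, size = 2,
                 signed = TRUE, endian = "little")
    samples <- v / 32768
  } else if (fmt$format == 3L && fmt$bits == 32L) {
    samples <- readBin(bytes, "double", n = data_len / 4, size = 4,
                       endian = "little")
  } else {
    stop2("unsupported WAV encoding (format ", fmt$format, ", ", fmt$bits,
          " bits); expected PCM16 or float32")
  }
  audio_signal(samples, fmt$rate)
}

#' Write a mono WAV file
#'
#' @param x an [audio_signal()].
#' @param path output path.
#' @param encoding `"pcm16"` (samples clipped to \[-1, 1\] and quantized) or
#'   `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, encoding = c("pcm16", "float32")) {
  stopifnot(inherits(x, "audio_signal"))
  encoding <- match.arg(encoding)
  n <- length(x$samples)
  bits <- if (encoding == "pcm16") 16L else 32L
  fmt_code <- if (encoding == "pcm16") 1L else 3L
  block <- bits %/% 8L
  data_len <- n * block
  con <- file(path, "wb"); on.exit(close(con))
  w32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  w16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  writeChar("RIFF", con, eos = NULL); w32(36 + data_len)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w32(16)
  w16(fmt_code); w16(1L); w32(round(x$rate_hz))
  w32(round(x$rate_hz) * block); w16(block); w16(bits)
  writeChar("data", con, eos = NULL); w32(data_len)
  if (encoding == "pcm16") {
    q <- as.integer(round(clamp(x$samples, -1, 1) * 32767))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    writeBin(x$samples, con, size = 4, endian = "little")
  }
  invisible(path)
}
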
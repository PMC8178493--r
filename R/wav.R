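#' Audio clip container
#'
#' A lightweight in-memory representation of a sampled waveform. Samples are
#' stored as a numeric vector normalized to \eqn{[-1, 1]}; the sampling rate and
#' the bit depth / channel count of the file of origin are kept as provenance.
#'
#' @param samples numeric vector of amplitudes in \eqn{[-1, 1]}.
#' @param rate sampling rate in Hz.
#' @param bit_depth bit depth of the source material (default 16).
#' @param channels channel count of the source material (always mono after load).
#' @return An object of class `audio_clip`.
#' @export
audio_clip <- function(samples, rate, bit_depth = 16L, channels = 1L) {
  stopifnot(is.numeric(samples), length(samples) > 0L, rate > 0)
  if (anyNA(samples)) stop("audio clip contains NA samples")
  structure(
    list(samples = as.numeric(samples), rate = as.numeric(rate),
         bit_depth = as.integer(bit_depth), channels = as.integer(channels)),
    class = "audio_clip"
  )
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip: %.3f s @ %g Hz, %d-bit origin, %d channel(s)>\n",
              length(x$samples) / x$rate, x$rate, x$bit_depth, x$channels))
  invisible(x)
}

#' Duration of an audio clip in seconds
#' @param clip an `audio_clip`.
#' @return duration in seconds.
#' @export
clip_duration <- function(clip) length(clip$samples) / clip$rate

#' Write a mono PCM WAV file
#'
#' Writes 16-bit little-endian PCM. Samples are clipped to \eqn{[-1, 1]} before
#' quantization.
#'
#' @param clip an `audio_clip`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path) {
  stopifnot(inherits(clip, "audio_clip"))
  x <- pmin(1, pmax(-1, clip$samples))
  pcm <- as.integer(round(x * 32767))
  rate <- as.integer(clip$rate)
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(rate, con, size = 4, endian = "little")
  writeBin(rate * 2L, con, size = 4, endian = "little")    # byte rate
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a PCM WAV file
#'
#' Parses the RIFF container directly (PCM integer formats, 8/16/24/32-bit).
#' Multi-channel input is averaged to mono with a warning; input not sampled at
#' 44,100 Hz is resampled to 44,100 Hz with a warning so that downstream framing
#' and spectral settings are uniform.
#'
#' @param path path to a WAV file.
#' @param target_rate rate every clip is brought to (default 44100 Hz).
#' @return an `audio_clip`, mono, amplitudes in \eqn{[-1, 1]}.
#' @export
read_wav <- function(path, target_rate = 44100) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw_all) < 44L) stop("not a valid WAV file (truncated header): ", path)
  if (rawToChar(raw_all[1:4]) != "RIFF" || rawToChar(raw_all[9:12]) != "WAVE")
    stop("not a RIFF/WAVE file: ", path)

  le_uint <- function(bytes) sum(as.numeric(bytes) * 256^(seq_along(bytes) - 1))
  pos <- 13L
  fmt <- NULL; data_raw <- NULL
  while (pos + 8L <= length(raw_all)) {
    cid <- rawToChar(raw_all[pos:(pos + 3L)])
    csz <- le_uint(raw_all[(pos + 4L):(pos + 7L)])
    body_start <- pos + 8L
    body_end <- body_start + csz - 1L
    if (cid == "fmt ") {
      if (body_end > length(raw_all)) stop("corrupt fmt chunk: ", path)
      b <- raw_all[body_start:body_end]
      fmt <- list(
        audio_format = le_uint(b[1:2]),
        channels = le_uint(b[3:4]),
        rate = le_uint(b[5:8]),
        bits = le_uint(b[15:16])
      )
    } else if (cid == "data") {
      if (body_end > length(raw_all)) stop("truncated WAV data chunk: ", path)
      data_raw <- raw_all[body_start:body_end]
    }
    pos <- body_start + as.integer(csz) + (csz %% 2L)  # chunks are word-aligned
  }
  if (is.null(fmt)) stop("WAV file has no fmt chunk: ", path)
  if (is.null(data_raw) || length(data_raw) == 0L) stop("WAV file has no samples: ", path)
  if (fmt$audio_format != 1) stop("unsupported WAV encoding (only integer PCM): ", path)

  bytes_per <- fmt$bits / 8
  n <- floor(length(data_raw) / bytes_per)
  if (n == 0L) stop("WAV file has no samples: ", path)
  if (fmt$bits == 8) {
    x <- (as.numeric(readBin(data_raw, "integer", n = n, size = 1, signed = FALSE)) - 128) / 128
  } else if (fmt$bits %in% c(16L, 32L)) {
    x <- readBin(data_raw, "integer", n = n, size = bytes_per, signed = TRUE,
                 endian = "little") / 2^(fmt$bits - 1)
  } else if (fmt$bits == 24) {
    b <- as.numeric(data_raw[seq_len(n * 3)])
    v <- b[seq(1, n * 3, 3)] + 256 * b[seq(2, n * 3, 3)] + 65536 * b[seq(3, n * 3, 3)]
    v[v >= 2^23] <- v[v >= 2^23] - 2^24
    x <- v / 2^23
  } else stop("unsupported bit depth: ", fmt$bits)

  if (fmt$channels > 1) {
    warning("multi-channel WAV averaged to mono: ", path)
    n_frames <- floor(length(x) / fmt$channels)
    x <- rowMeans(matrix(x[seq_len(n_frames * fmt$channels)],
                         nrow = n_frames, byrow = TRUE))
  }
  rate <- fmt$rate
  if (rate != target_rate) {
    warning(sprintf("resampling %g Hz -> %g Hz: %s", rate, target_rate, path))
    x <- resample_to(x, rate, target_rate)
    rate <- target_rate
  }
  audio_clip(x, rate, bit_depth = as.integer(fmt$bits), channels = 1L)
}

# Rational-factor resampling via signal::resample.
resample_to <- function(x, from, to) {
  if (from == to) return(x)
  f <- gcd_int(round(from), round(to))
  signal::resample(x, p = round(to) / f, q = round(from) / f)
}

gcd_int <- function(a, b) { while (b != 0) { t <- b; b <- a %% b; a <- t }; a }
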
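#' In-memory audio buffer
#'
#' A minimal mono audio container: a numeric sample vector in \[-1, 1\] plus
#' a sample rate. Diotic presentation is modelled as this single channel
#' duplicated at the playback interface.
#'
#' @param samples numeric vector of finite sample values.
#' @param rate sample rate in Hz.
#' @return An `audio_buffer` object.
#' @export
audio_buffer <- function(samples, rate = 22050) {
  samples <- as.numeric(samples)
  if (any(!is.finite(samples))) stop("samples must be finite", call. = FALSE)
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("rate must be a positive scalar", call. = FALSE)
  }
  structure(list(samples = samples, rate = rate), class = "audio_buffer")
}

#' @export
print.audio_buffer <- function(x, ...) {
  cat(sprintf("<audio_buffer> %d samples @ %g Hz (%.3f s)\n",
              length(x$samples), x$rate, length(x$samples) / x$rate))
  invisible(x)
}

duration_s <- function(buffer) length(buffer$samples) / buffer$rate

#' Software calibration map between digital RMS and dB SPL
#'
#' Hardware calibration is replaced by a single constant: the SPL assigned to
#' a digital RMS of 1.0. All level arithmetic then follows the 20*log10 rule.
#' The default (100 dB SPL at full-scale RMS) places the 65 dB SPL digit
#' level at a digital RMS of 10^(-35/20), leaving ample headroom.
#'
#' @param spl_at_full_scale_rms dB SPL corresponding to digital RMS 1.0.
#' @return A `calibration_map` object.
#' @export
calibration_map <- function(spl_at_full_scale_rms = 100) {
  stopifnot(is.numeric(spl_at_full_scale_rms), length(spl_at_full_scale_rms) == 1L)
  structure(list(spl_at_full_scale_rms = as.numeric(spl_at_full_scale_rms)),
            class = "calibration_map")
}

digital_rms <- function(samples) sqrt(mean(samples^2))

#' Measure the RMS level of a buffer in dB SPL
#'
#' @param buffer an [audio_buffer()].
#' @param calib a [calibration_map()].
#' @return Level in dB SPL: `20*log10(RMS) + spl_at_full_scale_rms`.
#' @export
#' @examples
#' buf <- audio_buffer(sin(2 * pi * 440 * seq(0, 1, by = 1 / 22050)))
#' rms_level_db(buf, calibration_map(100))  # ~96.99 dB (sine RMS = 1/sqrt(2))
rms_level_db <- function(buffer, calib = calibration_map()) {
  stopifnot(inherits(buffer, "audio_buffer"), inherits(calib, "calibration_map"))
  r <- digital_rms(buffer$samples)
  if (r == 0) stop("level of an all-zero buffer is undefined", call. = FALSE)
  20 * log10(r) + calib$spl_at_full_scale_rms
}

#' Scale a buffer to a target RMS level (pure gain)
#'
#' @param buffer an [audio_buffer()].
#' @param target_db_spl target level in dB SPL.
#' @param calib a [calibration_map()].
#' @param headroom maximum allowed absolute sample value after scaling;
#'   exceeding it raises a clipping error.
#' @return The scaled `audio_buffer`.
#' @export
scale_to_level <- function(buffer, target_db_spl, calib = calibration_map(),
                           headroom = 1.0) {
  current <- rms_level_db(buffer, calib)
  gain <- 10^((target_db_spl - current) / 20)
  out <- buffer$samples * gain
  if (max(abs(out)) > headroom) {
    stop(sprintf("scaling to %.1f dB SPL would clip (peak %.3f > headroom %.3f)",
                 target_db_spl, max(abs(out)), headroom), call. = FALSE)
  }
  audio_buffer(out, buffer$rate)
}

#' Draw a random contiguous segment from a longer noise buffer
#'
#' Emulates sampling a masker excerpt from a long (>= 5 min) babble-noise
#' recording: a uniformly random offset, no wraparound.
#'
#' @param noise an [audio_buffer()] at least `duration_s` long.
#' @param duration_s segment duration in seconds.
#' @return An `audio_buffer` of the requested duration.
#' @export
sample_noise_segment <- function(noise, duration_s) {
  n <- round(duration_s * noise$rate)
  total <- length(noise$samples)
  if (n > total) stop("requested segment longer than the noise source", call. = FALSE)
  offset <- if (n == total) 0L else sample.int(total - n + 1L, 1L) - 1L
  audio_buffer(noise$samples[(offset + 1L):(offset + n)], noise$rate)
}

# ---- WAV read/write (RIFF, PCM16 / IEEE float32, mono) ----------------------
# No audio I/O package is part of the supported stack, so the package carries
# a minimal RIFF reader/writer covering the formats the fixtures use.

#' Write an audio buffer to a WAV file
#'
#' Supports 16-bit PCM and 32-bit IEEE float, mono.
#'
#' @param buffer an [audio_buffer()].
#' @param path output file path.
#' @param bits 16 (PCM) or 32 (float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(buffer, path, bits = 16L) {
  stopifnot(inherits(buffer, "audio_buffer"), bits %in% c(16L, 32L))
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(buffer$samples)
  rate <- as.integer(round(buffer$rate))
  block_align <- as.integer(bits / 8)          # mono
  data_bytes <- n * block_align
  fmt_code <- if (bits == 16L) 1L else 3L      # PCM vs IEEE float

  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                 # channels
  writeBin(rate, con, size = 4, endian = "little")
  writeBin(as.integer(rate * block_align), con, size = 4, endian = "little")
  writeBin(block_align, con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  if (bits == 16L) {
    x <- pmax(pmin(buffer$samples, 1), -1)
    writeBin(as.integer(round(x * 32767)), con, size = 2, endian = "little")
  } else {
    writeBin(buffer$samples, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a WAV file into an audio buffer
#'
#' @param path WAV file (mono or multichannel; channels are averaged).
#' @return An [audio_buffer()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file", call. = FALSE)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAV file", call. = FALSE)

  fmt_code <- NULL; channels <- NULL; rate <- NULL; bits <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_code <- readBin(con, integer(), size = 2, endian = "little", signed = FALSE)
      channels <- readBin(con, integer(), size = 2, endian = "little", signed = FALSE)
      rate <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      invisible(readBin(con, integer(), size = 2, endian = "little"))
      bits <- readBin(con, integer(), size = 2, endian = "little", signed = FALSE)
      extra <- size - 16L
      if (extra > 0) invisible(readBin(con, raw(), n = extra))
    } else if (identical(id, "data")) {
      if (is.null(bits)) stop("malformed WAV: data before fmt", call. = FALSE)
      if (bits == 16L) {
        samples <- readBin(con, integer(), n = size / 2, size = 2,
                           endian = "little") / 32767
      } else if (bits == 32L && fmt_code == 3L) {
        samples <- readBin(con, numeric(), n = size / 4, size = 4,
                           endian = "little")
      } else {
        stop("unsupported WAV encoding (need PCM16 or float32)", call. = FALSE)
      }
      break
    } else {
      invisible(readBin(con, raw(), n = size))
    }
  }
  if (is.null(samples)) stop("WAV file has no data chunk", call. = FALSE)
  if (channels > 1L) {
    m <- matrix(samples, nrow = channels)
    samples <- colMeans(m)
  }
  audio_buffer(samples, rate)
}
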
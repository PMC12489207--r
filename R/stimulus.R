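#' Draw a random non-repeating digit triplet
#'
#' @param rng ignored placeholder for API symmetry; draws come from R's
#'   global RNG, so wrap calls in [withr::with_seed()] or `set.seed()` for
#'   reproducibility.
#' @return Integer vector of three pairwise-distinct digits 0-9, in
#'   presentation order.
#' @export
#' @examples
#' set.seed(1); sample_triplet()
sample_triplet <- function(rng = NULL) {
  sample(0:9, 3L, replace = FALSE)
}

#' Specification of one digit-triplet stimulus
#'
#' @param digits integer vector of three distinct digits.
#' @param target_snr_db requested SNR in dB.
#' @param speech_level_db_spl digit level (fixed-speech policy) or overall
#'   stimulus level (constant-overall policy), dB SPL.
#' @param level_policy as in [din_config()].
#' @param noise_lead_s seconds of noise before the first digit onset.
#' @param noise_trail_s seconds of noise after the last digit offset.
#' @param inter_digit_gap_s silent gap between consecutive digits, seconds.
#' @return A `stimulus_spec` object.
#' @export
stimulus_spec <- function(digits, target_snr_db,
                          speech_level_db_spl = 65,
                          level_policy = c("fixed_speech_adaptive_noise",
                                           "constant_overall_level"),
                          noise_lead_s = 0.5, noise_trail_s = 0.5,
                          inter_digit_gap_s = 0.5) {
  level_policy <- match.arg(level_policy)
  digits <- as.integer(digits)
  if (length(digits) != 3L || anyDuplicated(digits) ||
      any(digits < 0L | digits > 9L)) {
    stop("`digits` must be three distinct digits 0-9", call. = FALSE)
  }
  if (noise_lead_s < 0 || noise_trail_s < 0 || inter_digit_gap_s < 0) {
    stop("timing fields must be non-negative", call. = FALSE)
  }
  structure(list(
    digits = digits, target_snr_db = as.numeric(target_snr_db),
    speech_level_db_spl = as.numeric(speech_level_db_spl),
    level_policy = level_policy,
    noise_lead_s = noise_lead_s, noise_trail_s = noise_trail_s,
    inter_digit_gap_s = inter_digit_gap_s
  ), class = "stimulus_spec")
}

#' Assemble a digit-triplet-in-noise stimulus at an exact SNR
#'
#' Concatenates the three digit waveforms with silent inter-digit gaps,
#' scales speech and masker to realize the requested SNR under the level
#' policy, and lays the noise so it starts `noise_lead_s` before the first
#' digit and ends `noise_trail_s` after the last (sample-accurate).
#'
#' SNR convention: the speech level is the RMS of the digit content (gaps
#' excluded); the noise gain is set from the noise RMS measured over the
#' speech span, so the requested and measured pre-mix SNR agree to machine
#' precision regardless of the masker excerpt drawn. Under the
#' fixed-speech policy the digits sit at `speech_level_db_spl` and the noise
#' at `speech_level_db_spl - target_snr_db`; under the constant-overall
#' policy the mix is rescaled so the overall stimulus RMS (padding included)
#' equals `speech_level_db_spl` at every SNR.
#'
#' @param spec a [stimulus_spec()].
#' @param digit_waves named list of [audio_buffer()]s, names `"0"`..`"9"`.
#' @param noise an [audio_buffer()] masker at least as long as the stimulus.
#' @param calib a [calibration_map()].
#' @return A list with `mix` (the [audio_buffer()]), the pre-mix
#'   `speech_track` and `noise_track` buffers (same length as the mix, so
#'   the realized SNR can be re-measured), `layout` (a tibble of event
#'   onset/offset times in seconds and samples), and the realized component
#'   levels `speech_db_spl` / `noise_db_spl`.
#' @export
assemble_stimulus <- function(spec, digit_waves, noise,
                              calib = calibration_map()) {
  stopifnot(inherits(spec, "stimulus_spec"), inherits(noise, "audio_buffer"))
  keys <- as.character(spec$digits)
  missing <- setdiff(keys, names(digit_waves))
  if (length(missing)) {
    stop("missing digit waveform(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  waves <- digit_waves[keys]
  rates <- vapply(waves, function(w) w$rate, numeric(1))
  if (length(unique(c(rates, noise$rate))) != 1L) {
    stop("sample-rate mismatch between digit waveforms and noise", call. = FALSE)
  }
  rate <- noise$rate
  gap_n <- round(spec$inter_digit_gap_s * rate)
  lead_n <- round(spec$noise_lead_s * rate)
  trail_n <- round(spec$noise_trail_s * rate)

  # speech span: digit1 gap digit2 gap digit3
  lens <- vapply(waves, function(w) length(w$samples), integer(1))
  speech <- numeric(sum(lens) + 2L * gap_n)
  onsets <- integer(3)
  pos <- 0L
  for (i in 1:3) {
    onsets[i] <- pos
    speech[(pos + 1L):(pos + lens[i])] <- waves[[i]]$samples
    pos <- pos + lens[i] + if (i < 3L) gap_n else 0L
  }
  span_n <- length(speech)
  content_idx <- unlist(lapply(1:3, function(i) (onsets[i] + 1L):(onsets[i] + lens[i])))

  noise_n <- lead_n + span_n + trail_n
  if (length(noise$samples) < noise_n) {
    stop("noise buffer shorter than the stimulus span", call. = FALSE)
  }
  noise_seg <- noise$samples[seq_len(noise_n)]

  # component levels implied by the policy
  if (spec$level_policy == "fixed_speech_adaptive_noise") {
    speech_target <- spec$speech_level_db_spl
  } else {
    # provisional; the whole mix is rescaled afterwards
    speech_target <- spec$speech_level_db_spl
  }
  noise_target <- speech_target - spec$target_snr_db

  # speech gain from digit-content RMS; noise gain from its RMS over the span
  sp_rms <- digital_rms(speech[content_idx])
  sp_gain <- 10^((speech_target - calib$spl_at_full_scale_rms) / 20) / sp_rms
  span_noise <- noise_seg[(lead_n + 1L):(lead_n + span_n)]
  nz_rms <- digital_rms(span_noise)
  if (nz_rms == 0) stop("masker is silent over the speech span", call. = FALSE)
  nz_gain <- 10^((noise_target - calib$spl_at_full_scale_rms) / 20) / nz_rms

  speech_track <- numeric(noise_n)
  speech_track[(lead_n + 1L):(lead_n + span_n)] <- speech * sp_gain
  noise_track <- noise_seg * nz_gain
  mix <- speech_track + noise_track

  if (spec$level_policy == "constant_overall_level") {
    # hold the overall digits-plus-noise RMS at the configured level
    overall <- 20 * log10(digital_rms(mix)) + calib$spl_at_full_scale_rms
    g <- 10^((spec$speech_level_db_spl - overall) / 20)
    mix <- mix * g
    speech_track <- speech_track * g
    noise_track <- noise_track * g
    speech_target <- speech_target + 20 * log10(g)
    noise_target <- noise_target + 20 * log10(g)
  }
  if (max(abs(mix)) > 1) {
    warning("assembled stimulus clips (peak ", round(max(abs(mix)), 3), ")")
  }

  marks <- as.integer(c(0L, lead_n + onsets, lead_n + onsets + lens, noise_n))
  layout <- tibble::tibble(
    event = c("noise_onset", paste0("digit", 1:3, "_onset"),
              paste0("digit", 1:3, "_offset"), "noise_offset"),
    sample = marks,
    time_s = marks / rate
  )
  list(
    mix = audio_buffer(mix, rate),
    speech_track = audio_buffer(speech_track, rate),
    noise_track = audio_buffer(noise_track, rate),
    layout = layout[order(layout$sample), ],
    speech_db_spl = speech_target,
    noise_db_spl = noise_target
  )
}

# ---- synthetic fixtures -----------------------------------------------------

# A harmonic complex with a digit-specific fundamental and a Hann envelope.
# These fixtures exercise level/timing plumbing; they are not intelligible
# speech.
synth_digit_wave <- function(digit, rate = 22050, duration_s = NULL) {
  if (is.null(duration_s)) duration_s <- stats::runif(1, 0.3, 0.8)
  f0 <- 110 * 2^(digit / 10)            # 110..205 Hz across digits
  n <- round(duration_s * rate)
  t <- seq_len(n) / rate
  harmonics <- 1:6
  x <- rowSums(sapply(harmonics, function(k) sin(2 * pi * k * f0 * t) / k))
  env <- 0.5 * (1 - cos(2 * pi * seq_len(n) / n))    # Hann
  x <- x * env
  audio_buffer(0.4 * x / max(abs(x)), rate)
}

# Speech-shaped stationary masker: Gaussian noise through a one-pole lowpass,
# mimicking the long-term spectral tilt of babble. Long-term RMS stationary.
synth_babble_noise <- function(duration_s = 300, rate = 22050) {
  n <- round(duration_s * rate)
  w <- stats::rnorm(n)
  x <- as.numeric(stats::filter(w, 0.85, method = "recursive"))
  audio_buffer(0.2 * x / stats::sd(x), rate)
}

#' Generate the synthetic audio fixture set
#'
#' Produces ten digit waveforms (harmonic complexes with digit-specific
#' fundamentals, 0.3-0.8 s each) and one long stationary speech-shaped
#' masker, in memory or written as WAV files. The fixtures emulate the shape
#' of a DIN stimulus inventory (10 short utterances plus a >= 5-minute
#' masker) for level, timing and pipeline tests; they carry no linguistic
#' content.
#'
#' @param seed integer seed for reproducibility.
#' @param dir optional output directory; when given, writes `digit_0.wav` ..
#'   `digit_9.wav` and `noise.wav` (16-bit PCM).
#' @param noise_duration_s masker length in seconds (default 300 = 5 min).
#' @param rate sample rate in Hz (default 22050).
#' @return Invisibly, a list with `digit_waves` (named list of buffers) and
#'   `noise`.
#' @export
make_din_fixtures <- function(seed = 1L, dir = NULL,
                              noise_duration_s = 300, rate = 22050) {
  set.seed(seed)
  digit_waves <- stats::setNames(
    lapply(0:9, function(d) synth_digit_wave(d, rate = rate)),
    as.character(0:9)
  )
  noise <- synth_babble_noise(noise_duration_s, rate)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (d in names(digit_waves)) {
      write_wav(digit_waves[[d]], file.path(dir, paste0("digit_", d, ".wav")))
    }
    write_wav(noise, file.path(dir, "noise.wav"))
  }
  invisible(list(digit_waves = digit_waves, noise = noise))
}
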
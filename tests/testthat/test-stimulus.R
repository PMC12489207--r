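test_that("triplets are distinct, seed-reproducible and position-balanced", {
  set.seed(5)
  for (i in 1:50) {
    t3 <- sample_triplet()
    expect_length(t3, 3L)
    expect_equal(anyDuplicated(t3), 0L)
    expect_true(all(t3 %in% 0:9))
  }
  set.seed(99); a <- sample_triplet()
  set.seed(99); b <- sample_triplet()
  expect_identical(a, b)

  # each digit should appear in ~3/10 of draws (any position)
  set.seed(7)
  n <- 10000
  counts <- table(factor(unlist(replicate(n, sample_triplet(), simplify = FALSE)),
                         levels = 0:9))
  expected <- n * 3 / 10
  sigma <- sqrt(n * 0.3 * 0.7)
  expect_true(all(abs(counts - expected) < 3.5 * sigma))
})

test_that("RMS level measurement follows the calibration map", {
  rate <- 22050
  t <- seq_len(rate) / rate
  sine <- audio_buffer(sin(2 * pi * 441 * t), rate)   # integer periods
  expect_equal(rms_level_db(sine, calib100), 100 + 20 * log10(1 / sqrt(2)),
               tolerance = 1e-6)

  set.seed(2)
  buf <- audio_buffer(stats::rnorm(4410, sd = 0.05), rate)
  direct <- 20 * log10(sqrt(mean(buf$samples^2))) + 100
  expect_equal(rms_level_db(buf, calib100), direct, tolerance = 1e-9)

  half <- audio_buffer(buf$samples * 0.5, rate)
  expect_equal(rms_level_db(buf, calib100) - rms_level_db(half, calib100),
               20 * log10(2), tolerance = 1e-9)

  expect_error(rms_level_db(audio_buffer(numeric(100)), calib100), "undefined")
})

test_that("scaling to a target level is an exact pure gain", {
  set.seed(3)
  buf <- audio_buffer(stats::rnorm(4410, sd = 0.01))
  out <- scale_to_level(buf, 65, calib100)
  expect_equal(rms_level_db(out, calib100), 65, tolerance = 1e-6)
  # shape preserved: constant sample ratio
  expect_equal(stats::sd(out$samples / buf$samples), 0, tolerance = 1e-12)

  same <- scale_to_level(buf, rms_level_db(buf, calib100), calib100)
  expect_equal(same$samples, buf$samples, tolerance = 1e-12)

  expect_error(scale_to_level(buf, 99, calib100), "clip")
})

test_that("noise segments are contiguous, seeded and uniformly placed", {
  small <- audio_buffer(seq_len(2000) / 2000, rate = 100)  # strictly increasing
  whole <- sample_noise_segment(small, 20)                  # full 20 s
  expect_identical(whole$samples, small$samples)

  set.seed(4); s1 <- sample_noise_segment(small, 3)
  set.seed(4); s2 <- sample_noise_segment(small, 3)
  expect_identical(s1$samples, s2$samples)
  expect_length(s1$samples, 300L)

  expect_error(sample_noise_segment(small, 30), "longer than")

  # recover offsets (samples are unique) and test uniformity
  set.seed(6)
  offs <- replicate(600, {
    seg <- sample_noise_segment(small, 3)
    which(small$samples == seg$samples[1]) - 1L
  })
  ks <- stats::ks.test(offs + stats::runif(length(offs)), "punif", 0, 2000 - 300 + 1)
  expect_gt(ks$p.value, 0.001)
})

test_that("fixed-speech assembly realizes the presentation levels of the variants", {
  sp <- stimulus_spec(c(6, 1, 2), target_snr_db = 5)
  out <- assemble_stimulus(sp, fx$digit_waves, fx$noise, calib100)
  expect_equal(out$speech_db_spl, 65)
  expect_equal(out$noise_db_spl, 60)   # +5 dB SNR = noise at 60 dB SPL

  # noise spans speech plus exactly 0.5 s lead and trail, sample-accurate
  lay <- out$layout
  rate <- out$mix$rate
  expect_identical(lay$sample[lay$event == "digit1_onset"],
                   as.integer(round(0.5 * rate)))
  span <- lay$sample[lay$event == "digit3_offset"] -
    lay$sample[lay$event == "digit1_onset"]
  expect_identical(length(out$mix$samples),
                   as.integer(span + round(0.5 * rate) * 2))
})

test_that("requested and measured pre-mix SNR agree across the operating range", {
  for (snr in c(-20, -12, -5, 0, 5, 10)) {
    sp <- stimulus_spec(c(3, 5, 9), target_snr_db = snr)
    out <- assemble_stimulus(sp, fx$digit_waves, fx$noise, calib100)
    lay <- out$layout
    span <- (lay$sample[lay$event == "digit1_onset"] + 1L):
      lay$sample[lay$event == "digit3_offset"]
    content <- unlist(lapply(1:3, function(i) {
      (lay$sample[lay$event == paste0("digit", i, "_onset")] + 1L):
        lay$sample[lay$event == paste0("digit", i, "_offset")]
    }))
    speech_rms <- sqrt(mean(out$speech_track$samples[content]^2))
    noise_rms <- sqrt(mean(out$noise_track$samples[span]^2))
    measured <- 20 * log10(speech_rms / noise_rms)
    expect_equal(measured, snr, tolerance = 1e-9)
    if (snr == 0) {
      # equal measured RMS of the two component tracks at SNR 0
      expect_equal(speech_rms, noise_rms, tolerance = 1e-9)
    }
  }
})

test_that("the constant-overall policy holds the stimulus level across SNRs", {
  levels <- vapply(c(2, -5, -12), function(snr) {
    sp <- stimulus_spec(c(3, 5, 9), target_snr_db = snr,
                        level_policy = "constant_overall_level")
    out <- assemble_stimulus(sp, fx$digit_waves, fx$noise, calib100)
    rms_level_db(out$mix, calib100)
  }, numeric(1))
  expect_true(all(abs(levels - 65) < 0.1))
  expect_lt(max(levels) - min(levels), 1e-9)  # exactly constant by construction
})

test_that("assembly rejects inconsistent inputs", {
  sp <- stimulus_spec(c(3, 5, 9), target_snr_db = 0)
  expect_error(assemble_stimulus(sp, fx$digit_waves["3"], fx$noise, calib100),
               "missing digit")
  odd <- fx$digit_waves
  odd[["5"]] <- audio_buffer(odd[["5"]]$samples, rate = 16000)
  expect_error(assemble_stimulus(sp, odd, fx$noise, calib100),
               "sample-rate mismatch")
  expect_error(stimulus_spec(c(3, 3, 9), 0), "distinct")
})

test_that("WAV files round-trip through the PCM16 and float32 writers", {
  buf <- fx$digit_waves[["7"]]
  f16 <- withr::local_tempfile(fileext = ".wav")
  write_wav(buf, f16, bits = 16L)
  back16 <- read_wav(f16)
  expect_equal(back16$rate, buf$rate)
  expect_equal(back16$samples, buf$samples, tolerance = 1e-4)

  f32 <- withr::local_tempfile(fileext = ".wav")
  write_wav(buf, f32, bits = 32L)
  back32 <- read_wav(f32)
  expect_equal(back32$samples, buf$samples, tolerance = 1e-7)
})

test_that("the fixture generator emulates the stimulus inventory", {
  g <- make_din_fixtures(seed = 11, noise_duration_s = 12)
  expect_named(g$digit_waves, as.character(0:9))
  durs <- vapply(g$digit_waves, function(w) length(w$samples) / w$rate, numeric(1))
  expect_true(all(durs >= 0.3 & durs <= 0.8))
  expect_equal(length(g$noise$samples) / g$noise$rate, 12)
  # long-term RMS stationarity of the masker: thirds agree within 1 dB
  thirds <- split(g$noise$samples,
                  rep(1:3, each = length(g$noise$samples) / 3))
  lv <- vapply(thirds, function(s) 20 * log10(sqrt(mean(s^2))), numeric(1))
  expect_lt(max(lv) - min(lv), 1)
  # regeneration with the same seed is identical
  g2 <- make_din_fixtures(seed = 11, noise_duration_s = 12)
  expect_identical(g2$noise$samples, g$noise$samples)

  d <- withr::local_tempdir()
  make_din_fixtures(seed = 11, dir = d, noise_duration_s = 2)
  expect_true(file.exists(file.path(d, "digit_0.wav")))
  expect_true(file.exists(file.path(d, "noise.wav")))
})
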
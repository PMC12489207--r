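test_that("presets encode the three variants' staircase parameters", {
  ai <- din_preset("ai_powered")
  expect_equal(new_track(ai)$current_snr_db, 5)              # 65 vs 60 dB SPL
  expect_equal(ai$phase_steps_db, c(5, 3, 1))
  expect_equal(ai$phase_reversals, c(2L, 2L, 6L))
  expect_equal(ai$snr_floor_db, -15)
  expect_equal(ai$noise_cap_db_spl, 80)

  ind <- din_preset("independent")
  expect_equal(new_track(ind)$current_snr_db, 2)
  expect_equal(ind$phase_steps_db, c(6, 2))
  expect_equal(ind$phase_reversals, c(4L, 6L))
  expect_equal(ind$level_policy, "constant_overall_level")

  kb <- din_preset("keyboard")
  expect_equal(kb$phase_steps_db, din_preset("ai_powered")$phase_steps_db)
})

test_that("degenerate configurations are rejected", {
  expect_error(din_config(phase_steps_db = numeric(), phase_reversals = integer(),
                          initial_snr_db = 5), "non-empty")
  expect_error(din_config(phase_steps_db = c(5, 0), phase_reversals = c(2L, 2L),
                          initial_snr_db = 5), "positive")
  expect_error(din_config(phase_steps_db = 5, phase_reversals = 2L,
                          initial_snr_db = -20, snr_floor_db = -15),
               "below the configured SNR floor")
})

test_that("the step in force follows the reversal-phase schedule", {
  ai <- din_preset("ai_powered")
  st <- new_track(ai)
  expect_equal(current_step_db(st), 5)
  st$reversals_completed <- 4L
  expect_equal(current_step_db(st), 1)
  st$reversals_completed <- 2L
  expect_equal(current_step_db(st), 3)

  ind <- new_track(din_preset("independent"))
  ind$reversals_completed <- 3L
  expect_equal(current_step_db(ind), 6)
  ind$reversals_completed <- 4L
  expect_equal(current_step_db(ind), 2)
})

test_that("two correct responses lower the SNR by the phase step and reset the counter", {
  st <- new_track(din_preset("ai_powered"))
  st <- apply_response(st, TRUE)
  expect_equal(st$current_snr_db, 5)
  expect_equal(st$consecutive_correct, 1L)
  st <- apply_response(st, TRUE)
  expect_equal(st$current_snr_db, 0)          # 5 dB step in phase 1
  expect_equal(st$consecutive_correct, 0L)
})

test_that("one incorrect response raises the SNR and resets the counter", {
  st <- new_track(din_preset("ai_powered"))
  st <- apply_response(st, TRUE)
  st <- apply_response(st, FALSE)
  expect_equal(st$current_snr_db, 10)
  expect_equal(st$consecutive_correct, 0L)
  expect_error(apply_response(structure(modifyList(st, list(terminated = TRUE)),
                                        class = "din_track"), TRUE),
               "terminated")
})

test_that("a deterministic run matches an independent step-by-step re-enactment", {
  for (variant in c("ai_powered", "independent")) {
    cfg <- din_preset(variant)
    theta <- -8.2
    st <- new_track(cfg)
    while (!st$terminated) st <- apply_response(st, st$current_snr_db >= theta)
    log <- trials(st)
    orc <- oracle_staircase(log$correct, cfg$phase_steps_db, cfg$phase_reversals,
                            cfg$initial_snr_db, floor = cfg$snr_floor_db)
    expect_equal(log$snr_db, orc$snrs)
    expect_equal(st$reversals_completed, orc$reversals)
    expect_equal(log$reversal, orc$rev_flags)
    expect_equal(estimate_srt(st)$srt_db, orc$srt)
  }
})

test_that("an always-correct run floors at -15 dB with the noise capped at 80 dB SPL", {
  cfg <- din_preset("ai_powered")
  st <- new_track(cfg)
  n <- 0L
  while (!st$terminated && n < 100L) { st <- apply_response(st, TRUE); n <- n + 1L }
  expect_true(st$terminated)
  expect_true(st$floored)
  expect_lt(st$reversals_completed, cfg$total_reversals)
  log <- trials(st)
  expect_equal(max(log$noise_db_spl), 80)
  expect_equal(min(log$snr_db), -15)
  expect_equal(sum(log$correct & log$snr_db == -15), cfg$floor_correct_limit)
  srt <- estimate_srt(st)
  expect_equal(srt$srt_db, -15)
  expect_true(srt$floored)
})

test_that("the floor rule needs the configured number of correct floor responses", {
  cfg <- din_preset("ai_powered")
  st <- new_track(cfg)
  st$floor_correct_count <- 5L
  expect_false(check_floor_rule(st))
  st$floor_correct_count <- 6L
  expect_true(check_floor_rule(st))
  expect_false(check_floor_rule(new_track(din_preset("independent"))))
})

test_that("SRT estimation errors on a live track and recomputes from the log", {
  cfg <- din_preset("ai_powered")
  expect_error(estimate_srt(new_track(cfg)), "not terminated")

  tr <- run_session(cfg, listener_model(threshold_db = -9), seed = 11)
  log <- trials(tr)
  srt <- estimate_srt(tr)
  expect_equal(srt$srt_db, mean(log$snr_db[log$phase == 3]))
  expect_equal(srt$n_trials_averaged, sum(log$phase == 3))

  cfg_rev <- cfg
  cfg_rev$srt_estimator <- "mean_final_phase_reversal_snrs"
  srt_rev <- estimate_srt(tr, cfg_rev)
  expect_equal(srt_rev$srt_db, mean(log$snr_db[log$phase == 3 & log$reversal]))
})

test_that("seeded stochastic tracks respect the structural invariants", {
  for (variant in c("ai_powered", "keyboard", "independent")) {
    cfg <- din_preset(variant)
    for (seed in 1:8) {
      tr <- run_session(cfg, listener_model(threshold_db = -9), seed = seed)
      log <- trials(tr)
      if (!tr$floored) {
        expect_identical(tr$reversals_completed, cfg$total_reversals)
      }
      moves <- diff(log$snr_db)
      moves <- abs(moves[moves != 0])
      expect_true(all(moves %in% cfg$phase_steps_db |
                        # a clamped movement at the floor may be shorter
                        (!is.na(cfg$snr_floor_db) &
                           moves < max(cfg$phase_steps_db))))
      expect_true(all(moves <= max(cfg$phase_steps_db)))
      if (!is.na(cfg$snr_floor_db)) {
        expect_true(all(log$snr_db >= cfg$snr_floor_db))
        expect_true(all(log$noise_db_spl <= cfg$noise_cap_db_spl))
      }
      # phase bookkeeping is monotone and consistent with the budgets
      expect_true(all(diff(log$phase) >= 0))
      expect_true(all(cumsum(log$reversal) <= cfg$total_reversals))
    }
  }
})

test_that("configs and session logs survive a file round-trip", {
  cfg <- din_preset("independent")
  f <- withr::local_tempfile(fileext = ".yaml")
  write_din_config(cfg, f)
  cfg2 <- read_din_config(f)
  expect_equal(cfg2$phase_steps_db, cfg$phase_steps_db)
  expect_equal(cfg2$initial_snr_db, cfg$initial_snr_db)
  expect_equal(cfg2$level_policy, cfg$level_policy)

  tr <- run_session(din_preset("ai_powered"),
                    listener_model(threshold_db = -10), seed = 3)
  g <- withr::local_tempfile(fileext = ".jsonl")
  write_session_log(tr, g)
  back <- read_session_log(g)
  expect_identical(back$trials$snr_db, trials(tr)$snr_db)
  expect_identical(back$trials$correct, trials(tr)$correct)
  expect_true(back$terminated)
  # a replayed log reproduces the identical trajectory
  rp <- replay_track(back$config, back$trials$correct)
  expect_identical(trials(rp)$snr_db, back$trials$snr_db)
})
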
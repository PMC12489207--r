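#' Configure an adaptive digits-in-noise staircase
#'
#' Builds the full parameterization of one DIN test variant: the transformed
#' up-down rule (how many consecutive correct responses drive the SNR down,
#' how many errors drive it up), the phase schedule of step sizes with their
#' reversal budgets, starting SNR, presentation-level policy, and the floor
#' rule that ends a run early for listeners who keep answering correctly at
#' the lowest allowed SNR.
#'
#' Three named presets are available through [din_preset()]: `"ai_powered"`,
#' `"keyboard"` (identical staircase, differing only in response capture) and
#' `"independent"` (two phases, constant-overall-level presentation).
#'
#' @param name label for the variant.
#' @param n_down consecutive correct responses required before the SNR is
#'   made harder (2 for the classic 2-down/1-up rule, which converges near
#'   the 70.7%-correct point).
#' @param n_up incorrect responses required before the SNR is made easier
#'   (always 1 here).
#' @param phase_steps_db numeric vector of step sizes in dB, one per phase.
#' @param phase_reversals integer vector, same length: how many reversals are
#'   spent in each phase; their sum is the termination count.
#' @param initial_snr_db starting SNR in dB.
#' @param speech_level_db_spl digit presentation level in dB SPL (fixed-speech
#'   policy) or the constant overall stimulus level (constant-overall policy).
#' @param level_policy `"fixed_speech_adaptive_noise"` (digits fixed, noise
#'   level moves) or `"constant_overall_level"` (digits-plus-noise RMS held
#'   constant; both component levels move).
#' @param noise_cap_db_spl upper limit on the noise presentation level in
#'   dB SPL, or `NA` for none. With fixed speech at 65 dB SPL a cap of 80
#'   implies an SNR floor of -15 dB.
#' @param snr_floor_db lowest SNR the track may reach, or `NA` for none.
#' @param floor_correct_limit number of correct responses delivered at the
#'   floor SNR that triggers a "floored" termination (result recorded at the
#'   floor, meaning "this value or lower").
#' @param srt_estimator `"mean_final_phase_trial_snrs"` (default: average the
#'   SNR of every trial presented during the final phase) or
#'   `"mean_final_phase_reversal_snrs"` (average only the reversal points).
#' @param max_trials safety cap on trials per run; exceeding it is an error.
#'
#' @return A `din_config` object (a named list).
#' @seealso [din_preset()], [new_track()], [apply_response()]
#' @export
#' @examples
#' cfg <- din_preset("ai_powered")
#' cfg$initial_snr_db   # +5 dB: speech 65 dB SPL over noise starting at 60
din_config <- function(name = "custom",
                       n_down = 2L,
                       n_up = 1L,
                       phase_steps_db,
                       phase_reversals,
                       initial_snr_db,
                       speech_level_db_spl = 65,
                       level_policy = c("fixed_speech_adaptive_noise",
                                        "constant_overall_level"),
                       noise_cap_db_spl = NA_real_,
                       snr_floor_db = NA_real_,
                       floor_correct_limit = 6L,
                       srt_estimator = c("mean_final_phase_trial_snrs",
                                         "mean_final_phase_reversal_snrs"),
                       max_trials = 200L) {
  level_policy <- match.arg(level_policy)
  srt_estimator <- match.arg(srt_estimator)
  if (length(phase_steps_db) == 0L || length(phase_steps_db) != length(phase_reversals)) {
    stop("`phase_steps_db` and `phase_reversals` must be non-empty and the same length",
         call. = FALSE)
  }
  if (any(phase_steps_db <= 0)) {
    stop("every phase step must be a positive dB value", call. = FALSE)
  }
  if (any(phase_reversals < 1)) {
    stop("every phase reversal budget must be at least 1", call. = FALSE)
  }
  # with fixed speech, a noise cap implies an SNR floor; reconcile the two
  if (level_policy == "fixed_speech_adaptive_noise" && !is.na(noise_cap_db_spl)) {
    implied_floor <- speech_level_db_spl - noise_cap_db_spl
    if (is.na(snr_floor_db)) {
      snr_floor_db <- implied_floor
    } else if (snr_floor_db < implied_floor) {
      stop("`snr_floor_db` below the floor implied by the noise cap", call. = FALSE)
    }
  }
  if (!is.na(snr_floor_db) && initial_snr_db < snr_floor_db) {
    stop("`initial_snr_db` lies below the configured SNR floor", call. = FALSE)
  }
  structure(
    list(
      name = name,
      n_down = as.integer(n_down),
      n_up = as.integer(n_up),
      phase_steps_db = as.numeric(phase_steps_db),
      phase_reversals = as.integer(phase_reversals),
      total_reversals = sum(as.integer(phase_reversals)),
      initial_snr_db = as.numeric(initial_snr_db),
      speech_level_db_spl = as.numeric(speech_level_db_spl),
      level_policy = level_policy,
      noise_cap_db_spl = as.numeric(noise_cap_db_spl),
      snr_floor_db = as.numeric(snr_floor_db),
      floor_correct_limit = as.integer(floor_correct_limit),
      srt_estimator = srt_estimator,
      max_trials = as.integer(max_trials)
    ),
    class = "din_config"
  )
}

#' Named staircase presets for the three DIN test variants
#'
#' Encodes the three study configurations field-for-field: the AI-powered and
#' keyboard-based variants share a 2-down/1-up staircase with 5/3/1 dB steps
#' over reversal budgets 2/2/6, digits fixed at 65 dB SPL, noise starting at
#' 60 dB SPL (initial SNR +5 dB) and capped at 80 dB SPL so the SNR cannot
#' fall below -15 dB; the independent variant uses 6/2 dB steps over budgets
#' 4/6, starts at +2 dB SNR and holds the overall digits-plus-noise level
#' constant at 65 dB SPL.
#'
#' @param name one of `"ai_powered"`, `"keyboard"`, `"independent"`.
#' @return A [din_config()] object.
#' @export
#' @examples
#' din_preset("independent")$phase_steps_db  # 6 then 2 dB
din_preset <- function(name = c("ai_powered", "keyboard", "independent")) {
  name <- match.arg(name)
  switch(name,
    ai_powered = din_config(
      name = "ai_powered",
      phase_steps_db = c(5, 3, 1),
      phase_reversals = c(2L, 2L, 6L),
      initial_snr_db = 5,
      speech_level_db_spl = 65,
      level_policy = "fixed_speech_adaptive_noise",
      noise_cap_db_spl = 80,
      snr_floor_db = -15,
      floor_correct_limit = 6L
    ),
    keyboard = {
      cfg <- din_preset("ai_powered")
      cfg$name <- "keyboard"
      cfg
    },
    independent = din_config(
      name = "independent",
      phase_steps_db = c(6, 2),
      phase_reversals = c(4L, 6L),
      initial_snr_db = 2,
      speech_level_db_spl = 65,
      level_policy = "constant_overall_level"
    )
  )
}

#' Read or write a staircase configuration as YAML
#'
#' @param config a [din_config()] object.
#' @param path file path.
#' @return `write_din_config()` returns `path` invisibly; `read_din_config()`
#'   returns a `din_config`.
#' @export
write_din_config <- function(config, path) {
  stopifnot(inherits(config, "din_config"))
  x <- unclass(config)
  x$noise_cap_db_spl <- if (is.na(x$noise_cap_db_spl)) NULL else x$noise_cap_db_spl
  x$snr_floor_db <- if (is.na(x$snr_floor_db)) NULL else x$snr_floor_db
  x$total_reversals <- NULL
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_din_config
#' @export
read_din_config <- function(path) {
  x <- yaml::read_yaml(path)
  din_config(
    name = x$name %||% "custom",
    n_down = x$n_down %||% 2L,
    n_up = x$n_up %||% 1L,
    phase_steps_db = unlist(x$phase_steps_db),
    phase_reversals = unlist(x$phase_reversals),
    initial_snr_db = x$initial_snr_db,
    speech_level_db_spl = x$speech_level_db_spl %||% 65,
    level_policy = x$level_policy %||% "fixed_speech_adaptive_noise",
    noise_cap_db_spl = x$noise_cap_db_spl %||% NA_real_,
    snr_floor_db = x$snr_floor_db %||% NA_real_,
    floor_correct_limit = x$floor_correct_limit %||% 6L,
    srt_estimator = x$srt_estimator %||% "mean_final_phase_trial_snrs",
    max_trials = x$max_trials %||% 200L
  )
}

#' @export
print.din_config <- function(x, ...) {
  cat("<din_config> ", x$name, "\n", sep = "")
  cat("  rule: ", x$n_down, "-down/", x$n_up, "-up\n", sep = "")
  cat("  phases: steps", paste(x$phase_steps_db, collapse = "/"),
      "dB over reversals", paste(x$phase_reversals, collapse = "/"), "\n")
  cat("  initial SNR:", x$initial_snr_db, "dB;",
      "policy:", x$level_policy, "\n")
  if (!is.na(x$snr_floor_db)) {
    cat("  SNR floor:", x$snr_floor_db, "dB (",
        x$floor_correct_limit, "correct at floor terminates )\n")
  }
  invisible(x)
}

# phase index (1-based) for a given count of completed reversals
phase_of <- function(reversals_completed, config) {
  cuts <- cumsum(config$phase_reversals)
  idx <- which(reversals_completed < cuts)
  if (length(idx) == 0L) length(cuts) else idx[1L]
}

empty_trials <- function() {
  tibble::tibble(
    trial = integer(),
    digits = character(),
    snr_db = numeric(),
    speech_db_spl = numeric(),
    noise_db_spl = numeric(),
    response = character(),
    correct = logical(),
    raw_transcript = character(),
    asr_mistake = logical(),
    phase = integer(),
    reversal = logical()
  )
}

# the per-trial log is accumulated as a list of plain rows (appending a row
# to a tibble every trial is the hot path of a simulation); trials()
# materializes it
materialize_trials <- function(rows) {
  if (length(rows) == 0L) return(empty_trials())
  dplyr::bind_rows(rows)
}

#' Start a new staircase track
#'
#' @param config a [din_config()].
#' @return A `din_track` object holding the evolving state: current SNR,
#'   consecutive-correct counter, movement direction, reversal count, phase,
#'   floor-correct count, termination flags and the trial log (a tibble, one
#'   row per presentation).
#' @export
#' @examples
#' tr <- new_track(din_preset("ai_powered"))
#' tr$current_snr_db  # 5
new_track <- function(config) {
  stopifnot(inherits(config, "din_config"))
  structure(
    list(
      config = config,
      trial_index = 0L,
      current_snr_db = config$initial_snr_db,
      consecutive_correct = 0L,
      direction = "none",           # sign of the last SNR movement
      reversals_completed = 0L,
      phase_index = 1L,
      floor_correct_count = 0L,
      terminated = FALSE,
      floored = FALSE,
      trial_rows = list()
    ),
    class = "din_track"
  )
}

#' @export
print.din_track <- function(x, ...) {
  cat("<din_track> ", x$config$name,
      " | trial ", x$trial_index,
      " | SNR ", x$current_snr_db, " dB",
      " | reversals ", x$reversals_completed, "/", x$config$total_reversals,
      if (x$terminated) if (x$floored) " | floored" else " | terminated" else "",
      "\n", sep = "")
  invisible(x)
}

#' Step size in force for the next SNR movement
#'
#' The step belongs to the phase containing the number of reversals completed
#' so far, so a phase advance takes effect on the movement after the reversal
#' that completed the previous phase's budget.
#'
#' @param state a `din_track`.
#' @param config optional [din_config()]; defaults to the track's own.
#' @return Step size in dB.
#' @export
#' @examples
#' current_step_db(new_track(din_preset("ai_powered")))  # 5
current_step_db <- function(state, config = state$config) {
  if (state$terminated) stop("track already terminated", call. = FALSE)
  config$phase_steps_db[phase_of(state$reversals_completed, config)]
}

# presentation levels at a given SNR under the configured policy
levels_at_snr <- function(snr_db, config) {
  if (config$level_policy == "fixed_speech_adaptive_noise") {
    speech <- config$speech_level_db_spl
    noise <- speech - snr_db
    if (!is.na(config$noise_cap_db_spl)) noise <- min(noise, config$noise_cap_db_spl)
  } else {
    # split a constant overall power between speech and noise at the SNR ratio
    r <- 10^(snr_db / 10)
    speech <- config$speech_level_db_spl + 10 * log10(r / (1 + r))
    noise <- config$speech_level_db_spl + 10 * log10(1 / (1 + r))
  }
  c(speech = speech, noise = noise)
}

#' Advance a staircase by one scored response
#'
#' Applies the transformed up-down update: a run of `n_down` consecutive
#' correct responses moves the SNR down (harder) by the current phase's step
#' and resets the counter; any incorrect response resets the counter and
#' moves the SNR up (easier). A movement whose sign differs from the previous
#' movement's counts as a reversal; reversals advance the phase schedule and
#' the track terminates when the total reversal budget is spent. When an SNR
#' floor is configured, correct responses delivered at the floor are counted
#' and the track terminates "floored" once `floor_correct_limit` is reached.
#' Requested movements that would cross the floor are clamped but retain
#' their direction for reversal bookkeeping.
#'
#' The presented trial (at the pre-update SNR, with the policy's speech and
#' noise levels) is appended to the track's trial log.
#'
#' @param state a non-terminated `din_track`.
#' @param correct logical: was the triplet repeated fully and in order?
#' @param digits optional presented triplet (integer vector) for the log.
#' @param response optional responded digits for the log.
#' @param raw_transcript optional transcript text for the log.
#' @param asr_mistake logical: was this trial wrong only because the
#'   recognizer mis-transcribed a correctly spoken answer?
#' @return The updated `din_track`.
#' @export
#' @examples
#' tr <- new_track(din_preset("ai_powered"))
#' tr <- apply_response(tr, TRUE)   # counter 1, SNR unchanged
#' tr <- apply_response(tr, TRUE)   # second correct: SNR drops 5 dB
#' tr$current_snr_db                # 0
apply_response <- function(state, correct,
                           digits = NULL, response = NULL,
                           raw_transcript = NA_character_,
                           asr_mistake = FALSE) {
  stopifnot(inherits(state, "din_track"), is.logical(correct), length(correct) == 1L)
  if (state$terminated) stop("cannot apply a response to a terminated track", call. = FALSE)
  config <- state$config

  presented_snr <- state$current_snr_db
  lv <- levels_at_snr(presented_snr, config)
  phase_now <- phase_of(state$reversals_completed, config)

  rec <- list(
    trial = state$trial_index + 1L,
    digits = if (is.null(digits)) NA_character_ else paste(digits, collapse = "-"),
    snr_db = presented_snr,
    speech_db_spl = unname(lv["speech"]),
    noise_db_spl = unname(lv["noise"]),
    response = if (is.null(response)) NA_character_ else paste(response, collapse = "-"),
    correct = correct,
    raw_transcript = raw_transcript,
    asr_mistake = isTRUE(asr_mistake),
    phase = phase_now,
    reversal = FALSE
  )

  state$trial_index <- state$trial_index + 1L

  # floor rule: count correct answers given at the clamped floor SNR
  at_floor <- !is.na(config$snr_floor_db) &&
    isTRUE(all.equal(presented_snr, config$snr_floor_db))
  if (correct && at_floor) {
    state$floor_correct_count <- state$floor_correct_count + 1L
    if (state$floor_correct_count >= config$floor_correct_limit) {
      state$trial_rows[[length(state$trial_rows) + 1L]] <- rec
      state$floored <- TRUE
      state$terminated <- TRUE
      return(state)
    }
  }

  # 2-down / 1-up movement decision
  move <- 0L
  if (correct) {
    state$consecutive_correct <- state$consecutive_correct + 1L
    if (state$consecutive_correct >= config$n_down) {
      move <- -1L
      state$consecutive_correct <- 0L   # counter resets after each decrease
    }
  } else {
    state$consecutive_correct <- 0L
    move <- 1L
  }

  if (move != 0L) {
    step <- config$phase_steps_db[phase_now]  # step set by reversals before the move
    new_snr <- presented_snr + move * step
    if (!is.na(config$snr_floor_db)) new_snr <- max(new_snr, config$snr_floor_db)

    dir_chr <- if (move < 0L) "down" else "up"
    if (state$direction != "none" && state$direction != dir_chr) {
      state$reversals_completed <- state$reversals_completed + 1L
      rec$reversal <- TRUE
      if (state$reversals_completed >= config$total_reversals) {
        state$terminated <- TRUE
      }
    }
    state$direction <- dir_chr
    state$current_snr_db <- new_snr
    state$phase_index <- phase_of(state$reversals_completed, config)
  }

  state$trial_rows[[length(state$trial_rows) + 1L]] <- rec
  state
}

#' Has the floor rule fired?
#'
#' @param state a `din_track`.
#' @param config optional config (defaults to the track's).
#' @return `TRUE` when the number of correct responses given at the floor SNR
#'   has reached `floor_correct_limit`.
#' @export
check_floor_rule <- function(state, config = state$config) {
  if (is.na(config$snr_floor_db)) return(FALSE)
  state$floor_correct_count >= config$floor_correct_limit
}

#' Estimate the speech reception threshold from a terminated track
#'
#' For a floored run the result is the floor value itself, flagged as a bound
#' ("this value or lower"). Otherwise the default estimator averages the SNR
#' of every trial presented during the final phase; the alternative averages
#' only the final-phase reversal points.
#'
#' @param state a terminated `din_track`.
#' @param config optional config (defaults to the track's).
#' @return A one-row tibble with `srt_db`, `floored` and `n_trials_averaged`.
#' @export
estimate_srt <- function(state, config = state$config) {
  if (!state$terminated) stop("track has not terminated", call. = FALSE)
  if (state$floored) {
    return(tibble::tibble(
      srt_db = config$snr_floor_db, floored = TRUE, n_trials_averaged = 0L
    ))
  }
  final_phase <- length(config$phase_steps_db)
  logd <- trials(state)
  tr <- logd[logd$phase == final_phase, , drop = FALSE]
  if (config$srt_estimator == "mean_final_phase_reversal_snrs") {
    tr <- tr[tr$reversal, , drop = FALSE]
  }
  if (nrow(tr) == 0L) stop("no final-phase trials to average", call. = FALSE)
  tibble::tibble(
    srt_db = mean(tr$snr_db), floored = FALSE, n_trials_averaged = nrow(tr)
  )
}

#' Replay a sequence of scored responses through the update rule
#'
#' Rebuilds a track from scratch by re-applying a correctness sequence. Used
#' as the replay oracle: feeding back the `correct` column of any logged
#' session must reproduce the identical SNR trajectory.
#'
#' @param config a [din_config()].
#' @param corrects logical vector of scored responses, in trial order.
#' @return The resulting `din_track`.
#' @export
#' @examples
#' cfg <- din_preset("ai_powered")
#' tr <- replay_track(cfg, c(TRUE, TRUE, FALSE, TRUE, TRUE))
#' tr$trials$snr_db
replay_track <- function(config, corrects) {
  state <- new_track(config)
  for (ok in corrects) {
    if (state$terminated) break
    state <- apply_response(state, ok)
  }
  state
}

#' Trial log of a track as a tibble
#'
#' @param state a `din_track`.
#' @return The trial log tibble (one row per presentation).
#' @export
trials <- function(state) {
  stopifnot(inherits(state, "din_track"))
  materialize_trials(state$trial_rows)
}

#' Write or read a session log as JSON lines
#'
#' One JSON object per trial, preceded by a schema/config header line, so a
#' session can be archived as plain text and replayed bit-exactly.
#'
#' @param state a terminated or in-progress `din_track`.
#' @param path file path (".jsonl").
#' @return `write_session_log()` returns `path` invisibly; `read_session_log()`
#'   returns a list with `config` and `trials`.
#' @export
write_session_log <- function(state, path) {
  stopifnot(inherits(state, "din_track"))
  header <- jsonlite::toJSON(
    list(schema = "din-session/1", config = unclass(state$config),
         terminated = state$terminated, floored = state$floored),
    auto_unbox = TRUE, digits = NA, null = "null", na = "null"
  )
  rows <- vapply(state$trial_rows, function(r) {
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA, na = "null"))
  }, character(1))
  writeLines(c(as.character(header), rows), path)
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) {
  lines <- readLines(path)
  header <- jsonlite::fromJSON(lines[1L])
  if (!identical(header$schema, "din-session/1")) {
    stop("not a DIN session log (missing schema header)", call. = FALSE)
  }
  cfg <- header$config
  config <- din_config(
    name = cfg$name, n_down = cfg$n_down, n_up = cfg$n_up,
    phase_steps_db = cfg$phase_steps_db, phase_reversals = cfg$phase_reversals,
    initial_snr_db = cfg$initial_snr_db,
    speech_level_db_spl = cfg$speech_level_db_spl,
    level_policy = cfg$level_policy,
    noise_cap_db_spl = cfg$noise_cap_db_spl %||% NA_real_,
    snr_floor_db = cfg$snr_floor_db %||% NA_real_,
    floor_correct_limit = cfg$floor_correct_limit,
    srt_estimator = cfg$srt_estimator, max_trials = cfg$max_trials
  )
  trl <- purrr::map_dfr(lines[-1L], function(l) {
    x <- jsonlite::fromJSON(l)
    x <- lapply(x, function(v) if (is.null(v)) NA else v)
    tibble::as_tibble(x)
  })
  # JSON round-trip loses R's integer/double distinction; restore the schema
  num_cols <- c("snr_db", "speech_db_spl", "noise_db_spl")
  int_cols <- c("trial", "phase")
  chr_cols <- c("digits", "response", "raw_transcript")
  for (cc in intersect(num_cols, names(trl))) trl[[cc]] <- as.numeric(trl[[cc]])
  for (cc in intersect(int_cols, names(trl))) trl[[cc]] <- as.integer(trl[[cc]])
  for (cc in intersect(chr_cols, names(trl))) trl[[cc]] <- as.character(trl[[cc]])
  list(config = config, trials = trl,
       terminated = isTRUE(header$terminated), floored = isTRUE(header$floored))
}

#' Plot the SNR trajectory of a staircase track
#'
#' @param object a `din_track`.
#' @param ... ignored.
#' @return A ggplot: trial number against presented SNR, reversal points
#'   marked, phase shading, floor line when configured.
#' @method autoplot din_track
#' @export
autoplot.din_track <- function(object, ...) {
  df <- trials(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$trial, y = .data$snr_db)) +
    ggplot2::geom_step(direction = "hv", colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$correct, shape = .data$reversal),
                        size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17)) +
    ggplot2::labs(x = "Trial", y = "SNR (dB)",
                  title = paste0("Staircase track (", object$config$name, ")"),
                  colour = "Correct", shape = "Reversal") +
    ggplot2::theme_minimal()
  if (!is.na(object$config$snr_floor_db)) {
    p <- p + ggplot2::geom_hline(yintercept = object$config$snr_floor_db,
                                 linetype = "dashed", colour = "firebrick")
  }
  p
}
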
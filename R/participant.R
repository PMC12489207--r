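# ---- reproducible substreams ------------------------------------------------
# One root seed per experiment; each consumer (triplet sampling, listener,
# recognizer corruption) gets its own saved RNG state so, e.g., changing the
# corruption level never perturbs the listener's draws.

rng_stream <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  env
}

with_stream <- function(stream, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", stream$state, globalenv())
  on.exit({
    stream$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  })
  force(expr)
}

# derive k child seeds (< 2^31) from one root seed
derive_seeds <- function(root_seed, k) {
  st <- rng_stream(root_seed)
  with_stream(st, sample.int(.Machine$integer.max - 1L, k))
}

#' A stochastic virtual listener
#'
#' Parameterizes the psychometric function of a simulated participant: the
#' probability of repeating the whole triplet correctly as a function of SNR,
#' p(SNR) = guess + (1 - guess - lapse) * logistic(4 * slope * (SNR - threshold)),
#' scaled so `slope_per_db` is (for negligible guess/lapse) the derivative of
#' p at threshold and p(threshold) = 0.5 midway between the asymptotes.
#'
#' The triplet-level function is the default; `mode = "per_digit"` instead
#' treats the logistic as a per-digit probability and scores the triplet as
#' its cube.
#'
#' @param threshold_db SNR of 50% triplet correctness, dB.
#' @param slope_per_db psychometric slope at threshold, probability per dB.
#' @param lapse_rate probability of an error at arbitrarily easy SNR.
#' @param guess_rate floor probability at arbitrarily hard SNR (near zero for
#'   an open-set triplet task: one in 720 ordered triplets).
#' @param mode `"triplet"` or `"per_digit"`.
#' @return A `listener_model` object.
#' @export
listener_model <- function(threshold_db = -10, slope_per_db = 0.15,
                           lapse_rate = 0.01, guess_rate = 1 / 720,
                           mode = c("triplet", "per_digit")) {
  mode <- match.arg(mode)
  stopifnot(slope_per_db > 0,
            lapse_rate >= 0, lapse_rate <= 1,
            guess_rate >= 0, guess_rate <= 1)
  structure(list(threshold_db = threshold_db, slope_per_db = slope_per_db,
                 lapse_rate = lapse_rate, guess_rate = guess_rate, mode = mode),
            class = "listener_model")
}

#' Probability of a correct triplet response at a given SNR
#'
#' @param listener a [listener_model()].
#' @param snr_db SNR (vectorized), dB.
#' @return Probability vector.
#' @export
#' @examples
#' psychometric_p(listener_model(threshold_db = -10, lapse_rate = 0,
#'                               guess_rate = 0), -10)  # 0.5
psychometric_p <- function(listener, snr_db) {
  core <- stats::plogis(4 * listener$slope_per_db * (snr_db - listener$threshold_db))
  p <- listener$guess_rate + (1 - listener$guess_rate - listener$lapse_rate) * core
  if (listener$mode == "per_digit") p^3 else p
}

#' SNR at which the listener reaches a target proportion correct
#'
#' Solves p(SNR) = `p` numerically. The 2-down/1-up staircase converges near
#' p = 1/sqrt(2) ~ 0.707, so `snr_at_p(listener)` gives the convergence
#' point a well-behaved track should estimate.
#'
#' @param listener a [listener_model()].
#' @param p target proportion correct (default `1/sqrt(2)`).
#' @return SNR in dB.
#' @export
snr_at_p <- function(listener, p = 1 / sqrt(2)) {
  upper_lim <- 1 - listener$lapse_rate
  if (listener$mode == "per_digit") upper_lim <- upper_lim^3
  if (p >= upper_lim || p <= psychometric_p(listener, -1e3)) {
    stop("target proportion outside the listener's attainable range", call. = FALSE)
  }
  stats::uniroot(function(s) psychometric_p(listener, s) - p,
                 interval = listener$threshold_db + c(-200, 200),
                 tol = 1e-10)$root
}

#' Draw one response from a virtual listener
#'
#' @param listener a [listener_model()].
#' @param snr_db presented SNR, dB.
#' @return Logical: triplet repeated correctly?
#' @export
respond <- function(listener, snr_db) {
  stats::runif(1) < psychometric_p(listener, snr_db)
}

#' A recognizer-corruption model
#'
#' A single parameter: the probability that a *correctly spoken* triplet is
#' transcribed as a wrong digit sequence. Corruption only ever turns a
#' correct spoken answer into a wrong transcript — a wrong answer is never
#' transcribed into the correct one, matching how mis-transcriptions are
#' tallied (a trial wrong through both the listener and the recognizer is
#' attributed to the listener).
#'
#' @param corruption_prob probability in \[0, 1\].
#' @return An `asr_error_model` object.
#' @export
asr_error_model <- function(corruption_prob = 0) {
  stopifnot(corruption_prob >= 0, corruption_prob <= 1)
  structure(list(corruption_prob = corruption_prob), class = "asr_error_model")
}

#' Corrupt a spoken triplet through the recognizer model
#'
#' @param asr an [asr_error_model()].
#' @param spoken integer vector, the digits the listener said.
#' @param was_correct logical: did the spoken answer match the presented
#'   triplet?
#' @return A list: `digits` (the transcript) and `asr_mistake` (`TRUE` when a
#'   correct spoken answer was mis-transcribed).
#' @export
corrupt <- function(asr, spoken, was_correct) {
  spoken <- as.integer(spoken)
  if (was_correct && stats::runif(1) < asr$corruption_prob) {
    pos <- sample.int(length(spoken), 1L)
    spoken[pos] <- sample(setdiff(0:9, spoken[pos]), 1L)
    list(digits = spoken, asr_mistake = TRUE)
  } else {
    list(digits = spoken, asr_mistake = FALSE)
  }
}

# a plausible wrong spoken answer: perturb one digit of the presented triplet
perturb_triplet <- function(presented) {
  pos <- sample.int(3L, 1L)
  presented[pos] <- sample(setdiff(0:9, presented), 1L)
  presented
}

#' Simulate one complete staircase session
#'
#' Runs the full loop of a DIN test run against a virtual listener: draw a
#' non-repeating triplet, present it at the track's SNR (levels logged per
#' the level policy), draw the listener's response, optionally pass it
#' through the recognizer-corruption model, score order-sensitively, and
#' update the staircase until termination.
#'
#' Randomness is split into three substreams derived from `seed` (triplet
#' sampling, listener, recognizer), so e.g. two sessions with the same seed
#' but different corruption levels share their listener draws.
#'
#' @param config a [din_config()].
#' @param listener a [listener_model()].
#' @param asr an [asr_error_model()], or `NULL` for a keyed (error-free)
#'   response path.
#' @param seed integer seed for this run.
#' @return A terminated `din_track` with a full trial log.
#' @export
#' @examples
#' tr <- run_session(din_preset("ai_powered"),
#'                   listener_model(threshold_db = -8), seed = 42)
#' estimate_srt(tr)
run_session <- function(config, listener, asr = NULL, seed = 1L) {
  stopifnot(inherits(config, "din_config"), inherits(listener, "listener_model"))
  seeds <- derive_seeds(seed, 3L)
  triplet_stream <- rng_stream(seeds[1])
  listener_stream <- rng_stream(seeds[2])
  asr_stream <- rng_stream(seeds[3])

  state <- new_track(config)
  while (!state$terminated) {
    if (state$trial_index >= config$max_trials) {
      stop("staircase did not terminate within ", config$max_trials,
           " trials (runaway session)", call. = FALSE)
    }
    presented <- with_stream(triplet_stream, sample_triplet())
    spoken_correct <- with_stream(listener_stream, respond(listener, state$current_snr_db))
    spoken <- if (spoken_correct) presented
              else with_stream(listener_stream, perturb_triplet(presented))
    if (is.null(asr)) {
      transcript <- list(digits = spoken, asr_mistake = FALSE)
    } else {
      transcript <- with_stream(asr_stream, corrupt(asr, spoken, spoken_correct))
    }
    scored <- score_response(presented, transcript$digits)
    state <- apply_response(
      state, scored,
      digits = presented, response = transcript$digits,
      raw_transcript = paste(transcript$digits, collapse = " "),
      asr_mistake = transcript$asr_mistake
    )
  }
  state
}
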
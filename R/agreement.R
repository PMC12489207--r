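#' Recognizer error rate for a run
#'
#' The proportion (as a percentage) of all incorrect trials in a run that
#' were caused by the recognizer mis-transcribing a correctly spoken answer,
#' rather than by the listener: `100 * asr_mistakes / all_mistakes`. This is
#' a proportion of the *errors*, not of all trials, so it runs far higher
#' than word-error-rate style metrics. With no mistakes at all the rate is
#' undefined and returned as `NA` (not 0).
#'
#' @param asr_mistakes count of recognizer-caused mistakes.
#' @param all_mistakes count of all incorrect trials.
#' @return Percentage in \[0, 100\], or `NA_real_` when `all_mistakes` is 0.
#' @export
#' @examples
#' asr_error_rate(4, 10)  # 40
asr_error_rate <- function(asr_mistakes, all_mistakes) {
  stopifnot(all(asr_mistakes >= 0), all(all_mistakes >= 0),
            all(asr_mistakes <= all_mistakes | all_mistakes == 0))
  ifelse(all_mistakes == 0, NA_real_, 100 * asr_mistakes / all_mistakes)
}

#' Attribute an incorrect trial to the listener or the recognizer
#'
#' A wrong trial is a recognizer mistake only when the listener actually
#' spoke the presented triplet and the transcript differs. When the listener
#' was wrong — even if the recognizer then also mangled the answer — the
#' mistake belongs to the listener, because the next SNR would have been
#' wrong either way.
#'
#' @param presented integer triplet shown.
#' @param spoken integer vector the listener said (ground truth).
#' @param transcript integer vector the recognizer produced.
#' @return `"asr"` or `"participant"`.
#' @export
#' @examples
#' attribute_mistake(c(6, 1, 2), spoken = c(6, 1, 2), transcript = c(6, 1, 5))
attribute_mistake <- function(presented, spoken, transcript) {
  if (score_response(presented, transcript)) {
    stop("trial was scored correct; nothing to attribute", call. = FALSE)
  }
  spoken_ok <- length(spoken) == 3L && all(as.integer(spoken) == as.integer(presented))
  if (spoken_ok) "asr" else "participant"
}

#' Tally mistakes for each run of a results table
#'
#' @param results a run-level tibble with columns `asr_mistakes` and
#'   `all_mistakes` (as produced by [run_experiment()]).
#' @return The tibble with an `asr_error_rate` column appended.
#' @export
add_error_rates <- function(results) {
  dplyr::mutate(results,
                asr_error_rate = asr_error_rate(.data$asr_mistakes, .data$all_mistakes))
}

#' Exclude participants with excessive recognizer error rates
#'
#' Two policies mirror how outliers are handled in validity versus
#' reliability analyses of a spoken-response test:
#' `"validity_mean_of_runs"` excludes a participant when the error rate
#' averaged across their spoken-response runs exceeds the threshold;
#' `"reliability_either_of_first_two"` excludes when run 1 *or* run 2
#' exceeds it. Runs with no mistakes contribute no rate (NA) and are
#' ignored in the average; a participant with no computable rate is kept.
#'
#' @param results run-level tibble with columns `id`, `test`, `run`,
#'   `asr_mistakes`, `all_mistakes`.
#' @param threshold_pct exclusion threshold in percent (default 40).
#' @param mode exclusion policy.
#' @param test which test's runs carry the recognizer (default
#'   `"ai_powered"`).
#' @return A list: `kept` and `excluded` (character id vectors), and
#'   `rates`, a per-participant tibble of the statistic the rule used.
#' @export
exclude_outliers <- function(results, threshold_pct = 40,
                             mode = c("validity_mean_of_runs",
                                      "reliability_either_of_first_two"),
                             test = "ai_powered") {
  mode <- match.arg(mode)
  runs <- dplyr::filter(add_error_rates(results), .data$test == !!test)
  if (nrow(runs) == 0L) stop("no runs found for test '", test, "'", call. = FALSE)
  if (mode == "validity_mean_of_runs") {
    rates <- runs |>
      dplyr::group_by(.data$id) |>
      dplyr::summarise(rate = if (all(is.na(.data$asr_error_rate))) NA_real_
                              else mean(.data$asr_error_rate, na.rm = TRUE),
                       .groups = "drop")
  } else {
    first_two <- dplyr::filter(runs, .data$run <= 2L)
    if (any(tapply(first_two$run, first_two$id, length) < 2L)) {
      stop("reliability exclusion needs runs 1 and 2 for every participant",
           call. = FALSE)
    }
    rates <- first_two |>
      dplyr::group_by(.data$id) |>
      dplyr::summarise(rate = if (all(is.na(.data$asr_error_rate))) NA_real_
                              else max(.data$asr_error_rate, na.rm = TRUE),
                       .groups = "drop")
  }
  excluded <- rates$id[!is.na(rates$rate) & rates$rate > threshold_pct]
  list(kept = setdiff(rates$id, excluded), excluded = excluded, rates = rates)
}

#' Aggregate a participant's SRT runs
#'
#' @param srt_db numeric vector of per-run SRTs, in run order.
#' @param floored logical vector flagging runs recorded at the floor ("this
#'   value or lower").
#' @param mode `"mean_all"` (one pooled value) or `"first_two"` (the ordered
#'   pair for test-retest analysis).
#' @return A tibble with `srt_db` and `is_bound` (TRUE when any contributing
#'   run was floored, so the aggregate is an upper bound, not a point
#'   estimate); one row for `"mean_all"`, two for `"first_two"`.
#' @export
aggregate_srt <- function(srt_db, floored = rep(FALSE, length(srt_db)),
                          mode = c("mean_all", "first_two")) {
  mode <- match.arg(mode)
  if (length(srt_db) == 0L) stop("no runs to aggregate", call. = FALSE)
  if (mode == "mean_all") {
    tibble::tibble(srt_db = mean(srt_db), is_bound = any(floored))
  } else {
    if (length(srt_db) < 2L) stop("test-retest aggregation needs two runs", call. = FALSE)
    tibble::tibble(srt_db = srt_db[1:2], is_bound = floored[1:2])
  }
}

#' Bland-Altman agreement between two paired measurement series
#'
#' Computes the classical agreement report for paired SRT series: the bias
#' (mean of the differences `a - b`), the SD of the differences, the 95%
#' limits of agreement `bias +/- 1.96 * SD`, plus the Pearson correlation
#' and RMSE over the same pairs. The 1.96 multiplier is used without a
#' small-sample correction.
#'
#' @param a,b numeric vectors of equal length (>= 3), paired by participant.
#' @param ids optional participant labels.
#' @return A `din_agreement` object; see [tidy.din_agreement()].
#' @export
#' @examples
#' bland_altman(c(-8, -9, -10, -7), c(-9, -9, -11, -8))
bland_altman <- function(a, b, ids = NULL) {
  if (length(a) != length(b)) stop("series are not paired (length mismatch)", call. = FALSE)
  if (length(a) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("missing values in paired series", call. = FALSE)
  d <- a - b
  sd_d <- stats::sd(d)
  r <- if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero variance in a series; Pearson r undefined")
    NA_real_
  } else {
    stats::cor(a, b)
  }
  structure(
    list(
      bias = mean(d),
      sd_diff = sd_d,
      loa_halfwidth = 1.96 * sd_d,
      loa_lower = mean(d) - 1.96 * sd_d,
      loa_upper = mean(d) + 1.96 * sd_d,
      pearson_r = r,
      rmse = sqrt(mean(d^2)),
      n = length(d),
      a = a, b = b, ids = ids %||% as.character(seq_along(a))
    ),
    class = "din_agreement"
  )
}

#' @export
print.din_agreement <- function(x, ...) {
  cat(sprintf("<din_agreement> n = %d\n  bias %+.2f dB, LoA %+.2f to %+.2f dB (+/- %.2f)\n  Pearson r = %s, RMSE = %.2f dB\n",
              x$n, x$bias, x$loa_lower, x$loa_upper, x$loa_halfwidth,
              ifelse(is.na(x$pearson_r), "NA", sprintf("%.2f", x$pearson_r)),
              x$rmse))
  invisible(x)
}

#' Tidy an agreement report
#'
#' @param x a `din_agreement` object.
#' @param ... ignored.
#' @return One-row tibble: `bias`, `sd_diff`, `loa_halfwidth`, `loa_lower`,
#'   `loa_upper`, `pearson_r`, `rmse`, `n`.
#' @method tidy din_agreement
#' @export
tidy.din_agreement <- function(x, ...) {
  tibble::tibble(
    bias = x$bias, sd_diff = x$sd_diff, loa_halfwidth = x$loa_halfwidth,
    loa_lower = x$loa_lower, loa_upper = x$loa_upper,
    pearson_r = x$pearson_r, rmse = x$rmse, n = x$n
  )
}

#' @rdname tidy.din_agreement
#' @method glance din_agreement
#' @export
glance.din_agreement <- function(x, ...) tidy(x)

#' Bland-Altman plot of an agreement report
#'
#' @param object a `din_agreement` object.
#' @param ... ignored.
#' @return A ggplot: pair means against differences, with bias and limits of
#'   agreement.
#' @method autoplot din_agreement
#' @export
autoplot.din_agreement <- function(object, ...) {
  df <- tibble::tibble(mean = (object$a + object$b) / 2, diff = object$a - object$b)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$bias, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "Mean of pair (dB)", y = "Difference (dB)",
                  title = sprintf("Bland-Altman: bias %+.2f dB, LoA +/- %.2f dB",
                                  object$bias, object$loa_halfwidth)) +
    ggplot2::theme_minimal()
}
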
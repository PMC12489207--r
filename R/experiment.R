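#' Plan a simulated multi-run study
#'
#' Describes a virtual replication of a three-test session design: every
#' participant performs `n_ai` spoken-response (AI-powered) runs, `n_independent`
#' independent-test runs and `n_keyboard` keyboard runs, in a fixed order.
#' Listener thresholds are drawn per participant from group-specific ranges
#' (a normal-hearing and a hearing-impaired group); the recognizer-corruption
#' level applies to the spoken-response runs only. All randomness descends
#' deterministically from `root_seed`.
#'
#' @param n_normal,n_impaired group sizes (defaults 21 and 10).
#' @param threshold_range_normal,threshold_range_impaired SRT-threshold
#'   ranges (dB) the two groups' listeners are drawn from, uniformly.
#' @param slope_per_db,lapse_rate,guess_rate listener parameters shared by
#'   all participants.
#' @param corruption_prob recognizer corruption probability for spoken runs.
#' @param n_ai,n_independent,n_keyboard runs per test variant (default
#'   3/2/1).
#' @param root_seed integer root seed.
#' @return An `experiment_plan` object.
#' @export
experiment_plan <- function(n_normal = 21L, n_impaired = 10L,
                            threshold_range_normal = c(-12, -8),
                            threshold_range_impaired = c(-7, 0),
                            slope_per_db = 0.15, lapse_rate = 0.01,
                            guess_rate = 1 / 720,
                            corruption_prob = 0,
                            n_ai = 3L, n_independent = 2L, n_keyboard = 1L,
                            root_seed = 1L) {
  structure(list(
    n_normal = as.integer(n_normal), n_impaired = as.integer(n_impaired),
    threshold_range_normal = threshold_range_normal,
    threshold_range_impaired = threshold_range_impaired,
    slope_per_db = slope_per_db, lapse_rate = lapse_rate,
    guess_rate = guess_rate, corruption_prob = corruption_prob,
    n_ai = as.integer(n_ai), n_independent = as.integer(n_independent),
    n_keyboard = as.integer(n_keyboard),
    root_seed = as.integer(root_seed)
  ), class = "experiment_plan")
}

#' Read or write an experiment plan as YAML
#'
#' @param plan an [experiment_plan()].
#' @param path file path.
#' @return the path / the plan.
#' @export
write_experiment_plan <- function(plan, path) {
  yaml::write_yaml(unclass(plan), path)
  invisible(path)
}

#' @rdname write_experiment_plan
#' @export
read_experiment_plan <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(experiment_plan, lapply(x, function(v) if (length(v) > 1) unlist(v) else v))
}

run_one_participant <- function(id, group, listener, plan, pseed,
                                configs, keep_logs = TRUE) {
  schedule <- c(rep("ai_powered", plan$n_ai),
                rep("independent", plan$n_independent),
                rep("keyboard", plan$n_keyboard))
  run_no <- stats::ave(seq_along(schedule), schedule, FUN = seq_along)
  seeds <- derive_seeds(pseed, length(schedule))
  asr <- asr_error_model(plan$corruption_prob)

  rows <- vector("list", length(schedule))
  logs <- if (keep_logs) vector("list", length(schedule)) else NULL
  for (k in seq_along(schedule)) {
    test <- schedule[k]
    track <- tryCatch(
      run_session(configs[[test]], listener,
                  asr = if (test == "ai_powered") asr else NULL,
                  seed = seeds[k]),
      error = function(e) e
    )
    if (inherits(track, "error")) {
      rows[[k]] <- tibble::tibble(
        id = id, group = group, test = test, run = run_no[k],
        srt_db = NA_real_, floored = NA, n_trials = NA_integer_,
        asr_mistakes = NA_integer_, all_mistakes = NA_integer_,
        failed = TRUE
      )
      next
    }
    srt <- estimate_srt(track)
    tl <- trials(track)
    rows[[k]] <- tibble::tibble(
      id = id, group = group, test = test, run = run_no[k],
      srt_db = srt$srt_db, floored = srt$floored, n_trials = nrow(tl),
      asr_mistakes = sum(tl$asr_mistake),
      all_mistakes = sum(!tl$correct),
      failed = FALSE
    )
    if (keep_logs) logs[[k]] <- track
  }
  if (keep_logs) {
    names(logs) <- paste0(schedule, "_run", run_no)
  }
  list(results = dplyr::bind_rows(rows), logs = logs)
}

#' Run a simulated study
#'
#' Executes the full session design for every virtual participant and
#' collects one results row per run. Per-participant seeds descend from the
#' plan's root seed, so the same plan always reproduces the same archive.
#' A runaway session aborts only that run (flagged `failed`), never the
#' experiment.
#'
#' @param plan an [experiment_plan()].
#' @param out_dir optional directory; when given, per-run session logs are
#'   written as JSON-lines files plus a `results.csv`.
#' @param keep_logs keep full trial logs in memory (default TRUE).
#' @return A `din_experiment` list: `results` (a run-level tibble: id, group,
#'   test, run, srt_db, floored, n_trials, asr_mistakes, all_mistakes,
#'   failed), `logs`, and the `plan`.
#' @export
#' @examples
#' ex <- run_experiment(experiment_plan(n_normal = 3, n_impaired = 1,
#'                                      root_seed = 7))
#' ex$results
run_experiment <- function(plan, out_dir = NULL, keep_logs = TRUE) {
  stopifnot(inherits(plan, "experiment_plan"))
  configs <- list(ai_powered = din_preset("ai_powered"),
                  keyboard = din_preset("keyboard"),
                  independent = din_preset("independent"))
  n <- plan$n_normal + plan$n_impaired
  groups <- c(rep("normal_hearing", plan$n_normal),
              rep("hearing_impaired", plan$n_impaired))
  ids <- sprintf("P%02d", seq_len(n))

  seeds <- derive_seeds(plan$root_seed, n + 1L)
  draw_stream <- rng_stream(seeds[n + 1L])
  thresholds <- with_stream(draw_stream, {
    ifelse(groups == "normal_hearing",
           stats::runif(n, plan$threshold_range_normal[1], plan$threshold_range_normal[2]),
           stats::runif(n, plan$threshold_range_impaired[1], plan$threshold_range_impaired[2]))
  })

  out <- vector("list", n)
  for (i in seq_len(n)) {
    listener <- listener_model(threshold_db = thresholds[i],
                               slope_per_db = plan$slope_per_db,
                               lapse_rate = plan$lapse_rate,
                               guess_rate = plan$guess_rate)
    out[[i]] <- run_one_participant(ids[i], groups[i], listener, plan,
                                    pseed = seeds[i], configs = configs,
                                    keep_logs = keep_logs)
  }
  results <- dplyr::bind_rows(lapply(out, `[[`, "results"))
  logs <- if (keep_logs) stats::setNames(lapply(out, `[[`, "logs"), ids) else NULL

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(results, file.path(out_dir, "results.csv"), row.names = FALSE)
    if (keep_logs) {
      log_dir <- file.path(out_dir, "logs")
      if (!dir.exists(log_dir)) dir.create(log_dir)
      for (id in ids) {
        for (nm in names(logs[[id]])) {
          if (!is.null(logs[[id]][[nm]])) {
            write_session_log(logs[[id]][[nm]],
                              file.path(log_dir, paste0(id, "_", nm, ".jsonl")))
          }
        }
      }
    }
  }
  structure(list(results = results, logs = logs, plan = plan),
            class = "din_experiment")
}

#' @export
print.din_experiment <- function(x, ...) {
  cat("<din_experiment> ", length(unique(x$results$id)), " participants, ",
      nrow(x$results), " runs (corruption ", x$plan$corruption_prob, ")\n", sep = "")
  invisible(x)
}

# per-participant paired series for one named comparison
comparison_pairs <- function(results, comparison) {
  wide <- results |>
    dplyr::filter(!.data$failed) |>
    dplyr::group_by(.data$id)
  per <- switch(comparison,
    validity_ai_vs_independent = wide |>
      dplyr::summarise(
        a = mean(.data$srt_db[.data$test == "ai_powered"]),
        b = mean(.data$srt_db[.data$test == "independent"]),
        .groups = "drop"),
    validity_keyboard_vs_independent = wide |>
      dplyr::summarise(
        a = mean(.data$srt_db[.data$test == "keyboard"]),
        b = mean(.data$srt_db[.data$test == "independent"]),
        .groups = "drop"),
    reliability_ai = wide |>
      dplyr::summarise(
        a = .data$srt_db[.data$test == "ai_powered" & .data$run == 1L][1],
        b = .data$srt_db[.data$test == "ai_powered" & .data$run == 2L][1],
        .groups = "drop"),
    reliability_independent = wide |>
      dplyr::summarise(
        a = .data$srt_db[.data$test == "independent" & .data$run == 1L][1],
        b = .data$srt_db[.data$test == "independent" & .data$run == 2L][1],
        .groups = "drop"),
    stop("unknown comparison: ", comparison, call. = FALSE)
  )
  per[stats::complete.cases(per), ]
}

#' Analyze a simulated study: the full comparison grid
#'
#' Recomputes the evaluation grid of a three-test agreement study from a
#' run-level results table: validity of the spoken-response test (against
#' the independent test) and its keyboard baseline, plus test-retest
#' reliability of the spoken-response and independent tests — each with and
#' without recognizer-error outlier exclusion (threshold in percent of
#' mistakes attributable to the recognizer). Exclusion applies where the
#' recognizer is involved: the validity rule averages error rates over the
#' spoken runs, the reliability rule looks at the worse of runs 1 and 2;
#' keyboard and independent comparisons have no recognizer, so their
#' excluded set is empty.
#'
#' @param x a `din_experiment` or its run-level results tibble.
#' @param exclude_threshold_pct outlier threshold in percent (default 40).
#' @return A tibble, one row per comparison x exclusion mode, with agreement
#'   statistics (`bias`, `sd_diff`, `loa_halfwidth`, `pearson_r`, `rmse`,
#'   `n`, `n_excluded`) and the full `din_agreement` object in a `report`
#'   list-column.
#' @export
analyze_experiment <- function(x, exclude_threshold_pct = 40) {
  results <- if (inherits(x, "din_experiment")) x$results else x
  comparisons <- c("validity_ai_vs_independent",
                   "validity_keyboard_vs_independent",
                   "reliability_ai",
                   "reliability_independent")
  grid <- tidyr::expand_grid(
    comparison = comparisons,
    exclusion = c("none", "asr_error")
  )
  rows <- purrr::pmap(grid, function(comparison, exclusion) {
    excluded <- character()
    if (exclusion == "asr_error" &&
        comparison %in% c("validity_ai_vs_independent", "reliability_ai")) {
      mode <- if (comparison == "reliability_ai") "reliability_either_of_first_two"
              else "validity_mean_of_runs"
      excluded <- exclude_outliers(results, exclude_threshold_pct, mode)$excluded
    }
    pairs <- comparison_pairs(dplyr::filter(results, !(.data$id %in% excluded)),
                              comparison)
    rep <- bland_altman(pairs$a, pairs$b, ids = pairs$id)
    dplyr::bind_cols(
      tibble::tibble(comparison = comparison, exclusion = exclusion,
                     n_excluded = length(excluded)),
      tidy(rep),
      tibble::tibble(report = list(rep))
    )
  })
  dplyr::bind_rows(rows)
}

#' Render an analysis grid as a markdown summary
#'
#' @param grid output of [analyze_experiment()].
#' @return A character vector of markdown lines.
#' @export
format_analysis_md <- function(grid) {
  c("# Simulated DIN study: agreement grid",
    "",
    "| comparison | exclusion | n | excl. | bias (dB) | LoA (+/- dB) | r | RMSE (dB) |",
    "|---|---|---|---|---|---|---|---|",
    sprintf("| %s | %s | %d | %d | %+.2f | %.2f | %s | %.2f |",
            grid$comparison, grid$exclusion, grid$n, grid$n_excluded,
            grid$bias, grid$loa_halfwidth,
            ifelse(is.na(grid$pearson_r), "NA", sprintf("%.2f", grid$pearson_r)),
            grid$rmse))
}
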
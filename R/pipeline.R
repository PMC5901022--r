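#' Configure a pipeline run
#'
#' Exactly one of `generator` (a [cohort_config()], for a synthetic run)
#' or `paths` (named list with `participants`, `trials`, and optionally
#' `tapping`, for recorded data) must be supplied.
#'
#' @param generator A [cohort_config()], or `NULL`.
#' @param paths Named list of input CSV paths, or `NULL`.
#' @param mcmc An [mcmc_config()] for the hierarchical stage.
#' @param hier Run the hierarchical Bayesian stage (default `TRUE`;
#'   disabling it leaves the classical analyses, useful for replicate
#'   calibration studies).
#' @param drop_no_response Use the no-response-excluded trials as the
#'   primary scoring analysis (default `FALSE`; the pipeline always also
#'   emits the paired sensitivity comparison).
#' @param alpha,n_comparisons Familywise significance settings.
#' @param seed Integer seed recorded in every output.
#' @param output_dir Directory for the report bundle.
#' @return A list of class `run_config`.
#' @export
run_config <- function(generator = cohort_config(), paths = NULL,
                       mcmc = mcmc_config(), hier = TRUE,
                       drop_no_response = FALSE,
                       alpha = 0.05, n_comparisons = 6, seed = 1L,
                       output_dir = tempfile("visuosdt_run_")) {
  if (is.null(generator) == is.null(paths)) {
    rlang::abort("supply exactly one of `generator` or `paths`")
  }
  structure(list(generator = generator, paths = paths, mcmc = mcmc,
                 hier = hier,
                 drop_no_response = drop_no_response, alpha = alpha,
                 n_comparisons = n_comparisons, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

stage <- function(name, log, expr) {
  log(list(stage = name, status = "start"))
  res <- tryCatch(expr, error = function(e) {
    log(list(stage = name, status = "error", message = conditionMessage(e)))
    rlang::abort(sprintf("pipeline stage '%s' failed: %s", name,
                         conditionMessage(e)))
  })
  log(list(stage = name, status = "done"))
  res
}

#' Run the full analysis pipeline
#'
#' Orchestrates generate/load, exclusions, task scoring, classical signal
#' detection, the hierarchical Bayesian fits with group-difference
#' probabilities for the three 2AFC tasks, and the frequentist comparison
#' battery. Every stage writes its table under `output_dir` (CSV/JSON) so
#' the run can be inspected or resumed stage by stage, and a JSON-lines
#' provenance log records config, seed and stage progress. The scored-task
#' comparisons are emitted twice — with and without no-response trials —
#' as a paired sensitivity report.
#'
#' @param config A [run_config()].
#' @return A list with `exclusions`, `scores`, `scores_no_timeout`,
#'   `sdt_estimates`, `hier` (per task: tidied group fits and `p_theta`),
#'   `comparisons`, `sensitivity`, `output_dir`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$output_dir, "provenance.jsonl")
  log <- function(rec) {
    rec$time <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
        file = log_path, append = TRUE)
  }
  log(list(stage = "config", seed = config$seed,
           package_version = as.character(utils::packageVersion("visuosdt")),
           mode = if (is.null(config$paths)) "synthetic" else "files"))

  cohort <- stage("input", log, {
    if (!is.null(config$paths)) {
      read_cohort(config$paths$participants, config$paths$trials,
                  config$paths$tapping)
    } else {
      generate_cohort(config$generator)
    }
  })

  qc <- stage("qc", log, {
    res <- apply_exclusions(cohort$participants, cohort$trials,
                            cohort$tapping)
    readr::write_csv(res$report,
                     file.path(config$output_dir, "exclusions.csv"))
    res
  })

  trials_main <- if (config$drop_no_response) {
    drop_no_response_trials(qc$trials)
  } else qc$trials
  trials_nr <- drop_no_response_trials(qc$trials)

  scores <- stage("score", log, {
    s <- score_2afc(trials_main)
    eb <- score_ebbinghaus(trials_main)
    tap <- NULL
    if (!is.null(qc$tapping)) {
      tap <- dplyr::bind_cols(
        qc$tapping["participant_id"],
        tapping_score(qc$tapping$left_taps, qc$tapping$right_taps)
      )
    }
    readr::write_csv(s, file.path(config$output_dir, "scores.csv"))
    list(choice = s, ebbinghaus = eb, tapping = tap)
  })
  scores_nr <- score_2afc(trials_nr)

  sdt <- stage("sdt", log, {
    est <- dprime_criterion(count_outcomes(trials_nr))
    readr::write_csv(est, file.path(config$output_dir, "sdt_estimates.csv"))
    est
  })

  groups <- qc$participants[, c("participant_id", "group")]

  hier <- if (!config$hier) NULL else stage("hier", log, {
    counts <- dplyr::left_join(count_outcomes(trials_nr), groups,
                               by = "participant_id")
    out <- list()
    for (tk in intersect(SDT_TASKS, unique(counts$task))) {
      ct <- counts[counts$task == tk, ]
      fit_pd <- fit_hier_sdt(ct[ct$group == "pd", ], mcmc = config$mcmc,
                             monitor_subjects = FALSE)
      fit_ctrl <- fit_hier_sdt(ct[ct$group == "control", ],
                               mcmc = config$mcmc, monitor_subjects = FALSE)
      pt <- dplyr::bind_rows(lapply(c("mu_d", "mu_c"), function(p) {
        posterior_prob_diff(fit_ctrl, fit_pd, p, seed = config$seed)
      }))
      out[[tk]] <- list(pd = generics::tidy(fit_pd),
                        control = generics::tidy(fit_ctrl),
                        p_theta = pt,
                        fits = list(pd = fit_pd, control = fit_ctrl))
    }
    summ <- lapply(out, function(x) {
      list(pd = x$pd, control = x$control, p_theta = x$p_theta)
    })
    jsonlite::write_json(summ, file.path(config$output_dir, "hier_summary.json"),
                         dataframe = "rows", digits = NA)
    out
  })

  comparisons <- stage("stats", log, {
    cmp <- group_comparisons(scores$choice, scores$ebbinghaus,
                             scores$tapping, groups)
    cmp <- apply_bonferroni(cmp, config$alpha, config$n_comparisons)
    readr::write_csv(cmp, file.path(config$output_dir, "comparisons.csv"))
    cmp
  })

  sensitivity <- stage("sensitivity", log, {
    cmp_nr <- group_comparisons(scores_nr, scores$ebbinghaus,
                                scores$tapping, groups)
    cmp_nr <- apply_bonferroni(cmp_nr, config$alpha, config$n_comparisons)
    both <- dplyr::bind_rows(
      dplyr::mutate(comparisons, analysis = "all_trials"),
      dplyr::mutate(cmp_nr, analysis = "no_response_excluded")
    )
    readr::write_csv(both, file.path(config$output_dir, "sensitivity.csv"))
    both
  })

  log(list(stage = "pipeline", status = "complete"))
  list(exclusions = qc$report, scores = scores$choice,
       scores_no_timeout = scores_nr, sdt_estimates = sdt, hier = hier,
       comparisons = comparisons, sensitivity = sensitivity,
       output_dir = config$output_dir)
}

# Welch comparisons of every scored task x level between groups, plus the
# size-matching and tapping scores.
group_comparisons <- function(choice_scores, ebbinghaus, tapping, groups) {
  sc <- dplyr::left_join(choice_scores, groups, by = "participant_id")
  per_level <- dplyr::group_by(sc, .data$task, .data$difficulty_level)
  cmp <- dplyr::group_modify(per_level, function(df, key) {
    welch_t(df$proportion_correct[df$group == "pd"],
            df$proportion_correct[df$group == "control"])
  })
  cmp <- dplyr::ungroup(cmp)
  extras <- list()
  if (!is.null(ebbinghaus) && nrow(ebbinghaus) > 0) {
    eb <- dplyr::left_join(ebbinghaus, groups, by = "participant_id")
    extras$eb <- dplyr::mutate(
      welch_t(eb$log_mean_ratio[eb$group == "pd"],
              eb$log_mean_ratio[eb$group == "control"]),
      task = "ebbinghaus", difficulty_level = 1L)
  }
  if (!is.null(tapping)) {
    tp <- dplyr::left_join(tapping, groups, by = "participant_id")
    extras$tap <- dplyr::mutate(
      welch_t(tp$mean_taps[tp$group == "pd"],
              tp$mean_taps[tp$group == "control"]),
      task = "tapping", difficulty_level = 1L)
  }
  dplyr::bind_rows(cmp, extras$eb, extras$tap)
}
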
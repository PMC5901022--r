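#' Apply cohort-level exclusion rules
#'
#' Applies the participant-level quality-control rules used for the online
#' study cohort, in a fixed precedence order, and reports every decision:
#'
#' 1. `age_le_40` — participants aged 40 years or younger are removed.
#' 2. `atypical_pd` — participants flagged with an atypical parkinsonian
#'    syndrome are removed (the flag is an input, never inferred).
#' 3. `small_screen` — participants whose reported screen width falls below
#'    `screen_width_min` pixels (phone-sized devices) are removed.
#' 4. `duplicate` — repeated attempts by one `participant_id` are collapsed
#'    to the attempt with the highest overall score, defined as the mean
#'    proportion correct across all completed 2AFC tasks; equal scores keep
#'    the earliest attempt (lowest `attempt_rank`).
#'
#' Tapping runs with fewer than 10 or at least 100 taps in 30 s are
#' physiologically implausible (accidental key holds, missed starts) and are
#' dropped from the tapping analysis only; the participant is retained
#' elsewhere.
#'
#' Each excluded participant carries exactly one primary rule (the first
#' that fires). The filter never alters field values of surviving records,
#' and applying it twice equals applying it once.
#'
#' Trial tables carry no attempt identifier, so attempts of one id score
#' identically from trials and the earliest wins; a recording system that
#' keeps per-attempt trials can supply the overall score directly in an
#' `attempt_score` column on `participants`, which takes precedence.
#'
#' @param participants,trials Tibbles in the [cohort-schema] layout.
#' @param tapping Optional tapping tibble (`participant_id`, `left_taps`,
#'   `right_taps`).
#' @param screen_width_min Minimum screen width in pixels (default 768).
#' @return A list: `participants`, `trials`, `tapping` (filtered; per-hand
#'   tap counts outside the bounds set to `NA`), and `report`, one row per
#'   input attempt with columns `participant_id`, `attempt_rank`, `rule`
#'   (`NA` when retained) and `retained`. `tapping_report` enumerates
#'   dropped tapping runs.
#' @export
apply_exclusions <- function(participants, trials, tapping = NULL,
                             screen_width_min = 768) {
  p <- participants
  rule <- rep(NA_character_, nrow(p))
  mark <- function(cond, name) {
    cond <- !is.na(cond) & cond
    rule[is.na(rule) & cond] <<- name
  }
  mark(p$age <= 40, "age_le_40")
  mark(p$atypical_pd, "atypical_pd")
  mark(p$screen_width < screen_width_min, "small_screen")

  # Duplicate attempts: score each surviving attempt by mean proportion
  # correct over its completed 2AFC-style tasks, keep the best.
  alive <- is.na(rule)
  scores <- attempt_scores(p, trials)
  key <- paste(p$participant_id, p$attempt_rank, sep = "\r")
  sc <- scores$score[match(key, paste(scores$participant_id,
                                      scores$attempt_rank, sep = "\r"))]
  sc[is.na(sc)] <- -Inf
  keep_dup <- rep(TRUE, nrow(p))
  alive_ids <- p$participant_id[alive]
  for (id in unique(alive_ids[duplicated(alive_ids)])) {
    idx <- which(alive & p$participant_id == id)
    best <- idx[order(-sc[idx], p$attempt_rank[idx])][1]
    keep_dup[setdiff(idx, best)] <- FALSE
  }
  mark(!keep_dup, "duplicate")

  retained <- is.na(rule)
  report <- tibble::tibble(
    participant_id = p$participant_id,
    attempt_rank = p$attempt_rank,
    rule = rule,
    retained = retained
  )

  kept <- p[retained, , drop = FALSE]
  kept_trials <- trials[trials$participant_id %in% kept$participant_id, ,
                        drop = FALSE]

  tap_out <- NULL
  tap_report <- NULL
  if (!is.null(tapping)) {
    tap_out <- tapping[tapping$participant_id %in% kept$participant_id, ,
                       drop = FALSE]
    in_bounds <- function(x) !is.na(x) & x >= 10 & x < 100
    tap_report <- tibble::tibble(
      participant_id = rep(tap_out$participant_id, 2),
      hand = rep(c("left", "right"), each = nrow(tap_out)),
      taps = c(tap_out$left_taps, tap_out$right_taps),
      dropped = !in_bounds(c(tap_out$left_taps, tap_out$right_taps))
    )
    tap_out$left_taps[!in_bounds(tap_out$left_taps)] <- NA_real_
    tap_out$right_taps[!in_bounds(tap_out$right_taps)] <- NA_real_
  }

  list(participants = kept, trials = kept_trials, tapping = tap_out,
       report = report, tapping_report = tap_report)
}

# Mean proportion correct across completed choice tasks, per attempt.
# Trials tables carry no attempt_rank; when an id has several attempts the
# trials are shared, so scores tie and the earliest attempt wins.
attempt_scores <- function(participants, trials) {
  ch <- trials[trials$task %in% c(SDT_TASKS, "mental_rotation"), , drop = FALSE]
  per_id <- dplyr::summarise(
    dplyr::group_by(ch, .data$participant_id, .data$task),
    score = mean(.data$response_class == .data$stimulus_class, na.rm = TRUE),
    .groups = "drop"
  )
  per_id <- dplyr::summarise(dplyr::group_by(per_id, .data$participant_id),
                             score = mean(.data$score), .groups = "drop")
  out <- tibble::tibble(participant_id = participants$participant_id,
                        attempt_rank = participants$attempt_rank)
  out$score <- per_id$score[match(out$participant_id, per_id$participant_id)]
  if ("attempt_score" %in% names(participants)) {
    # generator-provided per-attempt score wins when present
    out$score <- participants$attempt_score
  }
  out
}

#' Floor exclusion at a task's easiest level
#'
#' For staircase-free 2AFC tasks with graded difficulty (object invariance,
#' biological motion) a participant at or below chance at the easiest level
#' is not measurably engaging with the task: anyone with proportion correct
#' \eqn{\le} 0.5 at that level is flagged for that task only. Participants
#' with no trials at the easiest level cannot be assessed and are flagged
#' separately.
#'
#' @param trials Trials tibble.
#' @param task Task name.
#' @param easiest_level Integer level regarded as easiest (default 1).
#' @param threshold Exclusion threshold on proportion correct (default 0.5;
#'   the boundary value is excluded).
#' @return Tibble with `participant_id`, `prop_correct` and `status`
#'   (`"floor_excluded"` or `"unassessable"`); participants retained for
#'   the task are absent.
#' @export
floor_exclusion <- function(trials, task, easiest_level = 1L,
                            threshold = 0.5) {
  stopifnot(task %in% TASKS)
  tt <- trials[trials$task == task, , drop = FALSE]
  ids <- unique(tt$participant_id)
  ez <- tt[tt$difficulty_level == easiest_level, , drop = FALSE]
  perf <- dplyr::summarise(
    dplyr::group_by(ez, .data$participant_id),
    prop_correct = mean(.data$response_class == .data$stimulus_class,
                        na.rm = TRUE),
    n = dplyr::n(), .groups = "drop"
  )
  floor_ids <- perf$participant_id[perf$prop_correct <= threshold]
  unass <- setdiff(ids, perf$participant_id)
  dplyr::bind_rows(
    tibble::tibble(participant_id = floor_ids,
                   prop_correct = perf$prop_correct[match(floor_ids,
                                                          perf$participant_id)],
                   status = "floor_excluded"),
    tibble::tibble(participant_id = unass, prop_correct = NA_real_,
                   status = "unassessable")
  )
}

#' Remove trials with no response
#'
#' Drops every trial whose `response_class` is `"none"` (a timed trial on
#' which the participant did not answer before the deadline). Used both for
#' the signal detection analyses, which need a classified response on every
#' trial, and for the sensitivity re-analysis of the scored tasks.
#'
#' @param trials Trials tibble.
#' @return The filtered tibble. The attribute `"removal_log"` holds a
#'   per-participant/task count of removed trials, also available through
#'   [no_response_log()].
#' @export
drop_no_response_trials <- function(trials) {
  none <- !is.na(trials$response_class) & trials$response_class == "none"
  log <- dplyr::count(trials[none, , drop = FALSE],
                      .data$participant_id, .data$task, name = "n_removed")
  out <- trials[!none, , drop = FALSE]
  attr(out, "removal_log") <- log
  out
}

#' @rdname drop_no_response_trials
#' @param x A tibble returned by [drop_no_response_trials()].
#' @export
no_response_log <- function(x) {
  attr(x, "removal_log") %||% tibble::tibble(participant_id = character(),
                                             task = character(),
                                             n_removed = integer())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
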
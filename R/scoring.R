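#' Score choice tasks by proportion correct
#'
#' Summarises forced-choice trials into one proportion-correct score per
#' participant x task x difficulty level. A trial is correct when the
#' response class equals the stimulus class; timed-out trials
#' (`response_class == "none"`) cannot be correct and count against the
#' participant, matching the primary analysis. Pass trials through
#' [drop_no_response_trials()] first for the sensitivity variant that
#' ignores timeouts.
#'
#' Participants with zero scorable trials at a level simply do not appear:
#' an unassessable cell is never reported as a score of 0.
#'
#' @param trials Trials tibble ([cohort-schema]).
#' @param task Optional task name to restrict to.
#' @param by_level Split scores by difficulty level (default `TRUE`); when
#'   `FALSE`, levels are pooled per task.
#' @return Tibble: `participant_id`, `task`, `difficulty_level` (absent if
#'   pooled), `n_trials`, `n_correct`, `proportion_correct`.
#' @export
score_2afc <- function(trials, task = NULL, by_level = TRUE) {
  tt <- trials[trials$task %in% c(SDT_TASKS, "mental_rotation"), , drop = FALSE]
  if (!is.null(task)) {
    stopifnot(task %in% TASKS)
    tt <- tt[tt$task == task, , drop = FALSE]
  }
  keys <- if (by_level) {
    dplyr::group_by(tt, .data$participant_id, .data$task,
                    .data$difficulty_level)
  } else {
    dplyr::group_by(tt, .data$participant_id, .data$task)
  }
  dplyr::summarise(
    keys,
    n_trials = dplyr::n(),
    n_correct = sum(.data$response_class == .data$stimulus_class,
                    na.rm = TRUE),
    proportion_correct = .data$n_correct / .data$n_trials,
    .groups = "drop"
  )
}

#' Score a hidden-figures click stream
#'
#' Scores visual-search performance on a scene containing hidden target
#' regions (the task caps responding at 75 clicks or 6 minutes, whichever
#' comes first, to discourage blanket clicking). The first click inside a
#' region finds that target; later clicks in an already-found region count
#' as repeat selections; clicks outside every region count as background
#' (non-target) selections. Clicks past the caps are ignored with a warning.
#'
#' @param clicks Tibble of time-ordered clicks with columns
#'   `participant_id`, `t_s` (seconds from task start), `x`, `y`.
#' @param regions Tibble of axis-aligned rectangular target regions:
#'   `region_id`, `xmin`, `xmax`, `ymin`, `ymax` (see
#'   [make_horse_regions()] for a synthetic 22-region layout).
#' @param max_clicks,max_time_s Truncation caps (defaults 75 clicks, 360 s).
#' @return Tibble: `participant_id`, `horses_found`, `repeat_selections`,
#'   `background_selections`, `total_clicks`, `total_time_s`.
#' @export
score_hidden_figures <- function(clicks, regions, max_clicks = 75,
                                 max_time_s = 360) {
  stopifnot(all(c("region_id", "xmin", "xmax", "ymin", "ymax") %in%
                  names(regions)))
  one <- function(df) {
    df <- df[order(df$t_s), , drop = FALSE]
    over <- df$t_s > max_time_s | seq_len(nrow(df)) > max_clicks
    if (any(over)) {
      rlang::warn(sprintf("ignoring %d click(s) past the %d-click/%ds limit",
                          sum(over), max_clicks, max_time_s))
      df <- df[!over, , drop = FALSE]
    }
    hit_region <- function(x, y) {
      m <- which(x >= regions$xmin & x <= regions$xmax &
                   y >= regions$ymin & y <= regions$ymax)
      if (length(m) == 0) NA_character_ else regions$region_id[m[1]]
    }
    reg <- mapply(hit_region, df$x, df$y)
    found <- character(0)
    repeats <- 0L
    background <- 0L
    for (r in reg) {
      if (is.na(r)) background <- background + 1L
      else if (r %in% found) repeats <- repeats + 1L
      else found <- c(found, r)
    }
    tibble::tibble(
      horses_found = length(found),
      repeat_selections = repeats,
      background_selections = background,
      total_clicks = nrow(df),
      total_time_s = if (nrow(df)) max(df$t_s) else 0
    )
  }
  out <- dplyr::group_modify(dplyr::group_by(clicks, .data$participant_id),
                             function(df, key) one(df))
  dplyr::ungroup(out)
}

#' Size-matching illusion magnitude
#'
#' Quantifies the size-contrast (Ebbinghaus) illusion from the circles a
#' participant selected as matching the central target. Each selection is
#' expressed as the ratio of selected to target diameter; the score is the
#' mean of the log ratios — the log of the geometric mean ratio. A value of
#' 0 means veridical matching; negative values mean systematically smaller
#' circles were chosen, the direction the surrounding small inducers push
#' perception.
#'
#' @param selected_diameters,target_diameter Positive diameters (pixels or
#'   any common unit; the score is scale-invariant).
#' @return Tibble with `log_mean_ratio` and `n_trials`.
#' @export
ebbinghaus_magnitude <- function(selected_diameters, target_diameter) {
  if (any(selected_diameters <= 0) || any(target_diameter <= 0)) {
    rlang::abort("diameters must be positive")
  }
  r <- log(selected_diameters / target_diameter)
  tibble::tibble(log_mean_ratio = mean(r), n_trials = length(r))
}

#' @rdname ebbinghaus_magnitude
#' @param trials Trials tibble containing `ebbinghaus` rows with
#'   `selected_diameter` and `target_diameter` columns.
#' @return For `score_ebbinghaus()`: one row per participant.
#' @export
score_ebbinghaus <- function(trials) {
  tt <- trials[trials$task == "ebbinghaus" & !is.na(trials$selected_diameter), ,
               drop = FALSE]
  dplyr::summarise(
    dplyr::group_by(tt, .data$participant_id),
    log_mean_ratio = mean(log(.data$selected_diameter /
                                .data$target_diameter)),
    n_trials = dplyr::n(),
    .groups = "drop"
  )
}

#' Run an adaptive acuity staircase
#'
#' Simulates (or replays) the online visual-acuity staircase: an optotype of
#' a given decimal-acuity size is presented; after a correct response the
#' next optotype shrinks by one step, after an incorrect response it grows
#' by one step (1-up/1-down, converging on the 50% point of the observer's
#' psychometric function; a 2-down/1-up variant targeting ~71% is
#' available). Sizes are floored one step above zero. The acuity estimate
#' is the mean of the sizes presented at the last 4 steps.
#'
#' @param observer Function of one argument (the presented size) returning
#'   `TRUE` for a correct response. See [threshold_observer()] and
#'   [chance_observer()].
#' @param start_size Starting optotype size in decimal acuity (default 1.0).
#' @param step Step size in decimal-acuity units (default 0.05).
#' @param n_steps Number of staircase steps (default 20).
#' @param rule `"1up1down"` (default) or `"2down1up"`.
#' @return An object of class `staircase_run`: a list with `steps` (tibble
#'   of `step`, `size`, `correct`), `acuity_estimate`, and the settings.
#' @export
run_staircase <- function(observer, start_size = 1.0, step = 0.05,
                          n_steps = 20L, rule = c("1up1down", "2down1up")) {
  rule <- match.arg(rule)
  sizes <- numeric(n_steps)
  correct <- logical(n_steps)
  size <- start_size
  streak <- 0L
  for (i in seq_len(n_steps)) {
    sizes[i] <- size
    correct[i] <- isTRUE(observer(size))
    if (rule == "1up1down") {
      size <- size + if (correct[i]) -step else step
    } else {
      if (correct[i]) {
        streak <- streak + 1L
        if (streak == 2L) { size <- size - step; streak <- 0L }
      } else {
        size <- size + step
        streak <- 0L
      }
    }
    size <- max(size, step)
  }
  structure(
    list(
      steps = tibble::tibble(step = seq_len(n_steps), size = sizes,
                             correct = correct),
      acuity_estimate = mean(sizes[(n_steps - 3L):n_steps]),
      start_size = start_size, step = step, n_steps = n_steps, rule = rule
    ),
    class = "staircase_run"
  )
}

#' @export
print.staircase_run <- function(x, ...) {
  cat(sprintf("<staircase_run> %d steps of %.2f (%s), estimate %.3f\n",
              x$n_steps, x$step, x$rule, x$acuity_estimate))
  invisible(x)
}

#' Ideal observers for staircase simulation
#'
#' `threshold_observer(theta)` answers correctly whenever the optotype size
#' is at or above `theta` and incorrectly below it (a step-function
#' psychometric observer). `chance_observer(p)` answers correctly with
#' probability `p` regardless of size.
#'
#' @param theta Threshold size in decimal acuity.
#' @param p Probability of a correct response (default 0.5).
#' @return A function suitable for [run_staircase()].
#' @export
threshold_observer <- function(theta) {
  force(theta)
  function(size) size >= theta
}

#' @rdname threshold_observer
#' @export
chance_observer <- function(p = 0.5) {
  force(p)
  function(size) runif(1) < p
}

#' Mean alternating-tap score
#'
#' Averages the 30-second alternating-tap counts of the two hands
#' (a bradykinesia proxy). Hands whose counts failed the plausibility
#' bounds arrive as `NA`; with one hand missing the available hand is used
#' and the result flagged partial.
#'
#' @param left_taps,right_taps Numeric vectors of per-hand tap counts
#'   (`NA` = excluded/missing run).
#' @return Tibble: `mean_taps` (`NA` when both hands missing), `partial`.
#' @export
tapping_score <- function(left_taps, right_taps) {
  m <- mapply(function(l, r) {
    if (is.na(l) && is.na(r)) NA_real_ else mean(c(l, r), na.rm = TRUE)
  }, left_taps, right_taps)
  tibble::tibble(mean_taps = as.numeric(m),
                 partial = xor(is.na(left_taps), is.na(right_taps)))
}

#' Pick the most discriminatory difficulty level
#'
#' For tasks with several difficulty levels the regression analyses use the
#' level that best separates the groups: the largest absolute standardized
#' effect size (Cohen's d), ties broken by the smaller p-value. If every
#' level is identical on both measures the lowest level is returned with a
#' warning.
#'
#' @param comparisons Tibble with columns `difficulty_level`, `effect_size`
#'   and `p_value`, one row per level.
#' @return The chosen level (integer).
#' @export
select_discriminatory_level <- function(comparisons) {
  stopifnot(nrow(comparisons) >= 2)
  es <- abs(comparisons$effect_size)
  p <- comparisons$p_value
  if (length(unique(es)) == 1 && length(unique(p)) == 1) {
    rlang::warn("all levels identical; returning lowest level")
    return(min(comparisons$difficulty_level))
  }
  ord <- order(-es, p, comparisons$difficulty_level)
  comparisons$difficulty_level[ord[1]]
}
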
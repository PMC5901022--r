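#' Tabulate signal detection outcomes
#'
#' Sorts each participant's 2AFC responses into hits (signal trial answered
#' "signal"), misses, false alarms (noise trial answered "signal") and
#' correct rejections. Trials with no response are removed first (they carry
#' no classifiable answer). Which physical alternative plays the "signal"
#' role is an arbitrary labelling fixed per task — sensitivity is invariant
#' to the choice and criterion merely changes sign — so `signal_class`
#' defaults to the `"signal"` label the trial tables already carry.
#'
#' @param trials Trials tibble ([cohort-schema]).
#' @param task Optional single task to restrict to (default: all three
#'   2AFC tasks).
#' @param by_level Tabulate per difficulty level (`FALSE`, the default,
#'   pools all levels of a task).
#' @param signal_class Which stimulus label counts as signal (`"signal"` or
#'   `"noise"`).
#' @return Tibble: `participant_id`, `task` (and `difficulty_level` if
#'   requested), `hits`, `misses`, `false_alarms`, `correct_rejections`,
#'   `n_signal`, `n_noise`, `assessable` (`FALSE` when either trial type
#'   is absent).
#' @export
count_outcomes <- function(trials, task = NULL, by_level = FALSE,
                           signal_class = c("signal", "noise")) {
  signal_class <- match.arg(signal_class)
  tt <- trials[trials$task %in% (task %||% SDT_TASKS), , drop = FALSE]
  tt <- tt[!is.na(tt$response_class) & tt$response_class != "none", ,
           drop = FALSE]
  if (signal_class == "noise") {
    flip <- function(x) c(signal = "noise", noise = "signal")[x]
    tt$stimulus_class <- unname(flip(tt$stimulus_class))
    tt$response_class <- unname(flip(tt$response_class))
  }
  g <- if (by_level) {
    dplyr::group_by(tt, .data$participant_id, .data$task,
                    .data$difficulty_level)
  } else {
    dplyr::group_by(tt, .data$participant_id, .data$task)
  }
  out <- dplyr::summarise(
    g,
    hits = sum(.data$stimulus_class == "signal" &
                 .data$response_class == "signal"),
    misses = sum(.data$stimulus_class == "signal" &
                   .data$response_class == "noise"),
    false_alarms = sum(.data$stimulus_class == "noise" &
                         .data$response_class == "signal"),
    correct_rejections = sum(.data$stimulus_class == "noise" &
                               .data$response_class == "noise"),
    .groups = "drop"
  )
  out$n_signal <- out$hits + out$misses
  out$n_noise <- out$false_alarms + out$correct_rejections
  out$assessable <- out$n_signal > 0 & out$n_noise > 0
  out
}

#' Per-participant d-prime and criterion
#'
#' The equal-variance signal detection estimators
#' \deqn{d' = z(H) - z(FA), \qquad c = -\tfrac{1}{2}\,(z(H) + z(FA)),}
#' where \eqn{z} is the inverse standard-normal CDF, \eqn{H} the hit rate
#' and \eqn{FA} the false-alarm rate. Rates of exactly 0 or 1 make \eqn{z}
#' infinite; the default correction replaces an observed 0 with
#' \eqn{1/(2N)} and a 1 with \eqn{1 - 1/(2N)} (N the relevant trial count),
#' applied only to the offending rate and flagged in the output. With
#' `correction = "none"` an extreme rate is an error.
#'
#' @param counts Outcome tibble from [count_outcomes()]; rows with
#'   `assessable == FALSE` are passed through with `NA` estimates.
#' @param correction `"half"` (default) or `"none"`.
#' @return The input with columns `hit_rate`, `fa_rate`, `dprime`,
#'   `criterion`, `corrected` appended.
#' @rdname dprime_criterion
#' @param hit_rate,fa_rate Hit and false-alarm rates in (0, 1) (already
#'   corrected if they came from extreme counts).
#' @return For `dprime_from_rates()`: tibble with `dprime` and `criterion`.
#' @export
dprime_from_rates <- function(hit_rate, fa_rate) {
  stopifnot(all(hit_rate > 0 & hit_rate < 1), all(fa_rate > 0 & fa_rate < 1))
  tibble::tibble(dprime = qnorm(hit_rate) - qnorm(fa_rate),
                 criterion = -0.5 * (qnorm(hit_rate) + qnorm(fa_rate)))
}

#' @export
dprime_criterion <- function(counts, correction = c("half", "none")) {
  correction <- match.arg(correction)
  ok <- if ("assessable" %in% names(counts)) counts$assessable else
    rep(TRUE, nrow(counts))

  h <- counts$hits / counts$n_signal
  fa <- counts$false_alarms / counts$n_noise
  extreme <- (h %in% c(0, 1)) | (fa %in% c(0, 1))
  if (correction == "none" && any(extreme & ok)) {
    rlang::abort(paste0(
      "hit or false-alarm rate of 0 or 1 gives an infinite estimate; ",
      "use correction = \"half\" or supply more trials"))
  }
  fix <- function(r, n) {
    r[r == 0] <- 1 / (2 * n[r == 0])
    r[r == 1] <- 1 - 1 / (2 * n[r == 1])
    r
  }
  if (correction == "half") {
    h <- fix(h, counts$n_signal)
    fa <- fix(fa, counts$n_noise)
  }
  # unassessable rows get placeholder rates; their estimates are NA'd below
  h_ok <- ifelse(ok & is.finite(h), pmin(pmax(h, 1e-12), 1 - 1e-12), 0.5)
  fa_ok <- ifelse(ok & is.finite(fa), pmin(pmax(fa, 1e-12), 1 - 1e-12), 0.5)
  dc <- dprime_from_rates(h_ok, fa_ok)
  out <- counts
  out$hit_rate <- ifelse(ok, h, NA_real_)
  out$fa_rate <- ifelse(ok, fa, NA_real_)
  out$dprime <- ifelse(ok, dc$dprime, NA_real_)
  out$criterion <- ifelse(ok, dc$criterion, NA_real_)
  out$corrected <- extreme & ok & correction == "half"
  out
}
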
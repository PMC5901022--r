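#' Cohort table schemas
#'
#' The pipeline exchanges three comma-delimited, UTF-8, headered tables:
#'
#' * `participants.csv` — one row per participant:
#'   `participant_id`, `group` (`pd`/`control`), `age` (years), `gender`
#'   (`male`/`female`), `disease_duration` (years; empty for controls),
#'   `hallucinations` (logical), `cohort` (`local`/`web`), `screen_width`
#'   (pixels), `attempt_rank` (integer; 1 = first attempt), `atypical_pd`
#'   (logical flag set by the clinician, never inferred), `acuity`
#'   (decimal visual acuity, optional).
#' * `trials.csv` — one row per stimulus presentation: `participant_id`,
#'   `task`, `difficulty_level` (1–3; 1 for single-level tasks),
#'   `stimulus_class` (`signal`/`noise`; empty for non-2AFC tasks),
#'   `response_class` (`signal`/`noise`/`none`), `rt_ms` (response time,
#'   milliseconds; empty when absent), `selected_diameter` and
#'   `target_diameter` (pixels; Ebbinghaus trials only).
#' * `tapping.csv` — `participant_id`, `left_taps`, `right_taps`
#'   (key presses in 30 s per hand).
#'
#' @name cohort-schema
NULL

participant_cols <- c(
  "participant_id", "group", "age", "gender", "disease_duration",
  "hallucinations", "cohort", "screen_width", "attempt_rank", "atypical_pd"
)

trial_cols <- c(
  "participant_id", "task", "difficulty_level", "stimulus_class",
  "response_class", "rt_ms"
)

#' Read a cohort from delimited files
#'
#' Parses the participant and trial tables, validating every row against the
#' schema in [cohort-schema]. Structurally broken files (a missing required
#' column) raise an error naming the column; individually malformed rows
#' (unparseable age, unknown task or group label, out-of-range difficulty)
#' are dropped with a row-level diagnostic and returned in `rejected`.
#'
#' @param participants_path,trials_path Paths to `participants.csv` and
#'   `trials.csv`.
#' @param tapping_path Optional path to `tapping.csv`.
#' @return A list with tibbles `participants`, `trials`, `tapping` (or
#'   `NULL`), and `rejected`, a tibble of dropped rows with columns
#'   `file`, `row`, `reason`.
#' @examples
#' cfg <- cohort_config(n_pd = 3, n_control = 3, seed = 1)
#' cohort <- generate_cohort(cfg)
#' dir <- tempfile(); dir.create(dir)
#' paths <- write_cohort(cohort, dir)
#' rt <- read_cohort(paths$participants, paths$trials, paths$tapping)
#' nrow(rt$participants)
#' @export
read_cohort <- function(participants_path, trials_path, tapping_path = NULL) {
  pt <- read_checked(participants_path, participant_cols)
  tr <- read_checked(trials_path, trial_cols)

  pv <- validate_participants(pt)
  tv <- validate_trials(tr)

  rejected <- dplyr::bind_rows(
    dplyr::mutate(pv$rejected, file = basename(participants_path)),
    dplyr::mutate(tv$rejected, file = basename(trials_path))
  )
  if (nrow(rejected) > 0) {
    rlang::inform(sprintf("read_cohort: %d row(s) rejected; see $rejected",
                          nrow(rejected)))
  }

  tapping <- NULL
  if (!is.null(tapping_path)) {
    tapping <- readr::read_csv(tapping_path, show_col_types = FALSE,
                               col_types = readr::cols(
                                 participant_id = readr::col_character(),
                                 left_taps = readr::col_double(),
                                 right_taps = readr::col_double()
                               ))
  }

  list(participants = pv$data, trials = tv$data, tapping = tapping,
       rejected = rejected)
}

read_checked <- function(path, required) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("file not found: %s", path))
  }
  x <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                       show_col_types = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    rlang::abort(sprintf("%s: missing required column(s): %s",
                         basename(path), paste(missing, collapse = ", ")))
  }
  x
}

parse_num <- function(x) suppressWarnings(as.numeric(x))
parse_lgl <- function(x) {
  out <- rep(NA, length(x))
  out[tolower(x) %in% c("true", "t", "1", "yes")] <- TRUE
  out[tolower(x) %in% c("false", "f", "0", "no")] <- FALSE
  out
}

validate_participants <- function(x) {
  x <- dplyr::mutate(x, .row = dplyr::row_number())
  age <- parse_num(x$age)
  dur <- parse_num(x$disease_duration)
  hall <- parse_lgl(x$hallucinations)
  sw <- parse_num(x$screen_width)
  ar <- parse_num(x$attempt_rank)
  atyp <- parse_lgl(x$atypical_pd)

  reason <- rep(NA_character_, nrow(x))
  bad <- function(cond, msg) {
    cond <- !is.na(cond) & cond
    reason[is.na(reason) & cond] <<- msg
  }
  bad(is.na(x$participant_id) | x$participant_id == "", "empty participant_id")
  bad(!(x$group %in% GROUPS), "unknown group label")
  bad(is.na(age) | age <= 0, "malformed or nonpositive age")
  bad(!(x$gender %in% c("male", "female")), "unknown gender label")
  bad(!is.na(dur) & dur < 0, "negative disease_duration")
  bad(x$group == "control" & !is.na(hall) & hall,
      "control flagged with hallucinations")
  bad(!(x$cohort %in% c("local", "web")), "unknown cohort label")

  ok <- is.na(reason)
  data <- tibble::tibble(
    participant_id = x$participant_id[ok],
    group = x$group[ok],
    age = age[ok],
    gender = x$gender[ok],
    disease_duration = dur[ok],
    hallucinations = dplyr::coalesce(hall[ok], FALSE),
    cohort = x$cohort[ok],
    screen_width = sw[ok],
    attempt_rank = as.integer(dplyr::coalesce(ar[ok], 1)),
    atypical_pd = dplyr::coalesce(atyp[ok], FALSE)
  )
  if ("acuity" %in% names(x)) data$acuity <- parse_num(x$acuity)[ok]
  rejected <- tibble::tibble(row = x$.row[!ok], reason = reason[!ok])
  list(data = data, rejected = rejected)
}

validate_trials <- function(x) {
  x <- dplyr::mutate(x, .row = dplyr::row_number())
  lvl <- parse_num(x$difficulty_level)
  rt <- parse_num(x$rt_ms)
  sel <- if ("selected_diameter" %in% names(x)) parse_num(x$selected_diameter) else rep(NA_real_, nrow(x))
  tgt <- if ("target_diameter" %in% names(x)) parse_num(x$target_diameter) else rep(NA_real_, nrow(x))

  reason <- rep(NA_character_, nrow(x))
  bad <- function(cond, msg) {
    cond <- !is.na(cond) & cond
    reason[is.na(reason) & cond] <<- msg
  }
  bad(is.na(x$participant_id) | x$participant_id == "", "empty participant_id")
  bad(!(x$task %in% TASKS), "unknown task label")
  bad(is.na(lvl) | lvl < 1 | lvl > 3 | lvl != round(lvl),
      "difficulty_level outside 1..3")
  bad(!is.na(x$stimulus_class) & !(x$stimulus_class %in% c("signal", "noise")),
      "unknown stimulus_class")
  bad(!is.na(x$response_class) &
        !(x$response_class %in% c("signal", "noise", "none")),
      "unknown response_class")
  bad(x$response_class %in% "none" & !(x$task %in% TIMED_TASKS),
      "no-response recorded for untimed task")

  ok <- is.na(reason)
  data <- tibble::tibble(
    participant_id = x$participant_id[ok],
    task = x$task[ok],
    difficulty_level = as.integer(lvl[ok]),
    stimulus_class = x$stimulus_class[ok],
    response_class = x$response_class[ok],
    rt_ms = rt[ok],
    selected_diameter = sel[ok],
    target_diameter = tgt[ok]
  )
  rejected <- tibble::tibble(row = x$.row[!ok], reason = reason[!ok])
  list(data = data, rejected = rejected)
}

#' Write a cohort to delimited files
#'
#' Inverse of [read_cohort()]: writes `participants.csv`, `trials.csv` and
#' (when present) `tapping.csv` under `dir` using the [cohort-schema]
#' dialect. A written cohort re-reads to identical tables.
#'
#' @param cohort A list with `participants`, `trials` and optionally
#'   `tapping` tibbles, e.g. from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(
    participants = file.path(dir, "participants.csv"),
    trials = file.path(dir, "trials.csv")
  )
  readr::write_csv(cohort$participants, paths$participants, na = "")
  readr::write_csv(cohort$trials, paths$trials, na = "")
  if (!is.null(cohort$tapping)) {
    paths$tapping <- file.path(dir, "tapping.csv")
    readr::write_csv(cohort$tapping, paths$tapping, na = "")
  }
  invisible(paths)
}
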
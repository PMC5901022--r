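#' Generative configuration for a synthetic study cohort
#'
#' Bundles every parameter of the synthetic-cohort generator. The defaults
#' reproduce the published study conditions: 91 Parkinson's (PD) and 275
#' control participants; ages 66.0 (SD 8.8) vs 61.7 (SD 9.5) years,
#' truncated above 40 (younger participants were excluded from the study
#' population the generator emulates); male fractions 54/91 and 68/275;
#' three 2AFC tasks (object invariance and biological motion with 3
#' difficulty levels sharing 24 trials, peripheral object recognition with
#' a single level of 24 trials, half signal / half noise); a 15-trial
#' size-matching task; a 24-trial mental-rotation task; per-hand tapping
#' counts (PD 42.2 SD 15, controls 52.7 SD 18); and decimal acuity
#' (PD 0.74 SD 0.3, controls 0.82 SD 0.3).
#'
#' Group-level signal detection means default to values back-solved from
#' the published proportion-correct table via \eqn{d' = 2\,z(p_c)} (the
#' unbiased equal-variance 2AFC identity), with criterion means 0,
#' between-subject SDs 0.5 (\eqn{d'}) and 0.3 (\eqn{c}); see
#' `default_sdt_params()`.
#'
#' @param n_pd,n_control Group sizes.
#' @param age_mean,age_sd Named vectors over `pd`/`control`, years.
#' @param prop_male Named vector of male proportions.
#' @param sdt_params Tibble of per-task/level generative SDT parameters:
#'   `task`, `difficulty_level`, `n_signal`, `n_noise`, `mu_d_pd`,
#'   `mu_d_control`, `mu_c_pd`, `mu_c_control`.
#' @param sd_dprime,sd_criterion Between-subject SDs of \eqn{d'} and
#'   \eqn{c} (SDT units).
#' @param no_response_rate Fraction of timed-task trials that time out with
#'   no response.
#' @param tapping_mean,tapping_sd Named vectors, taps per 30 s.
#' @param ebbinghaus_bias Named vector of mean log selected/target ratios.
#' @param ebbinghaus_sd SD of per-trial log ratios around a participant's
#'   bias.
#' @param rotation_accuracy Named vector of mental-rotation accuracies.
#' @param acuity_mean,acuity_sd Named vectors, decimal acuity.
#' @param duration_mean,duration_sd PD disease duration, years.
#' @param hallucination_rate Fraction of PD participants reporting visual
#'   hallucinations.
#' @param age_slope Optional linear coupling of \eqn{d'} to age (SDT units
#'   per year, centred at the overall mean age); 0 disables it. Used to
#'   exercise the age-adjustment analyses.
#' @param seed Integer seed; the full generator is reproducible from it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_pd = 91, n_control = 275,
                          age_mean = c(pd = 66.0, control = 61.7),
                          age_sd = c(pd = 8.8, control = 9.5),
                          prop_male = c(pd = 54 / 91, control = 68 / 275),
                          sdt_params = default_sdt_params(),
                          sd_dprime = 0.5, sd_criterion = 0.3,
                          no_response_rate = 0.05,
                          tapping_mean = c(pd = 42.2, control = 52.7),
                          tapping_sd = c(pd = 15, control = 18),
                          ebbinghaus_bias = c(pd = -0.06, control = -0.07),
                          ebbinghaus_sd = 0.1,
                          rotation_accuracy = c(pd = 0.84, control = 0.85),
                          acuity_mean = c(pd = 0.74, control = 0.82),
                          acuity_sd = c(pd = 0.3, control = 0.3),
                          duration_mean = 4.85, duration_sd = 3.89,
                          hallucination_rate = 15 / 91,
                          age_slope = 0,
                          seed = 1L) {
  stopifnot(n_pd >= 0, n_control >= 0,
            all(age_sd > 0), all(tapping_sd > 0), all(acuity_sd > 0),
            sd_dprime >= 0, sd_criterion >= 0, ebbinghaus_sd >= 0,
            no_response_rate >= 0, no_response_rate <= 1)
  if (any(sdt_params$n_signal < 0) || any(sdt_params$n_noise < 0)) {
    rlang::abort("trial counts must be nonnegative")
  }
  structure(as.list(environment()), class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_sdt_params <- function() {
  pc2d <- function(pc) 2 * qnorm(pc)
  tibble::tibble(
    task = c(rep("object_invariance", 3), "peripheral", rep("biomotion", 3)),
    difficulty_level = c(1:3, 1L, 1:3),
    n_signal = c(4L, 4L, 4L, 12L, 4L, 4L, 4L),
    n_noise = c(4L, 4L, 4L, 12L, 4L, 4L, 4L),
    mu_d_pd = pc2d(c(0.94, 0.64, 0.52, 0.69, 0.69, 0.70, 0.54)),
    mu_d_control = pc2d(c(0.98, 0.75, 0.63, 0.79, 0.73, 0.74, 0.57)),
    mu_c_pd = 0, mu_c_control = 0
  )
}

#' Generate a synthetic study cohort
#'
#' Draws a complete synthetic dataset with the statistical structure the
#' analyses assume. For every participant and 2AFC task/level, subject
#' sensitivity and criterion are drawn from their group's normal
#' distributions; each signal trial is answered "signal" with probability
#' \eqn{\Phi(d'/2 - c)} and each noise trial with probability
#' \eqn{\Phi(-d'/2 - c)} — the exact generative inverse of the
#' \eqn{d' = z(H) - z(FA)}, \eqn{c = -\tfrac12(z(H)+z(FA))} estimators.
#' Timed-task trials time out (response `"none"`) at `no_response_rate`.
#' Demographics, tapping counts, size-matching selections, mental-rotation
#' trials and acuity are drawn from the configured distributions. The same
#' seed yields identical tables.
#'
#' @param config A [cohort_config()].
#' @return A list: `participants`, `trials`, `tapping` tibbles
#'   ([cohort-schema]).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  set.seed(cfg$seed)

  n <- cfg$n_pd + cfg$n_control
  group <- rep(c("pd", "control"), c(cfg$n_pd, cfg$n_control))
  id <- sprintf("S%04d", seq_len(n))
  age <- pmax(41, rnorm(n, cfg$age_mean[group], cfg$age_sd[group]))
  gender <- ifelse(runif(n) < cfg$prop_male[group], "male", "female")
  duration <- ifelse(group == "pd",
                     pmax(0, rnorm(n, cfg$duration_mean, cfg$duration_sd)),
                     NA_real_)
  halluc <- group == "pd" & runif(n) < cfg$hallucination_rate
  acuity <- pmax(0.05, rnorm(n, cfg$acuity_mean[group], cfg$acuity_sd[group]))

  participants <- tibble::tibble(
    participant_id = id, group = group, age = round(age, 1),
    gender = gender, disease_duration = round(duration, 2),
    hallucinations = halluc,
    cohort = sample(c("local", "web"), n, replace = TRUE, prob = c(.15, .85)),
    screen_width = sample(c(1024L, 1280L, 1440L, 1920L), n, replace = TRUE),
    attempt_rank = 1L, atypical_pd = FALSE, acuity = round(acuity, 3)
  )

  mean_age <- mean(age)
  trials <- vector("list", n)
  for (i in seq_len(n)) {
    g <- group[i]
    rows <- list()
    for (k in seq_len(nrow(cfg$sdt_params))) {
      pr <- cfg$sdt_params[k, ]
      mu_d <- if (g == "pd") pr$mu_d_pd else pr$mu_d_control
      mu_c <- if (g == "pd") pr$mu_c_pd else pr$mu_c_control
      d_i <- rnorm(1, mu_d + cfg$age_slope * (age[i] - mean_age),
                   cfg$sd_dprime)
      c_i <- rnorm(1, mu_c, cfg$sd_criterion)
      stim <- rep(c("signal", "noise"), c(pr$n_signal, pr$n_noise))
      p_sig <- ifelse(stim == "signal",
                      pnorm(d_i / 2 - c_i), pnorm(-d_i / 2 - c_i))
      resp <- ifelse(runif(length(stim)) < p_sig, "signal", "noise")
      timeout <- pr$task %in% TIMED_TASKS &
        runif(length(stim)) < cfg$no_response_rate
      resp[timeout] <- "none"
      rows[[length(rows) + 1L]] <- tibble::tibble(
        participant_id = id[i], task = pr$task,
        difficulty_level = pr$difficulty_level,
        stimulus_class = stim, response_class = resp,
        rt_ms = ifelse(resp == "none", NA_real_,
                       round(rlnorm(length(stim), log(900), 0.35)))
      )
    }
    # mental rotation: 3-alternative task folded into correct/incorrect
    acc <- cfg$rotation_accuracy[g]
    mr_ok <- runif(24) < acc
    rows[[length(rows) + 1L]] <- tibble::tibble(
      participant_id = id[i], task = "mental_rotation",
      difficulty_level = 1L, stimulus_class = "signal",
      response_class = ifelse(mr_ok, "signal", "noise"),
      rt_ms = round(rlnorm(24, log(2000), 0.4))
    )
    # size matching: selected/target diameter per trial
    bias_i <- rnorm(1, cfg$ebbinghaus_bias[g], cfg$ebbinghaus_sd / 2)
    sel <- 20 * exp(rnorm(15, bias_i, cfg$ebbinghaus_sd))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      participant_id = id[i], task = "ebbinghaus", difficulty_level = 1L,
      stimulus_class = NA_character_, response_class = NA_character_,
      rt_ms = NA_real_, selected_diameter = round(sel, 3),
      target_diameter = 20
    )
    trials[[i]] <- dplyr::bind_rows(rows)
  }
  trials <- dplyr::bind_rows(trials)
  trials$selected_diameter <- trials$selected_diameter %||% NA_real_
  trials$target_diameter <- trials$target_diameter %||% NA_real_

  tapping <- tibble::tibble(
    participant_id = id,
    left_taps = round(pmax(1, rnorm(n, cfg$tapping_mean[group],
                                    cfg$tapping_sd[group]))),
    right_taps = round(pmax(1, rnorm(n, cfg$tapping_mean[group],
                                     cfg$tapping_sd[group])))
  )

  list(participants = participants, trials = trials, tapping = tapping)
}

#' Synthetic hidden-figures layout and click streams
#'
#' `make_horse_regions()` lays out 22 disjoint axis-aligned rectangular
#' target regions on a unit canvas — a synthetic stand-in for the
#' copyrighted hidden-horses artwork, adequate for testing the click
#' scorer. `generate_hidden_figures_clicks()` simulates participants who
#' find a Binomial(22, `p_find`) subset of regions (clicking inside each),
#' re-click a few found regions, and add background clicks.
#'
#' @param seed Integer seed.
#' @return `make_horse_regions()`: tibble `region_id`, `xmin`, `xmax`,
#'   `ymin`, `ymax` on the unit square.
#' @export
make_horse_regions <- function(seed = 1L) {
  set.seed(seed)
  # 22 cells of a jittered 5x5 grid, each shrunk to stay disjoint
  cells <- expand.grid(i = 0:4, j = 0:4)[seq_len(22), ]
  w <- 0.2
  pad <- runif(22, 0.02, 0.05)
  tibble::tibble(
    region_id = sprintf("H%02d", seq_len(22)),
    xmin = cells$i * w + pad, xmax = (cells$i + 1) * w - pad,
    ymin = cells$j * w + pad, ymax = (cells$j + 1) * w - pad
  )
}

#' @rdname make_horse_regions
#' @param participant_ids Character vector of ids.
#' @param regions Regions tibble from `make_horse_regions()`.
#' @param p_find Per-region find probability.
#' @param n_background,n_repeats Expected background clicks and repeat
#'   clicks per participant (Poisson).
#' @export
generate_hidden_figures_clicks <- function(participant_ids, regions,
                                           p_find = 0.7, n_background = 20,
                                           n_repeats = 11, seed = 1L) {
  set.seed(seed)
  one <- function(pid) {
    found <- which(runif(nrow(regions)) < p_find)
    in_region <- function(k) {
      r <- regions[k, ]
      c(runif(1, r$xmin, r$xmax), runif(1, r$ymin, r$ymax))
    }
    pts <- lapply(found, in_region)
    reps <- if (length(found)) sample(found, stats::rpois(1, n_repeats),
                                      replace = TRUE) else integer(0)
    pts <- c(pts, lapply(reps, in_region))
    nbg <- stats::rpois(1, n_background)
    # background clicks: rejection-sample points outside every region
    bg <- list()
    while (length(bg) < nbg) {
      p <- runif(2)
      inside <- any(p[1] >= regions$xmin & p[1] <= regions$xmax &
                      p[2] >= regions$ymin & p[2] <= regions$ymax)
      if (!inside) bg[[length(bg) + 1L]] <- p
    }
    pts <- c(pts, bg)
    m <- do.call(rbind, pts)
    k <- nrow(m)
    ord <- sample.int(k)
    tibble::tibble(participant_id = pid,
                   t_s = sort(runif(k, 0, 330)),
                   x = m[ord, 1], y = m[ord, 2])
  }
  dplyr::bind_rows(lapply(participant_ids, one))
}

#' Generate one size-matching trial
#'
#' Produces the 8 test-circle diameters of a size-matching trial: one test
#' circle exactly equals the target diameter (uniform random position); the
#' other 7 are drawn log-normally around the target.
#'
#' @param target_diameter Target circle diameter (default 20 px).
#' @param n_test Number of test circles (default 8).
#' @param sd_log SD of the log diameter ratios (default 0.1).
#' @param seed Optional integer seed.
#' @return Tibble: `position`, `diameter`, `is_match`.
#' @export
make_ebbinghaus_trial <- function(target_diameter = 20, n_test = 8L,
                                  sd_log = 0.1, seed = NULL) {
  stopifnot(target_diameter > 0, n_test >= 1)
  if (!is.null(seed)) set.seed(seed)
  d <- target_diameter * exp(rnorm(n_test, 0, sd_log))
  match_pos <- sample.int(n_test, 1)
  d[match_pos] <- target_diameter
  tibble::tibble(position = seq_len(n_test), diameter = d,
                 is_match = seq_len(n_test) == match_pos)
}
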
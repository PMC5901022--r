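test_that("proportion correct is counted per level and order-invariant", {
  tr <- counts_trials("A", 6, 6, 6, 6)   # 12 correct of 24
  s <- score_2afc(tr)
  expect_equal(s$proportion_correct, 0.5)
  expect_equal(s$n_trials, 24L)

  all_right <- counts_trials("B", 12, 0, 0, 12)
  expect_equal(score_2afc(all_right)$proportion_correct, 1.0)

  shuffled <- tr[sample(nrow(tr)), ]
  expect_equal(score_2afc(shuffled), s)

  # a participant with zero trials is absent, never scored 0
  expect_false("C" %in% score_2afc(tr)$participant_id)
})

test_that("binomial sampling noise of a 24-trial score matches its generative accuracy", {
  set.seed(4)
  p <- 0.75
  n <- 24
  correct <- rbinom(1, n, p)
  tr <- make_trials(rep("A", n), "peripheral", "signal",
                    rep(c("signal", "noise"), c(correct, n - correct)))
  s <- score_2afc(tr)
  ci <- qbinom(c(0.005, 0.995), n, p) / n
  expect_gte(s$proportion_correct, ci[1])
  expect_lte(s$proportion_correct, ci[2])
})

test_that("hidden-figures scoring counts finds, repeats, background and caps the stream", {
  regions <- make_horse_regions(seed = 3)
  centers <- tibble::tibble(
    participant_id = "A",
    t_s = seq_len(22),
    x = (regions$xmin + regions$xmax) / 2,
    y = (regions$ymin + regions$ymax) / 2
  )
  s <- score_hidden_figures(centers, regions)
  expect_equal(s$horses_found, 22)
  expect_equal(s$repeat_selections, 0)
  expect_equal(s$background_selections, 0)

  # repeats and a 76th click beyond the cap
  many <- dplyr::bind_rows(centers, centers, centers[rep(1:22, length.out = 32), ])
  many$t_s <- seq_len(nrow(many))
  many$participant_id <- "B"
  expect_warning(s2 <- score_hidden_figures(many, regions), "75")
  expect_equal(s2$total_clicks, 75)
  expect_equal(s2$horses_found, 22)
  expect_equal(s2$repeat_selections, 53)

  # clicks after the 6-minute mark are ignored
  late <- centers
  late$t_s <- c(rep(1, 21), 361)
  expect_warning(s3 <- score_hidden_figures(late, regions), "limit")
  expect_equal(s3$horses_found, 21)
})

test_that("uniform random clicks land outside regions at the area fraction", {
  regions <- make_horse_regions(seed = 3)
  area_in <- sum((regions$xmax - regions$xmin) * (regions$ymax - regions$ymin))
  set.seed(11)
  n <- 4000
  clicks <- tibble::tibble(participant_id = "A", t_s = seq_len(n) * 0.01,
                           x = runif(n), y = runif(n))
  # no truncation: raise caps above the stream length
  s <- score_hidden_figures(clicks, regions, max_clicks = n + 1,
                            max_time_s = 1e6)
  p_out <- 1 - area_in
  ci <- qbinom(c(0.0005, 0.9995), n, p_out) / n
  frac <- s$background_selections / n
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("illusion magnitude has its closed forms and scale invariance", {
  expect_equal(ebbinghaus_magnitude(c(20, 20, 20), 20)$log_mean_ratio, 0)
  expect_equal(ebbinghaus_magnitude(rep(40, 15), 20)$log_mean_ratio, log(2),
               tolerance = 1e-12)
  expect_error(ebbinghaus_magnitude(c(10, -1), 20), "positive")

  set.seed(8)
  sel <- 20 * exp(rnorm(15, 0.1, 0.05))
  m1 <- ebbinghaus_magnitude(sel, 20)$log_mean_ratio
  m2 <- ebbinghaus_magnitude(3.7 * sel, 3.7 * 20)$log_mean_ratio
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("log-normally biased selections recover the generating bias", {
  set.seed(21)
  b <- 1.1  # geometric-mean ratio
  reps <- replicate(200, {
    sel <- 20 * b * exp(rnorm(15, 0, 0.1))
    ebbinghaus_magnitude(sel, 20)$log_mean_ratio
  })
  se <- 0.1 / sqrt(15 * 200)
  expect_lt(abs(mean(reps) - log(b)), 4 * se)
})

test_that("staircase follows the 1-up/1-down contract", {
  run <- run_staircase(function(size) TRUE, start_size = 1, step = 0.05,
                       n_steps = 20)
  expect_true(all(diff(run$steps$size) < 0 | run$steps$size[-1] == 0.05))
  expect_equal(run$steps$size[1], 1)
  # sizes move by exactly one step until the floor
  d <- abs(diff(run$steps$size))
  expect_true(all(abs(d - 0.05) < 1e-12 | d < 1e-12))
  expect_gte(min(run$steps$size), 0.05)

  run2 <- run_staircase(function(size) FALSE, start_size = 0.5)
  expect_true(all(diff(run2$steps$size) > 0))
  expect_equal(abs(diff(run2$steps$size)), rep(0.05, 19))
})

test_that("a chance observer leaves the staircase estimate at the start size", {
  set.seed(13)
  est <- replicate(2000, run_staircase(chance_observer(0.5))$acuity_estimate)
  # symmetric walk: estimate expectation equals the start size
  expect_equal(mean(est), 1.0, tolerance = 0.02)
})

test_that("a deterministic threshold observer is recovered within two steps", {
  set.seed(17)
  thetas <- runif(100, 0.35, 0.95)
  err <- vapply(thetas, function(th) {
    abs(run_staircase(threshold_observer(th))$acuity_estimate - th)
  }, numeric(1))
  expect_true(all(err <= 0.10))
})

test_that("tapping score averages the hands and respects the bounds", {
  expect_equal(tapping_score(40, 50)$mean_taps, 45)
  expect_equal(tapping_score(10, 10)$mean_taps, 10)  # boundary retained
  one <- tapping_score(NA, 62)
  expect_equal(one$mean_taps, 62)
  expect_true(one$partial)
  expect_true(is.na(tapping_score(NA, NA)$mean_taps))
})

test_that("synthetic tapping generator recovers the configured group means", {
  co <- generate_cohort(cohort_config(n_pd = 150, n_control = 150, seed = 5))
  grp <- co$participants$group[match(co$tapping$participant_id,
                                     co$participants$participant_id)]
  m <- tapping_score(co$tapping$left_taps, co$tapping$right_taps)$mean_taps
  se <- c(pd = 15, control = 18) / sqrt(2 * 150)
  expect_equal(mean(m[grp == "pd"]), 42.2, tolerance = 4 * se["pd"],
               ignore_attr = TRUE)
  expect_equal(mean(m[grp == "control"]), 52.7, tolerance = 4 * se["control"],
               ignore_attr = TRUE)
})

test_that("the most discriminatory level is the effect-size argmax with p tie-break", {
  cmp <- tibble::tibble(difficulty_level = 1:3,
                        effect_size = c(0.2, 0.8, 0.5),
                        p_value = c(0.5, 0.01, 0.05))
  expect_equal(select_discriminatory_level(cmp), 2L)

  tied <- tibble::tibble(difficulty_level = 1:2,
                         effect_size = c(0.4, -0.4),
                         p_value = c(0.04, 0.001))
  expect_equal(select_discriminatory_level(tied), 2L)

  flat <- tibble::tibble(difficulty_level = 1:3, effect_size = 0.3,
                         p_value = 0.2)
  expect_warning(lvl <- select_discriminatory_level(flat), "identical")
  expect_equal(lvl, 1L)
})

test_that("level selection agrees with brute-force argmax over random inputs", {
  brute <- function(cmp) {
    best <- which(abs(cmp$effect_size) == max(abs(cmp$effect_size)))
    if (length(best) > 1) best <- best[cmp$p_value[best] == min(cmp$p_value[best])]
    cmp$difficulty_level[min(best)]
  }
  set.seed(3)
  for (i in 1:200) {
    cmp <- tibble::tibble(
      difficulty_level = 1:3,
      effect_size = sample(c(-1, 1), 3, TRUE) * sample(seq(0, 1, 0.25), 3, TRUE),
      p_value = sample(c(0.001, 0.04, 0.5), 3, TRUE)
    )
    if (length(unique(abs(cmp$effect_size))) == 1 &&
        length(unique(cmp$p_value)) == 1) next
    expect_equal(select_discriminatory_level(cmp), brute(cmp))
  }
})
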
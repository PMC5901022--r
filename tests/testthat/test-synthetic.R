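test_that("the generator is deterministic in its seed", {
  a <- generate_cohort(cohort_config(n_pd = 8, n_control = 8, seed = 99))
  b <- generate_cohort(cohort_config(n_pd = 8, n_control = 8, seed = 99))
  expect_identical(a, b)
  c <- generate_cohort(cohort_config(n_pd = 8, n_control = 8, seed = 100))
  expect_false(identical(a$trials, c$trials))
})

test_that("chance-level configuration yields hit and false-alarm rates near 0.5", {
  pars <- default_sdt_params()
  pars$mu_d_pd <- 0; pars$mu_d_control <- 0
  co <- generate_cohort(cohort_config(n_pd = 30, n_control = 30,
                                      sdt_params = pars, sd_dprime = 0,
                                      sd_criterion = 0, no_response_rate = 0,
                                      seed = 12))
  tr <- co$trials[co$trials$task %in% c("object_invariance", "peripheral",
                                        "biomotion"), ]
  h <- mean(tr$response_class[tr$stimulus_class == "signal"] == "signal")
  fa <- mean(tr$response_class[tr$stimulus_class == "noise"] == "signal")
  n <- sum(tr$stimulus_class == "signal")
  ci <- qbinom(c(0.0005, 0.9995), n, 0.5) / n
  expect_true(h > ci[1] && h < ci[2])
  expect_true(fa > ci[1] && fa < ci[2])
})

test_that("hit rate converges to Phi(d'/2 - c) at large trial counts", {
  pars <- default_sdt_params()[4, ]  # single-level task
  pars$n_signal <- 50000L; pars$n_noise <- 50000L
  pars$mu_d_pd <- 2; pars$mu_c_pd <- 0
  co <- generate_cohort(cohort_config(n_pd = 1, n_control = 0,
                                      sdt_params = pars, sd_dprime = 0,
                                      sd_criterion = 0, no_response_rate = 0,
                                      seed = 2))
  tr <- co$trials[co$trials$task == "peripheral", ]
  h <- mean(tr$response_class[tr$stimulus_class == "signal"] == "signal")
  fa <- mean(tr$response_class[tr$stimulus_class == "noise"] == "signal")
  expect_lt(abs(h - pnorm(1)), 0.005)
  expect_lt(abs(fa - pnorm(-1)), 0.005)
})

test_that("group summaries key only on the label: relabelling swaps them exactly", {
  co <- generate_cohort(cohort_config(n_pd = 30, n_control = 30, seed = 77))
  flipped <- co$participants
  flipped$group <- ifelse(flipped$group == "pd", "control", "pd")

  tap <- tapping_score(co$tapping$left_taps, co$tapping$right_taps)$mean_taps
  grp <- co$participants$group[match(co$tapping$participant_id,
                                     co$participants$participant_id)]
  grp_f <- flipped$group[match(co$tapping$participant_id,
                               flipped$participant_id)]
  a <- welch_t(tap[grp == "pd"], tap[grp == "control"])
  b <- welch_t(tap[grp_f == "pd"], tap[grp_f == "control"])
  expect_equal(b$statistic, -a$statistic)
  expect_equal(b$estimate, -a$estimate)
  expect_equal(b$df, a$df)
})

test_that("size-matching trials contain exactly one exact match, log-normal foils", {
  tr <- make_ebbinghaus_trial(target_diameter = 20, seed = 1)
  expect_equal(sum(tr$is_match), 1)
  expect_equal(tr$diameter[tr$is_match], 20)
  expect_equal(nrow(tr), 8)

  degenerate <- make_ebbinghaus_trial(target_diameter = 20, sd_log = 0,
                                      seed = 2)
  expect_equal(degenerate$diameter, rep(20, 8))

  set.seed(3)
  ratios <- unlist(lapply(1:400, function(i) {
    tr <- make_ebbinghaus_trial(20, sd_log = 0.1)
    log(tr$diameter[!tr$is_match] / 20)
  }))
  expect_lt(abs(mean(ratios)), 4 * 0.1 / sqrt(length(ratios)))
  expect_equal(sd(ratios), 0.1, tolerance = 0.05)
})

test_that("match position is uniform over the eight slots", {
  set.seed(6)
  pos <- vapply(1:800, function(i) {
    which(make_ebbinghaus_trial(20)$is_match)
  }, integer(1))
  expect_gt(chisq.test(table(factor(pos, levels = 1:8)))$p.value, 0.001)
})

test_that("walker trials preserve trajectories, speeds and dot counts", {
  j <- walker_trajectories()
  expect_equal(dplyr::n_distinct(j$dot), 12)

  plain <- make_walker_trial(j, n_noise_dots = 0, scrambled = FALSE)
  expect_equal(plain$x, j$x)
  expect_equal(plain$y, j$y)

  scr <- make_walker_trial(j, n_noise_dots = 0, scrambled = TRUE, seed = 4)
  speeds <- function(df) {
    s <- dplyr::group_by(df, dot)
    s <- dplyr::summarise(s, sp = list(sort(sqrt(diff(x)^2 + diff(y)^2))),
                          .groups = "drop")
    s$sp
  }
  expect_equal(speeds(scr), speeds(j))
  # form destroyed: positions differ
  expect_false(isTRUE(all.equal(scr$x, j$x)))

  noisy <- make_walker_trial(j, n_noise_dots = 30, scrambled = FALSE, seed = 5)
  expect_equal(dplyr::n_distinct(noisy$dot), 42)
  # noise speeds are drawn from the walker speed pool
  walker_speeds <- sort(unique(round(unlist(speeds(j)), 12)))
  noise_speeds <- unlist(speeds(noisy[noisy$kind == "noise", ]))
  expect_true(all(round(noise_speeds, 12) %in% walker_speeds))

  expect_warning(make_walker_trial(j, n_noise_dots = 5, seed = 1), "0, 10, 30")
})

test_that("phase morphing reconstructs the input at zero noise and zero skew", {
  set.seed(9)
  img <- matrix(runif(64 * 64), 64)
  img <- (img - min(img)) / diff(range(img))
  mag <- Mod(fft(img))
  out <- morph_object_image(img, mag, noise_weight = 0, skew = 0)
  # reconstruction is exact up to the [0,1] rescale of the original
  expect_equal(out, (img - min(img)) / diff(range(img)), tolerance = 1e-8)
})

test_that("full phase noise decorrelates the output phase from the input", {
  set.seed(10)
  img <- matrix(0, 32, 32)
  img[10:22, 14:18] <- 1
  circ_corr <- vapply(1:30, function(s) {
    out <- morph_object_image(img, Mod(fft(img)), noise_weight = 1, seed = s)
    mean(cos(Arg(fft(out)) - Arg(fft(img))))
  }, numeric(1))
  expect_lt(abs(mean(circ_corr)), 0.05)
})

test_that("shear tilts a vertical bar by the declared slope", {
  img <- matrix(0, 64, 64)
  img[, 32] <- 1
  out <- morph_object_image(img, Mod(fft(img)), noise_weight = 0, skew = 2.3)
  # centroid of each row tracks the shear line
  centroid <- apply(out, 1, function(r) sum(r * seq_along(r)) / sum(r))
  rows <- 10:55  # away from edge fill
  fit <- stats::lm(centroid[rows] ~ rows)
  expect_equal(unname(stats::coef(fit)[2]), shear_slope(2.3),
               tolerance = 0.02)
})

test_that("synthetic hidden-figures click streams score consistently", {
  regions <- make_horse_regions(seed = 2)
  clicks <- generate_hidden_figures_clicks(c("A", "B"), regions,
                                           p_find = 1, n_background = 0,
                                           n_repeats = 0, seed = 7)
  s <- score_hidden_figures(clicks, regions)
  expect_equal(s$horses_found, c(22, 22))
  expect_equal(s$background_selections, c(0, 0))
})
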
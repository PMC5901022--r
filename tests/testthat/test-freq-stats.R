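test_that("published demographic t statistics are recovered from their summaries", {
  age <- welch_t_summary(66.0, 8.8, 91, 61.7, 9.5, 275)
  expect_equal(round(age$statistic, 1), 4.0)
  expect_lt(age$p_value, 0.001)

  updrs1 <- welch_t_summary(8.74, 5.4, 31, 2.0, 2.4, 23)
  expect_equal(round(updrs1$statistic, 1), 6.2)

  # one group constant: Satterthwaite df collapse to n - 1 of the other
  updrs4 <- welch_t_summary(1.16, 2.8, 31, 0, 0, 23)
  expect_equal(round(updrs4$statistic, 1), 2.3)
  expect_equal(updrs4$df, 30)

  total <- welch_t_summary(39.6, 16.5, 31, 5.9, 5.8, 23)
  expect_equal(round(total$statistic, 1), 10.5)
})

test_that("welch t from raw data equals its summary form and t.test", {
  set.seed(5)
  x <- rnorm(20, 1, 2); y <- rnorm(35, 0, 1)
  a <- welch_t(x, y)
  b <- welch_t_summary(mean(x), sd(x), 20, mean(y), sd(y), 35)
  expect_equal(a, b)
  ref <- t.test(x, y)
  expect_equal(a$statistic, unname(ref$statistic))
  expect_equal(a$df, unname(ref$parameter))
  expect_equal(a$p_value, ref$p.value)

  same <- welch_t_summary(5, 1, 10, 5, 1, 10)
  expect_equal(same$statistic, 0)
  expect_error(welch_t_summary(3, 0, 5, 3, 0, 5), "undefined")
})

test_that("gender contingency chi-squares match the published values", {
  overall <- pearson_chi2(matrix(c(54, 37, 68, 207), 2, byrow = TRUE))
  expect_equal(round(overall$statistic, 1), 36.9)
  expect_equal(overall$df, 1)

  local <- pearson_chi2(matrix(c(18, 13, 10, 13), 2, byrow = TRUE))
  expect_equal(round(local$statistic, 2), 1.13)
})

test_that("chi-square is symmetric under transpose and zero for proportional tables", {
  tab <- matrix(c(20, 30, 10, 15), 2)
  expect_equal(pearson_chi2(tab)$statistic, pearson_chi2(t(tab))$statistic)
  expect_equal(pearson_chi2(tab[2:1, ])$statistic,
               pearson_chi2(tab)$statistic)
  prop <- matrix(c(10, 20, 30, 60), 2)
  expect_equal(pearson_chi2(prop)$statistic, 0)
  expect_error(pearson_chi2(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)), "margin")
})

test_that("rank-sum test matches exhaustive permutation enumeration", {
  exhaustive_p <- function(x, y) {
    pooled <- c(x, y)
    n <- length(x)
    U_obs <- sum(rank(pooled)[seq_len(n)]) - n * (n + 1) / 2
    idx <- utils::combn(length(pooled), n)
    Us <- apply(idx, 2, function(i) {
      sum(rank(pooled)[i]) - n * (n + 1) / 2
    })
    centre <- length(x) * length(y) / 2
    mean(abs(Us - centre) >= abs(U_obs - centre))
  }
  set.seed(7)
  for (i in 1:20) {
    x <- rnorm(sample(3:7, 1))
    y <- rnorm(sample(3:7, 1), 0.5)
    res <- mann_whitney(x, y)
    expect_equal(res$p_value, exhaustive_p(x, y), tolerance = 1e-12)
  }
})

test_that("rank-sum extremes behave correctly", {
  sep <- mann_whitney(1:5, 6:10)
  expect_equal(sep$statistic, 0)
  expect_equal(mann_whitney(6:10, 1:5)$statistic, 25)
  tied <- mann_whitney(rep(1, 4), rep(1, 4), exact = FALSE)
  expect_equal(tied$statistic, 8)
  expect_equal(tied$p_value, 1)
})

test_that("mixed ANOVA reproduces the split-plot df structure", {
  set.seed(13)
  n_pd <- 81; n_hc <- 248   # 329 complete participants
  df <- tidyr::expand_grid(
    participant_id = sprintf("P%03d", seq_len(n_pd + n_hc)),
    difficulty_level = 1:3
  )
  df$group <- rep(rep(c("pd", "control"), c(n_pd, n_hc)), each = 3)
  df$proportion_correct <- 0.8 - 0.1 * df$difficulty_level -
    0.05 * (df$group == "pd") + rnorm(nrow(df), 0, 0.1)
  res <- mixed_anova(df)
  expect_equal(res$df2[res$effect == "group"], 327)
  expect_equal(res$df2[res$effect == "difficulty"], 654)
  expect_equal(res$df[res$effect == "difficulty"], 2)
  expect_equal(res$df[res$effect == "interaction"], 2)
  expect_lt(res$p_value[res$effect == "group"], 0.001)
  expect_lt(res$p_value[res$effect == "difficulty"], 0.001)
})

test_that("mixed ANOVA sums of squares partition and degenerate input is handled", {
  set.seed(17)
  df <- tidyr::expand_grid(participant_id = sprintf("P%02d", 1:20),
                           difficulty_level = 1:3)
  df$group <- rep(rep(c("pd", "control"), each = 10), each = 3)
  df$proportion_correct <- rnorm(60, 0.7, 0.1)
  fit <- stats::aov(proportion_correct ~ group * factor(difficulty_level) +
                      Error(factor(participant_id)), data = df)
  ss <- unlist(lapply(summary(fit), function(s) s[[1]][, "Sum Sq"]))
  total <- sum((df$proportion_correct - mean(df$proportion_correct))^2)
  expect_equal(sum(ss), total, tolerance = 1e-8)

  flat <- df
  flat$proportion_correct <- 0.5
  expect_warning(z <- mixed_anova(flat), "equal")
  expect_equal(z$statistic, rep(0, 3))
})

test_that("null simulations reject at close to the nominal 5% rate", {
  set.seed(19)
  p_welch <- replicate(2000, welch_t(rnorm(15), rnorm(20))$p_value)
  expect_gt(mean(p_welch < 0.05), 0.035)
  expect_lt(mean(p_welch < 0.05), 0.065)

  p_anova <- replicate(300, {
    df <- tidyr::expand_grid(participant_id = sprintf("P%02d", 1:24),
                             difficulty_level = 1:3)
    df$group <- rep(rep(c("pd", "control"), each = 12), each = 3)
    df$proportion_correct <- rnorm(72, 0.7, 0.1)
    mixed_anova(df)$p_value[1]
  })
  expect_gt(mean(p_anova < 0.05), 0.02)
  expect_lt(mean(p_anova < 0.05), 0.09)
})

test_that("covariate-adjusted regression isolates the group effect", {
  set.seed(23)
  n <- 300
  d <- tibble::tibble(
    group = rep(c("pd", "control"), each = n / 2),
    age = rnorm(n, 64, 9),
    outcome = 0.10 * (group == "pd") + 0.005 * age + rnorm(n, 0, 0.05)
  )
  res <- adjusted_regression(d, "outcome", "group", "age")
  expect_lt(abs(res$estimate - 0.10), 4 * res$std_error)
  expect_lt(res$p_value, 1e-6)

  # orthogonal covariate leaves the group estimate at the raw difference
  d$cov <- rep(c(-1, 1), n / 2)  # balanced within groups
  raw <- diff(tapply(d$outcome, d$group, mean))
  adj <- adjusted_regression(d, "outcome", "group", "cov")
  expect_equal(abs(adj$estimate), abs(unname(raw)), tolerance = 1e-10)

  d$dup <- d$age
  expect_error(adjusted_regression(d, "outcome", "group", c("age", "dup")),
               "collinear.*dup")
})

test_that("bonferroni arithmetic and flagging", {
  expect_equal(round(bonferroni_threshold(0.05, 6), 4), 0.0083)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 2), 0.025)

  res <- dplyr::bind_rows(
    welch_t_summary(1, 1, 30, 0, 1, 30),    # strong effect
    welch_t_summary(0.1, 1, 30, 0, 1, 30)   # weak
  )
  flagged <- apply_bonferroni(res)
  expect_true(flagged$bonferroni_significant[1])
  expect_false(flagged$bonferroni_significant[2])
})

test_that("age matching trims the oldest patients until groups match", {
  set.seed(29)
  ctrl <- make_participants(80, age = rnorm(80, 62, 8))
  pd <- make_participants(40, group = "pd", age = rnorm(40, 62, 8))
  pd$participant_id <- paste0("Q", pd$participant_id)
  matched <- age_match_trim(pd, ctrl)
  expect_equal(matched$n_removed, 0)

  pd_old <- pd
  pd_old$age <- pd$age + 10
  res <- age_match_trim(pd_old, ctrl)
  expect_gt(res$n_removed, 0)
  expect_gt(res$p_value, 0.05)

  # removal order is monotone in age
  removed_ages <- pd_old$age[match(res$removed_ids, pd_old$participant_id)]
  expect_true(all(diff(removed_ages) <= 0))
  expect_true(min(removed_ages) >= max(res$participants$age))

  # brute-force scan over trim depths gives the same count
  ord <- order(-pd_old$age, pd_old$participant_id)
  depths <- 0:(nrow(pd_old) - 2)
  brute <- depths[vapply(depths, function(k) {
    keep <- pd_old[setdiff(seq_len(nrow(pd_old)), ord[seq_len(k)]), ]
    welch_t(keep$age, ctrl$age)$p_value > 0.05
  }, logical(1))][1]
  expect_equal(res$n_removed, brute)

  young <- pd
  young$age <- ctrl$age[1:40] - 40
  expect_error(age_match_trim(young, ctrl), "exhausted")
})
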
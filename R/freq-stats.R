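comparison_result <- function(test, statistic, df, p_value, df2 = NA_real_,
                              estimate = NA_real_, std_error = NA_real_,
                              effect = NA_character_) {
  tibble::tibble(test = test, effect = effect, statistic = statistic,
                 df = df, df2 = df2, p_value = p_value,
                 estimate = estimate, std_error = std_error,
                 bonferroni_significant = NA)
}

#' Welch's two-sample t test
#'
#' `welch_t()` runs the unequal-variance t test on raw data;
#' `welch_t_summary()` computes the identical test from group summaries
#' (mean, SD, n), which is how published tables are recomputed:
#' \deqn{t = \frac{\bar x_a - \bar x_b}
#'            {\sqrt{s_a^2/n_a + s_b^2/n_b}},}
#' with Welch–Satterthwaite degrees of freedom. When one group has zero
#' variance its term contributes nothing to the Satterthwaite formula and
#' the df reduce to \eqn{n_{other} - 1}. Both SDs zero with equal means is
#' undefined and raises an error.
#'
#' @param x,y Numeric vectors (raw-data form).
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b Group summaries.
#' @return A one-row comparison tibble: `test`, `statistic` (t), `df`
#'   (fractional), `p_value` (two-sided), `estimate` (mean difference),
#'   `std_error`.
#' @export
welch_t_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  stopifnot(n_a > 1, n_b > 1, sd_a >= 0, sd_b >= 0)
  va <- sd_a^2 / n_a
  vb <- sd_b^2 / n_b
  se <- sqrt(va + vb)
  if (se == 0) {
    if (mean_a == mean_b) rlang::abort("both variances zero, means equal: t undefined")
    return(comparison_result("welch_t", Inf * sign(mean_a - mean_b),
                             NA_real_, 0, estimate = mean_a - mean_b,
                             std_error = 0))
  }
  t <- (mean_a - mean_b) / se
  df <- se^4 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  p <- 2 * stats::pt(-abs(t), df)
  comparison_result("welch_t", t, df, p, estimate = mean_a - mean_b,
                    std_error = se)
}

#' @rdname welch_t_summary
#' @export
welch_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  welch_t_summary(mean(x), sd(x), length(x), mean(y), sd(y), length(y))
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson's chi-square without Yates continuity correction (the
#' uncorrected statistic is what the published contingency comparisons
#' print); the corrected variant is available by flag.
#'
#' @param tab A 2x2 matrix of counts.
#' @param correct Apply the continuity correction (default `FALSE`).
#' @return One-row comparison tibble (`df` = 1).
#' @export
pearson_chi2 <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    rlang::abort("zero row or column margin")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  comparison_result("chi2", unname(ht$statistic), unname(ht$parameter),
                    ht$p.value)
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Rank-sum comparison for non-normal outcomes. For small tie-free samples
#' the p-value is exact (identical to enumerating all rank assignments);
#' otherwise the tie-corrected normal approximation is used. The statistic
#' is W, the number of (x, y) pairs with x > y (ties counted half).
#'
#' @param x,y Numeric vectors.
#' @param exact Force the exact (`TRUE`) or approximate (`FALSE`) p-value;
#'   `NULL` (default) picks exact when both n < 50 and there are no ties.
#' @return One-row comparison tibble (`statistic` = W, `df` = `NA`).
#' @export
mann_whitney <- function(x, y, exact = NULL) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = FALSE)
  )
  p <- ht$p.value
  if (is.nan(p)) p <- 1  # zero rank variance (all observations tied)
  comparison_result("mann_whitney", unname(ht$statistic), NA_real_, p)
}

#' Mixed-design (split-plot) ANOVA
#'
#' Two-way mixed ANOVA with a between-subject factor (group) and a
#' within-subject factor (difficulty level), using the classical
#' sphericity-assuming F tests, which give the integer degrees of freedom
#' a published table prints: with N complete participants and k levels,
#' group is tested on (1, N-2) df and difficulty and the interaction on
#' (k-1, (k-1)(N-2)) df. Participants missing any level are dropped
#' (listwise deletion).
#'
#' @param data Long tibble with one score per participant x level.
#' @param score,group,difficulty,participant Column names (strings).
#' @return Comparison tibble with rows `group`, `difficulty`,
#'   `interaction`; `df`/`df2` are the numerator/denominator degrees of
#'   freedom. Degenerate inputs (zero variance everywhere) return F = 0
#'   with a warning.
#' @export
mixed_anova <- function(data, score = "proportion_correct", group = "group",
                        difficulty = "difficulty_level",
                        participant = "participant_id") {
  df <- tibble::tibble(
    score = data[[score]],
    group = factor(data[[group]]),
    difficulty = factor(data[[difficulty]]),
    participant = factor(data[[participant]])
  )
  df <- df[stats::complete.cases(df), , drop = FALSE]
  k <- nlevels(droplevels(df$difficulty))
  complete <- names(which(table(unique(df[c("participant", "difficulty")])$participant) == k))
  df <- df[df$participant %in% complete, , drop = FALSE]
  df$participant <- droplevels(df$participant)
  if (min(table(unique(df[c("participant", "group")])$group)) < 2) {
    rlang::abort("need at least 2 complete participants per group")
  }
  if (var(df$score) == 0) {
    rlang::warn("all scores equal; returning F = 0")
    z <- comparison_result("anova_mixed", 0, NA_real_, 1,
                           effect = c("group", "difficulty", "interaction"))
    return(z)
  }
  fit <- stats::aov(score ~ group * difficulty + Error(participant),
                    data = df)
  s <- summary(fit)
  between <- s[["Error: participant"]][[1]]
  within <- s[["Error: Within"]][[1]]
  grab <- function(tab, row) {
    i <- grep(row, trimws(rownames(tab)), fixed = TRUE)[1]
    res <- grep("Residuals", trimws(rownames(tab)), fixed = TRUE)[1]
    comparison_result("anova_mixed", tab[i, "F value"], tab[i, "Df"],
                      tab[i, "Pr(>F)"], df2 = tab[res, "Df"])
  }
  out <- dplyr::bind_rows(
    grab(between, "group"),
    grab(within, "difficulty"),
    grab(within, "group:difficulty")
  )
  out$effect <- c("group", "difficulty", "interaction")
  out
}

#' Covariate-adjusted group regression
#'
#' Ordinary least squares of an outcome on group plus nuisance covariates
#' (age, gender, acuity in the study's robustness analyses), reporting the
#' group coefficient with covariates partialled out. A rank-deficient
#' design raises an error naming the collinear columns.
#'
#' @param data Tibble containing the outcome, group and covariates.
#' @param outcome Outcome column name.
#' @param group Group column name (2-level factor or character).
#' @param covariates Character vector of covariate column names (may be
#'   empty).
#' @return One-row comparison tibble for the group term: `estimate`
#'   (group coefficient), `std_error`, `statistic` (t), `df` (residual),
#'   `p_value`.
#' @export
adjusted_regression <- function(data, outcome, group,
                                covariates = character(0)) {
  rhs <- paste(c(group, covariates), collapse = " + ")
  fml <- stats::as.formula(paste(outcome, "~", rhs))
  mm <- stats::model.matrix(fml, data = data)
  qr_ <- qr(mm)
  if (qr_$rank < ncol(mm)) {
    dropped <- colnames(mm)[qr_$pivot[(qr_$rank + 1):ncol(mm)]]
    rlang::abort(sprintf("rank-deficient design; collinear column(s): %s",
                         paste(dropped, collapse = ", ")))
  }
  fit <- stats::lm(fml, data = data)
  co <- summary(fit)$coefficients
  i <- grep(paste0("^", group), rownames(co))[1]
  comparison_result("ols", co[i, "t value"], fit$df.residual,
                    co[i, "Pr(>|t|)"], estimate = co[i, "Estimate"],
                    std_error = co[i, "Std. Error"], effect = group)
}

#' Bonferroni-corrected significance threshold
#'
#' Family-wise error control by dividing the significance level by the
#' number of comparisons; with the study's six task comparisons at
#' \eqn{\alpha = 0.05} the threshold is \eqn{0.05/6 = 0.00833}.
#'
#' @param alpha Family-wise significance level.
#' @param n_comparisons Number of comparisons.
#' @return The per-comparison threshold `alpha / n_comparisons`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_comparisons = 6) {
  stopifnot(alpha > 0, alpha < 1, n_comparisons >= 1)
  alpha / n_comparisons
}

#' @rdname bonferroni_threshold
#' @param results A comparison tibble.
#' @return For `apply_bonferroni()`: the tibble with
#'   `bonferroni_significant` filled against the unrounded threshold.
#' @export
apply_bonferroni <- function(results, alpha = 0.05, n_comparisons = 6) {
  results$bonferroni_significant <-
    results$p_value < bonferroni_threshold(alpha, n_comparisons)
  results
}

#' Age-match groups by trimming the oldest patients
#'
#' Iteratively removes the single oldest PD participant (age ties broken
#' by id order, deterministically) until a Welch t test on age between the
#' trimmed PD group and the controls is non-significant at `alpha` — the
#' study's "oldest patients removed until the groups were age matched"
#' robustness check.
#'
#' @param pd,controls Participant tibbles with an `age` column.
#' @param alpha Matching criterion: stop once the age comparison has
#'   p > `alpha` (default 0.05).
#' @return A list: `participants` (trimmed PD tibble), `n_removed`,
#'   `removed_ids`, `p_value` (final age comparison). Errors if the PD
#'   group would be exhausted (fewer than 2 left) before matching.
#' @export
age_match_trim <- function(pd, controls, alpha = 0.05) {
  stopifnot(nrow(pd) > 0, nrow(controls) > 0)
  removed <- character(0)
  current <- pd
  repeat {
    p <- welch_t(current$age, controls$age)$p_value
    if (p > alpha) break
    if (nrow(current) <= 2) {
      rlang::abort(sprintf(
        "PD group exhausted before age matching (last p = %.4g, %d removed)",
        p, length(removed)))
    }
    oldest <- order(-current$age, current$participant_id)[1]
    removed <- c(removed, current$participant_id[oldest])
    current <- current[-oldest, , drop = FALSE]
  }
  list(participants = current, n_removed = length(removed),
       removed_ids = removed, p_value = p)
}
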
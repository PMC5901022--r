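#' Priors for the hierarchical signal detection model
#'
#' Uninformative (high-variance) priors on the group-level parameters,
#' written JAGS-style with precisions (reciprocal variances):
#' \deqn{\mu_{d'} \sim N(0, 0.001), \quad \mu_c \sim N(0, 0.001),}
#' \deqn{\lambda_{d'} \sim \mathrm{Gamma}(0.001, 0.001), \quad
#'       \lambda_c \sim \mathrm{Gamma}(0.001, 0.001),}
#' so the prior SD of each group mean is \eqn{1/\sqrt{0.001} \approx 31.6}
#' SDT units.
#'
#' @param mu_mean,mu_precision Normal prior on the group means.
#' @param lambda_shape,lambda_rate Gamma prior (shape, rate) on the
#'   group precisions.
#' @return A list of class `hier_priors`.
#' @export
hier_priors <- function(mu_mean = 0, mu_precision = 0.001,
                        lambda_shape = 0.001, lambda_rate = 0.001) {
  stopifnot(mu_precision > 0, lambda_shape > 0, lambda_rate > 0)
  structure(list(mu_mean = mu_mean, mu_precision = mu_precision,
                 lambda_shape = lambda_shape, lambda_rate = lambda_rate),
            class = "hier_priors")
}

#' MCMC settings for the hierarchical fit
#'
#' Desk-scale defaults (3 chains of 5,000 retained draws after 500
#' adaptation and 1,000 burn-in steps) keep a fit to a few seconds while
#' leaving Monte Carlo error well below the scientific tolerances.
#' `full_settings = TRUE` switches to the full production run:
#' 2,000 adaptation steps, 5,000 burn-in, 50,000 retained draws
#' ("effective samples" read as retained iterations), 3 chains.
#'
#' @param n_adapt,n_burn,n_samples,n_chains Sampler settings; at least 2
#'   chains are required for the split-chain convergence diagnostic.
#' @param seed Integer seed for the chains' generators.
#' @param full_settings Use the full production settings (2,000 adaptation, 5,000 burn-in, 50,000 retained draws, 3 chains).
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_adapt = 500, n_burn = 1000, n_samples = 5000,
                        n_chains = 3, seed = 1L, full_settings = FALSE) {
  if (full_settings) {
    n_adapt <- 2000; n_burn <- 5000; n_samples <- 50000; n_chains <- 3
  }
  stopifnot(n_adapt > 0, n_burn > 0, n_samples > 0, n_chains >= 2)
  structure(list(n_adapt = n_adapt, n_burn = n_burn, n_samples = n_samples,
                 n_chains = n_chains, seed = as.integer(seed)),
            class = "mcmc_config")
}

hier_sdt_model_string <- function(prior_only = FALSE) {
  # prior-only: hyperparameters alone (the subject layer is integrated out
  # of nothing; sampling it under the raw vague gamma underflows precisions)
  if (prior_only) {
    return("
model {
  mu_d ~ dnorm(prior_mu_mean, prior_mu_prec)
  mu_c ~ dnorm(prior_mu_mean, prior_mu_prec)
  lambda_d ~ dgamma(prior_shape, prior_rate)
  lambda_c ~ dgamma(prior_shape, prior_rate)
}")
  }
  "
model {
  mu_d ~ dnorm(prior_mu_mean, prior_mu_prec)
  mu_c ~ dnorm(prior_mu_mean, prior_mu_prec)
  lambda_d ~ dgamma(prior_shape, prior_rate)
  lambda_c ~ dgamma(prior_shape, prior_rate)
  for (i in 1:S) {
    d[i] ~ dnorm(mu_d, lambda_d)
    crit[i] ~ dnorm(mu_c, lambda_c)
    thetaH[i] <- phi( d[i] / 2 - crit[i])
    thetaF[i] <- phi(-d[i] / 2 - crit[i])
    hits[i] ~ dbin(thetaH[i], n_signal[i])
    fas[i]  ~ dbin(thetaF[i], n_noise[i])
  }
}"
}

#' Fit the hierarchical Bayesian signal detection model
#'
#' Fits, by Gibbs sampling in JAGS, the partial-pooling binomial-probit
#' model that ties few-trial subjects together through group-level
#' parameters:
#' \deqn{h_i \sim \mathrm{Bin}(\Phi(d'_i/2 - c_i),\, n^{sig}_i), \quad
#'       f_i \sim \mathrm{Bin}(\Phi(-d'_i/2 - c_i),\, n^{noise}_i),}
#' \deqn{d'_i \sim N(\mu_{d'}, \lambda_{d'}), \quad
#'       c_i \sim N(\mu_c, \lambda_c),}
#' with the hyperpriors of [hier_priors()]. This likelihood is the unique
#' one consistent with the estimators \eqn{z(H) = d'/2 - c} and
#' \eqn{z(FA) = -d'/2 - c}. The model is fitted to one group at a time;
#' group contrasts come from [posterior_prob_diff()] across two fits.
#'
#' Convergence is checked with the potential scale reduction statistic
#' ([rhat()]) on every group-level parameter; any value above 1.1 flags
#' the fit as non-converged (the result is still returned, carrying the
#' flag).
#'
#' @param counts Outcome tibble from [count_outcomes()] for one group;
#'   participants lacking signal or noise trials are dropped (no rate can
#'   be formed).
#' @param priors A [hier_priors()].
#' @param mcmc An [mcmc_config()].
#' @param prior_only Fit with the likelihood removed, so posteriors
#'   reproduce the priors (prior predictive check).
#' @param monitor_subjects Keep per-subject draws (default `TRUE`).
#' @return Object of class `hier_sdt_fit`: `draws` (tibble `chain`,
#'   `iteration`, `parameter`, `value` for the group-level parameters),
#'   `samples` (the full `coda::mcmc.list`), `rhat` (named vector),
#'   `converged`, `n_subjects`, `priors`, `mcmc`.
#' @export
fit_hier_sdt <- function(counts, priors = hier_priors(),
                         mcmc = mcmc_config(), prior_only = FALSE,
                         monitor_subjects = TRUE) {
  stopifnot(inherits(priors, "hier_priors"), inherits(mcmc, "mcmc_config"))
  ok <- counts$n_signal > 0 & counts$n_noise > 0
  if (any(!ok)) {
    rlang::inform(sprintf(
      "dropping %d participant(s) with no signal or no noise trials",
      sum(!ok)))
    counts <- counts[ok, , drop = FALSE]
  }
  S <- nrow(counts)
  if (S < 2) rlang::abort("need at least 2 assessable participants")

  data <- list(
    prior_mu_mean = priors$mu_mean, prior_mu_prec = priors$mu_precision,
    prior_shape = priors$lambda_shape, prior_rate = priors$lambda_rate
  )
  if (!prior_only) {
    data$S <- S
    data$n_signal <- counts$n_signal
    data$n_noise <- counts$n_noise
    data$hits <- counts$hits
    data$fas <- counts$false_alarms
  }

  inits <- lapply(seq_len(mcmc$n_chains), function(ch) {
    ii <- list(mu_d = 0, mu_c = 0, lambda_d = 1, lambda_c = 1,
               .RNG.name = "base::Mersenne-Twister",
               .RNG.seed = (abs(mcmc$seed) * 1009L + ch) %% .Machine$integer.max)
    if (!prior_only) {
      ii$d <- rep(0, S)
      ii$crit <- rep(0, S)
    }
    ii
  })
  monitor <- c("mu_d", "mu_c", "lambda_d", "lambda_c")
  if (monitor_subjects && !prior_only) monitor <- c(monitor, "d", "crit")

  model <- rjags::jags.model(
    textConnection(hier_sdt_model_string(prior_only)),
    data = data, inits = inits, n.chains = mcmc$n_chains,
    n.adapt = mcmc$n_adapt, quiet = TRUE
  )
  stats::update(model, n.iter = mcmc$n_burn, progress.bar = "none")
  samples <- rjags::coda.samples(model, monitor, n.iter = mcmc$n_samples,
                                 progress.bar = "none")

  group_pars <- c("mu_d", "mu_c", "lambda_d", "lambda_c")
  rh <- vapply(group_pars, function(p) {
    rhat(sapply(samples, function(ch) as.numeric(ch[, p])))
  }, numeric(1))
  converged <- all(rh < 1.1, na.rm = TRUE)
  if (!converged) {
    rlang::warn(sprintf("fit flagged non-converged: max R-hat = %.3f",
                        max(rh, na.rm = TRUE)))
  }

  draws <- dplyr::bind_rows(lapply(seq_along(samples), function(ch) {
    m <- as.matrix(samples[[ch]])[, group_pars, drop = FALSE]
    tidyr::pivot_longer(
      dplyr::mutate(tibble::as_tibble(m),
                    chain = ch, iteration = dplyr::row_number()),
      dplyr::all_of(group_pars),
      names_to = "parameter", values_to = "value"
    )
  }))

  structure(
    list(draws = draws, samples = samples, rhat = rh, converged = converged,
         n_subjects = S, participant_id = counts$participant_id,
         priors = priors, mcmc = mcmc, prior_only = prior_only),
    class = "hier_sdt_fit"
  )
}

#' @export
print.hier_sdt_fit <- function(x, ...) {
  cat(sprintf(
    "<hier_sdt_fit> %d subjects, %d chains x %d draws%s; max R-hat %.3f%s\n",
    x$n_subjects, x$mcmc$n_chains, x$mcmc$n_samples,
    if (x$prior_only) " (prior only)" else "",
    max(x$rhat), if (x$converged) "" else " [NOT CONVERGED]"))
  print(generics::tidy(x))
  invisible(x)
}

#' Potential scale reduction statistic (R-hat)
#'
#' The Gelman–Rubin convergence diagnostic: with \eqn{m} chains of length
#' \eqn{n}, within-chain variance \eqn{W} and between-chain variance
#' \eqn{B}, \deqn{\hat R = \sqrt{\frac{(n-1)/n\,W + B/n}{W}}.}
#' Values near 1 indicate the chains sample the same distribution; above
#' about 1.1 the fit has not converged.
#'
#' @param draws A matrix (iterations x chains), a list of equal-length
#'   numeric vectors, or a `coda::mcmc.list` with one variable.
#' @return The \eqn{\hat R} statistic (scalar).
#' @export
rhat <- function(draws) {
  if (inherits(draws, "mcmc.list")) {
    draws <- sapply(draws, as.numeric)
  }
  if (is.list(draws)) draws <- do.call(cbind, draws)
  draws <- as.matrix(draws)
  m <- ncol(draws); n <- nrow(draws)
  if (m < 2) rlang::abort("R-hat needs at least 2 chains")
  if (n < 2) rlang::abort("R-hat needs at least 2 draws per chain")
  W <- mean(apply(draws, 2, var))
  B <- n * var(colMeans(draws))
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Posterior probability of a group difference
#'
#' Estimates \eqn{P_\theta = \Pr(\theta_A - \theta_B > 0)} for a
#' group-level parameter from two independently fitted groups by pairing
#' random posterior draws across the fits (independent pairing is the
#' correct combination for separately fitted models). High values are
#' strong evidence the parameter is larger in group A; values near 0.5
#' indicate no evidence of a difference.
#'
#' @param fit_a,fit_b `hier_sdt_fit` objects (e.g. controls and patients).
#' @param parameter Group-level parameter (`"mu_d"`, `"mu_c"`,
#'   `"lambda_d"`, `"lambda_c"`).
#' @param n_pairs Number of random cross-fit pairs (default 1e5).
#' @param seed Optional seed for the pairing.
#' @return Tibble: `parameter`, `p_theta`, `n_pairs`, `converged` (both
#'   inputs converged; a non-converged input propagates its flag).
#' @export
posterior_prob_diff <- function(fit_a, fit_b, parameter = "mu_d",
                                n_pairs = 1e5, seed = NULL) {
  stopifnot(inherits(fit_a, "hier_sdt_fit"), inherits(fit_b, "hier_sdt_fit"))
  if (!is.null(seed)) set.seed(seed)
  da <- fit_a$draws$value[fit_a$draws$parameter == parameter]
  db <- fit_b$draws$value[fit_b$draws$parameter == parameter]
  if (length(da) == 0 || length(db) == 0) {
    rlang::abort(sprintf("parameter '%s' not found in fits", parameter))
  }
  a <- da[sample.int(length(da), n_pairs, replace = TRUE)]
  b <- db[sample.int(length(db), n_pairs, replace = TRUE)]
  tibble::tibble(parameter = parameter,
                 p_theta = mean(a - b > 0),
                 n_pairs = as.integer(n_pairs),
                 converged = fit_a$converged && fit_b$converged)
}

#' Tidy a hierarchical SDT fit
#'
#' `tidy()` returns one row per group-level parameter with posterior mean,
#' SD, central 95% credible interval and R-hat. `glance()` returns a
#' one-row fit summary.
#'
#' @param x A `hier_sdt_fit`.
#' @param ... Unused.
#' @export
tidy.hier_sdt_fit <- function(x, ...) {
  out <- dplyr::summarise(
    dplyr::group_by(x$draws, .data$parameter),
    mean = mean(.data$value), sd = sd(.data$value),
    ci_lower = stats::quantile(.data$value, 0.025),
    ci_upper = stats::quantile(.data$value, 0.975),
    .groups = "drop"
  )
  out$rhat <- x$rhat[out$parameter]
  out
}

#' @rdname tidy.hier_sdt_fit
#' @export
glance.hier_sdt_fit <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$n_subjects,
    n_chains = x$mcmc$n_chains,
    n_draws = x$mcmc$n_samples * x$mcmc$n_chains,
    max_rhat = max(x$rhat),
    converged = x$converged,
    prior_only = x$prior_only
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
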
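---
title: "Methods: hierarchical signal detection analysis of online visuo-perceptual tasks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical signal detection analysis of online visuo-perceptual tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Short online visuo-perceptual tasks can reach large case-control cohorts
(people with Parkinson's disease and controls) that no lab study could,
but at a price: two dozen trials per task per person, self-reported
metadata, heterogeneous devices, and timed trials that sometimes elapse
with no response. This vignette describes the modelling and the
numerical choices `visuosdt` makes at each step, and what its synthetic
cohorts can and cannot tell you about real data.

## Cohort quality control

Exclusion rules are applied in a fixed precedence order so that each
removed participant carries exactly one primary reason: age at or below
40 years (the study population is adult-onset PD and age-matched
controls), a clinician-supplied atypical-parkinsonism flag (never
inferred from the data), a screen narrower than 768 px (phone-sized
devices render the stimuli too small; the threshold is configurable),
and duplicate attempts. "Highest-scoring attempt" is defined as the
highest mean proportion correct across the completed choice tasks — the
only aggregate that is symmetric across tasks; equal scores keep the
earliest attempt, which makes the filter deterministic and idempotent.
Tapping runs below 10 or at or above 100 taps per 30 s are treated as
recording artefacts and removed from the tapping analysis only. For the
two graded-difficulty recognition tasks, participants at or below 50%
correct at the easiest level are flagged per task: at chance on the
easiest stimuli there is no measurable engagement, and retaining such
runs would contaminate the difficulty gradient.

Timed trials can end with no response. The primary scoring counts these
against the participant (a timeout cannot be a correct identification),
while the signal detection analyses must drop them (no response class
exists). The pipeline therefore always emits a paired sensitivity
report — every group comparison with and without timed-out trials — so
that any conclusion's dependence on timeout handling is visible.

## Task scoring

Choice tasks score as proportion correct per difficulty level. The
size-matching (Ebbinghaus) task scores as the mean of
$\log(\text{selected}/\text{target})$ diameters: 0 is veridical,
negative means systematically smaller circles are chosen, and the log
scale makes the score symmetric and scale-invariant. The score is kept
in log space and exponentiated only for display.

The acuity staircase is 1-up/1-down with 0.05 decimal-acuity steps over
20 presentations, estimate = mean size of the last 4 steps. The
up-down rule itself is a design choice (the converging rule was not
recorded with the task); 1-up/1-down converges on the 50% point of the
psychometric function and is the default, with 2-down/1-up (~71%)
available. The start size defaults to 1.0 decimal acuity — normal
adult acuity — and is configurable. Sizes are floored one step above
zero. With a deterministic threshold observer the procedure reaches
any threshold at least 16 steps away and then oscillates one step
around it, which bounds the estimate error by two steps (0.10); the
test suite checks this over 100 random thresholds, and checks on 2,000
chance-observer runs that the estimate is unbiased at the start size
(the walk is then symmetric).

Where a task has several difficulty levels, downstream regressions use
the most discriminatory level: largest absolute standardized effect
size, ties broken by smaller p-value. Effect size is Cohen's d
(difference of group means over pooled SD) — the conventional choice
when none is named.

## Classical signal detection

For the three 2AFC tasks, responses sort into hits, misses, false alarms
and correct rejections; difficulty levels are pooled by default (the
per-subject trial budget is too small to resolve level-specific
parameters; a per-level option exists). The equal-variance estimators
are $d' = z(H) - z(FA)$ and $c = -\tfrac12(z(H)+z(FA))$. Observed rates
of exactly 0 or 1 make $z$ infinite; the default correction replaces 0
with $1/(2N)$ and 1 with $1-1/(2N)$, applied only to the offending rate
and flagged in the output. The correction is symmetric under relabelling
of the two response classes, so the identities the estimators must
satisfy — $d'$ invariant and $c$ negated under relabelling — hold
exactly even for corrected counts. Which physical alternative counts as
"signal" is an arbitrary per-task convention (person = signal for
biological motion, "same" = signal for the peripheral task, dog = signal
for object invariance); $d'$ does not depend on it.

## The hierarchical Bayesian model

Twenty-four trials cannot support a stable per-person $d'$; partial
pooling can. Per group (fitted separately for PD and controls):

$$h_i \sim \mathrm{Bin}\!\left(\Phi(d'_i/2 - c_i),\, n^{sig}_i\right),
\qquad
f_i \sim \mathrm{Bin}\!\left(\Phi(-d'_i/2 - c_i),\, n^{noise}_i\right)$$
$$d'_i \sim N(\mu_{d'}, \lambda_{d'}), \qquad c_i \sim N(\mu_c, \lambda_c)$$
$$\mu \sim N(0, 0.001), \qquad \lambda \sim \mathrm{Gamma}(0.001, 0.001)$$

(normals parameterised by precision; Gamma by shape and rate). The
binomial-probit likelihood is the unique one whose maximum-likelihood
inversion reproduces the classical estimators ($z(H) = d'/2 - c$,
$z(FA) = -d'/2 - c$), so the hierarchical and classical analyses
estimate the same quantities. Participants lacking either trial type
after timeout removal are dropped — no rate can be formed for them.

Sampling is Gibbs via JAGS (`rjags`), 3 chains. Desk-scale defaults are
500 adaptation / 1,000 burn-in / 5,000 retained draws per chain, which
puts the Monte Carlo error of group-level means well below the
scientific tolerances while a fit takes seconds;
`mcmc_config(full_settings = TRUE)` switches to 2,000 / 5,000 / 50,000.
"Retained draws" are iterations kept after burn-in, not an
autocorrelation-adjusted effective sample size. Chains are initialised
at $\mu = 0$, $\lambda = 1$, subject parameters 0 — overdispersed starts
are unnecessary here because the conditionals are well behaved, and the
convergence diagnostic guards the rest. Every group-level parameter gets
the classic Gelman–Rubin $\hat R$ (between/within chain variance, no
degrees-of-freedom correction; cross-checked against `coda` in the test
suite), and any $\hat R > 1.1$ flags the whole fit non-converged — the
result is returned with the flag rather than suppressed, and the flag
propagates into the group-difference output.

Group differences are summarised as
$P_\theta = \Pr(\mu_{A} - \mu_{B} > 0)$, estimated from $10^5$ randomly
paired draws across the two independent fits; independent pairing is
correct precisely because the groups are fitted separately. A
prior-only fit (likelihood removed) is available as a prior-predictive
check; the hyperparameter-only model is sampled directly because
sampling the subject layer under the raw vague Gamma prior underflows
precisions to zero. The posterior SD of $\mu_{d'}$ must then reproduce
the prior SD $1/\sqrt{0.001} \approx 31.6$.

Two behaviours of this model are worth knowing. First, with 12+12
trials per subject the Gamma(0.001, 0.001) precision prior shrinks
aggressively: binomial noise already explains most of the observed
variance, so the posterior often concentrates on large $\lambda_{d'}$
and single-replicate 95% credible intervals for $\mu_{d'}$ cover the
generating value at somewhat below nominal rate (~85–90% in our
replicate experiments). The test suite therefore asserts interval
coverage as a rate over replicates, not on one dataset. Second, for
two groups drawn independently from identical generative distributions,
$P_\theta$ is approximately uniform over replicates — that is what
posterior calibration means — so "no difference" shows up as
$P_\theta \approx 0.5$ only when the same data are fitted twice; across
independent null replicates any fixed interval around 0.5 captures a
bounded fraction. The null checks in the tests and acceptance script
are built accordingly.

## Frequentist battery

Welch's t is implemented in closed form from group summaries (mean, SD,
n) so that published tables can be recomputed exactly, with the raw-data
form deferring to the same arithmetic; when one group has zero variance
the Satterthwaite formula degenerates to $n_{\text{other}} - 1$ df.
Pearson's χ² uses no continuity correction by default — that is the
convention the recomputed contingency statistics match — with the
corrected variant behind a flag. The Mann–Whitney test returns the
exact p-value for small tie-free samples (identical to enumerating all
rank assignments, which the tests verify by brute force) and the
tie-corrected normal approximation otherwise. The mixed-design ANOVA
uses classical sphericity-assuming F tests, giving the integer
df structure ($1, N-2$ between; $k-1, (k-1)(N-2)$ within) that published
tables print; no Greenhouse–Geisser correction is applied, matching
that convention. Covariate adjustment is ordinary least squares with an
explicit rank check that names collinear columns. Age matching removes
the single oldest patient (ties by id, deterministically) until Welch's
p on age exceeds 0.05 — the stopping rule is a design choice where only
the procedure was specified. Bonferroni significance is computed
against the unrounded $\alpha/6 = 0.008\overline{3}$.

## What the synthetic cohort emulates — and what it does not

The generator's defaults are the study conditions: 91 PD / 275
controls; ages $N(66.0, 8.8^2)$ vs $N(61.7, 9.5^2)$ truncated above 40;
male fractions 54/91 and 68/275; disease duration $N(4.85, 3.89^2)$
(PD only, floored at 0); 15/91 hallucination rate; tapping
$N(42.2, 15^2)$ vs $N(52.7, 18^2)$; acuity $N(0.74, 0.3^2)$ vs
$N(0.82, 0.3^2)$; Ebbinghaus log-ratio bias $-0.06$ vs $-0.07$; 24
trials per 2AFC task (8 per level for the two graded tasks, half
signal), 15 size-matching trials, 5% timeouts on timed tasks. Group
$d'$ means are back-solved from the published proportion-correct table
through the unbiased 2AFC identity $d' = 2\,z(p_c)$ (e.g. control skew
levels 0.98/0.75/0.63 give 4.11/1.35/0.66); criterion means are 0.
Between-subject SDs — 0.5 for $d'$, 0.3 for $c$ — are not published and
were fixed once at values typical for perceptual case-control work.
Trial responses are generated by the exact inverse of the estimators:
signal trials answered "signal" with probability $\Phi(d'_i/2 - c_i)$,
noise trials with $\Phi(-d'_i/2 - c_i)$, which the tests verify against
$\Phi$ at $10^5$ trials.

Deliberately not emulated: age–performance coupling is off unless a
slope is configured (it exists in real data and is the reason the
age-adjusted analyses exist); demographics are drawn independently of
performance; devices, learning effects, lapses and serial dependence
between trials do not exist; Ebbinghaus selections are drawn from a
per-subject log-normal rather than from a model of inducer-driven bias.
Passing tests on synthetic cohorts therefore demonstrate that the
estimators and the pipeline are correct under the stated generative
model — not that the model captures every property of web-collected
patient data.

Stimulus constructors exist for fixture generation: Fourier
phase-morphing mixes unit phasors of the image phase and white-noise
phase (mixing weight 0.5 by default; the combination rule is fixed but
the proportion was never published), recombines with a reference
magnitude spectrum, shears rows by `shear_slope(skew)` columns/row and
rescales to $[0,1]$ — with zero noise, zero skew and the image's own
magnitude spectrum the input is reconstructed to numerical tolerance.
Point-light walkers come from a 12-joint sinusoidal gait model (the
cited motion-capture data are not available); "motion-matched" noise
dots copy a random walker dot's displacement sequence under a circular
time shift from a random start, which preserves the per-dot speed
distribution exactly — one defensible reading of a phrase the source
never operationalised. The hidden-figures layout is 22 disjoint
rectangles on the unit square, a synthetic stand-in for a copyrighted
artwork.

## Problem sizes and numerical tolerances

The default test run uses cohorts of 15–50 subjects per group, fits of
2 chains × 1,000–2,500 retained draws, 20–40 replicate studies for
calibration and coverage checks, and $10^5$-trial runs for
law-of-large-numbers checks; the full suite completes in about a
minute. Closed-form identities are asserted to $10^{-9}$–$10^{-12}$;
Monte Carlo checks use 99–99.9% binomial or normal-theory intervals
around the generating values, computed from the simulation size rather
than tuned constants. Degenerate inputs are contracts, not accidents:
zero scorable trials is "unassessable", never a score of 0; an all-tied
rank-sum has p = 1; an all-constant ANOVA returns F = 0 with a warning;
a rank-deficient regression refuses with the offending columns named.

## Known limitations

The hierarchical model is equal-variance SDT with probit links; ROC
asymmetry, lapses and unequal-variance extensions are out of scope, as
is any model comparison between tasks. The per-task signal-class
convention is fixed in configuration, and difficulty levels are pooled
for the SDT analyses by default. The acceptance checks recompute
summary statistics from published summary rows, not from raw study data
(none were deposited), so their agreement validates formulas and
conventions — Welch arithmetic, χ² without continuity correction,
integer ANOVA df — rather than the original data handling. Welch df
printed in the source tables were computed from unrounded raw data and
cannot always be matched from two-decimal summaries; the t statistics
can, and are what the recomputation targets pin.
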
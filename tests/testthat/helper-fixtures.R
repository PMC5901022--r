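# Hand-built trial rows for unit tests.
make_trials <- function(participant_id, task, stim, resp,
                        difficulty_level = 1L, rt_ms = 800) {
  tibble::tibble(
    participant_id = participant_id, task = task,
    difficulty_level = as.integer(difficulty_level),
    stimulus_class = stim, response_class = resp, rt_ms = rt_ms,
    selected_diameter = NA_real_, target_diameter = NA_real_
  )
}

make_participants <- function(n, group = "control", age = 60, ...) {
  tibble::tibble(
    participant_id = sprintf("P%03d", seq_len(n)),
    group = group, age = age, gender = "female",
    disease_duration = ifelse(group == "pd", 5, NA_real_),
    hallucinations = FALSE, cohort = "web", screen_width = 1280L,
    attempt_rank = 1L, atypical_pd = FALSE, ...
  )
}

# Trials realising exact confusion counts for one participant.
counts_trials <- function(id, hits, misses, fas, crs,
                          task = "peripheral") {
  make_trials(
    id, task,
    stim = rep(c("signal", "noise"), c(hits + misses, fas + crs)),
    resp = c(rep(c("signal", "noise"), c(hits, misses)),
             rep(c("signal", "noise"), c(fas, crs)))
  )
}

# Simulated confusion-count table for a group with known (mu_d, mu_c).
simulate_counts <- function(n_subjects, mu_d, sd_d, mu_c = 0, sd_c = 0.2,
                            n_signal = 12, n_noise = 12) {
  d <- rnorm(n_subjects, mu_d, sd_d)
  cc <- rnorm(n_subjects, mu_c, sd_c)
  hits <- rbinom(n_subjects, n_signal, pnorm(d / 2 - cc))
  fas <- rbinom(n_subjects, n_noise, pnorm(-d / 2 - cc))
  tibble::tibble(
    participant_id = sprintf("S%03d", seq_len(n_subjects)),
    task = "peripheral",
    hits = hits, misses = n_signal - hits,
    false_alarms = fas, correct_rejections = n_noise - fas,
    n_signal = n_signal, n_noise = n_noise, assessable = TRUE
  )
}

quick_mcmc <- function(seed = 1L, n_samples = 1500) {
  mcmc_config(n_adapt = 300, n_burn = 300, n_samples = n_samples,
              n_chains = 2, seed = seed)
}
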
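# Shared fixtures built in code.

toy_path <- function(file) {
  system.file("extdata", "toy", file, package = "modulewise", mustWork = TRUE)
}

read_toy <- function() {
  read_cohort(baseline = toy_path("baseline.csv"),
              calendar = toy_path("calendar.csv"),
              modules = toy_path("modules.csv"),
              feedback = toy_path("feedback.csv"))
}

# Truth with every module effect zeroed (for null-calibration checks).
null_truth <- function(...) {
  z <- setNames(rep(0, 6), module_topics())
  default_truth(module_log_odds_offsets = z,
                module_high_risk_interaction = z,
                feedback_module_offsets = z, ...)
}

# Fully observed two-participant micro dataset for the drinking model:
# two 7-day windows per participant, deterministic outcomes, complete
# covariates. Small enough for an independent sampler to handle.
micro_alcohol_rows <- function() {
  win <- function(pid, topic, risk, pw, t0, y, age_s, sexm, asi, tr2) {
    tibble::tibble(
      participant_id = pid, module_topic = topic,
      completion_date = as.Date("2022-03-07") + t0,
      date = as.Date("2022-03-07") + t0 + 0:6, offset = 0:6,
      drank = y, high_risk = risk, prior_week_use = pw,
      days_since_randomization = t0 + 0:6, time_scaled = (t0 + 0:6) / 28,
      age_years = 21 + 10 * age_s, age_scaled = age_s, sex_male = sexm,
      asi_alcohol = asi, trial2 = tr2)
  }
  risk_a <- c(0, 0, 0, 0, 1, 1, 1)
  dplyr::bind_rows(
    win("p1", "functional_analysis", risk_a, 0, 0,
        c(0, 1, 0, 0, 1, 1, 0), 2.0, 1, 0.4, 0),
    win("p1", "assertive_communication", risk_a, 1, 7,
        c(1, 0, 0, 1, 1, 0, 1), 2.0, 1, 0.4, 0),
    win("p2", "coping_with_craving", risk_a, 0, 0,
        c(0, 0, 0, 0, 1, 0, 0), 1.0, 0, 0.2, 1),
    win("p2", "cognitive_restructuring", risk_a, 1, 7,
        c(0, 0, 1, 0, 0, 1, 0), 1.0, 0, 0.2, 1))
}

fast_config <- function(seed, chains = 2, iter = 1000, warmup = 1000) {
  mcmc_config(chains = chains, iter = iter, warmup = warmup, thin = 1,
              seed = seed)
}
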
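#' Ground-truth parameter set for the synthetic cohort generator
#'
#' The default truth is calibrated to the reported study conditions: the
#' high-risk-day and prior-week odds ratios (3.83 and 3.17), one-vs-rest
#' module odds ratios of 0.48 (coping with craving), 0.75 (cognitive
#' restructuring) and 0.80 (problem solving) with the remaining three
#' modules sharing an equal positive contrast so the per-draw contrasts
#' sum to zero, feedback module contrasts of +0.14 (cognitive
#' restructuring) and +0.09 (decision making), and missingness rates of
#' 0.30 for calendar days and 0.21 for ratings. Module offsets `a_m` are
#' stored on the random-effect scale, related to the one-vs-rest log
#' contrasts `d_m` by `a_m = (5/6) d_m` (so that
#' `d_m = a_m - mean(a_[-m])` recovers the target contrasts exactly).
#'
#' @param ... Named overrides of any default field.
#' @return A `simulation_truth` list.
#' @export
default_truth <- function(...) {
  rest <- -(log(0.48) + log(0.75) + log(0.80)) / 3   # exp(rest) = 1.514
  d_alc <- c(functional_analysis = rest, assertive_communication = rest,
             coping_with_craving = log(0.48),
             cognitive_restructuring = log(0.75),
             problem_solving = log(0.80), decision_making = rest)
  d_fb <- c(functional_analysis = -0.06, assertive_communication = -0.06,
            coping_with_craving = -0.05, cognitive_restructuring = 0.14,
            problem_solving = -0.06, decision_making = 0.09)
  truth <- list(
    # alcohol model (log-odds scale)
    module_log_odds_offsets = 5 / 6 * d_alc,
    module_high_risk_interaction = setNames(rep(0, 6), module_topics()),
    beta_high_risk = log(3.83),
    beta_prior_week = log(3.17),
    beta_time = -0.11,                   # per 28 days
    intercept = -3.9,
    beta_age = -0.05,                    # per 10 years
    beta_sex = 0.2,
    beta_asi = 1.0,
    beta_trial = 0,
    participant_sd = 1.0,
    # feedback model (0-4 rating scale)
    feedback_module_offsets = 5 / 6 * (d_fb - mean(d_fb)),
    feedback_item_offsets = c(effectiveness = 0.31, novelty = -0.24,
                              applicability = -0.08, navigation = 0.24,
                              enjoyability = 0.06, relatability = -0.29),
    feedback_intercept = 2.48,
    feedback_participant_sd = 0.5,
    residual_sd = 1.0,
    # cohort structure
    age_mean = 42.6, age_sd = 11.4,
    prop_male = 0.79,
    asi_mean = 0.35, asi_sd = 0.19,
    prop_trial2 = 0.53,
    module_skip_prob = 0.075,
    prop_weekday_completion = 0.83,
    # missingness (completely at random unless mar_missingness = TRUE)
    missing_calendar = 0.30,
    missing_rating = 0.21,
    missing_asi = 1 / 43,
    mar_missingness = FALSE,
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(truth))
  if (length(bad) > 0) {
    stop("unknown truth field(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  truth[names(over)] <- over
  structure(truth, class = "simulation_truth")
}

rtrunc_norm_min <- function(n, mean, sd, lower) {
  out <- rnorm(n, mean, sd)
  while (any(out < lower)) {
    k <- out < lower
    out[k] <- rnorm(sum(k), mean, sd)
  }
  out
}

#' Simulate a synthetic cohort with known ground truth
#'
#' Draws baseline covariates matching the configured moments (age
#' truncated at 18, ASI from a beta distribution, trial split), weekly
#' module completions (fixed topic order in trial 1, free order in trial
#' 2, with random skips and dates preferring weekdays), a daily drinking
#' calendar from the logistic model — the day's active module window,
#' high-risk status, the window's prior-week-use indicator, scaled time
#' and a participant random intercept drive the linear predictor — and
#' post-completion feedback ratings from the linear model, rounded and
#' clipped to the 0-4 grid. Missingness is then applied at the configured
#' rates, completely at random by default, or depending on observed
#' day/participant covariates when `mar_missingness` is set. The calendar
#' covers the 7 days before randomization so the first window's
#' prior-week indicator is derivable.
#'
#' @param truth A `simulation_truth` from [default_truth()].
#' @param n_participants Number of participants (>= 2).
#' @param n_weeks Treatment weeks over which modules are scheduled.
#' @param seed Integer seed; defaults to `truth$seed`.
#' @return List with `bundle` (a `cohort_bundle`) and `truth` (the truth
#'   record including the seed actually used).
#' @export
simulate_cohort <- function(truth = default_truth(), n_participants = 43,
                            n_weeks = 8, seed = truth$seed) {
  stopifnot(n_participants >= 2, n_weeks >= 1)
  set.seed(seed)
  truth$seed <- seed
  topics <- module_topics()
  items <- feedback_items()

  ids <- sprintf("P%03d", seq_len(n_participants))
  trial <- 1L + rbinom(n_participants, 1, truth$prop_trial2)
  rand_date <- as.Date(ifelse(
    trial == 2,
    as.Date("2019-08-01") + floor(runif(n_participants, 0, 1200)),
    as.Date("2014-03-01") + floor(runif(n_participants, 0, 960))),
    origin = "1970-01-01")
  age <- round(rtrunc_norm_min(n_participants, truth$age_mean, truth$age_sd, 18))
  sex <- ifelse(rbinom(n_participants, 1, truth$prop_male) == 1, "male", "female")
  ab_sum <- truth$asi_mean * (1 - truth$asi_mean) / truth$asi_sd^2 - 1
  asi <- round(rbeta(n_participants, truth$asi_mean * ab_sum,
                     (1 - truth$asi_mean) * ab_sum), 3)
  u <- rnorm(n_participants, 0, truth$participant_sd)
  u_fb <- rnorm(n_participants, 0, truth$feedback_participant_sd)

  baseline <- tibble::tibble(
    participant_id = ids, trial_id = as.numeric(trial), age_years = age,
    sex = sex, asi_alcohol = asi, randomization_date = rand_date)

  pick_completion_day <- function(week_start) {
    # anchor day within the week; ~83% of completions on Mon-Thu
    wd <- as.POSIXlt(week_start + 0:6)$wday
    weekday <- which(wd %in% 1:4)
    weekend <- which(!(wd %in% 1:4))
    pool <- if (runif(1) < truth$prop_weekday_completion) weekday else weekend
    week_start + (sample(c(pool, pool), 1) - 1)  # duplicated: sample() scalar guard
  }

  sim_one <- function(i) {
    done <- which(rbinom(6, 1, 1 - truth$module_skip_prob) == 1)
    if (length(done) == 0) done <- sample(1:6, 1)   # everyone starts something
    n_done <- length(done)
    ord <- if (trial[i] == 1) topics[sort(done)] else sample(topics[done])
    weeks <- sort(sample(seq_len(max(n_weeks, n_done)), n_done))
    cdates <- as.Date(vapply(
      weeks, function(w) pick_completion_day(rand_date[i] + 7 * (w - 1)),
      numeric(1)), origin = "1970-01-01")
    modules <- tibble::tibble(participant_id = ids[i], module_topic = ord,
                              completion_date = cdates)

    first_day <- rand_date[i] - 7
    last_day <- max(rand_date[i] + 7 * n_weeks - 1, max(cdates) + 6)
    dates <- seq(first_day, last_day, by = "day")
    nd <- length(dates)
    drank <- integer(nd)
    high <- as.integer(classify_risk_day(
      dates, default_holidays(unique(as.integer(format(dates, "%Y"))))) == "high")
    # active window per day: latest completion c with c <= d <= c + 6
    mod_off <- rep(0, nd)
    pw_vec <- rep(NA_real_, nd)
    window_of <- rep(NA_integer_, nd)
    for (k in seq_len(n_done)) {
      span <- dates >= cdates[k] & dates <= cdates[k] + 6
      if (k < n_done) span <- span & dates < cdates[k + 1]
      window_of[span] <- k
    }
    for (d in seq_len(nd)) {
      k <- window_of[d]
      if (!is.na(k)) {
        mod_off[d] <- truth$module_log_odds_offsets[[ord[k]]] +
          high[d] * truth$module_high_risk_interaction[[ord[k]]]
        wk <- dates >= cdates[k] - 7 & dates < cdates[k]
        pw <- as.numeric(any(drank[wk] == 1))
      } else {
        wk <- dates >= dates[d] - 7 & dates < dates[d]
        pw <- as.numeric(any(drank[wk] == 1))
      }
      pw_vec[d] <- pw
      lp <- truth$intercept +
        truth$beta_age * (age[i] - 21) / 10 +
        truth$beta_sex * (sex[i] == "male") +
        truth$beta_asi * asi[i] +
        truth$beta_trial * (trial[i] == 2) +
        truth$beta_time * as.numeric(dates[d] - rand_date[i]) / 28 +
        truth$beta_high_risk * high[d] +
        truth$beta_prior_week * pw +
        mod_off[d] + u[i]
      drank[d] <- rbinom(1, 1, plogis(lp))
    }
    calendar <- tibble::tibble(participant_id = ids[i], date = dates,
                               drank = as.numeric(drank))

    fb <- tidyr::expand_grid(module_topic = ord, item = items) |>
      dplyr::mutate(participant_id = ids[i]) |>
      dplyr::left_join(modules, by = c("participant_id", "module_topic"))
    mu <- truth$feedback_intercept +
      truth$feedback_module_offsets[fb$module_topic] +
      truth$feedback_item_offsets[fb$item] +
      truth$beta_time * 0 +               # feedback covariate effects are zero
      u_fb[i]
    fb$rating <- pmin(4, pmax(0, round(rnorm(nrow(fb), mu, truth$residual_sd))))
    list(modules = modules, calendar = calendar,
         feedback = fb[, c("participant_id", "module_topic", "item", "rating")])
  }

  parts <- lapply(seq_len(n_participants), sim_one)
  modules <- dplyr::bind_rows(lapply(parts, `[[`, "modules"))
  calendar <- dplyr::bind_rows(lapply(parts, `[[`, "calendar"))
  feedback <- dplyr::bind_rows(lapply(parts, `[[`, "feedback"))

  # missingness
  if (truth$mar_missingness) {
    # depends on observed structure: more gaps on weekends and later days
    hi <- classify_risk_day(calendar$date,
                            default_holidays(unique(as.integer(format(calendar$date, "%Y"))))) == "high"
    p_cal <- plogis(qlogis(truth$missing_calendar) + 0.5 * hi - 0.25)
    p_cal <- pmin(pmax(p_cal, 0), 1)
  } else {
    p_cal <- truth$missing_calendar
  }
  calendar$drank[runif(nrow(calendar)) < p_cal] <- NA_real_
  feedback$rating[runif(nrow(feedback)) < truth$missing_rating] <- NA_real_
  baseline$asi_alcohol[runif(n_participants) < truth$missing_asi] <- NA_real_

  bundle <- structure(list(baseline = baseline, calendar = calendar,
                           modules = modules, feedback = feedback),
                      class = "cohort_bundle")
  list(bundle = bundle, truth = truth)
}

#' One-vs-rest contrasts implied by a truth record
#'
#' Recovers the generative one-vs-rest contrast for each module from the
#' stored offsets: `d_m = a_m - mean(a_[-m])`.
#'
#' @param truth A `simulation_truth`.
#' @param model `"alcohol"` (returns odds ratios) or `"feedback"` (mean
#'   differences).
#' @return Named numeric vector of length 6.
#' @export
truth_one_vs_rest <- function(truth, model = c("alcohol", "feedback")) {
  model <- match.arg(model)
  a <- if (model == "alcohol") truth$module_log_odds_offsets else
    truth$feedback_module_offsets
  d <- vapply(seq_along(a), function(m) a[[m]] - mean(a[-m]), numeric(1))
  names(d) <- names(a)
  if (model == "alcohol") exp(d) else d
}
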
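test_that("risk classification covers weekends, holidays and eves", {
  # 2022-03-11 is a Friday; 2022-03-09 a Wednesday
  expect_equal(classify_risk_day(as.Date("2022-03-11")), "high")
  expect_equal(classify_risk_day(as.Date("2022-03-12")), "high")
  expect_equal(classify_risk_day(as.Date("2022-03-13")), "high")
  expect_equal(classify_risk_day(as.Date("2022-03-09")), "low")
  july4 <- as.Date("2023-07-04")                       # a Tuesday
  expect_equal(classify_risk_day(july4, july4), "high")
  expect_equal(classify_risk_day(as.Date("2023-07-03"), july4), "high")
  expect_equal(classify_risk_day(as.Date("2023-07-05"), july4), "low")
  # pure function of weekday and holiday set: same weekday, same answer
  mondays <- as.Date("2022-03-07") + 7 * (0:25)
  expect_true(all(classify_risk_day(mondays) == "low"))
})

test_that("default holiday calendar contains the drinking-associated days", {
  h <- default_holidays(2022)
  expect_true(all(as.Date(c("2022-01-01", "2022-05-30", "2022-07-04",
                            "2022-09-05", "2022-11-24", "2022-12-25",
                            "2022-12-31")) %in% h))
  expect_length(h, 7)
})

test_that("prior-week-use follows the exhaustive partial-observation rules", {
  mk_cal <- function(drank) {
    tibble::tibble(date = as.Date("2022-03-07") - 7:1, drank = drank)
  }
  cdate <- as.Date("2022-03-07")
  # exhaustive over number observed x any-drink x strictness
  for (n_obs in 0:7) {
    for (has_one in c(FALSE, TRUE)) {
      if (has_one && n_obs == 0) next
      drank <- rep(NA_real_, 7)
      if (n_obs > 0) drank[seq_len(n_obs)] <- 0
      if (has_one) drank[1] <- 1
      for (strict in c(FALSE, TRUE)) {
        got <- derive_prior_week_use(mk_cal(drank), cdate, strict)
        want <- if (has_one) 1 else if (n_obs == 7) 0 else
          if (n_obs >= 1 && !strict) 0 else NA_real_
        expect_identical(got, want,
                         label = sprintf("n_obs=%d one=%s strict=%s -> %s",
                                         n_obs, has_one, strict, got))
      }
    }
  }
  # days absent from the calendar count as missing
  expect_identical(derive_prior_week_use(
    tibble::tibble(date = as.Date(character()), drank = numeric()), cdate), NA_real_)
})

test_that("truncation attributes each day to at most one module window", {
  # module A at day 0 and B at day 4: A keeps offsets 0-3, B its full 7
  b <- read_toy()
  alc <- apply_eligibility(b, "alcohol")
  w <- build_module_windows(alc)
  fa <- w$days[[which(w$module_topic == "functional_analysis")]]
  ac <- w$days[[which(w$module_topic == "assertive_communication")]]
  expect_equal(sum(!is.na(fa$drank)), 4)
  expect_true(all(is.na(fa$drank[fa$offset >= 4])))
  expect_equal(sum(!is.na(ac$drank)), 6)        # one day absent from calendar
  expect_equal(nrow(fa), 7)
  expect_equal(nrow(ac), 7)
  attributed <- c(fa$date[!is.na(fa$drank)], ac$date[!is.na(ac$drank)])
  expect_false(any(duplicated(attributed)))
})

test_that("same-day completions exclude both windows", {
  b <- read_toy()
  w <- build_module_windows(b)
  t02 <- w[w$participant_id == "T02", ]
  expect_equal(nrow(t02), 2)
  expect_true(all(t02$excluded))
  expect_true(all(t02$exclusion_reason == "same-day completion"))
  expect_equal(sum(!w$excluded), 2)
})

test_that("every non-excluded window has 7 slots with >= 3 high-risk days", {
  # property over random anchor dates and random holiday sets
  set.seed(99)
  for (rep in 1:40) {
    anchor <- as.Date("2015-01-01") + sample.int(3000, 1)
    holidays <- as.Date("2015-01-01") + sample.int(3000, 3)
    risk <- classify_risk_day(anchor + 0:6, holidays)
    expect_gte(sum(risk == "high"), 3)
    # exactly 3 weekend days in any 7 consecutive days
    expect_equal(sum(classify_risk_day(anchor + 0:6) == "high"), 3)
  }
})

test_that("windowing validates inputs", {
  b <- read_toy()
  early <- b
  early$modules$completion_date[1] <- as.Date("2022-03-01")
  expect_error(build_module_windows(early), "before randomization")
  orphan <- b
  orphan$baseline <- orphan$baseline[-1, ]
  expect_error(build_module_windows(orphan), "not baseline")
  dup <- b
  dup$modules <- rbind(dup$modules, tibble::tibble(
    participant_id = "T01", module_topic = "functional_analysis",
    completion_date = as.Date("2022-03-20")))
  expect_warning(w <- build_module_windows(dup), "repeated module topic")
  expect_equal(sum(w$participant_id == "T01" &
                     w$module_topic == "functional_analysis"), 1)
  expect_equal(w$completion_date[w$participant_id == "T01" &
                                   w$module_topic == "functional_analysis"],
               as.Date("2022-03-07"))
})

test_that("day-level assembly yields 7 rows per window with covariates", {
  b <- read_toy()
  alc <- apply_eligibility(b, "alcohol")
  w <- build_module_windows(alc)
  rows <- assemble_alcohol_rows(w, alc$baseline)
  expect_equal(nrow(rows), 14)                   # 2 windows x 7 slots
  expect_equal(sum(!is.na(rows$drank)), 10)      # 3 truncated + 1 absent
  fa <- rows[rows$module_topic == "functional_analysis", ]
  expect_equal(sum(!is.na(fa$drank)), 4)         # Mon-Thu before truncation
  expect_equal(fa$days_since_randomization, 0:6)
  expect_equal(fa$age_scaled, rep(2.4, 7))
  expect_equal(fa$prior_week_use, rep(1, 7))
  expect_equal(rows$time_scaled, rows$days_since_randomization / 28)
  # participant in windows but absent from baseline is a hard error
  expect_error(assemble_alcohol_rows(w, alc$baseline[0, ]), "missing from baseline")
})

test_that("feedback assembly builds the full participant x module x item grid", {
  b <- read_toy()
  fb <- apply_eligibility(b, "feedback")
  rows <- assemble_feedback_rows(fb)
  expect_equal(nrow(rows), 2 * 6 * 6)
  expect_equal(sum(!is.na(rows$rating)), 7)
  # time is the completion day for completed modules, missing otherwise
  t01_fa <- rows[rows$participant_id == "T01" &
                   rows$module_topic == "functional_analysis", ]
  expect_equal(unique(t01_fa$days_since_randomization), 0L)
  t01_cc <- rows[rows$participant_id == "T01" &
                   rows$module_topic == "coping_with_craving", ]
  expect_true(all(is.na(t01_cc$time_scaled)))
})

test_that("window audit reports hand-tallied counts", {
  b <- read_toy()
  audit_all <- window_audit(build_module_windows(b))
  expect_equal(audit_all$n_windows, 4)
  expect_equal(audit_all$n_excluded_same_day, 2)
  alc <- apply_eligibility(b, "alcohol")
  audit <- window_audit(build_module_windows(alc))
  expect_equal(audit$n_windows, 2)
  expect_equal(audit$n_truncated, 1)
  expect_equal(audit$n_day_slots, 14)
  expect_equal(audit$n_observed_days, 10)
  expect_equal(audit$n_missing_days, 4)
})

test_that("covariate rescaling matches the stated conventions", {
  sc <- rescale_covariates(c(21, 41, NA), c(28, 0, 56))
  expect_equal(sc$age_scaled, c(0, 2, NA))
  expect_equal(sc$time_scaled, c(1, 0, 2))
})
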
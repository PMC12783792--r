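#' Default U.S. holiday calendar for high-risk drinking days
#'
#' Drinking-associated holidays: New Year's Day, Memorial Day (last Monday
#' of May), Independence Day, Labor Day (first Monday of September),
#' Thanksgiving (fourth Thursday of November), Christmas Day and New
#' Year's Eve. The day *before* each listed holiday is classified
#' high-risk by [classify_risk_day()], so eves need not be listed
#' separately (New Year's Eve is listed because Jan 1 of the *next* year
#' may fall outside `years`).
#'
#' @param years Integer vector of calendar years to cover.
#' @return A `Date` vector.
#' @export
default_holidays <- function(years) {
  nth_weekday <- function(year, month, wday, n) {
    # wday: 0 = Sunday ... 6 = Saturday; n > 0 from start, n < 0 from end
    first <- as.Date(sprintf("%d-%02d-01", year, month))
    last <- seq(first, by = "month", length.out = 2)[2] - 1
    days <- seq(first, last, by = "day")
    hits <- days[as.POSIXlt(days)$wday == wday]
    if (n > 0) hits[n] else hits[length(hits) + 1 + n]
  }
  out <- lapply(years, function(y) {
    c(as.Date(sprintf("%d-01-01", y)),
      nth_weekday(y, 5, 1, -1),           # Memorial Day
      as.Date(sprintf("%d-07-04", y)),
      nth_weekday(y, 9, 1, 1),            # Labor Day
      nth_weekday(y, 11, 4, 4),           # Thanksgiving
      as.Date(sprintf("%d-12-25", y)),
      as.Date(sprintf("%d-12-31", y)))
  })
  sort(unique(do.call(c, out)))
}

#' Classify a calendar date as a high- or low-risk drinking day
#'
#' A day is high-risk when it falls on a weekend (Friday through Sunday),
#' on a configured holiday, or on the day immediately before a configured
#' holiday. All other days are low-risk.
#'
#' @param date A `Date` vector.
#' @param holidays A `Date` vector of holidays (see [default_holidays()]).
#' @return Character vector, `"high"` or `"low"`.
#' @export
classify_risk_day <- function(date, holidays = as.Date(character())) {
  wday <- as.POSIXlt(date)$wday           # 0 = Sunday, 5 = Friday, 6 = Saturday
  high <- wday %in% c(5L, 6L, 0L) | date %in% holidays | (date + 1) %in% holidays
  ifelse(high, "high", "low")
}

#' Indicator of any drinking in the week before a module completion
#'
#' Inspects the 7 calendar days strictly before `completion_date`. Returns
#' 1 if any of them is an observed drinking day. With the default
#' (`strict = FALSE`) rule, returns 0 when at least one of the 7 days is
#' observed and none records drinking; under `strict = TRUE`, a 0 is only
#' returned when all 7 days are observed abstinent, otherwise `NA`. Days
#' absent from the calendar count as missing.
#'
#' @param calendar Calendar tibble for one participant (`date`, `drank`).
#' @param completion_date A `Date` scalar.
#' @param strict Logical; strictness of the partial-observation rule.
#' @return 0, 1 or `NA`.
#' @export
derive_prior_week_use <- function(calendar, completion_date, strict = FALSE) {
  week <- seq(completion_date - 7, completion_date - 1, by = "day")
  drank <- calendar$drank[match(week, calendar$date)]
  if (any(drank == 1, na.rm = TRUE)) return(1)
  n_obs <- sum(!is.na(drank))
  if (n_obs == 7 || (!strict && n_obs >= 1)) return(0)
  NA_real_
}

#' Build module-anchored 7-day windows from completion logs and calendars
#'
#' Each completion anchors a window of its completion day plus the six
#' following days. Days on or after the next module's completion date are
#' not attributed (their outcome is set missing), so no calendar day feeds
#' more than one window. When two or more modules share a completion date,
#' all of their windows are excluded outright. Repeated topics keep the
#' first completion with a warning. Every non-excluded window carries
#' exactly 7 day slots; slots absent from the calendar are missing.
#'
#' @param bundle A `cohort_bundle` (needs `modules`, `calendar`, `baseline`).
#' @param holidays `Date` vector used for risk classification.
#' @param strict_prior_week Passed to [derive_prior_week_use()].
#' @return Tibble with one row per window: `participant_id`,
#'   `module_topic`, `completion_date`, `excluded`, `exclusion_reason`,
#'   `prior_week_use`, and a `days` list-column of 7-row tibbles (`date`,
#'   `offset`, `drank`, `risk`, `days_since_randomization`).
#' @export
build_module_windows <- function(bundle, holidays = NULL,
                                 strict_prior_week = FALSE) {
  if (is.null(holidays)) {
    span <- range(c(bundle$modules$completion_date, bundle$calendar$date))
    holidays <- default_holidays(seq(as.integer(format(span[1], "%Y")),
                                     as.integer(format(span[2], "%Y")) + 1))
  }
  rand <- setNames(bundle$baseline$randomization_date,
                   bundle$baseline$participant_id)
  n_dropped <- nrow(bundle$modules) -
    nrow(dplyr::distinct(bundle$modules, .data$participant_id, .data$module_topic))
  if (n_dropped > 0) {
    warning(sprintf("%d repeated module topic(s) dropped (first completion kept)",
                    n_dropped), call. = FALSE)
  }
  plan <- attribution_plan(bundle$modules)
  unknown <- setdiff(plan$participant_id, names(rand))
  if (length(unknown) > 0) {
    stop(sprintf("participant(s) in completion log but not baseline: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  early <- plan$completion_date < rand[plan$participant_id]
  if (any(early)) {
    stop(sprintf("completion before randomization for participant(s): %s",
                 paste(unique(plan$participant_id[early]), collapse = ", ")),
         call. = FALSE)
  }

  one_window <- function(pid, topic, cdate, same_day, last_attr) {
    if (same_day) {
      return(tibble::tibble(
        participant_id = pid, module_topic = topic, completion_date = cdate,
        excluded = TRUE, exclusion_reason = "same-day completion",
        n_attributed = 0L, prior_week_use = NA_real_, days = list(NULL)))
    }
    cal <- bundle$calendar[bundle$calendar$participant_id == pid, ]
    dates <- cdate + 0:6
    drank <- cal$drank[match(dates, cal$date)]
    drank[dates > last_attr] <- NA_real_   # truncation: next module owns these
    days <- tibble::tibble(
      date = dates, offset = 0:6, drank = drank,
      risk = classify_risk_day(dates, holidays),
      days_since_randomization = as.integer(dates - rand[[pid]]))
    tibble::tibble(
      participant_id = pid, module_topic = topic, completion_date = cdate,
      excluded = FALSE, exclusion_reason = NA_character_,
      n_attributed = sum(dates <= last_attr),
      prior_week_use = derive_prior_week_use(cal, cdate, strict_prior_week),
      days = list(days))
  }
  out <- purrr::pmap(
    list(plan$participant_id, plan$module_topic, plan$completion_date,
         plan$same_day, plan$last_attr),
    one_window)
  dplyr::bind_rows(out)
}

#' Assemble the day-level analysis table for the drinking model
#'
#' Unnests the non-excluded windows into one row per window day, joins
#' participant baseline covariates, and applies the model's covariate
#' rescaling. Rows with a missing outcome are retained: the sampler
#' imputes them. Fails if a windowed participant has no baseline row.
#'
#' @param windows Output of [build_module_windows()].
#' @param baseline Baseline tibble of the same bundle.
#' @return Tibble with one row per attributed day slot, carrying `drank`,
#'   `high_risk`, `prior_week_use`, scaled covariates and identifiers.
#' @export
assemble_alcohol_rows <- function(windows, baseline) {
  w <- dplyr::filter(windows, !.data$excluded)
  missing_bl <- setdiff(w$participant_id, baseline$participant_id)
  if (length(missing_bl) > 0) {
    stop(sprintf("participant(s) missing from baseline: %s",
                 paste(missing_bl, collapse = ", ")), call. = FALSE)
  }
  rows <- w |>
    dplyr::select("participant_id", "module_topic", "completion_date",
                  "prior_week_use", "days") |>
    tidyr::unnest("days") |>
    dplyr::left_join(baseline, by = "participant_id")
  sc <- rescale_covariates(age_years = rows$age_years,
                           days_since_randomization = rows$days_since_randomization)
  rows |>
    dplyr::mutate(
      high_risk = as.integer(.data$risk == "high"),
      age_scaled = sc$age_scaled,
      time_scaled = sc$time_scaled,
      sex_male = as.integer(.data$sex == "male"),
      trial2 = as.integer(.data$trial_id == 2)) |>
    dplyr::select("participant_id", "module_topic", "completion_date", "date",
                  "offset", "drank", "high_risk", "prior_week_use",
                  "days_since_randomization", "time_scaled", "age_years",
                  "age_scaled", "sex_male", "asi_alcohol", "trial2")
}

#' Assemble the item-level analysis table for the feedback model
#'
#' Builds the complete participant x module x item grid so that every
#' participant has a potential rating for every item of every module;
#' ratings absent from the feedback table are missing and imputed by the
#' sampler. `days_since_randomization` is the module's completion day for
#' completed modules and missing otherwise (imputed half-normal).
#'
#' @param bundle A `cohort_bundle`.
#' @return Tibble with one row per (participant, module, item) cell.
#' @export
assemble_feedback_rows <- function(bundle) {
  grid <- tidyr::expand_grid(
    participant_id = bundle$baseline$participant_id,
    module_topic = module_topics(),
    item = feedback_items())
  comp <- attribution_plan(bundle$modules) |>
    dplyr::select("participant_id", "module_topic", "completion_date")
  rows <- grid |>
    dplyr::left_join(bundle$feedback,
                     by = c("participant_id", "module_topic", "item")) |>
    dplyr::left_join(comp, by = c("participant_id", "module_topic")) |>
    dplyr::left_join(bundle$baseline, by = "participant_id") |>
    dplyr::mutate(days_since_randomization =
                    as.integer(.data$completion_date - .data$randomization_date))
  sc <- rescale_covariates(age_years = rows$age_years,
                           days_since_randomization = rows$days_since_randomization)
  rows |>
    dplyr::mutate(
      age_scaled = sc$age_scaled,
      time_scaled = sc$time_scaled,
      sex_male = as.integer(.data$sex == "male"),
      trial2 = as.integer(.data$trial_id == 2)) |>
    dplyr::select("participant_id", "module_topic", "item", "rating",
                  "days_since_randomization", "time_scaled", "age_years",
                  "age_scaled", "sex_male", "asi_alcohol", "trial2")
}

#' Audit counts for a set of module windows
#'
#' @param windows Output of [build_module_windows()].
#' @return List of counts: windows built, excluded, truncated, attributed
#'   day slots and observed outcomes.
#' @export
window_audit <- function(windows) {
  kept <- dplyr::filter(windows, !.data$excluded)
  day_rows <- if (nrow(kept) > 0) dplyr::bind_rows(kept$days) else
    tibble::tibble(drank = numeric())
  list(
    n_windows = nrow(windows),
    n_excluded_same_day = sum(windows$excluded),
    n_truncated = sum(kept$n_attributed < 7L),
    n_day_slots = nrow(day_rows),
    n_observed_days = sum(!is.na(day_rows$drank)),
    n_missing_days = sum(is.na(day_rows$drank)))
}
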
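#' Default column mapping for the four cohort tables
#'
#' Column names loosely follow the CDISC ADaM conventions (`USUBJID`,
#' `STUDYID`, date columns ending in `DT`). Override any entry to read
#' files with different headers.
#'
#' @return Nested named list with one entry per table (`baseline`,
#'   `calendar`, `modules`, `feedback`) mapping canonical field names to
#'   on-disk column names.
#' @export
default_col_map <- function() {
  list(
    baseline = list(participant_id = "USUBJID", trial_id = "STUDYID",
                    age_years = "AGE", sex = "SEX", asi_alcohol = "ASIALC",
                    randomization_date = "RANDDT"),
    calendar = list(participant_id = "USUBJID", date = "ADT", drank = "DRINK"),
    modules  = list(participant_id = "USUBJID", module_topic = "MODULE",
                    completion_date = "COMPDT"),
    feedback = list(participant_id = "USUBJID", module_topic = "MODULE",
                    item = "ITEM", rating = "RATING")
  )
}

stop_rows <- function(msg, rows, file) {
  stop(sprintf("%s [file: %s; row(s): %s]", msg, file,
               paste(utils::head(rows, 10L), collapse = ", ")),
       call. = FALSE)
}

parse_iso_date <- function(x, col, file) {
  out <- as.Date(rep(NA_real_, length(x)), origin = "1970-01-01")
  nonblank <- !is.na(x) & x != ""
  parsed <- as.Date(x[nonblank], format = "%Y-%m-%d")
  bad <- which(nonblank)[is.na(parsed) | format(parsed, "%Y-%m-%d") != x[nonblank]]
  if (length(bad) > 0) {
    stop_rows(sprintf("malformed ISO-8601 date in column '%s'", col), bad, file)
  }
  out[nonblank] <- parsed
  out
}

read_mapped_csv <- function(path, map) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  missing_cols <- setdiff(unlist(map), names(raw))
  if (length(missing_cols) > 0) {
    stop(sprintf("file '%s' lacks expected column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  out <- raw[, unlist(map), drop = FALSE]
  names(out) <- names(map)
  out
}

num_or_na <- function(x, col, file, lo = -Inf, hi = Inf, integer_only = FALSE) {
  out <- rep(NA_real_, length(x))
  nonblank <- !is.na(x) & x != ""
  suppressWarnings(v <- as.numeric(x[nonblank]))
  bad <- which(nonblank)[is.na(v) | v < lo | v > hi |
                           (integer_only & !is.na(v) & v != round(v))]
  if (length(bad) > 0) {
    stop_rows(sprintf("invalid value in column '%s' (expected %s in [%s, %s])",
                      col, if (integer_only) "integer" else "number", lo, hi),
              bad, file)
  }
  out[nonblank] <- v
  out
}

check_unique <- function(keys, what, file) {
  dup <- duplicated(keys)
  if (any(dup)) {
    stop_rows(sprintf("duplicate %s key: %s", what, keys[which(dup)[1]]),
              which(dup), file)
  }
}

#' Read and validate the four cohort tables
#'
#' Reads the participant baseline table, the daily alcohol calendar, the
#' module-completion log and the feedback-form ratings from comma-delimited
#' files with ISO-8601 dates and empty fields for missing values. Every
#' type invariant is checked on load and violations are hard errors naming
#' the offending rows.
#'
#' @param baseline,calendar,modules,feedback Paths to the four CSV files.
#' @param col_map Column mapping as returned by [default_col_map()].
#' @param summary_path Optional path; when given, a JSON sidecar with row
#'   counts and missingness fractions per table is written on load.
#' @return A `cohort_bundle`: a list of four validated tibbles
#'   (`baseline`, `calendar`, `modules`, `feedback`).
#' @export
read_cohort <- function(baseline, calendar, modules, feedback,
                        col_map = default_col_map(), summary_path = NULL) {
  bl <- read_mapped_csv(baseline, col_map$baseline)
  bl$trial_id <- num_or_na(bl$trial_id, "trial_id", baseline, 1, 2, TRUE)
  if (anyNA(bl$trial_id)) {
    stop_rows("trial_id must be 1 or 2", which(is.na(bl$trial_id)), baseline)
  }
  bl$age_years <- num_or_na(bl$age_years, "age_years", baseline, 18, 120)
  bad_sex <- which(!(bl$sex %in% c("M", "F", "")))
  if (length(bad_sex) > 0) stop_rows("sex must be 'M', 'F' or blank", bad_sex, baseline)
  bl$sex <- ifelse(bl$sex == "", NA_character_,
                   ifelse(bl$sex == "M", "male", "female"))
  bl$asi_alcohol <- num_or_na(bl$asi_alcohol, "asi_alcohol", baseline, 0, 1)
  bl$randomization_date <- parse_iso_date(bl$randomization_date,
                                          "randomization_date", baseline)
  if (anyNA(bl$randomization_date)) {
    stop_rows("randomization_date is required", which(is.na(bl$randomization_date)),
              baseline)
  }
  check_unique(bl$participant_id, "participant_id", baseline)

  cal <- read_mapped_csv(calendar, col_map$calendar)
  cal$date <- parse_iso_date(cal$date, "date", calendar)
  if (anyNA(cal$date)) stop_rows("date is required", which(is.na(cal$date)), calendar)
  cal$drank <- num_or_na(cal$drank, "drank", calendar, 0, 1, TRUE)
  check_unique(paste(cal$participant_id, cal$date), "(participant_id, date)",
               calendar)

  md <- read_mapped_csv(modules, col_map$modules)
  bad_topic <- which(!(md$module_topic %in% module_topics()))
  if (length(bad_topic) > 0) {
    stop_rows(sprintf("unknown module_topic '%s'", md$module_topic[bad_topic[1]]),
              bad_topic, modules)
  }
  md$completion_date <- parse_iso_date(md$completion_date, "completion_date", modules)
  if (anyNA(md$completion_date)) {
    stop_rows("completion_date is required", which(is.na(md$completion_date)), modules)
  }
  check_unique(paste(md$participant_id, md$module_topic),
               "(participant_id, module_topic)", modules)

  fb <- read_mapped_csv(feedback, col_map$feedback)
  bad_topic <- which(!(fb$module_topic %in% module_topics()))
  if (length(bad_topic) > 0) {
    stop_rows(sprintf("unknown module_topic '%s'", fb$module_topic[bad_topic[1]]),
              bad_topic, feedback)
  }
  bad_item <- which(!(fb$item %in% feedback_items()))
  if (length(bad_item) > 0) {
    stop_rows(sprintf("unknown item '%s'", fb$item[bad_item[1]]), bad_item, feedback)
  }
  fb$rating <- num_or_na(fb$rating, "rating", feedback, 0, 4, TRUE)
  check_unique(paste(fb$participant_id, fb$module_topic, fb$item),
               "(participant_id, module_topic, item)", feedback)

  bundle <- structure(
    list(baseline = tibble::as_tibble(bl), calendar = tibble::as_tibble(cal),
         modules = tibble::as_tibble(md), feedback = tibble::as_tibble(fb)),
    class = "cohort_bundle")

  if (!is.null(summary_path)) {
    jsonlite::write_json(cohort_summary(bundle), summary_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  bundle
}

#' Summarise a cohort bundle
#'
#' @param bundle A `cohort_bundle`.
#' @return List with per-table row counts and missingness fractions.
#' @export
cohort_summary <- function(bundle) {
  list(
    n_participants = nrow(bundle$baseline),
    n_calendar_days = nrow(bundle$calendar),
    n_module_completions = nrow(bundle$modules),
    n_feedback_ratings = nrow(bundle$feedback),
    missing_frac = list(
      drank = mean(is.na(bundle$calendar$drank)),
      rating = mean(is.na(bundle$feedback$rating)),
      asi_alcohol = mean(is.na(bundle$baseline$asi_alcohol)),
      age_years = mean(is.na(bundle$baseline$age_years))
    )
  )
}

#' Write a cohort bundle back to the four CSV files
#'
#' Inverse of [read_cohort()] under the same dialect: comma-delimited,
#' ISO-8601 dates, empty fields for missing values. Writing then re-reading
#' then re-writing is byte-stable.
#'
#' @inheritParams read_cohort
#' @param bundle A `cohort_bundle`.
#' @export
write_cohort <- function(bundle, baseline, calendar, modules, feedback,
                         col_map = default_col_map()) {
  fmt_num <- function(x) ifelse(is.na(x), "", format(x, trim = TRUE, scientific = FALSE))
  bl <- bundle$baseline
  out <- tibble::tibble(
    a = bl$participant_id, b = fmt_num(bl$trial_id), c = fmt_num(bl$age_years),
    d = ifelse(is.na(bl$sex), "", ifelse(bl$sex == "male", "M", "F")),
    e = fmt_num(bl$asi_alcohol), f = format(bl$randomization_date, "%Y-%m-%d"))
  names(out) <- unlist(col_map$baseline)
  readr::write_csv(out, baseline, na = "", progress = FALSE)

  cal <- bundle$calendar
  out <- tibble::tibble(a = cal$participant_id, b = format(cal$date, "%Y-%m-%d"),
                        c = fmt_num(cal$drank))
  names(out) <- unlist(col_map$calendar)
  readr::write_csv(out, calendar, na = "", progress = FALSE)

  md <- bundle$modules
  out <- tibble::tibble(a = md$participant_id, b = md$module_topic,
                        c = format(md$completion_date, "%Y-%m-%d"))
  names(out) <- unlist(col_map$modules)
  readr::write_csv(out, modules, na = "", progress = FALSE)

  fb <- bundle$feedback
  out <- tibble::tibble(a = fb$participant_id, b = fb$module_topic, c = fb$item,
                        d = fmt_num(fb$rating))
  names(out) <- unlist(col_map$feedback)
  readr::write_csv(out, feedback, na = "", progress = FALSE)
  invisible(bundle)
}

# Attribution of calendar days to module windows, shared by eligibility
# filtering and window construction. For each participant: drop repeated
# topics (keep first completion), mark same-date completions excluded, and
# give each remaining completion the days from its date up to
# min(date + 6, next completion date - 1).
attribution_plan <- function(modules) {
  modules |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::arrange(.data$completion_date, .by_group = TRUE) |>
    dplyr::filter(!duplicated(.data$module_topic)) |>
    dplyr::mutate(
      same_day = duplicated(.data$completion_date) |
        duplicated(.data$completion_date, fromLast = TRUE),
      next_date = dplyr::lead(.data$completion_date),
      last_attr = pmin(.data$completion_date + 6,
                       dplyr::coalesce(.data$next_date - 1,
                                       .data$completion_date + 6))
    ) |>
    dplyr::ungroup()
}

n_attributed_observed <- function(bundle) {
  plan <- attribution_plan(bundle$modules) |> dplyr::filter(!.data$same_day)
  if (nrow(plan) == 0) {
    return(tibble::tibble(participant_id = character(), n_obs = integer()))
  }
  days <- plan |>
    dplyr::rowwise() |>
    dplyr::mutate(date = list(seq(.data$completion_date, .data$last_attr, by = "day"))) |>
    dplyr::ungroup() |>
    tidyr::unnest("date") |>
    dplyr::select("participant_id", "date")
  days |>
    dplyr::left_join(bundle$calendar, by = c("participant_id", "date")) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(n_obs = sum(!is.na(.data$drank)), .groups = "drop")
}

keep_participants <- function(bundle, ids) {
  structure(list(
    baseline = dplyr::filter(bundle$baseline, .data$participant_id %in% ids),
    calendar = dplyr::filter(bundle$calendar, .data$participant_id %in% ids),
    modules  = dplyr::filter(bundle$modules, .data$participant_id %in% ids),
    feedback = dplyr::filter(bundle$feedback, .data$participant_id %in% ids)
  ), class = "cohort_bundle")
}

#' Filter a cohort to the analyzable participants for one outcome
#'
#' Retains participants who completed at least one core module and have at
#' least one non-missing observation of the named outcome: an observed,
#' module-attributed calendar day for `"alcohol"`, or one non-missing
#' feedback rating for `"feedback"`. Idempotent and monotone.
#'
#' @param bundle A `cohort_bundle`.
#' @param outcome `"alcohol"` or `"feedback"`.
#' @return The filtered `cohort_bundle`.
#' @export
apply_eligibility <- function(bundle, outcome = c("alcohol", "feedback")) {
  outcome <- match.arg(outcome)
  has_module <- unique(bundle$modules$participant_id)
  if (outcome == "alcohol") {
    obs <- n_attributed_observed(bundle)
    has_obs <- obs$participant_id[obs$n_obs > 0]
  } else {
    has_obs <- unique(bundle$feedback$participant_id[!is.na(bundle$feedback$rating)])
  }
  keep_participants(bundle, intersect(has_module, has_obs))
}

#' Restrict a cohort to participants who completed all six core modules
#'
#' Sensitivity-analysis filter: keeps only participants whose completion
#' log contains every one of the six core topics.
#'
#' @param bundle A `cohort_bundle`.
#' @return The filtered `cohort_bundle`.
#' @export
completer_filter <- function(bundle) {
  counts <- bundle$modules |>
    dplyr::distinct(.data$participant_id, .data$module_topic) |>
    dplyr::count(.data$participant_id)
  keep_participants(bundle, counts$participant_id[counts$n == 6L])
}

#' @export
print.cohort_bundle <- function(x, ...) {
  s <- cohort_summary(x)
  cat(sprintf(paste0(
    "<cohort_bundle> %d participants | %d calendar days (%.0f%% missing) | ",
    "%d completions | %d ratings (%.0f%% missing)\n"),
    s$n_participants, s$n_calendar_days, 100 * s$missing_frac$drank,
    s$n_module_completions, s$n_feedback_ratings, 100 * s$missing_frac$rating))
  invisible(x)
}
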
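#' Clean self-reported bed and wake times
#'
#' Applies the AM/PM-misreport cleaning rules to a sleep survey table:
#' bedtimes reported between 08:00 and 14:00 (inclusive) and wake times
#' reported between 18:00 and 24:00 are set to missing, separately for the
#' weekday and weekend fields. Midnight itself (00:00) is a valid wake time
#' and is retained. All other values pass through unchanged; cleaning is
#' total and never errors.
#'
#' @param survey data.frame with columns `participant_id`, `weekday_bed`,
#'   `weekday_wake`, `weekend_bed`, `weekend_wake` (minutes since midnight)
#'   and `completion_date`.
#' @param bed_window,wake_window numeric length-2 vectors, minutes since
#'   midnight, giving the implausible reporting windows. Bedtimes are dropped
#'   on the closed interval; wake times on `[lo, hi)` so that a configured
#'   upper bound of 1440 retains 00:00.
#' @return the survey with implausible values set to `NA`; the number of
#'   values removed by each rule is attached as attribute `"drop_counts"`.
#' @export
clean_survey <- function(survey,
                         bed_window = c(8 * 60, 14 * 60),
                         wake_window = c(18 * 60, 24 * 60)) {
  drop <- c(weekday_bed = 0L, weekend_bed = 0L, weekday_wake = 0L, weekend_wake = 0L)
  for (col in c("weekday_bed", "weekend_bed")) {
    bad <- !is.na(survey[[col]]) &
      survey[[col]] >= bed_window[1] & survey[[col]] <= bed_window[2]
    survey[[col]][bad] <- NA_real_
    drop[col] <- sum(bad)
  }
  for (col in c("weekday_wake", "weekend_wake")) {
    bad <- !is.na(survey[[col]]) &
      survey[[col]] >= wake_window[1] & survey[[col]] < wake_window[2]
    survey[[col]][bad] <- NA_real_
    drop[col] <- sum(bad)
  }
  attr(survey, "drop_counts") <- drop
  survey
}

#' Weekly weighted time in bed
#'
#' Weighted average of weekday and weekend time in bed with 5/7 and 2/7
#' weights. Missing if either input is missing.
#'
#' @param tib_weekday,tib_weekend time in bed, hours.
#' @return hours.
#' @examples
#' weighted_time_in_bed(8, 9) # 58/7
#' @export
weighted_time_in_bed <- function(tib_weekday, tib_weekend) {
  (5 * tib_weekday + 2 * tib_weekend) / 7
}

#' Social jetlag
#'
#' Circular absolute difference between the weekend and weekday sleep
#' midpoints, in hours (capped at 12 by the circular metric). "Absolute
#' difference" is read on the 24-hour circle so that midpoints straddling
#' midnight (e.g. 23:00 vs 01:00) give 2 h, not 22 h.
#'
#' @param midpoint_weekday,midpoint_weekend clock times, minutes since
#'   midnight.
#' @return hours in `[0, 12]`.
#' @export
social_jetlag <- function(midpoint_weekday, midpoint_weekend) {
  circular_hours_diff(midpoint_weekend, midpoint_weekday)
}

#' Derive the four continuous sleep traits from a cleaned survey
#'
#' Computes, per participant: weekday and weekend time in bed (implausible
#' values < 3 h or > 18 h set missing), the 5/7-2/7 weighted weekly time in
#' bed, time-in-bed irregularity (absolute weekday-weekend difference),
#' weekday and weekend sleep midpoints, and social jetlag. Each trait is
#' computed only when all of its contributing times are present; no
#' imputation is performed.
#'
#' @param survey a (cleaned) survey data.frame; see [clean_survey()].
#' @return data.frame with one row per participant: `participant_id`,
#'   `tib_weekday`, `tib_weekend`, `tib_weighted`, `tib_irregularity` (hours),
#'   `midpoint_weekday`, `midpoint_weekend` (minutes since midnight),
#'   `social_jetlag` (hours).
#' @export
derive_sleep_traits <- function(survey) {
  tib_wd <- time_in_bed(survey$weekday_bed, survey$weekday_wake)
  tib_we <- time_in_bed(survey$weekend_bed, survey$weekend_wake)
  mid_wd <- ifelse(is.na(survey$weekday_bed) | is.na(survey$weekday_wake), NA_real_,
                   sleep_midpoint(survey$weekday_bed, survey$weekday_wake))
  mid_we <- ifelse(is.na(survey$weekend_bed) | is.na(survey$weekend_wake), NA_real_,
                   sleep_midpoint(survey$weekend_bed, survey$weekend_wake))
  data.frame(
    participant_id = survey$participant_id,
    tib_weekday = tib_wd,
    tib_weekend = tib_we,
    tib_weighted = weighted_time_in_bed(tib_wd, tib_we),
    tib_irregularity = abs(tib_wd - tib_we),
    midpoint_weekday = mid_wd,
    midpoint_weekend = mid_we,
    social_jetlag = social_jetlag(mid_wd, mid_we),
    stringsAsFactors = FALSE
  )
}

#' Names of the eight sleep lifestyle index components, in reporting order
#'
#' @return character vector of length 8.
#' @export
index_components <- function() {
  c("adequate_tib", "regular_tib", "healthy_midpoint", "low_social_jetlag",
    "no_sleep_medication", "no_insomnia_disorder", "no_breathing_disorder",
    "no_other_sleep_disorder")
}

#' Score the eight sleep lifestyle components
#'
#' Converts derived traits and EHR sleep flags into the eight tri-state
#' components of the sleep lifestyle index, coded 1 (favorable), 0
#' (unfavorable) or `NA` (missing). Cut-points follow their printed symbols:
#' adequate time in bed is the closed interval `[7, 9]` h on the weighted
#' weekly value; regular time in bed requires irregularity strictly below
#' 1 h; a healthy weekend sleep midpoint lies in the closed window
#' 02:00-04:00; low social jetlag is strictly below 2 h. The four EHR
#' components are favorable when the corresponding disorder flag is absent
#' (or, for medication, false), unfavorable when present, and missing when
#' the flag is missing (exactly one qualifying code).
#'
#' @param traits data.frame from [derive_sleep_traits()].
#' @param flags data.frame from [derive_sleep_flags()]; participants absent
#'   from `flags` get all-favorable EHR components only if `flags` is `NULL`
#'   for none -- both tables are merged on `participant_id` and participants
#'   missing from `flags` get `NA` EHR components.
#' @return data.frame `participant_id` plus the eight component columns.
#' @export
score_components <- function(traits, flags) {
  df <- merge(traits, flags, by = "participant_id", all.x = TRUE, sort = TRUE)
  tri <- function(favorable) ifelse(is.na(favorable), NA_real_, as.numeric(favorable))
  mid_lo <- 2 * 60; mid_hi <- 4 * 60
  out <- data.frame(
    participant_id = df$participant_id,
    adequate_tib = tri(df$tib_weighted >= 7 & df$tib_weighted <= 9),
    regular_tib = tri(df$tib_irregularity < 1),
    healthy_midpoint = tri(df$midpoint_weekend >= mid_lo & df$midpoint_weekend <= mid_hi),
    low_social_jetlag = tri(df$social_jetlag < 2),
    no_sleep_medication = tri(!df$sleep_medication),
    no_insomnia_disorder = flag_to_component(df$insomnia_disorder),
    no_breathing_disorder = flag_to_component(df$breathing_disorder),
    no_other_sleep_disorder = flag_to_component(df$other_sleep_disorder),
    stringsAsFactors = FALSE
  )
  out
}

# tri-state disorder flag {"present","absent","missing"} -> favorable 1/0/NA
flag_to_component <- function(flag) {
  out <- rep(NA_real_, length(flag))
  out[!is.na(flag) & flag == "absent"] <- 1
  out[!is.na(flag) & flag == "present"] <- 0
  out
}

#' Aggregate the 0-8 sleep lifestyle index
#'
#' One point per favorable component. Complete-case: if any of the eight
#' components is missing the index is missing (no prorating).
#'
#' @param components data.frame from [score_components()].
#' @return the input with an `index` column (integer 0-8 or `NA`) appended.
#' @export
aggregate_index <- function(components) {
  comp <- as.matrix(components[, index_components()])
  idx <- rowSums(comp)            # NA if any component missing
  components$index <- as.integer(idx)
  components
}

#' Build the sleep lifestyle index from raw survey and EHR inputs
#'
#' Convenience wrapper: cleans the survey, derives traits, scores the eight
#' components against the EHR sleep flags and aggregates the index.
#'
#' @inheritParams clean_survey
#' @param flags EHR sleep flags; see [derive_sleep_flags()].
#' @return list with `traits`, `components` (including `index`), and the
#'   cleaning `drop_counts`.
#' @export
build_sleep_index <- function(survey, flags) {
  cleaned <- clean_survey(survey)
  traits <- derive_sleep_traits(cleaned)
  comp <- aggregate_index(score_components(traits, flags))
  list(traits = traits, components = comp,
       drop_counts = attr(cleaned, "drop_counts"))
}
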
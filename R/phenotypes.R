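#' Calendar-year date shift
#'
#' Adds whole calendar years to a date; Feb 29 in a non-leap target year
#' normalises to Mar 1. Used for the symmetric "within N years" diagnosis
#' window.
#'
#' @param date a `Date` vector.
#' @param years integer number of years (may be negative).
#' @return a `Date` vector.
#' @keywords internal
add_years <- function(date, years) {
  lt <- as.POSIXlt(date)
  lt$year <- lt$year + years
  as.Date(lt)
}

# coerce to Date, failing loudly with the offending values
parse_event_dates <- function(x) {
  d <- suppressWarnings(as.Date(as.character(x), format = "%Y-%m-%d"))
  bad <- is.na(d) & !is.na(x)
  if (any(bad)) {
    stop("unparseable event date(s): ",
         paste(utils::head(unique(as.character(x)[bad]), 5), collapse = ", "),
         " (row ", which(bad)[1], ")")
  }
  d
}

#' Deduplicate ICD billing events
#'
#' Removes same-day duplicated diagnoses (at most one event per participant,
#' ICD version, code and date) and drops events whose version is not ICD-9 or
#' ICD-10. Output is stably ordered by participant, date, then code.
#'
#' @param events data.frame with columns `participant_id`, `icd_version`
#'   (9 or 10), `code`, `date` (`Date` or ISO-8601 string).
#' @return the deduplicated events, with attribute `"n_dropped_version"`
#'   giving how many rows were removed for a non-ICD-9/10 version.
#' @export
deduplicate_events <- function(events) {
  events$date <- parse_event_dates(events$date)
  keep_version <- events$icd_version %in% c(9, 10)
  n_bad_version <- sum(!keep_version)
  events <- events[keep_version, , drop = FALSE]
  key <- paste(events$participant_id, events$icd_version, events$code,
               events$date, sep = "\r")
  events <- events[!duplicated(key), , drop = FALSE]
  ord <- order(events$participant_id, events$date, events$code)
  events <- events[ord, , drop = FALSE]
  rownames(events) <- NULL
  attr(events, "n_dropped_version") <- n_bad_version
  events
}

#' Restrict events to a symmetric window around a per-participant reference
#'
#' Keeps events dated within `window_years` calendar years of the
#' participant's reference date (survey completion), on a closed interval:
#' an event exactly `window_years` years before or after the reference date
#' is retained. Participants with no reference date have their events
#' removed from the output but are reported in the `"unusable_ids"`
#' attribute rather than silently dropped.
#'
#' @param events event data.frame (see [deduplicate_events()]).
#' @param reference_dates data.frame with columns `participant_id` and
#'   `reference_date`.
#' @param window_years half-width of the window, years (default 5).
#' @return filtered events with attribute `"unusable_ids"`.
#' @export
window_filter <- function(events, reference_dates, window_years = 5) {
  events$date <- parse_event_dates(events$date)
  ref <- reference_dates$reference_date[
    match(events$participant_id, reference_dates$participant_id)]
  ref <- as.Date(ref)
  unusable <- unique(events$participant_id[is.na(ref)])
  if (length(unusable)) {
    warning(length(unusable),
            " participant(s) with events but no reference date; their events are unusable")
  }
  keep <- !is.na(ref) &
    events$date >= add_years(ref, -window_years) &
    events$date <= add_years(ref, window_years)
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unusable_ids") <- unusable
  out
}

#' Call phecode case/control status from billing events
#'
#' Maps deduplicated ICD events to phecodes, restricts them to the
#' `window_years` window around each participant's reference date, and
#' applies the counting rule: at least two qualifying codes make a case,
#' zero make a control, exactly one is excluded. Phecodes with fewer than
#' `min_cases` cases are dropped from the retained list, but their calls are
#' still available. ICD codes absent from the map are counted and reported,
#' never fatal.
#'
#' @param events deduplicated event data.frame (see [deduplicate_events()];
#'   deduplication is a precondition, same-day duplicates would otherwise be
#'   double counted).
#' @param map phecode map with columns `icd_version`, `icd_code`,
#'   `phecode_id`, `phecode_label`, `disease_group`.
#' @param reference_dates data.frame `participant_id`, `reference_date`; the
#'   set of participants defines who can be a control.
#' @param window_years window half-width, years.
#' @param min_cases minimum case count for a phecode to be retained in scans.
#' @return an object of class `phecode_calls`: a list with `counts` (long
#'   table of nonzero qualifying-code counts), `participants`, `phecodes`
#'   (id, label, group), `case_counts`, `retained` (phecode ids with at least
#'   `min_cases` cases), `n_unmapped`, `unusable_ids`, and the parameters.
#' @seealso [phecode_status()] to extract one phecode's case/control vector.
#' @export
call_phecodes <- function(events, map, reference_dates,
                          window_years = 5, min_cases = 100) {
  mkey <- paste(map$icd_version, map$icd_code, sep = "\r")
  ekey <- paste(events$icd_version, events$code, sep = "\r")
  idx <- match(ekey, mkey)
  n_unmapped <- sum(is.na(idx) & !is.na(events$code))
  if (n_unmapped > 0) {
    message(n_unmapped, " event(s) with ICD codes absent from the phecode map")
  }
  mapped <- events[!is.na(idx), , drop = FALSE]
  mapped$phecode_id <- map$phecode_id[idx[!is.na(idx)]]
  windowed <- window_filter(mapped, reference_dates, window_years)

  if (nrow(windowed) > 0) {
    key <- paste(windowed$participant_id, windowed$phecode_id, sep = "\r")
    tab <- table(key)
    split_key <- strsplit(names(tab), "\r", fixed = TRUE)
    counts <- data.frame(
      participant_id = vapply(split_key, `[`, "", 1L),
      phecode_id = vapply(split_key, `[`, "", 2L),
      n_qualifying_codes = as.integer(tab),
      stringsAsFactors = FALSE
    )
  } else {
    counts <- data.frame(participant_id = character(0),
                         phecode_id = character(0),
                         n_qualifying_codes = integer(0),
                         stringsAsFactors = FALSE)
  }
  rownames(counts) <- NULL

  phecodes <- unique(map[, c("phecode_id", "phecode_label", "disease_group")])
  rownames(phecodes) <- NULL
  case_tab <- table(factor(counts$phecode_id[counts$n_qualifying_codes >= 2],
                           levels = phecodes$phecode_id))
  case_counts <- as.integer(case_tab)
  names(case_counts) <- phecodes$phecode_id

  # a missing reference date leaves the whole window undefined: such
  # participants are unusable for every phecode, not silently controls
  na_ref <- as.character(
    reference_dates$participant_id[is.na(reference_dates$reference_date)])
  out <- list(
    counts = counts,
    participants = sort(unique(as.character(reference_dates$participant_id))),
    phecodes = phecodes,
    case_counts = case_counts,
    retained = phecodes$phecode_id[case_counts >= min_cases],
    n_unmapped = n_unmapped,
    unusable_ids = sort(unique(c(attr(windowed, "unusable_ids"), na_ref))),
    window_years = window_years,
    min_cases = min_cases
  )
  class(out) <- "phecode_calls"
  out
}

#' Case/control status vector for one phecode
#'
#' @param calls a `phecode_calls` object.
#' @param phecode_id a single phecode id.
#' @return named numeric vector over all participants: 1 = case (>= 2
#'   qualifying codes), 0 = control (no codes), `NA` = excluded (exactly one
#'   code). Participants lacking a usable reference date are also `NA`.
#' @export
phecode_status <- function(calls, phecode_id) {
  status <- rep(0, length(calls$participants))
  names(status) <- calls$participants
  sub <- calls$counts[calls$counts$phecode_id == phecode_id, , drop = FALSE]
  status[sub$participant_id[sub$n_qualifying_codes >= 2]] <- 1
  status[sub$participant_id[sub$n_qualifying_codes == 1]] <- NA
  if (length(calls$unusable_ids)) {
    status[names(status) %in% calls$unusable_ids] <- NA
  }
  status
}

#' @export
print.phecode_calls <- function(x, ...) {
  cat("Phecode calls:", length(x$participants), "participants,",
      nrow(x$phecodes), "phecodes mapped\n")
  cat("  retained (>=", x$min_cases, "cases):", length(x$retained), "phecodes\n")
  cat("  window: +/-", x$window_years, "years;",
      x$n_unmapped, "unmapped events\n")
  invisible(x)
}

#' @export
as.data.frame.phecode_calls <- function(x, ...) {
  grid <- expand.grid(participant_id = x$participants,
                      phecode_id = x$phecodes$phecode_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(grid$participant_id, grid$phecode_id, sep = "\r")
  ckey <- paste(x$counts$participant_id, x$counts$phecode_id, sep = "\r")
  n <- x$counts$n_qualifying_codes[match(key, ckey)]
  n[is.na(n)] <- 0L
  grid$n_qualifying_codes <- n
  grid$status <- ifelse(n >= 2, "case", ifelse(n == 1, "excluded", "control"))
  grid
}

#' Derive EHR sleep-disorder and medication flags
#'
#' Classifies windowed billing and medication events into the four
#' EHR-derived index inputs. A disorder flag is `"present"` with at least two
#' codes in the category on at least two distinct dates within the window,
#' `"absent"` with no codes, and `"missing"` with codes on exactly one date.
#' Sleep-medication exposure is `TRUE` with at least one listed medication
#' event in the window.
#'
#' @param events ICD events (deduplicated; see [deduplicate_events()]).
#' @param med_events data.frame `participant_id`, `code`, `date`.
#' @param classification data.frame with columns `code_type`
#'   (`"icd9"`, `"icd10"` or `"medication"`), `code`, `category`
#'   (`"insomnia"`, `"breathing"`, `"other_sleep"` or `"medication"`).
#' @param reference_dates data.frame `participant_id`, `reference_date`.
#' @param window_years window half-width, years.
#' @return data.frame `participant_id`, `insomnia_disorder`,
#'   `breathing_disorder`, `other_sleep_disorder` (each
#'   `"present"`/`"absent"`/`"missing"`), `sleep_medication` (logical), one
#'   row per participant in `reference_dates`.
#' @export
derive_sleep_flags <- function(events, med_events, classification,
                               reference_dates, window_years = 5) {
  needed <- c("code_type", "code", "category")
  if (!all(needed %in% names(classification))) {
    stop("classification table must have columns: ",
         paste(needed, collapse = ", "))
  }
  ids <- sort(unique(as.character(reference_dates$participant_id)))
  out <- data.frame(participant_id = ids, stringsAsFactors = FALSE)

  ev <- window_filter(events, reference_dates, window_years)
  ev_type <- ifelse(ev$icd_version == 9, "icd9", "icd10")
  ckey <- paste(classification$code_type, classification$code, sep = "\r")
  cat_of <- classification$category[match(paste(ev_type, ev$code, sep = "\r"), ckey)]

  for (cat_name in c("insomnia", "breathing", "other_sleep")) {
    sub <- ev[!is.na(cat_of) & cat_of == cat_name, , drop = FALSE]
    ndates <- tapply(as.character(sub$date), sub$participant_id,
                     function(d) length(unique(d)))
    n <- rep(0L, length(ids))
    names(n) <- ids
    n[names(ndates)] <- as.integer(ndates)
    flag <- ifelse(n >= 2, "present", ifelse(n == 1, "missing", "absent"))
    col <- c(insomnia = "insomnia_disorder", breathing = "breathing_disorder",
             other_sleep = "other_sleep_disorder")[cat_name]
    out[[col]] <- flag
  }

  med_codes <- classification$code[classification$category == "medication"]
  med <- med_events[med_events$code %in% med_codes, , drop = FALSE]
  med <- window_filter(med, reference_dates, window_years)
  out$sleep_medication <- out$participant_id %in% med$participant_id

  # no reference date, no window: every EHR flag is missing
  na_ref <- as.character(
    reference_dates$participant_id[is.na(reference_dates$reference_date)])
  bad <- out$participant_id %in% na_ref
  out$insomnia_disorder[bad] <- NA_character_
  out$breathing_disorder[bad] <- NA_character_
  out$other_sleep_disorder[bad] <- NA_character_
  out$sleep_medication[bad] <- NA
  out
}
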
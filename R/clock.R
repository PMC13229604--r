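#' Clock-time utilities
#'
#' Survey bed and wake times are represented internally as minutes since
#' midnight, in `[0, 1440)`. Survey instruments collect them in half-hour
#' increments; values off the 30-minute grid are accepted with a warning
#' (validation, not rejection).
#'
#' @param x character vector of `"HH:MM"` clock strings (24-hour). `NA` and
#'   empty strings pass through as `NA`.
#' @return `parse_clock()`: integer minutes since midnight in `[0, 1440)`;
#'   `format_clock()`: character `"HH:MM"`.
#' @examples
#' parse_clock("23:30")
#' format_clock(90)
#' @export
parse_clock <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & x == ""] <- NA_character_
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  if (any(ok)) {
    parts <- regmatches(x[ok], regexec("^([0-9]{1,2}):([0-9]{2})$", x[ok]))
    bad <- lengths(parts) != 3L
    if (any(bad)) stop("unparseable clock time: ", paste(unique(x[ok][bad]), collapse = ", "))
    h <- as.numeric(vapply(parts, `[`, "", 2L))
    m <- as.numeric(vapply(parts, `[`, "", 3L))
    if (any(h > 23 | m > 59)) stop("clock time out of range (expected 00:00-23:59)")
    out[ok] <- h * 60 + m
  }
  check_half_hour_grid(out)
  out
}

#' @rdname parse_clock
#' @param minutes numeric vector of minutes since midnight.
#' @export
format_clock <- function(minutes) {
  out <- rep(NA_character_, length(minutes))
  ok <- !is.na(minutes)
  m <- as.integer(round(minutes[ok])) %% 1440L
  out[ok] <- sprintf("%02d:%02d", m %/% 60L, m %% 60L)
  out
}

# warn (once per call) about values off the 30-minute survey grid
check_half_hour_grid <- function(minutes) {
  off <- !is.na(minutes) & (minutes %% 30 != 0)
  if (any(off)) {
    warning(sum(off), " clock time(s) off the half-hour survey grid")
  }
  invisible(minutes)
}

#' Circular clock-time arithmetic
#'
#' `time_in_bed()` is the forward (clockwise) interval from bed to wake on the
#' 24-hour circle, in hours; intervals shorter than 3 h or longer than 18 h
#' are treated as implausible and set to missing. `sleep_midpoint()` is the
#' clock time halfway along that forward interval. `circular_hours_diff()` is
#' the circular absolute difference between two clock times (at most 12 h).
#'
#' @param bed,wake clock times in minutes since midnight (vectors recycle).
#' @param min_hours,max_hours plausibility bounds on time in bed, hours.
#' @return `time_in_bed()`: hours (NA where missing or implausible);
#'   `sleep_midpoint()`: minutes since midnight; `circular_hours_diff()`:
#'   hours in `[0, 12]`.
#' @examples
#' time_in_bed(parse_clock("23:00"), parse_clock("07:00")) # 8
#' format_clock(sleep_midpoint(parse_clock("22:00"), parse_clock("04:00"))) # "01:00"
#' @export
time_in_bed <- function(bed, wake, min_hours = 3, max_hours = 18) {
  tib <- ((wake - bed) %% 1440) / 60
  tib[!is.na(tib) & (tib < min_hours | tib > max_hours)] <- NA_real_
  tib
}

#' @rdname time_in_bed
#' @export
sleep_midpoint <- function(bed, wake) {
  (bed + ((wake - bed) %% 1440) / 2) %% 1440
}

#' @rdname time_in_bed
#' @param t1,t2 clock times in minutes since midnight.
#' @export
circular_hours_diff <- function(t1, t2) {
  d <- abs(t1 - t2) %% 1440
  pmin(d, 1440 - d) / 60
}
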
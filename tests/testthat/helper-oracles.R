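# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's arithmetic: clock intervals are found by stepping
# around the 24-hour dial minute by minute, circular distances through the
# cosine of the angle, and phenotype calls by nested-loop recounting.

# forward minutes from bed to wake: smallest k >= 0 with (bed + k) == wake
# on the 1440-minute dial
oracle_tib_minutes <- function(bed, wake) {
  match(TRUE, ((bed + 0:1439) %% 1440) == wake) - 1
}

oracle_midpoint <- function(bed, wake) {
  (bed + oracle_tib_minutes(bed, wake) / 2) %% 1440
}

# circular distance via the angle between two points on the dial
oracle_circular_hours <- function(t1, t2) {
  theta <- 2 * pi * (t1 - t2) / 1440
  (1440 / (2 * pi)) * acos(pmin(pmax(cos(theta), -1), 1)) / 60
}

# nested-loop phecode caller: for every participant and phecode, count
# mapped, deduplicated codes inside the closed +/- window and apply the
# 2/1/0 rule
oracle_phecode_calls <- function(events, map, reference_dates, window_years = 5) {
  shift_year <- function(d, k) {
    lt <- as.POSIXlt(d)
    lt$year <- lt$year + k
    as.Date(lt)
  }
  ids <- sort(unique(as.character(reference_dates$participant_id)))
  phecodes <- sort(unique(map$phecode_id))
  out <- list()
  for (id in ids) {
    ref <- reference_dates$reference_date[reference_dates$participant_id == id]
    for (ph in phecodes) {
      seen <- character(0)
      for (i in seq_len(nrow(events))) {
        ev <- events[i, ]
        if (as.character(ev$participant_id) != id) next
        if (!(ev$icd_version %in% c(9, 10))) next
        hit <- map$phecode_id[map$icd_version == ev$icd_version &
                                map$icd_code == ev$code]
        if (!(ph %in% hit)) next
        if (is.na(ref)) next
        d <- as.Date(ev$date)
        if (d < shift_year(ref, -window_years) || d > shift_year(ref, window_years)) next
        key <- paste(ev$icd_version, ev$code, d)  # same-day duplicate guard
        if (key %in% seen) next
        seen <- c(seen, key)
      }
      n <- length(seen)
      status <- if (is.na(ref)) NA_real_ else if (n >= 2) 1 else if (n == 1) NA_real_ else 0
      out[[length(out) + 1]] <- data.frame(
        participant_id = id, phecode_id = ph, n = n, status = status,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# exhaustive minimum vertex cover size on a small edge list
oracle_min_vertex_cover <- function(edges) {
  nodes <- sort(unique(c(edges$a, edges$b)))
  if (nrow(edges) == 0) return(0L)
  for (k in 0:length(nodes)) {
    combos <- utils::combn(nodes, k, simplify = FALSE)
    for (cover in combos) {
      if (all(edges$a %in% cover | edges$b %in% cover)) return(k)
    }
  }
  length(nodes)
}

# count connected components of a small graph
oracle_n_components <- function(edges, nodes) {
  comp <- stats::setNames(seq_along(nodes), nodes)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(edges))) {
      a <- edges$a[i]; b <- edges$b[i]
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) {
        comp[comp == comp[a] | comp == comp[b]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  length(unique(comp))
}

# minimal valid survey data.frame
make_survey <- function(id, wd_bed, wd_wake, we_bed, we_wake,
                        date = as.Date("2020-01-01")) {
  data.frame(participant_id = id,
             weekday_bed = wd_bed, weekday_wake = wd_wake,
             weekend_bed = we_bed, weekend_wake = we_wake,
             completion_date = date, stringsAsFactors = FALSE)
}

hm <- function(x) suppressWarnings(parse_clock(x))  # terse clock literal
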
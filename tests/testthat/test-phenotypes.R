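events_df <- function(...) {
  rows <- list(...)
  data.frame(participant_id = vapply(rows, `[[`, "", 1),
             icd_version = as.numeric(vapply(rows, `[[`, "", 2)),
             code = vapply(rows, `[[`, "", 3),
             date = vapply(rows, `[[`, "", 4),
             stringsAsFactors = FALSE)
}

refs_df <- function(ids, dates) {
  data.frame(participant_id = ids, reference_date = as.Date(dates),
             stringsAsFactors = FALSE)
}

test_that("same-day duplicates collapse and non-ICD versions are dropped", {
  ev <- events_df(c("p1", "9", "311", "2020-01-01"),
                  c("p1", "9", "311", "2020-01-01"),
                  c("p1", "9", "311", "2020-03-01"),
                  c("p1", "8", "311", "2020-01-01"))
  out <- deduplicate_events(ev)
  expect_equal(nrow(out), 2)                       # dup removed, v8 removed
  expect_equal(attr(out, "n_dropped_version"), 1)
  expect_equal(out$date, as.Date(c("2020-01-01", "2020-03-01")))

  empty <- deduplicate_events(ev[0, ])
  expect_equal(nrow(empty), 0)
  expect_error(deduplicate_events(events_df(c("p1", "9", "311", "not-a-date"))),
               "unparseable")
})

test_that("the diagnosis window is symmetric and closed at five years", {
  ref <- refs_df("p1", "2015-06-01")
  ev <- events_df(c("p1", "9", "311", "2020-04-20"),   # 4.9 y after
                  c("p1", "9", "311", "2010-04-25"),   # 5.1 y before
                  c("p1", "9", "311", "2020-06-01"),   # exactly +5 y
                  c("p1", "9", "311", "2010-06-01"))   # exactly -5 y
  out <- window_filter(ev, ref)
  expect_equal(sort(as.character(out$date)),
               c("2010-06-01", "2020-04-20", "2020-06-01"))
  expect_warning(
    out2 <- window_filter(events_df(c("p9", "9", "311", "2020-01-01")), ref),
    "no reference date")
  expect_equal(nrow(out2), 0)
  expect_equal(attr(out2, "unusable_ids"), "p9")
})

test_that("two windowed codes make a case, one is excluded, none a control", {
  map <- toy_phecode_map()
  ref <- refs_df(c("p1", "p2", "p3"), rep("2019-05-01", 3))
  ev <- events_df(c("p1", "9", "311", "2020-01-01"),
                  c("p1", "10", "F32.9", "2021-06-01"),
                  c("p2", "9", "311", "2020-01-01"))
  calls <- call_phecodes(deduplicate_events(ev), map, ref, min_cases = 1)
  st <- phecode_status(calls, "296.20")
  expect_equal(st[["p1"]], 1)          # case: two mapped codes in window
  expect_true(is.na(st[["p2"]]))       # excluded: exactly one code
  expect_equal(st[["p3"]], 0)          # control: no codes
  expect_true("296.20" %in% calls$retained)
})

test_that("phecodes below the case floor leave the retained list, calls remain", {
  map <- toy_phecode_map()
  n <- 99
  ids <- sprintf("q%03d", 1:n)
  ev <- rbind(
    data.frame(participant_id = ids, icd_version = 9, code = "311",
               date = as.Date("2020-01-01"), stringsAsFactors = FALSE),
    data.frame(participant_id = ids, icd_version = 9, code = "311",
               date = as.Date("2020-06-01"), stringsAsFactors = FALSE))
  calls <- call_phecodes(deduplicate_events(ev), map,
                         refs_df(ids, rep("2020-01-01", n)), min_cases = 100)
  expect_equal(unname(calls$case_counts["296.20"]), 99L)
  expect_false("296.20" %in% calls$retained)
  expect_equal(sum(phecode_status(calls, "296.20"), na.rm = TRUE), 99)
})

test_that("unmapped codes are counted but never fatal", {
  map <- toy_phecode_map()
  ev <- events_df(c("p1", "9", "NOPE", "2020-01-01"))
  expect_message(
    calls <- call_phecodes(deduplicate_events(ev), map,
                           refs_df("p1", "2020-01-01"), min_cases = 1),
    "absent from the phecode map")
  expect_equal(calls$n_unmapped, 1)
})

test_that("sleep flags need two distinct dates; one code means missing", {
  cls <- toy_sleep_classification()
  ref <- refs_df(c("p1", "p2", "p3", "p4"), rep("2020-01-01", 4))
  ev <- events_df(c("p1", "10", "G47.00", "2020-02-01"),
                  c("p1", "9", "780.52", "2021-02-01"),
                  c("p2", "10", "G47.30", "2020-02-01"),   # single apnea code
                  c("p4", "10", "G47.8", "2020-02-01"),    # same-day pair:
                  c("p4", "10", "G47.9", "2020-02-01"))    # one distinct date
  med <- data.frame(participant_id = "p3", code = "ZOLPIDEM",
                    date = as.Date("2020-03-01"), stringsAsFactors = FALSE)
  flags <- derive_sleep_flags(deduplicate_events(ev), med, cls, ref)
  expect_equal(flags$insomnia_disorder, c("present", "absent", "absent", "absent"))
  expect_equal(flags$breathing_disorder, c("absent", "missing", "absent", "absent"))
  expect_equal(flags$other_sleep_disorder[4], "missing")
  expect_equal(flags$sleep_medication, c(FALSE, FALSE, TRUE, FALSE))
  expect_error(derive_sleep_flags(deduplicate_events(ev), med,
                                  cls[, c("code_type", "code")], ref),
               "must have columns")
})

test_that("every participant-phecode pair has exactly one status", {
  set.seed(11)
  map <- toy_phecode_map()
  ids <- sprintf("r%02d", 1:12)
  ev <- data.frame(
    participant_id = sample(ids, 60, replace = TRUE),
    icd_version = sample(c(9, 10), 60, replace = TRUE),
    code = sample(map$icd_code, 60, replace = TRUE),
    date = as.Date("2018-01-01") + sample(-2500:2500, 60, replace = TRUE),
    stringsAsFactors = FALSE)
  calls <- suppressMessages(call_phecodes(
    deduplicate_events(ev), map, refs_df(ids, rep("2018-06-01", 12)),
    min_cases = 1))
  long <- as.data.frame(calls)
  expect_equal(nrow(long), 12 * nrow(calls$phecodes))
  expect_true(all(long$status %in% c("case", "control", "excluded")))
  expect_true(all((long$status == "case") == (long$n_qualifying_codes >= 2)))
  expect_true(all((long$status == "excluded") == (long$n_qualifying_codes == 1)))
})

test_that("enlarging the window never turns a case into a control", {
  set.seed(12)
  map <- toy_phecode_map()
  ids <- sprintf("s%02d", 1:10)
  ev <- data.frame(
    participant_id = sample(ids, 80, replace = TRUE),
    icd_version = sample(c(9, 10), 80, replace = TRUE),
    code = sample(map$icd_code, 80, replace = TRUE),
    date = as.Date("2018-01-01") + sample(-4000:4000, 80, replace = TRUE),
    stringsAsFactors = FALSE)
  refs <- refs_df(ids, rep("2018-06-01", 10))
  c5 <- suppressMessages(call_phecodes(deduplicate_events(ev), map, refs,
                                       window_years = 5, min_cases = 1))
  c9 <- suppressMessages(call_phecodes(deduplicate_events(ev), map, refs,
                                       window_years = 9, min_cases = 1))
  for (ph in c5$phecodes$phecode_id) {
    s5 <- phecode_status(c5, ph)
    s9 <- phecode_status(c9, ph)
    was_case <- !is.na(s5) & s5 == 1
    expect_false(any(s9[was_case] %in% 0))
  }
})
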
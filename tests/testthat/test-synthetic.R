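test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_participants = 1), "n_participants")
  expect_error(sim_config(ampm_misreport_rate = 1.2))
  expect_error(sim_config(allele_freq_range = c(0, 0.5)))
  expect_error(outcome_spec("x", prevalence = 0))
  expect_error(outcome_spec("x", 0.2, or_per_sd_prs = -1))
  expect_error(sim_config(outcome_specs = list(1, 2)), "outcome_spec")
})

test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- sim_config(n_participants = 300, n_variants = 15, seed = 5)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  for (tab in c("participants", "survey", "icd_events", "med_events",
                "kinship_pairs", "weights")) {
    expect_identical(a[[tab]], b[[tab]], info = tab)
  }
  expect_identical(a$dosages, b$dosages)
  expect_identical(a$truth$index_true, b$truth$index_true)
})

test_that("generated tables respect the cohort contracts", {
  cfg <- sim_config(n_participants = 400, n_variants = 12, seed = 6)
  co <- simulate_cohort(cfg)
  ids <- co$participants$participant_id
  expect_true(all(co$survey$participant_id %in% ids))
  expect_true(all(co$icd_events$participant_id %in% ids))
  expect_true(all(co$med_events$participant_id %in% ids))
  expect_true(all(rownames(co$dosages) %in% ids))
  expect_true(all(co$dosages >= 0 & co$dosages <= 2))
  expect_identical(co$truth$config, cfg)   # truth echoes the configuration
  # survey times sit on the half-hour grid
  for (col in c("weekday_bed", "weekday_wake", "weekend_bed", "weekend_wake")) {
    expect_true(all(co$survey[[col]] %% 30 == 0), info = col)
  }
})

test_that("disabling contamination leaves no bedtime in the implausible window", {
  cfg <- sim_config(n_participants = 500, seed = 8, ampm_misreport_rate = 0)
  co <- simulate_cohort(cfg)
  beds <- c(co$survey$weekday_bed, co$survey$weekend_bed)
  expect_false(any(beds >= 8 * 60 & beds <= 14 * 60))
  wakes <- c(co$survey$weekday_wake, co$survey$weekend_wake)
  expect_false(any(wakes >= 18 * 60))   # wake cleaning window never hit
})

test_that("the generator realises the planted components exactly", {
  cfg <- sim_config(n_participants = 600, seed = 9, ampm_misreport_rate = 0,
                    one_code_rate = 0, window_violation_rate = 0)
  co <- simulate_cohort(cfg)
  events <- deduplicate_events(co$icd_events)
  refs <- data.frame(participant_id = co$participants$participant_id,
                     reference_date = co$participants$survey_date)
  flags <- derive_sleep_flags(events, co$med_events,
                              toy_sleep_classification(), refs)
  idx <- build_sleep_index(co$survey, flags)
  comp <- idx$components[match(co$participants$participant_id,
                               idx$components$participant_id), ]
  truth <- co$truth$components_true
  for (k in index_components()) {
    expect_equal(comp[[k]], unname(truth[, k]), info = k)
  }
  expect_equal(comp$index, unname(as.integer(rowSums(truth))))
})

test_that("case fraction matches the requested prevalence", {
  prev <- 0.2
  cfg <- sim_config(n_participants = 20000, seed = 10, one_code_rate = 0,
                    window_violation_rate = 0,
                    outcome_specs = list(outcome_spec("296.20", prev,
                                                      or_per_sd_prs = 0.85)))
  co <- simulate_cohort(cfg)
  events <- deduplicate_events(co$icd_events)
  refs <- data.frame(participant_id = co$participants$participant_id,
                     reference_date = co$participants$survey_date)
  calls <- suppressMessages(call_phecodes(events, toy_phecode_map(), refs))
  st <- phecode_status(calls, "296.20")
  frac <- mean(st, na.rm = TRUE)
  se <- sqrt(prev * (1 - prev) / cfg$n_participants)
  expect_lt(abs(frac - prev), 3 * se)
})

test_that("impossible prevalence-effect combinations fail naming the outcome", {
  cfg <- sim_config(n_participants = 200, seed = 12,
                    outcome_specs = list(outcome_spec("296.20", 1e-10,
                                                      or_per_sd_prs = 0.85)))
  expect_error(simulate_cohort(cfg), "296.20")
})

test_that("a written cohort round-trips losslessly and lists 7+1 files", {
  cfg <- sim_config(n_participants = 50, n_variants = 8, seed = 13)
  co <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  manifest <- write_cohort(co, dir)
  expect_length(manifest, 8)             # 7 data files + truth.json
  expect_true(all(file.exists(manifest)))
  expect_equal(sum(grepl("\\.tsv$", manifest)), 7)
  expect_equal(sum(grepl("truth\\.json$", manifest)), 1)

  back <- read_cohort(dir)
  expect_equal(back$participants, co$participants)
  expect_equal(back$survey, co$survey)
  expect_equal(back$icd_events, co$icd_events)
  expect_equal(back$med_events, co$med_events)
  expect_equal(back$kinship_pairs, co$kinship_pairs)
  expect_equal(back$weights, co$weights)
  expect_equal(unclass(back$dosages), unclass(co$dosages),
               ignore_attr = "counted_allele")
  expect_equal(attr(back$dosages, "counted_allele"),
               attr(co$dosages, "counted_allele"))
  expect_equal(back$truth$config$prs_index_beta, cfg$prs_index_beta)
})

test_that("the minimum-size cohort still writes valid files", {
  cfg <- sim_config(n_participants = 2, n_variants = 3, seed = 14,
                    outcome_specs = list(), related_pair_rate = 0)
  co <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  manifest <- write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(nrow(back$participants), 2)
  expect_equal(nrow(back$icd_events), nrow(co$icd_events))
})
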
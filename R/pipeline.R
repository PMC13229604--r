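#' Cohort descriptives
#'
#' Mean, SD and range of the four derived sleep traits, prevalence of each
#' EHR flag, the distribution of the 0-8 index (histogram counts), and the
#' percentage of complete-index participants holding all eight favorable
#' behaviors.
#'
#' @param traits data.frame from [derive_sleep_traits()].
#' @param components data.frame from [aggregate_index()].
#' @param flags data.frame from [derive_sleep_flags()].
#' @return list of class `cohort_descriptives`.
#' @export
describe_cohort <- function(traits, components, flags) {
  msr <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(c(mean = NA, sd = NA, min = NA, max = NA))
    c(mean = mean(x), sd = stats::sd(x), min = min(x), max = max(x))
  }
  trait_stats <- rbind(
    tib_weighted = msr(traits$tib_weighted),
    tib_irregularity = msr(traits$tib_irregularity),
    midpoint_weekend = msr(traits$midpoint_weekend / 60),
    social_jetlag = msr(traits$social_jetlag))

  flag_prev <- c(
    insomnia_disorder = mean(flags$insomnia_disorder == "present", na.rm = TRUE),
    breathing_disorder = mean(flags$breathing_disorder == "present", na.rm = TRUE),
    other_sleep_disorder = mean(flags$other_sleep_disorder == "present", na.rm = TRUE),
    sleep_medication = mean(flags$sleep_medication, na.rm = TRUE))

  idx <- components$index
  hist_counts <- table(factor(idx[!is.na(idx)], levels = 0:8))
  out <- list(
    n = nrow(components),
    n_complete_index = sum(!is.na(idx)),
    trait_stats = trait_stats,
    flag_prevalence = flag_prev,
    index_histogram = hist_counts,
    pct_all_eight = 100 * mean(idx[!is.na(idx)] == 8))
  class(out) <- "cohort_descriptives"
  out
}

#' @export
print.cohort_descriptives <- function(x, ...) {
  cat("Cohort:", x$n, "participants,", x$n_complete_index, "with complete index\n")
  s <- x$trait_stats
  cat(sprintf("  weighted time in bed: %.2f +/- %.2f h (range %.1f-%.1f)\n",
              s["tib_weighted", "mean"], s["tib_weighted", "sd"],
              s["tib_weighted", "min"], s["tib_weighted", "max"]))
  cat(sprintf("  time in bed irregularity: %.2f +/- %.2f h\n",
              s["tib_irregularity", "mean"], s["tib_irregularity", "sd"]))
  cat(sprintf("  weekend sleep midpoint: %s +/- %.2f h\n",
              format_clock(s["midpoint_weekend", "mean"] * 60),
              s["midpoint_weekend", "sd"]))
  cat(sprintf("  social jetlag: %.2f +/- %.2f h\n",
              s["social_jetlag", "mean"], s["social_jetlag", "sd"]))
  cat(sprintf("  disorder prevalence: insomnia %.1f%%, breathing %.1f%%, other %.1f%%; medication %.1f%%\n",
              100 * x$flag_prevalence["insomnia_disorder"],
              100 * x$flag_prevalence["breathing_disorder"],
              100 * x$flag_prevalence["other_sleep_disorder"],
              100 * x$flag_prevalence["sleep_medication"]))
  cat(sprintf("  all eight favorable: %.2f%%\n", x$pct_all_eight))
  cat("  index histogram (0-8):", paste(x$index_histogram, collapse = " "), "\n")
  invisible(x)
}

#' Run the full analysis pipeline
#'
#' Sequences the stages end to end: event deduplication and windowed
#' phenotyping, EHR sleep flags, survey cleaning and index construction,
#' polygenic scoring with kinship pruning and standardization, the
#' score-index association models, both phenome-wide scans, and
#' score-by-index interaction tests on the top mental-health outcomes
#' associated with both exposures.
#'
#' @param cohort a `synthetic_cohort` (from [simulate_cohort()] or
#'   [read_cohort()]).
#' @param map phecode map (default [toy_phecode_map()]).
#' @param classification sleep code classification (default
#'   [toy_sleep_classification()]).
#' @param window_years diagnosis window half-width, years.
#' @param min_cases minimum case count for a phecode to enter the scans.
#' @param kinship_threshold relatedness cutoff for pruning.
#' @param alpha family-wise error rate for Bonferroni correction.
#' @param n_interaction number of top mental-health outcomes (smallest
#'   combined p among those significant for both exposures) carried into the
#'   interaction tests.
#' @param interaction_outcomes optional explicit phecode ids for the
#'   interaction tests, overriding the automatic selection.
#' @param restrict_prs_to_survey if `TRUE`, the polygenic-score PheWAS is
#'   restricted to participants with a survey completion date (sensitivity
#'   analysis); default uses all unrelated scored participants.
#' @param out_dir optional directory; when given, every stage's output table
#'   is written there as TSV along with `report.json`.
#' @return object of class `sleepdex_report`: descriptives, the score-index
#'   association table, both `phewas_scan` objects, the interaction table,
#'   per-stage row-drop accounting, and the configuration fingerprint.
#' @export
run_pipeline <- function(cohort,
                         map = toy_phecode_map(),
                         classification = toy_sleep_classification(),
                         window_years = 5, min_cases = 100,
                         kinship_threshold = 0.0625, alpha = 0.05,
                         n_interaction = 5, interaction_outcomes = NULL,
                         restrict_prs_to_survey = FALSE,
                         out_dir = NULL) {
  stage <- "phenotypes"
  report <- tryCatch({
    ## phenotypes -----------------------------------------------------------
    events <- deduplicate_events(cohort$icd_events)
    refs <- data.frame(participant_id = cohort$participants$participant_id,
                       reference_date = cohort$participants$survey_date,
                       stringsAsFactors = FALSE)
    calls <- call_phecodes(events, map, refs, window_years, min_cases)
    flags <- derive_sleep_flags(events, cohort$med_events, classification,
                                refs, window_years)

    ## sleep index ----------------------------------------------------------
    stage <- "sleep_index"
    idx <- build_sleep_index(cohort$survey, flags)

    ## genetics -------------------------------------------------------------
    stage <- "genetics"
    scores <- harmonize_and_score(cohort$weights, cohort$dosages)
    prune <- prune_related(cohort$kinship_pairs, kinship_threshold,
                           ids = cohort$participants$participant_id)
    scores <- standardize_scores(scores, sample_ids = prune$kept)

    ## analysis table -------------------------------------------------------
    stage <- "association"
    data <- merge(cohort$participants,
                  scores[, c("participant_id", "standardized")],
                  by = "participant_id", all.x = TRUE)
    names(data)[names(data) == "standardized"] <- "prs_std"
    data <- merge(data, idx$components, by = "participant_id", all.x = TRUE)
    data$unrelated <- data$participant_id %in% prune$kept

    n_pcs <- sum(grepl("^PC[0-9]+$", names(cohort$participants)))
    covs_primary <- covariate_set("primary", n_pcs)
    covs_full <- covariate_set("fully_adjusted", n_pcs)
    covs_index <- covariate_set("index_phewas")

    assoc <- index_prs_association(
      data[data$unrelated, , drop = FALSE],
      covariate_sets = list(primary = covs_primary, fully_adjusted = covs_full))

    prs_sample <- data[data$unrelated, , drop = FALSE]
    if (restrict_prs_to_survey) {
      with_survey <- cohort$survey$participant_id[!is.na(cohort$survey$completion_date)]
      prs_sample <- prs_sample[prs_sample$participant_id %in% with_survey, , drop = FALSE]
    }
    scan_prs <- run_phewas(calls, prs_sample, "prs_std", covs_primary,
                           alpha = alpha, label = "primary")
    scan_index <- run_phewas(calls, data, "index", covs_index,
                             alpha = alpha, label = "index_phewas")

    ## interactions ---------------------------------------------------------
    stage <- "interaction"
    targets <- interaction_outcomes
    if (is.null(targets)) {
      targets <- select_interaction_outcomes(scan_prs, scan_index, n_interaction)
    }
    inter <- list()
    for (ph in targets) {
      status <- phecode_status(calls, ph)
      d <- data
      d$.status <- status[match(as.character(d$participant_id), names(status))]
      for (lab in c("primary", "fully_adjusted")) {
        covs <- if (lab == "primary") covs_primary else covs_full
        row <- test_interaction(d[d$unrelated, , drop = FALSE], ".status",
                                covariates = covs, label = lab)
        row$outcome <- ph
        inter[[length(inter) + 1]] <- row
      }
    }
    inter <- if (length(inter)) do.call(rbind, inter) else NULL

    ## report ---------------------------------------------------------------
    stage <- "report"
    desc <- describe_cohort(idx$traits, idx$components, flags)
    out <- list(
      descriptives = desc,
      index_prs = assoc,
      scan_prs = scan_prs,
      scan_index = scan_index,
      interactions = inter,
      drop_counts = idx$drop_counts,
      n_unmapped_events = calls$n_unmapped,
      n_pruned = length(prune$removed),
      fingerprint = list(
        n_participants = nrow(cohort$participants),
        window_years = window_years, min_cases = min_cases,
        kinship_threshold = kinship_threshold, alpha = alpha,
        seed = if (!is.null(cohort$truth)) cohort$truth$config$seed else NA),
      calls = calls, index = idx, prs = scores, prune = prune, data = data)
    class(out) <- "sleepdex_report"
    out
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(out_dir)) write_report_files(report, out_dir)
  report
}

# top mental-health outcomes significant for BOTH exposures, smallest
# combined p first
select_interaction_outcomes <- function(scan_prs, scan_index, n = 5) {
  a <- scan_prs$results
  b <- scan_index$results
  both <- intersect(a$outcome[a$significant], b$outcome[b$significant])
  both <- both[a$disease_group[match(both, a$outcome)] == "mental disorders"]
  if (!length(both)) return(character(0))
  pmin_p <- pmin(a$p[match(both, a$outcome)], b$p[match(both, b$outcome)])
  utils::head(both[order(pmin_p)], n)
}

#' @export
print.sleepdex_report <- function(x, ...) {
  cat("== sleepdex pipeline report ==\n")
  print(x$descriptives)
  cat("\nScore-index association (linear, index on PRS):\n")
  lin <- x$index_prs[x$index_prs$outcome == "index", , drop = FALSE]
  for (i in seq_len(nrow(lin))) {
    cat(sprintf("  [%s] beta = %.4f (95%% CI %.4f, %.4f), p = %.3g\n",
                lin$model[i], lin$estimate[i], lin$ci_low[i], lin$ci_high[i],
                lin$p[i]))
  }
  cat("\nPRS PheWAS: ", x$scan_prs$n_tests, " tests, ",
      x$scan_prs$n_significant, " significant (threshold ",
      format(x$scan_prs$alpha_corrected, digits = 3), ")\n", sep = "")
  cat("Index PheWAS: ", x$scan_index$n_tests, " tests, ",
      x$scan_index$n_significant, " significant (threshold ",
      format(x$scan_index$alpha_corrected, digits = 3), ")\n", sep = "")
  if (!is.null(x$interactions)) {
    cat("\nInteraction tests (PRS x index):\n")
    for (i in seq_len(nrow(x$interactions))) {
      r <- x$interactions[i, ]
      cat(sprintf("  %s [%s]: OR = %.3f (%.3f, %.3f), p = %.3g\n",
                  r$outcome, r$model, r$estimate, r$ci_low, r$ci_high, r$p))
    }
  } else cat("\nNo interaction outcomes selected.\n")
  cat("\nPruned for relatedness:", x$n_pruned,
      "| survey values removed by cleaning:", sum(x$drop_counts),
      "| unmapped events:", x$n_unmapped_events, "\n")
  invisible(x)
}

# write every stage output as TSV plus a JSON report
write_report_files <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_tsv(report$index$traits, p("sleep_traits.tsv"))
  write_tsv(report$index$components, p("sleep_index.tsv"))
  write_tsv(report$prs, p("prs.tsv"))
  write_tsv(data.frame(participant_id = report$prune$removed,
                       stringsAsFactors = FALSE), p("prune_report.tsv"))
  write_tsv(as.data.frame(report$calls), p("phenotype_calls.tsv"))
  write_tsv(report$scan_prs$results, p("phewas_prs.tsv"))
  write_tsv(report$scan_index$results, p("phewas_index.tsv"))
  write_tsv(report$index_prs, p("association_results.tsv"))
  if (!is.null(report$interactions)) {
    write_tsv(report$interactions, p("interaction_results.tsv"))
  }
  manhattan <- rbind(
    cbind(report$scan_prs$results[, c("outcome", "disease_group",
                                      "neg_log10_p", "direction")],
          exposure = "prs"),
    cbind(report$scan_index$results[, c("outcome", "disease_group",
                                        "neg_log10_p", "direction")],
          exposure = "index"))
  write_tsv(manhattan, p("manhattan_table.tsv"))
  json <- list(
    fingerprint = report$fingerprint,
    n = report$descriptives$n,
    n_complete_index = report$descriptives$n_complete_index,
    pct_all_eight = report$descriptives$pct_all_eight,
    index_histogram = as.integer(report$descriptives$index_histogram),
    prs_phewas = list(n_tests = report$scan_prs$n_tests,
                      n_significant = report$scan_prs$n_significant),
    index_phewas = list(n_tests = report$scan_index$n_tests,
                        n_significant = report$scan_index$n_significant))
  jsonlite::write_json(json, p("report.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Run the pipeline from a YAML configuration file
#'
#' A single YAML file drives an end-to-end run. Recognised keys:
#' `cohort_dir` (read an existing cohort) or `simulate` (a mapping of
#' [sim_config()] arguments; `outcome_specs` as a list of mappings), plus the
#' constants `window_years`, `min_cases`, `kinship_threshold`, `alpha`,
#' `n_interaction`, `restrict_prs_to_survey`, and `out_dir`. Omitted keys
#' take the package defaults, which match the analysis constants documented
#' in the function reference.
#'
#' @param path YAML file path.
#' @return a `sleepdex_report` (invisibly if `out_dir` was written).
#' @export
run_from_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cohort <- if (!is.null(cfg$cohort_dir)) {
    read_cohort(cfg$cohort_dir)
  } else {
    sim_args <- cfg$simulate
    if (is.null(sim_args)) stop("config needs either 'cohort_dir' or 'simulate'")
    if (!is.null(sim_args$outcome_specs)) {
      sim_args$outcome_specs <- lapply(sim_args$outcome_specs,
                                       function(s) do.call(outcome_spec, s))
    }
    if (!is.null(sim_args$component_base_probs)) {
      sim_args$component_base_probs <- unlist(sim_args$component_base_probs)
    }
    if (!is.null(sim_args$allele_freq_range)) {
      sim_args$allele_freq_range <- unlist(sim_args$allele_freq_range)
    }
    simulate_cohort(do.call(sim_config, sim_args))
  }
  args <- cfg[intersect(names(cfg),
                        c("window_years", "min_cases", "kinship_threshold",
                          "alpha", "n_interaction", "interaction_outcomes",
                          "restrict_prs_to_survey", "out_dir"))]
  do.call(run_pipeline, c(list(cohort = cohort), args))
}
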
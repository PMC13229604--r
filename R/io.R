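# write a data.frame as TSV with full-precision numerics so that
# write -> read round-trips exactly
write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- ifelse(is.na(out[[j]]), NA, sprintf("%.17g", out[[j]]))
    }
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("failed to write ", path)
  path
}

read_tsv <- function(path, colClasses = NA) {
  utils::read.delim(path, colClasses = colClasses, na.strings = "",
                    check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write a synthetic cohort to a directory of TSV files
#'
#' Emits the pipeline's tabular input formats: `participants.tsv`,
#' `survey.tsv` (clock times as `HH:MM`, dates ISO-8601), `icd_events.tsv`,
#' `med_events.tsv`, `kinship.tsv`, `weights.tsv`, `dosages.tsv`
#' (participants by variants; column headers `variant_id:counted_allele`)
#' and `truth.json`. The emitted files round-trip losslessly through
#' [read_cohort()].
#'
#' @param cohort a `synthetic_cohort`.
#' @param directory output directory (created if missing).
#' @return named character vector: the manifest of written file paths.
#' @export
write_cohort <- function(cohort, directory) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  p <- function(f) file.path(directory, f)
  manifest <- c(participants = p("participants.tsv"),
                survey = p("survey.tsv"),
                icd_events = p("icd_events.tsv"),
                med_events = p("med_events.tsv"),
                kinship = p("kinship.tsv"),
                weights = p("weights.tsv"),
                dosages = p("dosages.tsv"),
                truth = p("truth.json"))

  part <- cohort$participants
  part$survey_date <- as.character(part$survey_date)
  write_tsv(part, manifest["participants"])

  survey <- cohort$survey
  for (col in c("weekday_bed", "weekday_wake", "weekend_bed", "weekend_wake")) {
    survey[[col]] <- format_clock(survey[[col]])
  }
  survey$completion_date <- as.character(survey$completion_date)
  write_tsv(survey, manifest["survey"])

  icd <- cohort$icd_events
  icd$date <- as.character(icd$date)
  write_tsv(icd, manifest["icd_events"])
  med <- cohort$med_events
  med$date <- as.character(med$date)
  write_tsv(med, manifest["med_events"])
  write_tsv(cohort$kinship_pairs, manifest["kinship"])
  write_tsv(cohort$weights, manifest["weights"])

  dos <- as.data.frame(cohort$dosages)
  counted <- attr(cohort$dosages, "counted_allele")
  names(dos) <- paste0(colnames(cohort$dosages), ":",
                       counted[colnames(cohort$dosages)])
  dos <- cbind(participant_id = rownames(cohort$dosages), dos)
  write_tsv(dos, manifest["dosages"])

  truth <- cohort$truth
  truth$prs_std <- NULL          # per-participant vectors stay in memory;
  truth$index_true <- NULL       # truth.json records the planted parameters
  truth$components_true <- NULL
  truth$config <- unclass(truth$config)
  truth$config$component_base_probs <- as.list(truth$config$component_base_probs)
  truth$alphas <- as.list(truth$alphas)
  jsonlite::write_json(truth, manifest["truth"], auto_unbox = TRUE,
                       digits = NA, null = "null")
  manifest
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param directory directory containing the cohort TSV files.
#' @return a `synthetic_cohort` (the `truth` element holds the parameters
#'   recorded in `truth.json`; the per-participant planted vectors are not
#'   persisted).
#' @export
read_cohort <- function(directory) {
  p <- function(f) file.path(directory, f)
  part <- read_tsv(p("participants.tsv"))
  part$participant_id <- as.character(part$participant_id)
  part$survey_date <- as.Date(part$survey_date)

  survey <- read_tsv(p("survey.tsv"))
  survey$participant_id <- as.character(survey$participant_id)
  for (col in c("weekday_bed", "weekday_wake", "weekend_bed", "weekend_wake")) {
    survey[[col]] <- parse_clock(survey[[col]])
  }
  survey$completion_date <- as.Date(survey$completion_date)

  icd <- read_tsv(p("icd_events.tsv"),
                  colClasses = c(participant_id = "character",
                                 icd_version = "integer",
                                 code = "character", date = "character"))
  icd$date <- as.Date(icd$date)
  med <- read_tsv(p("med_events.tsv"),
                  colClasses = c(participant_id = "character",
                                 code = "character", date = "character"))
  med$date <- as.Date(med$date)
  kin <- read_tsv(p("kinship.tsv"),
                  colClasses = c(id_a = "character", id_b = "character",
                                 coefficient = "numeric"))
  weights <- read_tsv(p("weights.tsv"),
                      colClasses = c(variant_id = "character",
                                     effect_allele = "character",
                                     other_allele = "character",
                                     weight = "numeric"))

  dos_df <- read_tsv(p("dosages.tsv"))
  ids <- as.character(dos_df$participant_id)
  dos_df$participant_id <- NULL
  spl <- strsplit(names(dos_df), ":", fixed = TRUE)
  variant_ids <- vapply(spl, `[`, "", 1L)
  counted <- stats::setNames(vapply(spl, `[`, "", 2L), variant_ids)
  dosages <- as.matrix(dos_df)
  dimnames(dosages) <- list(ids, variant_ids)
  attr(dosages, "counted_allele") <- counted

  truth <- if (file.exists(p("truth.json"))) {
    jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
  } else NULL

  out <- list(participants = part, survey = survey, dosages = dosages,
              weights = weights, icd_events = icd, med_events = med,
              kinship_pairs = kin, truth = truth)
  class(out) <- "synthetic_cohort"
  out
}
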
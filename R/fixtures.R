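#' Bundled toy code vocabularies
#'
#' A 30-phecode toy ICD-9/10 to phecode map and a sleep-relevant code
#' classification (insomnia, sleep-related breathing, other sleep disorders,
#' and sleep-affecting medications), bundled as plain TSV fixtures. These are
#' deliberately tiny stand-ins for the full clinical vocabularies: they use
#' plausible code formats and disease groups, but are synthetic and carry no
#' claim of clinical completeness. A user-supplied map in the same format is
#' accepted everywhere a map is consumed.
#'
#' @return `toy_phecode_map()`: data.frame with `icd_version`, `icd_code`,
#'   `phecode_id`, `phecode_label`, `disease_group`.
#'   `toy_sleep_classification()`: data.frame with `code_type`, `code`,
#'   `category`.
#' @export
toy_phecode_map <- function() {
  path <- system.file("extdata", "toy_phecode_map.tsv", package = "sleepdex",
                      mustWork = TRUE)
  utils::read.delim(path, colClasses = c(icd_version = "integer",
                                         icd_code = "character",
                                         phecode_id = "character"))
}

#' @rdname toy_phecode_map
#' @export
toy_sleep_classification <- function() {
  path <- system.file("extdata", "toy_sleep_classification.tsv",
                      package = "sleepdex", mustWork = TRUE)
  utils::read.delim(path, colClasses = "character")
}

#' Generate a synthetic phecode map of arbitrary size
#'
#' Programmatically builds a map with `n_phecodes` synthetic phecodes (one
#' ICD-9 and one ICD-10 code each) spread across the toy disease groups.
#' Useful for scans that need more outcomes than the bundled 30-phecode
#' vocabulary, e.g. null calibration experiments.
#'
#' @param n_phecodes number of phecodes.
#' @return data.frame in the same format as [toy_phecode_map()].
#' @export
synthetic_phecode_map <- function(n_phecodes) {
  stopifnot(n_phecodes >= 1)
  groups <- c("mental disorders", "endocrine/metabolic", "circulatory system",
              "respiratory", "digestive", "genitourinary", "neurological",
              "musculoskeletal", "dermatologic", "neoplasms",
              "infectious diseases", "sleep disorders")
  ph <- sprintf("S%03d.00", seq_len(n_phecodes))
  data.frame(
    icd_version = rep(c(9L, 10L), each = n_phecodes),
    icd_code = c(sprintf("900.%d", seq_len(n_phecodes)),
                 sprintf("Z90.%d", seq_len(n_phecodes))),
    phecode_id = rep(ph, 2),
    phecode_label = rep(sprintf("Synthetic phenotype %d", seq_len(n_phecodes)), 2),
    disease_group = rep(groups[(seq_len(n_phecodes) - 1) %% length(groups) + 1], 2),
    stringsAsFactors = FALSE
  )
}
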
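#' Specify one simulated disease outcome
#'
#' Disease status is drawn from the logistic model
#' `logit(p) = alpha + log(or_per_sd_prs) * PRS_std +
#' log(or_per_index_unit) * index + interaction_log_or * PRS_std * index +
#' confounder terms`, with `alpha` solved so that the marginal prevalence
#' matches `prevalence`.
#'
#' @param phecode phecode id the outcome's billing codes map to.
#' @param prevalence target marginal prevalence, in (0, 1).
#' @param or_per_sd_prs odds ratio per SD of the polygenic score (> 0).
#' @param or_per_index_unit odds ratio per unit of the lifestyle index (> 0).
#' @param interaction_log_or log odds ratio of the product term.
#' @return a named list (an `outcome_spec`).
#' @export
outcome_spec <- function(phecode, prevalence, or_per_sd_prs = 1,
                         or_per_index_unit = 1, interaction_log_or = 0) {
  stopifnot(prevalence > 0, prevalence < 1,
            or_per_sd_prs > 0, or_per_index_unit > 0,
            is.finite(interaction_log_or))
  list(phecode = as.character(phecode), prevalence = prevalence,
       or_per_sd_prs = or_per_sd_prs, or_per_index_unit = or_per_index_unit,
       interaction_log_or = interaction_log_or)
}

#' Configuration for the synthetic biobank generator
#'
#' Collects and validates every knob of the simulator. Defaults describe a
#' plausible clinical-biobank survey cohort: component base rates chosen so
#' sleep-disorder prevalences sit near the low single-digit percentages seen
#' in EHR data and roughly a fifth to a quarter of participants hold all
#' eight favorable behaviors; contamination and record-quality rates are a
#' few percent.
#'
#' @param n_participants cohort size (>= 2).
#' @param n_variants number of simulated variants in the weight table.
#' @param allele_freq_range range the per-variant allele frequencies are
#'   drawn from, both in (0, 1).
#' @param prs_index_beta planted per-SD effect of the polygenic score on the
#'   expected lifestyle index (index units per SD).
#' @param outcome_specs list of [outcome_spec()]s.
#' @param ampm_misreport_rate fraction of reported bedtimes shifted into the
#'   implausible 08:00-14:00 window (AM/PM misreporting).
#' @param one_code_rate fraction of cases given exactly one qualifying code
#'   (exercises the exclusion rule).
#' @param window_violation_rate fraction of cases with one qualifying code
#'   redated outside the +/-5-year window.
#' @param related_pair_rate number of planted related pairs (kinship 0.25)
#'   as a fraction of `n_participants`; an equal number of sub-threshold
#'   pairs (0.04) is added.
#' @param confounding_strength multiplier on the mild age/sex confounding of
#'   both the index components and the disease outcomes (0 disables).
#' @param component_base_probs named length-8 vector of baseline favorable
#'   probabilities for the index components.
#' @param n_pcs number of ancestry principal-component columns.
#' @param seed integer random seed.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 1000,
                       n_variants = 50,
                       allele_freq_range = c(0.1, 0.9),
                       prs_index_beta = 0.05,
                       outcome_specs = list(
                         outcome_spec("296.20", prevalence = 0.2,
                                      or_per_sd_prs = 0.85,
                                      or_per_index_unit = 0.9)),
                       ampm_misreport_rate = 0.02,
                       one_code_rate = 0.01,
                       window_violation_rate = 0.01,
                       related_pair_rate = 0.01,
                       confounding_strength = 1,
                       component_base_probs = c(
                         adequate_tib = 0.65, regular_tib = 0.75,
                         healthy_midpoint = 0.60, low_social_jetlag = 0.85,
                         no_sleep_medication = 0.90, no_insomnia_disorder = 0.981,
                         no_breathing_disorder = 0.965,
                         no_other_sleep_disorder = 0.971),
                       n_pcs = 5,
                       seed = 1L) {
  props <- c(ampm_misreport_rate, one_code_rate, window_violation_rate,
             related_pair_rate)
  stopifnot(n_participants >= 2, n_variants >= 1,
            length(allele_freq_range) == 2,
            all(allele_freq_range > 0), all(allele_freq_range < 1),
            allele_freq_range[1] <= allele_freq_range[2],
            is.finite(prs_index_beta),
            all(props >= 0), all(props <= 1),
            confounding_strength >= 0,
            length(component_base_probs) == 8,
            all(component_base_probs > 0), all(component_base_probs < 1),
            n_pcs >= 1, length(seed) == 1)
  if (!all(index_components() %in% names(component_base_probs))) {
    stop("component_base_probs must be named with the eight index components")
  }
  if (length(outcome_specs) > 0 &&
      (is.null(names(outcome_specs[[1]])) || !"phecode" %in% names(outcome_specs[[1]]))) {
    stop("outcome_specs must be a list of outcome_spec() objects")
  }
  cfg <- list(n_participants = as.integer(n_participants),
              n_variants = as.integer(n_variants),
              allele_freq_range = allele_freq_range,
              prs_index_beta = prs_index_beta,
              outcome_specs = outcome_specs,
              ampm_misreport_rate = ampm_misreport_rate,
              one_code_rate = one_code_rate,
              window_violation_rate = window_violation_rate,
              related_pair_rate = related_pair_rate,
              confounding_strength = confounding_strength,
              component_base_probs = component_base_probs[index_components()],
              n_pcs = as.integer(n_pcs),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# time-in-bed pair grid (hours, half-hour steps), partitioned by the
# (adequate, regular) component pair of the weighted weekly value
tib_pair_groups <- function() {
  t_vals <- seq(3, 12, by = 0.5)
  pairs <- expand.grid(t_wd = t_vals, t_we = t_vals, KEEP.OUT.ATTRS = FALSE)
  wt <- (5 * pairs$t_wd + 2 * pairs$t_we) / 7
  adequate <- wt >= 7 & wt <= 9
  regular <- abs(pairs$t_wd - pairs$t_we) < 1
  split(pairs, paste(as.integer(adequate), as.integer(regular)))
}

# uniform draw from the 30-minute ladder {first + 30k} within [first, hi]
sample_ladder <- function(first, hi) {
  count <- pmax(0L, floor((hi - first) / 30) + 1L)
  if (any(count == 0)) stop("empty quantization ladder (internal error)")
  first + 30 * floor(stats::runif(length(first)) * count)
}

# realise half-hour-grid bed/wake times whose derived traits reproduce the
# four survey component targets exactly (no rounding after construction)
realize_survey_times <- function(c_adequate, c_regular, c_midpoint, c_jetlag) {
  n <- length(c_adequate)
  groups <- tib_pair_groups()
  grp_key <- paste(c_adequate, c_regular)
  t_wd <- numeric(n); t_we <- numeric(n)
  for (key in unique(grp_key)) {
    members <- which(grp_key == key)
    g <- groups[[key]]
    sel <- sample.int(nrow(g), length(members), replace = TRUE)
    t_wd[members] <- g$t_wd[sel]
    t_we[members] <- g$t_we[sel]
  }

  # weekend midpoint (minutes): favorable on [120, 240] closed, otherwise in
  # [0, 105] or [270, 420]; constrained to the ladder compatible with bed and
  # wake landing on the half-hour grid
  r_we <- (t_we * 30) %% 30
  m_we <- numeric(n)
  fav <- c_midpoint == 1
  m_we[fav] <- sample_ladder(120 + r_we[fav], 240)
  if (any(!fav)) {
    early <- stats::runif(sum(!fav)) < 0.4
    first <- ifelse(early, r_we[!fav], 270 + r_we[!fav])
    hi <- ifelse(early, 105, 420)
    m_we[!fav] <- sample_ladder(first, hi)
  }

  # social jetlag offset s (minutes): favorable < 120, unfavorable in
  # [120, 210]; ladder residue depends on the sign of the weekday shift
  sigma <- ifelse(m_we <= 210, 1, -1)
  rho <- (t_wd * 30) %% 30
  s0 <- ifelse(sigma == 1, (rho - m_we) %% 30, (m_we - rho) %% 30)
  s <- ifelse(c_jetlag == 1,
              sample_ladder(s0, 105),
              sample_ladder(120 + s0, 210))
  m_wd <- m_we + sigma * s

  data.frame(
    weekday_bed = (m_wd - t_wd * 30) %% 1440,
    weekday_wake = (m_wd + t_wd * 30) %% 1440,
    weekend_bed = (m_we - t_we * 30) %% 1440,
    weekend_wake = (m_we + t_we * 30) %% 1440
  )
}

# move a fraction of bedtimes into the implausible 08:00-14:00 window:
# a 12-hour shift where that lands in the window, else a uniform grid draw
contaminate_bedtimes <- function(bed, rate) {
  hit <- stats::runif(length(bed)) < rate
  if (any(hit)) {
    shifted <- (bed[hit] + 720) %% 1440
    in_window <- shifted >= 480 & shifted <= 840
    shifted[!in_window] <- 480 + 30 * floor(stats::runif(sum(!in_window)) * 13)
    bed[hit] <- shifted
  }
  attr(bed, "n_contaminated") <- sum(hit)
  bed
}

# solve the logistic intercept so mean(plogis(alpha + eta)) = prevalence
solve_alpha <- function(eta, prevalence, phecode) {
  f <- function(a) mean(stats::plogis(a + eta)) - prevalence
  if (f(-20) > 0 || f(20) < 0) {
    stop("cannot achieve prevalence ", prevalence, " for outcome ", phecode,
         ": required intercept outside [-20, 20] on the logit scale")
  }
  stats::uniroot(f, c(-20, 20), tol = 1e-10)$root
}

#' Simulate a synthetic biobank cohort with planted effects
#'
#' Generates all eight input tables of the analysis pipeline -- participants
#' with demographics and covariates, a sleep survey on the half-hour grid,
#' genotype dosages with a variant weight table, ICD and medication event
#' streams, and kinship pairs -- with known planted effect sizes recorded in
#' `truth` so that every downstream stage can be validated by parameter
#' recovery.
#'
#' The planted polygenic-score effect on the lifestyle index uses a
#' linear-probability liability: each of the eight components is favorable
#' with probability `base + (prs_index_beta / 8) * PRS_std` (clipped to
#' `[0.01, 0.99]`), so the expected index is linear in the score with slope
#' `prs_index_beta`. Bed/wake times are then constructed exactly on the
#' half-hour grid to realise the drawn survey components, and EHR events are
#' emitted to realise the disorder/medication components. Disease outcomes
#' follow the logistic model documented in [outcome_spec()]; cases receive
#' two dated billing codes within the window (minus the engineered
#' `one_code_rate` and `window_violation_rate` fractions), controls none.
#'
#' @param config a [sim_config()].
#' @param map phecode map used to pick billing codes for outcomes (default
#'   [toy_phecode_map()]).
#' @param classification sleep code classification used for disorder and
#'   medication events (default [toy_sleep_classification()]).
#' @return object of class `synthetic_cohort`: list with `participants`,
#'   `survey`, `dosages` (matrix with `counted_allele` attribute), `weights`,
#'   `icd_events`, `med_events`, `kinship_pairs` and `truth` (the config plus
#'   solved intercepts and the per-participant planted index and score).
#' @export
simulate_cohort <- function(config, map = toy_phecode_map(),
                            classification = toy_sleep_classification()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_participants
  ids <- sprintf("P%06d", seq_len(n))

  ## participants -----------------------------------------------------------
  age <- round(pmin(pmax(stats::rnorm(n, 54.4, 16.3), 20), 90))
  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.586, 0.414))
  participants <- data.frame(
    participant_id = ids, age = age, sex = sex,
    array = sample(c("GSA-A", "GSA-B"), n, replace = TRUE),
    batch = sample(sprintf("B%02d", 1:4), n, replace = TRUE),
    stringsAsFactors = FALSE)
  for (k in seq_len(config$n_pcs)) {
    participants[[paste0("PC", k)]] <- stats::rnorm(n)
  }
  participants$employment <- sample(c("employed", "retired", "unemployed"),
                                    n, replace = TRUE, prob = c(0.55, 0.35, 0.10))
  participants$education <- sample(c("college", "graduate", "high_school"),
                                   n, replace = TRUE, prob = c(0.4, 0.3, 0.3))
  participants$exercise <- round(stats::rexp(n, 1 / 3), 1)
  participants$smoking <- sample(c("never", "former", "current"),
                                 n, replace = TRUE, prob = c(0.55, 0.35, 0.10))
  participants$alcohol <- sample(c("none", "moderate", "heavy"),
                                 n, replace = TRUE, prob = c(0.3, 0.6, 0.1))
  participants$bmi <- round(pmin(pmax(stats::rnorm(n, 27, 5), 16), 55), 1)
  participants$comorbidity <- stats::rpois(n, 0.8)
  survey_date <- as.Date("2017-06-15") + sample.int(1401, n, replace = TRUE) - 701
  participants$survey_date <- survey_date

  ## genotypes and weights --------------------------------------------------
  m <- config$n_variants
  freqs <- stats::runif(m, config$allele_freq_range[1], config$allele_freq_range[2])
  dosages <- matrix(stats::rbinom(n * m, 2, rep(freqs, each = n)), nrow = n,
                    dimnames = list(ids, sprintf("v%04d", seq_len(m))))
  bases <- c("A", "C", "G", "T")
  effect_allele <- sample(bases, m, replace = TRUE)
  other_allele <- vapply(effect_allele,
                         function(a) sample(setdiff(bases, a), 1), "")
  weights <- data.frame(variant_id = colnames(dosages),
                        effect_allele = effect_allele,
                        other_allele = other_allele,
                        weight = stats::rnorm(m, 0, 0.05),
                        stringsAsFactors = FALSE)
  # counted allele: mostly the effect allele, some flipped, a few mismatched
  # (exercising the harmonization drop path)
  counted_class <- sample(c("effect", "other", "mismatch"), m, replace = TRUE,
                          prob = c(0.86, 0.10, 0.04))
  counted <- ifelse(counted_class == "effect", effect_allele,
             ifelse(counted_class == "other", other_allele,
                    vapply(seq_len(m), function(i)
                      sample(setdiff(bases, c(effect_allele[i], other_allele[i])), 1), "")))
  names(counted) <- colnames(dosages)
  attr(dosages, "counted_allele") <- counted

  scores <- suppressWarnings(harmonize_and_score(weights, dosages))
  # degenerate micro-cohorts can carry zero score variance; plant a null
  # score rather than refusing to simulate
  prs_std <- tryCatch(standardize_scores(scores)$standardized,
                      error = function(e) rep(0, n))

  ## index components via linear-probability liability ----------------------
  conf <- config$confounding_strength *
    (0.002 * (age - 55) - 0.004 * (participants$bmi - 27))
  base <- config$component_base_probs
  comp <- matrix(NA_real_, n, 8, dimnames = list(ids, index_components()))
  for (k in seq_len(8)) {
    p <- pmin(pmax(base[k] + (config$prs_index_beta / 8) * prs_std + conf, 0.01), 0.99)
    comp[, k] <- stats::rbinom(n, 1, p)
  }
  index_true <- rowSums(comp)

  ## survey realization -----------------------------------------------------
  times <- realize_survey_times(comp[, "adequate_tib"], comp[, "regular_tib"],
                                comp[, "healthy_midpoint"],
                                comp[, "low_social_jetlag"])
  wd_bed <- contaminate_bedtimes(times$weekday_bed, config$ampm_misreport_rate)
  we_bed <- contaminate_bedtimes(times$weekend_bed, config$ampm_misreport_rate)
  n_contaminated <- attr(wd_bed, "n_contaminated") + attr(we_bed, "n_contaminated")
  survey <- data.frame(
    participant_id = ids,
    weekday_bed = as.numeric(wd_bed), weekday_wake = times$weekday_wake,
    weekend_bed = as.numeric(we_bed), weekend_wake = times$weekend_wake,
    completion_date = survey_date,
    stringsAsFactors = FALSE)

  ## EHR events: sleep disorder flags and medications -----------------------
  icd_list <- list()
  class_icd <- classification[classification$code_type %in% c("icd9", "icd10"), ]
  emit_category <- function(unfavorable_ids, category) {
    rows <- class_icd[class_icd$category == category, ]
    if (nrow(rows) == 0 || length(unfavorable_ids) == 0) return(NULL)
    k <- length(unfavorable_ids)
    ref <- survey_date[match(unfavorable_ids, ids)]
    off1 <- sample(-1800:1800, k, replace = TRUE)
    gap <- sample(30:400, k, replace = TRUE)
    # reflect at the window edge so the second date stays inside and distinct
    off2 <- ifelse(off1 + gap > 1800, off1 - gap, off1 + gap)
    # two codes on two distinct dates within the window
    pick <- sample.int(nrow(rows), 2 * k, replace = TRUE)
    data.frame(
      participant_id = rep(unfavorable_ids, 2),
      icd_version = ifelse(rows$code_type[pick] == "icd9", 9L, 10L),
      code = rows$code[pick],
      date = c(ref + off1, ref + off2),
      stringsAsFactors = FALSE)
  }
  icd_list$insomnia <- emit_category(ids[comp[, "no_insomnia_disorder"] == 0], "insomnia")
  icd_list$breathing <- emit_category(ids[comp[, "no_breathing_disorder"] == 0], "breathing")
  icd_list$other <- emit_category(ids[comp[, "no_other_sleep_disorder"] == 0], "other_sleep")

  med_codes <- classification$code[classification$category == "medication"]
  med_ids <- ids[comp[, "no_sleep_medication"] == 0]
  med_events <- data.frame(
    participant_id = med_ids,
    code = sample(med_codes, length(med_ids), replace = TRUE),
    date = survey_date[match(med_ids, ids)] +
      sample(-1800:1800, length(med_ids), replace = TRUE),
    stringsAsFactors = FALSE)

  ## disease outcomes -------------------------------------------------------
  truth_alphas <- numeric(0)
  gamma <- config$confounding_strength *
    (0.01 * (age - 55) + 0.2 * (sex == "F"))
  for (spec in config$outcome_specs) {
    eta <- log(spec$or_per_sd_prs) * prs_std +
      log(spec$or_per_index_unit) * index_true +
      spec$interaction_log_or * prs_std * index_true + gamma
    alpha <- solve_alpha(eta, spec$prevalence, spec$phecode)
    truth_alphas[spec$phecode] <- alpha
    y <- stats::rbinom(n, 1, stats::plogis(alpha + eta))
    case_ids <- ids[y == 1]
    k <- length(case_ids)
    if (k == 0) next
    rows <- map[map$phecode_id == spec$phecode, ]
    if (nrow(rows) == 0) stop("outcome phecode ", spec$phecode, " absent from map")
    ref <- survey_date[match(case_ids, ids)]
    off1 <- sample(-1800:1800, k, replace = TRUE)
    off2 <- sample(-1800:1800, k, replace = TRUE)
    # engineered record-quality defects
    one_code <- stats::runif(k) < config$one_code_rate
    violate <- !one_code & stats::runif(k) < config$window_violation_rate
    off2[violate] <- sample(1900:2400, sum(violate), replace = TRUE) *
      sample(c(-1, 1), sum(violate), replace = TRUE)
    pick1 <- sample.int(nrow(rows), k, replace = TRUE)
    pick2 <- sample.int(nrow(rows), k, replace = TRUE)
    ev <- rbind(
      data.frame(participant_id = case_ids,
                 icd_version = rows$icd_version[pick1],
                 code = rows$icd_code[pick1],
                 date = ref + off1, stringsAsFactors = FALSE),
      data.frame(participant_id = case_ids[!one_code],
                 icd_version = rows$icd_version[pick2][!one_code],
                 code = rows$icd_code[pick2][!one_code],
                 date = (ref + off2)[!one_code], stringsAsFactors = FALSE))
    icd_list[[paste0("outcome_", spec$phecode)]] <- ev
  }

  icd_events <- do.call(rbind, icd_list[!vapply(icd_list, is.null, TRUE)])
  if (is.null(icd_events)) {
    icd_events <- data.frame(participant_id = character(0),
                             icd_version = integer(0), code = character(0),
                             date = as.Date(character(0)),
                             stringsAsFactors = FALSE)
  }
  # a sprinkle of same-day duplicates, removed again by deduplication
  if (nrow(icd_events) > 0) {
    dup <- icd_events[stats::runif(nrow(icd_events)) < 0.02, , drop = FALSE]
    icd_events <- rbind(icd_events, dup)
  }
  ord <- order(icd_events$participant_id, icd_events$date, icd_events$code)
  icd_events <- icd_events[ord, , drop = FALSE]
  rownames(icd_events) <- NULL

  ## kinship ----------------------------------------------------------------
  n_rel <- floor(config$related_pair_rate * n)
  kin <- NULL
  if (n_rel > 0 && n >= 4) {
    pick <- matrix(sample(ids, 4 * n_rel, replace = TRUE), ncol = 2)
    pick <- pick[pick[, 1] != pick[, 2], , drop = FALSE]
    pick <- utils::head(pick, 2 * n_rel)
    coefs <- rep(c(0.25, 0.04), length.out = nrow(pick))
    kin <- data.frame(id_a = pmin(pick[, 1], pick[, 2]),
                      id_b = pmax(pick[, 1], pick[, 2]),
                      coefficient = coefs, stringsAsFactors = FALSE)
    kin <- kin[!duplicated(paste(kin$id_a, kin$id_b)), , drop = FALSE]
    rownames(kin) <- NULL
  }
  if (is.null(kin)) {
    kin <- data.frame(id_a = character(0), id_b = character(0),
                      coefficient = numeric(0), stringsAsFactors = FALSE)
  }

  truth <- list(
    config = config,
    alphas = truth_alphas,
    prs_std = stats::setNames(prs_std, ids),
    index_true = stats::setNames(index_true, ids),
    components_true = comp,
    n_contaminated_bedtimes = n_contaminated,
    generative_path = paste(
      "linear-probability liability: component favorable prob =",
      "base + (prs_index_beta/8)*PRS_std + confounding, clipped to [0.01,0.99]"))

  out <- list(participants = participants, survey = survey, dosages = dosages,
              weights = weights, icd_events = icd_events,
              med_events = med_events, kinship_pairs = kin, truth = truth)
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cfg <- x$truth$config
  cat("Synthetic biobank cohort:", nrow(x$participants), "participants,",
      cfg$n_variants, "variants\n")
  cat("  planted PRS->index beta:", cfg$prs_index_beta, "per SD\n")
  for (spec in cfg$outcome_specs) {
    cat(sprintf("  outcome %s: prevalence %.2f, OR/SD(PRS) %.2f, OR/unit(index) %.2f, interaction logOR %.2f\n",
                spec$phecode, spec$prevalence, spec$or_per_sd_prs,
                spec$or_per_index_unit, spec$interaction_log_or))
  }
  cat("  events:", nrow(x$icd_events), "ICD,", nrow(x$med_events),
      "medication;", nrow(x$kinship_pairs), "kinship pairs\n")
  invisible(x)
}
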
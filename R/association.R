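#' Covariate sets for the two adjustment models
#'
#' The primary model for polygenic-score analyses adjusts for age, sex,
#' genotyping array, batch and ancestry principal components; the fully
#' adjusted model further adds employment, education, exercise, smoking,
#' alcohol intake, body mass index and a comorbidity index. Lifestyle-index
#' PheWAS models use age, sex and the lifestyle/comorbidity block (no
#' genotyping technical covariates).
#'
#' @param label one of `"primary"`, `"fully_adjusted"`, `"index_phewas"`.
#' @param n_pcs number of ancestry principal-component columns (named
#'   `PC1..PCk`).
#' @return character vector of covariate column names.
#' @export
covariate_set <- function(label = c("primary", "fully_adjusted", "index_phewas"),
                          n_pcs = 5) {
  label <- match.arg(label)
  genetic <- c("age", "sex", "array", "batch", paste0("PC", seq_len(n_pcs)))
  lifestyle <- c("employment", "education", "exercise", "smoking", "alcohol",
                 "bmi", "comorbidity")
  switch(label,
         primary = genetic,
         fully_adjusted = c(genetic, lifestyle),
         index_phewas = c("age", "sex", lifestyle))
}

# categorical covariates get deterministic (sorted) level order,
# first level as reference
as_model_frame <- function(data, vars) {
  df <- data[, vars, drop = FALSE]
  for (v in names(df)) {
    if (is.character(df[[v]]) || is.logical(df[[v]])) {
      df[[v]] <- factor(df[[v]], levels = sort(unique(df[[v]])))
    }
  }
  df
}

unfit_result <- function(outcome, exposure, family, label, n = 0L, n_cases = NA_integer_) {
  structure(data.frame(
    outcome = outcome, exposure = exposure,
    estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
    p = NA_real_, n = n, n_cases = n_cases,
    family = family, model = label,
    significant = NA, converged = FALSE,
    stringsAsFactors = FALSE), class = c("assoc_result", "data.frame"))
}

#' Fit one association model
#'
#' Maximum-likelihood linear or logistic regression of `outcome` on
#' `exposure` plus covariates, reporting the exposure coefficient with a Wald
#' 95% confidence interval and two-sided Wald p-value. Logistic estimates are
#' exponentiated to odds ratios. Complete-case rows only; for logistic models
#' the outcome must be 0/1 (`NA` rows -- excluded phenotype status -- are
#' dropped). Separation or non-convergence (any coefficient beyond 15 on the
#' logit scale, or IRLS not converged within 100 iterations) yields
#' `converged = FALSE` with all statistics `NA`; so does a design with fewer
#' cases than estimated parameters.
#'
#' @param data data.frame holding outcome, exposure and covariate columns.
#' @param outcome,exposure column names; `exposure` may be an interaction
#'   written `"a:b"`, in which case main effects for `a` and `b` are included
#'   and the product-term coefficient is reported.
#' @param covariates character vector of covariate column names.
#' @param family `"logistic"` or `"linear"`.
#' @param label model label carried into the result (e.g. `"primary"`).
#' @param alpha significance level used for the `significant` flag
#'   (uncorrected here; scans apply their own Bonferroni threshold).
#' @return one-row data.frame of class `assoc_result`: `outcome`, `exposure`,
#'   `estimate` (beta or OR), `ci_low`, `ci_high`, `p`, `n`, `n_cases`,
#'   `family`, `model`, `significant`, `converged`.
#' @export
fit_assoc <- function(data, outcome, exposure, covariates = character(),
                      family = c("logistic", "linear"), label = "primary",
                      alpha = 0.05) {
  family <- match.arg(family)
  is_interaction <- grepl(":", exposure, fixed = TRUE)
  exp_vars <- strsplit(exposure, ":", fixed = TRUE)[[1]]
  vars <- unique(c(outcome, exp_vars, covariates))
  df <- as_model_frame(data, vars)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  n_cases <- if (family == "logistic") sum(df[[outcome]] == 1) else NA_integer_

  rhs <- paste(c(if (is_interaction) c(exp_vars, exposure) else exposure,
                 covariates), collapse = " + ")
  fml <- stats::as.formula(paste0("`", outcome, "` ~ ", rhs))

  n_params <- length(exp_vars) + is_interaction + length(covariates) + 1
  if (n == 0 || (family == "logistic" && (n_cases < n_params || n_cases == n))) {
    return(unfit_result(outcome, exposure, family, label, n, n_cases))
  }

  fit <- tryCatch({
    if (family == "logistic") {
      stats::glm(fml, data = df, family = stats::binomial(),
                 control = stats::glm.control(epsilon = 1e-10, maxit = 100))
    } else {
      stats::lm(fml, data = df)
    }
  }, error = function(e) NULL, warning = function(w) {
    # refit, keeping the object; glm warns on separation-ish fits
    suppressWarnings(if (family == "logistic") {
      stats::glm(fml, data = df, family = stats::binomial(),
                 control = stats::glm.control(epsilon = 1e-10, maxit = 100))
    } else {
      stats::lm(fml, data = df)
    })
  })
  if (is.null(fit)) return(unfit_result(outcome, exposure, family, label, n, n_cases))

  cf <- stats::coef(fit)
  term <- if (is_interaction) grep(":", names(cf), fixed = TRUE, value = TRUE)[1]
          else names(cf)[2]
  se_all <- tryCatch(suppressWarnings(sqrt(diag(stats::vcov(fit)))),
                     error = function(e) NULL)
  converged <- !is.null(se_all) && !anyNA(cf) &&
    (family == "linear" || (isTRUE(fit$converged) && all(abs(cf) <= 15)))
  if (!converged || is.na(cf[term]) || is.na(se_all[term]) || se_all[term] == 0) {
    return(unfit_result(outcome, exposure, family, label, n, n_cases))
  }

  beta <- cf[[term]]
  se <- se_all[[term]]
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  lo <- beta - 1.96 * se
  hi <- beta + 1.96 * se
  if (family == "logistic") {
    est <- exp(beta); lo <- exp(lo); hi <- exp(hi)
  } else {
    est <- beta
  }
  structure(data.frame(
    outcome = outcome, exposure = exposure,
    estimate = est, ci_low = lo, ci_high = hi, p = p,
    n = n, n_cases = n_cases, family = family, model = label,
    significant = p < alpha, converged = TRUE,
    stringsAsFactors = FALSE), class = c("assoc_result", "data.frame"))
}

#' @export
print.assoc_result <- function(x, ...) {
  lab <- if (x$family == "logistic") "OR" else "beta"
  cat(sprintf("%s ~ %s [%s]: %s = %.3f (95%% CI %.3f, %.3f), p = %.3g, n = %d%s%s\n",
              x$outcome, x$exposure, x$model, lab,
              x$estimate, x$ci_low, x$ci_high, x$p, x$n,
              if (!is.na(x$n_cases)) paste0(", cases = ", x$n_cases) else "",
              if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}

#' Phenome-wide association scan
#'
#' Fits one logistic model per retained phecode (phecodes with at least
#' `min_cases` cases; see [call_phecodes()]) regressing case/control status
#' on the exposure plus covariates, and applies a Bonferroni threshold of
#' `alpha / n_tests`, where `n_tests` counts every retained phecode whether
#' or not its fit converged (conservative).
#'
#' @param calls a `phecode_calls` object.
#' @param data per-participant data.frame with `participant_id`, the exposure
#'   column and covariate columns.
#' @param exposure exposure column name (e.g. `"prs_std"` or `"index"`).
#' @param covariates character vector of covariate column names.
#' @param alpha family-wise error rate (default 0.05).
#' @param label model label.
#' @return object of class `phewas_scan`: list with `results` (one row per
#'   phecode, sorted by p, with `disease_group`, `neg_log10_p` and
#'   `direction` columns ready for Manhattan/Miami plotting), `n_tests`,
#'   `alpha`, `alpha_corrected`, `n_significant`, `exposure`, `model`.
#' @export
run_phewas <- function(calls, data, exposure, covariates = character(),
                       alpha = 0.05, label = "primary") {
  retained <- calls$retained
  if (length(retained) == 0) stop("no phecodes retained: empty scan")
  rows <- vector("list", length(retained))
  for (i in seq_along(retained)) {
    ph <- retained[i]
    status <- phecode_status(calls, ph)
    d <- data
    d$.status <- status[match(as.character(d$participant_id), names(status))]
    rows[[i]] <- fit_assoc(d, ".status", exposure, covariates,
                           family = "logistic", label = label, alpha = alpha)
  }
  res <- do.call(rbind, rows)
  res$outcome <- retained
  info <- calls$phecodes[match(retained, calls$phecodes$phecode_id), ]
  res$phecode_label <- info$phecode_label
  res$disease_group <- info$disease_group

  n_tests <- length(retained)
  alpha_corrected <- alpha / n_tests
  res$significant <- !is.na(res$p) & res$p < alpha_corrected
  res$neg_log10_p <- -log10(res$p)
  res$direction <- ifelse(is.na(res$estimate), NA_character_,
                          ifelse(res$estimate >= 1, "up", "down"))
  res <- res[order(res$p), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- "data.frame"

  out <- list(results = res, n_tests = n_tests, alpha = alpha,
              alpha_corrected = alpha_corrected,
              n_significant = sum(res$significant),
              exposure = exposure, model = label)
  class(out) <- "phewas_scan"
  out
}

#' @export
print.phewas_scan <- function(x, ...) {
  cat("PheWAS scan of", x$n_tests, "phecodes on exposure '", x$exposure,
      "' [", x$model, " model]\n", sep = "")
  cat(sprintf("  Bonferroni threshold: %.3g (alpha = %.2f); %d significant\n",
              x$alpha_corrected, x$alpha, x$n_significant))
  top <- utils::head(x$results, 5)
  for (i in seq_len(nrow(top))) {
    cat(sprintf("  %-12s %-28s OR %.3f (%.3f, %.3f)  p %.3g%s\n",
                top$outcome[i], substr(top$phecode_label[i], 1, 28),
                top$estimate[i], top$ci_low[i], top$ci_high[i], top$p[i],
                if (isTRUE(top$significant[i])) " *" else ""))
  }
  invisible(x)
}

#' @export
summary.phewas_scan <- function(object, ...) {
  res <- object$results
  by_group <- table(res$disease_group[res$significant])
  out <- list(n_tests = object$n_tests,
              alpha_corrected = object$alpha_corrected,
              n_significant = object$n_significant,
              n_converged = sum(res$converged),
              significant_by_group = by_group)
  class(out) <- "summary.phewas_scan"
  out
}

#' @export
print.summary.phewas_scan <- function(x, ...) {
  cat("PheWAS:", x$n_tests, "tests,", x$n_converged, "converged,",
      x$n_significant, "significant at", format(x$alpha_corrected, digits = 3), "\n")
  if (length(x$significant_by_group)) {
    cat("Significant outcomes by disease group:\n")
    print(x$significant_by_group)
  }
  invisible(x)
}

#' @export
as.data.frame.phewas_scan <- function(x, ...) x$results

#' Manhattan plot of a PheWAS scan
#'
#' Base-graphics Manhattan plot: outcomes grouped and coloured by disease
#' group on the x axis, `-log10(p)` on the y axis, upward/downward triangles
#' for odds ratios above/below 1, and a horizontal line at the Bonferroni
#' threshold.
#'
#' @param x a `phewas_scan`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.phewas_scan <- function(x, ...) {
  res <- x$results[!is.na(x$results$p), , drop = FALSE]
  res <- res[order(res$disease_group, res$outcome), , drop = FALSE]
  grp <- factor(res$disease_group)
  graphics::plot(seq_len(nrow(res)), res$neg_log10_p,
                 col = as.integer(grp) %% 8 + 1,
                 pch = ifelse(res$direction == "up", 24, 25),
                 bg = as.integer(grp) %% 8 + 1,
                 xlab = "disease outcomes (by group)",
                 ylab = expression(-log[10](p)),
                 main = paste("PheWAS:", x$exposure, "-", x$model, "model"), ...)
  graphics::abline(h = -log10(x$alpha_corrected), col = "red", lty = 2)
  invisible(x)
}

#' Polygenic-score by lifestyle-index interaction test
#'
#' Logistic model of a case/control outcome on the polygenic score, the
#' lifestyle index, their product term, and covariates; reports the
#' interaction odds ratio with Wald confidence interval and p-value.
#'
#' @param data data.frame with outcome (0/1/NA), score, index and covariates.
#' @param outcome,prs,index column names.
#' @param covariates covariate column names.
#' @param label model label (`"primary"` or `"fully_adjusted"`).
#' @return an `assoc_result` row for the product term.
#' @export
test_interaction <- function(data, outcome, prs = "prs_std", index = "index",
                             covariates = character(), label = "primary") {
  fit_assoc(data, outcome, paste(prs, index, sep = ":"), covariates,
            family = "logistic", label = label)
}

#' Association between the polygenic score and the lifestyle index
#'
#' Linear regression of the 0-8 index on the standardized polygenic score
#' (beta per SD), plus one logistic regression per binary index component on
#' the score, each under the supplied covariate sets.
#'
#' @param data per-participant data.frame with `index`, the component
#'   columns, the score and covariates.
#' @param prs score column name.
#' @param components component column names (default the eight index
#'   components).
#' @param covariate_sets named list of covariate vectors, one model per
#'   entry (e.g. `list(primary = ..., fully_adjusted = ...)`).
#' @return data.frame of `assoc_result` rows.
#' @export
index_prs_association <- function(data, prs = "prs_std",
                                  components = index_components(),
                                  covariate_sets = list(
                                    primary = covariate_set("primary"),
                                    fully_adjusted = covariate_set("fully_adjusted"))) {
  rows <- list()
  for (label in names(covariate_sets)) {
    covs <- covariate_sets[[label]]
    rows[[length(rows) + 1]] <-
      fit_assoc(data, "index", prs, covs, family = "linear", label = label)
    for (comp in components) {
      rows[[length(rows) + 1]] <-
        fit_assoc(data, comp, prs, covs, family = "logistic", label = label)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate.
#' @param n_tests number of tests in the scan.
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_threshold(0.05, 898) # ~5.57e-5
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(n_tests >= 1)
  alpha / n_tests
}
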
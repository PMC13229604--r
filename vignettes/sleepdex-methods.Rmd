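---
title: "Multidimensional sleep health: models, rules and validation in sleepdex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multidimensional sleep health: models, rules and validation in sleepdex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepdex)
```

# The problem

Sleep is increasingly analysed as a multidimensional construct rather than a
single trait. `sleepdex` implements a complete biobank-style analysis of
multidimensional sleep: a behavioral **Sleep Lifestyle Index** built from
self-reported bed/wake clock times plus electronic health record (EHR)
billing codes, a **polygenic sleep health score** computed from an external
variant weight table, phecode-based case/control **phenotyping**, two
**phenome-wide association scans** (PheWAS), and **score-by-index
interaction tests** on mental-health outcomes. Because the clinical data
such analyses run on are access-restricted, the package ships a synthetic
cohort generator with *planted* effect sizes, so every stage can be
validated end to end by parameter recovery rather than by comparison to
unavailable patient records.

# The Sleep Lifestyle Index

## Cleaning self-reported clock times

Survey bed/wake times arrive in half-hour increments (values off the grid
are flagged, not rejected). Two misreport patterns dominate this kind of
survey data, both AM/PM confusions:

* bedtimes reported between **08:00 and 14:00** (closed interval) are set
  missing;
* wake times reported between **18:00 and 24:00** are set missing. We read
  this window as `[18:00, 24:00)`: midnight itself (00:00) is a plausible
  wake time and is retained. Both bounds are arguments of `clean_survey()`.

Cleaning is total — it never errors — and each rule's removal count is
returned for audit (`drop_counts`).

## Derived traits and circular arithmetic

All clock arithmetic happens on the 1440-minute dial:

* **time in bed** is the forward (clockwise) interval from bed to wake,
  `((wake − bed) mod 24h)`; durations under 3 h or over 18 h are
  implausible and set missing;
* **weighted weekly time in bed** is `(5·weekday + 2·weekend) / 7`;
* **irregularity** is the absolute weekday–weekend difference of time in
  bed (a plain difference of durations — no circularity is involved);
* the **sleep midpoint** is the clock time halfway along the forward
  bed→wake interval;
* **social jetlag** is the absolute difference between weekend and weekday
  midpoints. "Absolute difference" is ambiguous for clock times near
  midnight: 23:00 vs 01:00 could be read as 22 h or 2 h. We use the
  **circular distance** (capped at 12 h), since the quantity of interest is
  how far the two midpoints sit apart on the dial. This was a genuinely
  open design choice; the linear reading would misclassify every
  midnight-straddling pair.

The weekday midpoint, needed only for social jetlag, is computed by the
same formula as the weekend midpoint on weekday times. Traits are computed
only when every contributing time survived cleaning; nothing is imputed.

## The eight components and the 0–8 index

One point per favorable behavior, with cut-points following their printed
symbols exactly:

| component | favorable when | boundary |
|---|---|---|
| adequate time in bed | weighted TIB in `[7, 9]` h | closed |
| regular time in bed | irregularity `< 1` h | strict |
| healthy sleep midpoint | weekend midpoint in `[02:00, 04:00]` | closed |
| low social jetlag | `< 2` h | strict |
| no sleep medication | no listed medication event in window | — |
| no insomnia disorder | EHR flag absent | — |
| no breathing disorder | EHR flag absent | — |
| no other sleep disorder | EHR flag absent | — |

The midpoint window is read as closed (both 02:00 and 04:00 favorable) and
documented as such. A disorder flag is *missing* when the participant has
codes on exactly one date; the corresponding component is then missing.
**A missing component makes the whole index missing** (complete-case
aggregation). The alternative — prorating over observed components — would
silently change the index's scale across participants, so it was rejected;
this mirrors restricting analysis to complete responders.

# Phenotyping from billing codes

`deduplicate_events()` removes same-day duplicated diagnoses and non-ICD-9/10
rows. The diagnosis window is **symmetric and closed**: events within
±`window_years` (default 5) calendar years of the participant's survey
completion date count, the boundary dates included. Calendar-year
arithmetic is used (a Feb 29 anchor normalises to Mar 1); the symmetric
reading supports cross-sectional analysis, where conditions present around
the time of the survey are the target. Participants with events but no
reference date are reported as unusable, never silently dropped; their
status is missing.

The case rule is deliberately simple and matches standard windowed
phenotyping: **≥ 2** qualifying codes → case, **0** → control, exactly
**1** → excluded. For the general phecode calls the two codes need not fall
on distinct dates (after deduplication, same-day double counting is
impossible anyway); the EHR *sleep-disorder flags* additionally require two
**distinct dates**, and medication exposure needs a single listed event.
Phecodes with fewer than `min_cases` (default 100) cases are dropped from
the scan's retained list, though their calls remain available. Control
exclusion ranges of standard phecode maps are intentionally not
implemented: the two-code/zero-code rule is the whole contract here.

# The polygenic score

`harmonize_and_score()` aligns each dosage column's counted allele with the
weight table: matching effect allele uses the dosage as-is, matching other
allele flips it to `2 − d`, anything else drops the variant with a count
(an error if nothing overlaps, a warning past 50% dropped). The raw score
is the weighted dosage sum. `standardize_scores()` centers and scales to
mean 0, SD 1 over the analytic sample using the **n − 1** (sample SD)
denominator — the conventional choice, pinned by tests. Relatedness
pruning (`prune_related()`) removes vertices of the kinship graph
(coefficient strictly `> 0.0625`) greedily by descending degree until no
related pair survives; ties are broken by removing the lexicographically
largest id, making the output deterministic. Pruning runs before
standardization by default (the score scale is then defined on the
unrelated analytic sample); the standardization sample is an explicit
argument, so the other order is available. PRS shrinkage, imputation and
ancestry PCs are upstream of this package: the weight table is an input
contract.

# Association models

All fits are maximum-likelihood `lm()`/`glm()` fits with **Wald** 95%
confidence intervals (`estimate ± 1.96·SE`, exponentiated for logistic
models) and two-sided Wald p-values, matching standard PheWAS reporting.
Two covariate sets mirror common biobank practice: the *primary* model for
genetic exposures (age, sex, array, batch, ancestry PCs) and the *fully
adjusted* model adding employment, education, exercise, smoking, alcohol,
BMI and a comorbidity index; index-PheWAS models use age, sex and the
lifestyle/comorbidity block. Categorical covariates get deterministic
(sorted) level ordering with first-level reference.

Numerical sentinels: IRLS tolerance `1e-10` with up to 100 iterations; a
fit is flagged non-converged when `glm` fails to converge, any coefficient
exceeds 15 on the logit scale (separation), or the design has fewer cases
than parameters. Non-converged outcomes stay in `n_tests`, so the
Bonferroni threshold `alpha / n_tests` is conservative. Scans report a
plot-ready table (disease group, −log10 p, direction) and a significance
flag `p < alpha / n_tests`.

Interaction tests add a product term to the logistic model with both main
effects. The outcomes carried into interaction testing are the top
mental-health phecodes significant for **both** exposures (smallest
combined p first, five by default); an explicit outcome list can be
supplied instead.

# The synthetic cohort generator

The generator emulates the eight input tables of a survey-linked clinical
biobank. Its defaults are the package's reference study conditions: a
survey-responder cohort (ages ~54 ± 16, 59% female), sleep-disorder flag
prevalences in the low single-digit percent range, roughly a fifth of
participants holding all eight favorable behaviors, a 2% AM/PM misreport
rate, and 1% rates for the engineered record-quality defects (single-code
cases and out-of-window codes). Variants are independent binomial dosages
(allele frequencies uniform on a configurable range) with Gaussian weights
and a small fraction of flipped or mismatched counted alleles to exercise
harmonization.

Two planting mechanisms matter:

* **Score → index.** Each of the eight components is favorable with
  probability `base + (β/8)·PRS_std` plus a mild age/BMI confounding term,
  clipped to `[0.01, 0.99]` (a linear-probability liability). The expected
  index is then *exactly* linear in the standardized score with slope `β`.
  Bed/wake times are constructed directly **on the half-hour grid** to
  realise the drawn survey components — the quantization ladders for
  midpoint and jetlag are chosen so that cleaning never touches an
  uncontaminated record and the downstream-computed components equal the
  planted ones exactly. Only the marginal score–index association is
  specified by the estimand, so this generative path is the package's own
  construction, recorded in the cohort's `truth`.
* **Score/index → disease.** Outcome status follows
  `logit(p) = α + log(OR_prs)·PRS + log(OR_index)·index +
  γ_int·PRS·index + confounders`, with `α` solved numerically for the
  requested prevalence (an explicit error names the outcome if the required
  intercept leaves `[−20, 20]`). Cases emit two dated billing codes within
  ±5 years of the survey date; the engineered defect fractions emit one
  code only, or redate one of the two codes outside the window — both turn
  the participant into an *excluded* call downstream, exercising the rules
  without biasing recovery.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: linkage disequilibrium and population structure,
realistic ICD vocabularies (a 30-code toy map is bundled), correlated index
components beyond the shared liability, informative missingness, secular
coding trends, or care-seeking processes. Recovery results demonstrate the
*pipeline's* correctness, not clinical generalisability.

# Validation design and problem sizes

The suite validates each layer against an independent oracle: clock
arithmetic against a minute-walk enumeration over the full 48-point
half-hour grid (all bed/wake pairs; ~5 × 10⁶ jetlag checks), phecode calls
against a nested-loop recount on cohorts of ≤ 20 participants with
window-edge dates, the logistic fitter against the closed-form 2×2
cross-product OR (1e−8) and the linear fitter against normal-equation
solves (1e−10), and greedy pruning against exhaustive minimum vertex
covers on small random graphs. Stochastic guarantees use fixed seeds:
planted odds ratios (0.85/SD and 0.90/unit at prevalence 0.2, n = 20,000)
must show 93–97% Wald CI coverage over 200 replicates; a planted null
interaction must reject at 3–7% over 500 replicates at n = 2,000; an
all-null 100-outcome scan must average ≤ 0.1 Bonferroni-significant
results over 100 replicates. These sizes were chosen so the whole suite
runs comfortably on a single CPU while leaving the asymptotic
approximations (Wald intervals at a few thousand cases) in their valid
range.

# Known limitations

* The Wald interval undercovers in very sparse cells; scans flag rather
  than repair separation (no Firth correction).
* Phecode exclusion ranges and hierarchical rollup are out of scope.
* The toy vocabulary maps a code to exactly one phecode; real maps are
  many-to-many.
* Greedy pruning is not minimum-cardinality (bounded in tests by the
  minimum vertex cover plus the component count).
* The generator's component independence (given liability) understates the
  real correlation between e.g. jetlag and irregularity.
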
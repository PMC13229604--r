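#' Harmonize alleles and compute raw polygenic scores
#'
#' Aligns the counted allele of each dosage column with the weight table's
#' effect allele and accumulates the weighted dosage sum. If the counted
#' allele equals the effect allele the dosage is used as-is; if it equals the
#' other allele the dosage is flipped to `2 - d`; variants whose counted
#' allele matches neither are dropped with a count. Variants in the weight
#' table but absent from the dosage matrix are likewise dropped.
#'
#' @param weights data.frame with columns `variant_id`, `effect_allele`,
#'   `other_allele`, `weight`.
#' @param dosages numeric matrix, participants in rows (rownames are ids),
#'   variants in columns (colnames are variant ids), values in `[0, 2]`,
#'   with a named character attribute `"counted_allele"` giving the allele
#'   each column counts. See [read_dosages()] for the TSV encoding.
#' @return data.frame `participant_id`, `raw`, with attributes
#'   `"n_variants_used"` and `"n_variants_dropped"`.
#' @export
harmonize_and_score <- function(weights, dosages) {
  counted <- attr(dosages, "counted_allele")
  if (is.null(counted)) stop("dosage matrix lacks the 'counted_allele' attribute")
  idx <- match(weights$variant_id, colnames(dosages))
  present <- !is.na(idx)
  w <- weights[present, , drop = FALSE]
  d <- dosages[, idx[present], drop = FALSE]
  cnt <- counted[colnames(d)]

  use_as_is <- cnt == w$effect_allele
  flip <- cnt == w$other_allele
  mismatch <- !(use_as_is | flip)
  n_dropped <- sum(mismatch) + sum(!present)
  if (!any(use_as_is | flip)) stop("no overlapping, allele-consistent variants between weights and dosages")
  if (n_dropped > 0.5 * nrow(weights)) {
    warning(n_dropped, " of ", nrow(weights), " variants dropped (>50%)")
  }

  keep <- which(!mismatch)
  d <- d[, keep, drop = FALSE]
  w <- w[keep, , drop = FALSE]
  fl <- flip[keep]
  if (any(fl)) d[, fl] <- 2 - d[, fl, drop = FALSE]
  raw <- as.numeric(d %*% w$weight)

  out <- data.frame(participant_id = rownames(dosages), raw = raw,
                    stringsAsFactors = FALSE)
  attr(out, "n_variants_used") <- length(keep)
  attr(out, "n_variants_dropped") <- n_dropped
  out
}

#' Standardize polygenic scores over an analytic sample
#'
#' Centers and scales the raw score to mean 0, SD 1 over exactly the supplied
#' sample (sample SD, `n - 1` denominator). All participants present in
#' `scores` receive a standardized value on that scale, so participants
#' outside the analytic sample remain comparable.
#'
#' @param scores data.frame `participant_id`, `raw` (from
#'   [harmonize_and_score()]).
#' @param sample_ids participant ids defining the standardization sample;
#'   defaults to all scored participants.
#' @return `scores` with a `standardized` column appended.
#' @export
standardize_scores <- function(scores, sample_ids = scores$participant_id) {
  in_sample <- scores$participant_id %in% sample_ids
  if (sum(in_sample) < 2) stop("need at least 2 participants to standardize")
  mu <- mean(scores$raw[in_sample])
  sdv <- stats::sd(scores$raw[in_sample])
  if (sdv == 0) stop("zero variance in raw polygenic scores; cannot standardize")
  scores$standardized <- (scores$raw - mu) / sdv
  scores
}

#' Prune related participants by kinship
#'
#' Builds the relatedness graph over pairs whose kinship coefficient exceeds
#' `threshold` (strictly) and greedily removes vertices of maximal degree
#' until no edge survives, so that no retained pair is related. Ties among
#' maximal-degree vertices are broken deterministically by removing the
#' lexicographically largest id (the smaller id of a tied pair is kept).
#'
#' @param pairs data.frame `id_a`, `id_b`, `coefficient`.
#' @param threshold kinship cutoff; pairs with coefficient strictly greater
#'   are considered related (default 0.0625, i.e. closer than third-degree).
#' @param ids optional full vector of participant ids; ids not in any pair
#'   are always kept.
#' @return list with `kept` and `removed` character vectors of ids.
#' @export
prune_related <- function(pairs, threshold = 0.0625, ids = NULL) {
  rel <- pairs[pairs$coefficient > threshold, , drop = FALSE]
  edges <- unique(data.frame(
    a = pmin(as.character(rel$id_a), as.character(rel$id_b)),
    b = pmax(as.character(rel$id_a), as.character(rel$id_b)),
    stringsAsFactors = FALSE))
  edges <- edges[edges$a != edges$b, , drop = FALSE]
  removed <- character(0)
  while (nrow(edges) > 0) {
    deg <- table(c(edges$a, edges$b))
    victims <- names(deg)[deg == max(deg)]
    victim <- max(victims)  # lexicographically largest among ties
    removed <- c(removed, victim)
    edges <- edges[edges$a != victim & edges$b != victim, , drop = FALSE]
  }
  all_ids <- unique(c(ids, as.character(pairs$id_a), as.character(pairs$id_b)))
  list(kept = sort(setdiff(all_ids, removed)), removed = sort(removed))
}
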
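dos_matrix <- function(values, ids, variants, counted) {
  m <- matrix(values, nrow = length(ids), byrow = TRUE,
              dimnames = list(ids, variants))
  attr(m, "counted_allele") <- stats::setNames(counted, variants)
  m
}

test_that("allele harmonization flips, matches and drops correctly", {
  w <- data.frame(variant_id = c("v1", "v2"),
                  effect_allele = c("A", "C"), other_allele = c("G", "T"),
                  weight = c(0.1, -0.2), stringsAsFactors = FALSE)
  # matched counted alleles: 0.1*2 + (-0.2)*1 = 0
  d <- dos_matrix(c(2, 1), "p1", c("v1", "v2"), c("A", "C"))
  expect_equal(harmonize_and_score(w, d)$raw, 0)

  # counted allele equals the other allele: dosage flips to 2 - d
  w1 <- data.frame(variant_id = "v1", effect_allele = "A", other_allele = "G",
                   weight = 0.3, stringsAsFactors = FALSE)
  d1 <- dos_matrix(0.5, "p1", "v1", "G")
  expect_equal(harmonize_and_score(w1, d1)$raw, 0.3 * 1.5)

  # counted alleles matching neither, or variants absent from the dosages,
  # are dropped; past 50% that draws a warning
  w2 <- rbind(w1,
              data.frame(variant_id = "v2", effect_allele = "C",
                         other_allele = "T", weight = 1),
              data.frame(variant_id = "v8", effect_allele = "A",
                         other_allele = "T", weight = 2))
  d2 <- dos_matrix(c(1, 2), "p1", c("v1", "v2"), c("A", "G"))
  expect_warning(sc <- harmonize_and_score(w2, d2), "dropped")
  expect_equal(sc$raw, 0.3)
  expect_equal(attr(sc, "n_variants_dropped"), 2)

  # zero usable overlap is an error
  expect_error(harmonize_and_score(w1, dos_matrix(1, "p1", "v9", "A")),
               "no overlapping")

  # all-zero weights give all-zero scores
  w0 <- w
  w0$weight <- 0
  d0 <- dos_matrix(c(2, 1, 0, 2), c("p1", "p2"), c("v1", "v2"), c("A", "C"))
  expect_equal(harmonize_and_score(w0, d0)$raw, c(0, 0))
})

test_that("standardization hits mean 0, SD 1 with the n-1 denominator", {
  sc <- data.frame(participant_id = c("a", "b", "c"), raw = c(1, 2, 3),
                   stringsAsFactors = FALSE)
  out <- standardize_scores(sc)
  expect_equal(out$standardized, c(-1, 0, 1))  # sample-SD convention

  set.seed(31)
  big <- data.frame(participant_id = sprintf("p%03d", 1:200),
                    raw = rnorm(200, 5, 3), stringsAsFactors = FALSE)
  z <- standardize_scores(big)$standardized
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(stats::sd(z) - 1), 1e-9)

  expect_error(standardize_scores(data.frame(participant_id = c("a", "b"),
                                             raw = c(2, 2))), "zero variance")
})

test_that("standardized scores are invariant to positive affine transforms", {
  set.seed(32)
  sc <- data.frame(participant_id = sprintf("p%02d", 1:50), raw = rnorm(50),
                   stringsAsFactors = FALSE)
  z1 <- standardize_scores(sc)$standardized
  sc$raw <- 3.7 * sc$raw + 11
  z2 <- standardize_scores(sc)$standardized
  expect_equal(z1, z2, tolerance = 1e-12)
})

test_that("scoring is linear in the weights", {
  set.seed(33)
  ids <- sprintf("p%02d", 1:8)
  vars <- sprintf("v%d", 1:6)
  d <- dos_matrix(sample(0:2, 48, replace = TRUE), ids, vars,
                  rep(c("A", "G"), 3))
  w <- data.frame(variant_id = vars, effect_allele = rep(c("A", "G"), 3),
                  other_allele = rep(c("T", "C"), 3),
                  weight = rnorm(6), stringsAsFactors = FALSE)
  r1 <- harmonize_and_score(w, d)$raw
  w$weight <- w$weight * -2.5
  r2 <- harmonize_and_score(w, d)$raw
  expect_equal(r2, -2.5 * r1)
})

test_that("kinship pruning removes one of each related pair, strict threshold", {
  one <- data.frame(id_a = "A", id_b = "B", coefficient = 0.25)
  out <- prune_related(one)
  expect_equal(out$removed, "B")            # deterministic tie-break
  expect_equal(out$kept, "A")

  low <- data.frame(id_a = "A", id_b = "B", coefficient = 0.05)
  expect_equal(prune_related(low)$removed, character(0))  # 0.05 <= 0.0625
  boundary <- data.frame(id_a = "A", id_b = "B", coefficient = 0.0625)
  expect_equal(prune_related(boundary)$removed, character(0))  # strict >

  chain <- data.frame(id_a = c("A", "B"), id_b = c("B", "C"),
                      coefficient = c(0.25, 0.25))
  expect_equal(prune_related(chain)$removed, "B")  # cut vertex alone suffices
})

test_that("pruning is idempotent", {
  set.seed(34)
  ids <- LETTERS[1:10]
  pairs <- data.frame(id_a = sample(ids, 15, replace = TRUE),
                      id_b = sample(ids, 15, replace = TRUE),
                      coefficient = runif(15, 0, 0.5), stringsAsFactors = FALSE)
  pairs <- pairs[pairs$id_a != pairs$id_b, ]
  out <- prune_related(pairs, ids = ids)
  surviving <- pairs[pairs$id_a %in% out$kept & pairs$id_b %in% out$kept, ]
  expect_equal(prune_related(surviving, ids = out$kept)$removed, character(0))
})

test_that("greedy pruning stays near the brute-force minimum vertex cover", {
  set.seed(35)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    ids <- LETTERS[1:n]
    k <- sample(2:min(12, n * (n - 1) / 2), 1)
    pairs <- unique(data.frame(
      id_a = sample(ids, 3 * k, replace = TRUE),
      id_b = sample(ids, 3 * k, replace = TRUE), stringsAsFactors = FALSE))
    pairs <- head(pairs[pairs$id_a != pairs$id_b, ], k)
    if (nrow(pairs) == 0) next
    pairs$coefficient <- 0.25
    edges <- data.frame(a = pmin(pairs$id_a, pairs$id_b),
                        b = pmax(pairs$id_a, pairs$id_b),
                        stringsAsFactors = FALSE)
    edges <- unique(edges)
    n_removed <- length(prune_related(pairs)$removed)
    mvc <- oracle_min_vertex_cover(edges)
    ncomp <- oracle_n_components(edges, sort(unique(c(edges$a, edges$b))))
    expect_gte(n_removed, mvc)            # a cover cannot beat the minimum
    expect_lte(n_removed, mvc + ncomp)    # greedy overshoot is bounded
    # and the result is a valid cover: no surviving related pair
    kept <- prune_related(pairs)$kept
    expect_false(any(edges$a %in% kept & edges$b %in% kept))
  }
})
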
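test_that("the score formula reproduces hand-computed values", {
  c0 <- score_components(frequency = 1, signature_p = 0,
                         avg_mutation_load = 10)
  expect_equal(synmicdb_score(dplyr::mutate(c0, snp_score = 0)), 0.0)
  c1 <- score_components(frequency = 4, signature_p = 0.5,
                         avg_mutation_load = 100, cgc_score = 2,
                         phastcons = 1, snp_score = 1, fathmm = 1,
                         cadd_qrank = 1, structure_qrank = 1)
  # (log2 4 + 1) * 0.5 - log10 100 + (2+1+1+1+1+1) = 1.5 - 2 + 7
  expect_equal(synmicdb_score(c1), 6.5)
  expect_error(score_components(frequency = 0.5, signature_p = 0,
                                avg_mutation_load = 10), ">= 1")
  expect_error(score_components(frequency = 1, signature_p = 2,
                                avg_mutation_load = 10), "\\[0, 1\\]")
})

test_that("the score is monotone in each component", {
  set.seed(80)
  base <- score_components(
    frequency = sample(1:50, 200, TRUE),
    signature_p = runif(200),
    avg_mutation_load = runif(200, 1, 5000),
    cgc_score = sample(c(0, 2), 200, TRUE),
    phastcons = runif(200), snp_score = sample(0:1, 200, TRUE),
    fathmm = runif(200), cadd_qrank = runif(200),
    structure_qrank = runif(200))
  s0 <- synmicdb_score(base)
  bump <- function(comp, field, delta) {
    comp[[field]] <- pmin(pmax(comp[[field]] + delta, 0),
                          if (field == "frequency") Inf
                          else if (field == "avg_mutation_load") Inf
                          else if (field == "cgc_score") 2 else 1)
    comp
  }
  for (f in c("frequency", "cgc_score", "phastcons", "snp_score", "fathmm",
              "cadd_qrank", "structure_qrank")) {
    expect_true(all(synmicdb_score(bump(base, f, 0.3)) >= s0 - 1e-12))
  }
  expect_true(all(synmicdb_score(bump(base, "signature_p", 0.1)) <= s0 + 1e-12))
  expect_true(all(synmicdb_score(bump(base, "avg_mutation_load", 100)) <= s0))
})

test_that("leave-one-out has nine balanced parameters", {
  set.seed(81)
  comp <- score_components(
    frequency = sample(1:20, 50, TRUE), signature_p = runif(50),
    avg_mutation_load = runif(50, 1, 1000), cgc_score = sample(c(0, 2), 50, TRUE),
    phastcons = runif(50), snp_score = sample(0:1, 50, TRUE),
    fathmm = runif(50), cadd_qrank = runif(50), structure_qrank = runif(50))
  loo <- leave_one_out(comp)
  expect_identical(ncol(loo), 9L)
  expect_setequal(names(loo), SCORE_PARAMETERS)
  full <- synmicdb_score(comp)
  # neutral-element parameters leave the score unchanged
  neutral <- score_components(frequency = 1, signature_p = 0,
                              avg_mutation_load = 1, cgc_score = 0,
                              phastcons = 0, snp_score = 0, fathmm = 0,
                              cadd_qrank = 0, structure_qrank = 0)
  loo_n <- leave_one_out(neutral)
  for (p in SCORE_PARAMETERS) {
    expect_equal(loo_n[[p]], synmicdb_score(neutral))
  }
  # additive terms: sum of (S - S_loo) equals the sum of the term values
  add_gap <- rowSums(full - as.matrix(loo[, synmut::SCORE_PARAMETERS[4:9]]))
  add_sum <- rowSums(as.matrix(comp[, c("cgc_score", "phastcons", "snp_score",
                                        "fathmm", "cadd_qrank",
                                        "structure_qrank")]))
  expect_equal(add_gap, add_sum)
  # leave-one-out rankings stay positively correlated with the full score
  for (p in SCORE_PARAMETERS) {
    expect_gt(rank_correlation(full, loo[[p]]), 0)
  }
})

test_that("top-decile retention behaves at its extremes", {
  s <- rnorm(100)
  expect_equal(top_decile_retention(s, s), 1.0)
  expect_equal(top_decile_retention(sort(s), rev(sort(s))), 0.0)
  expect_equal(top_decile_retention(s, 10 * s + 3), 1.0)  # monotone rescale
})

test_that("percentile thresholds match a sorting oracle", {
  th <- percentile_thresholds(1:100)
  expect_true(th$threshold[th$top_percent == 50] >= 50 &&
                th$threshold[th$top_percent == 50] <= 51)
  expect_true(all(diff(th$threshold) >= 0))  # deeper top = higher threshold
  expect_true(all(percentile_thresholds(rep(3.3, 10))$threshold == 3.3))
  set.seed(82)
  x <- rnorm(5000)
  th2 <- percentile_thresholds(x, top_percents = c(10, 1))
  expect_equal(unname(th2$threshold),
               unname(stats::quantile(x, c(0.9, 0.99))))
})

test_that("scoring a cohort recovers injected cancer-gene enrichment", {
  co <- small_cohort()
  ann <- co$ann[co$ann$consequence == "synonymous", ]
  st <- co$refs$structure
  st$mutation_id <- paste0(st$chrom, ":", st$pos, ":", st$ref, ">", st$alt)
  ann <- dplyr::left_join(ann, st[, c("mutation_id", "remurna_entropy")],
                          by = "mutation_id")
  # inject the enrichment the score is designed to detect
  set.seed(83)
  cg <- ann$cancer_gene
  ann$phastcons[cg] <- pmin(1, ann$phastcons[cg] + 0.5)
  ann$frequency[cg] <- ann$frequency[cg] + 3L
  scored <- score_cohort(ann)
  expect_equal(scored$score,
               synmicdb_score(scored[, c("frequency", "signature_p",
                                         "avg_mutation_load", "cgc_score",
                                         "phastcons", "snp_score", "fathmm",
                                         "cadd_qrank", "structure_qrank")]))
  w <- stats::wilcox.test(scored$score[cg], scored$score[!cg],
                          alternative = "greater")
  expect_lt(w$p.value, 0.01)
  expect_true(all(scored$score_percentile > 0 & scored$score_percentile <= 1))
})
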
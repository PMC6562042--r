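test_that("positional distributions sum to one and respect strata", {
  co <- small_cohort()
  syn <- co$ann[co$ann$consequence == "synonymous", ]
  d <- positional_distribution(syn, by = "cds")
  expect_equal(sum(d$fraction), 1, tolerance = 1e-9)
  expect_identical(sum(d$count), nrow(syn))
  strat <- positional_distribution(syn, by = "cds",
                                   stratify_by = "substitution_class")
  recomb <- strat |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(count = sum(.data$count))
  expect_identical(recomb$count, d$count)
  # point mass fixture
  pm <- tibble::tibble(cds_decile = rep(1L, 5))
  dpm <- positional_distribution(pm, by = "cds")
  expect_equal(dpm$fraction[dpm$bin == 1], 1)
  expect_equal(sum(dpm$fraction), 1)
})

test_that("first-200-codon mode only uses long CDS", {
  co <- small_cohort()
  syn <- co$ann[co$ann$consequence == "synonymous", ]
  d <- positional_distribution(syn, by = "first_200_codons")
  long_tx <- co$tt$transcripts$transcript_id[
    co$tt$transcripts$cds_end - co$tt$transcripts$cds_start + 1L > 600L]
  eligible <- syn[syn$transcript_id %in% long_tx & syn$codon_index <= 200, ]
  expect_identical(sum(d$count), nrow(eligible))
})

test_that("metric-by-bin means, SEM and tests behave on fixtures", {
  n <- 2000
  set.seed(90)
  tbl <- tibble::tibble(cds_decile = sample(1:10, n, replace = TRUE))
  tbl$metric_const <- 5
  mb <- metric_by_bin(tbl, "metric_const")
  expect_true(all(abs(mb$diff_from_mean) < 1e-12))
  expect_true(all(mb$mean == 5))
  tbl$metric_inc <- tbl$cds_decile + rnorm(n, 0, 1e-6)
  mb2 <- metric_by_bin(tbl, "metric_inc")
  expect_true(all(diff(mb2$mean) > 0))
  # SEM agrees with a bootstrap oracle
  tbl$metric_rand <- rnorm(n, sd = 3)
  mb3 <- metric_by_bin(tbl, "metric_rand")
  x5 <- tbl$metric_rand[tbl$cds_decile == 5]
  boot <- replicate(2000, mean(sample(x5, replace = TRUE)))
  expect_lt(abs(mb3$sem[mb3$bin == 5] - stats::sd(boot)) / stats::sd(boot),
            0.1)
})

test_that("amino-acid shares are codon-count-normalized", {
  met <- tibble::tibble(amino_acid = rep("M", 10))
  am <- amino_acid_distribution(met)
  expect_equal(unname(am$normalized_share[am$amino_acid == "M"]), 1)
  # equal raw counts: Met (1 codon) gets 6x the Leu (6 codons) share
  lm <- tibble::tibble(amino_acid = c(rep("L", 12), rep("M", 12)))
  am2 <- amino_acid_distribution(lm)
  expect_equal(unname(am2$normalized_share[am2$amino_acid == "M"]),
               unname(6 * am2$normalized_share[am2$amino_acid == "L"]))
  expect_equal(sum(am2$normalized_share), 1)
})

test_that("expected amino-acid model matches brute-force enumeration", {
  sig <- default_signature()
  set.seed(91)
  usage <- runif(61)
  names(usage) <- synmut:::SENSE_CODONS
  usage <- usage / sum(usage)
  exp_tbl <- expected_aa_distribution(usage, sig)
  # independent brute force: explicit loop over 61 codons x 9 substitutions
  gc <- Biostrings::getGeneticCode("1")
  pyr <- function(r, a) {
    if (r %in% c("A", "G")) {
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      paste0(comp[[r]], ">", comp[[a]])
    } else paste0(r, ">", a)
  }
  acc <- numeric(0)
  for (codon in names(gc)) {
    if (gc[[codon]] == "*") next
    mass <- 0
    for (i in 1:3) {
      r <- substr(codon, i, i)
      for (a in setdiff(c("A", "C", "G", "T"), r)) {
        mut <- codon
        substr(mut, i, i) <- a
        if (gc[[mut]] == gc[[codon]]) mass <- mass + sig[[pyr(r, a)]]
      }
    }
    aa <- gc[[codon]]
    acc[aa] <- ifelse(is.na(acc[aa]), 0, acc[aa]) + usage[[codon]] * mass
  }
  acc <- acc / sum(acc)
  for (aa in exp_tbl$amino_acid) {
    want <- if (aa %in% names(acc)) acc[[aa]] else 0
    expect_equal(exp_tbl$expected_share[exp_tbl$amino_acid == aa], want,
                 tolerance = 1e-12)
  }
  expect_equal(sum(exp_tbl$expected_share), 1, tolerance = 1e-12)
  expect_error(expected_aa_distribution(usage[1:10], sig), "61 sense codons")
})

test_that("group comparison reproduces textbook t-tests", {
  a <- c(4, 5, 6)
  b <- c(1, 2, 3)
  gc1 <- group_compare(a, b)
  tt <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(gc1$t, unname(tt$statistic))
  expect_equal(gc1$p_value, tt$p.value)
  expect_equal(gc1$relative_difference, 100 * (5 - 2) / 2)
  same <- group_compare(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$p_value, 1)
  expect_equal(same$relative_difference, 0)
  expect_equal(group_compare(c(2, 2.1, 1.9), c(1, 1.1, 0.9))$relative_difference,
               100)
  expect_error(group_compare(1, c(1, 2)), "at least 2")
})

test_that("null p-values are uniform", {
  set.seed(92)
  p <- replicate(1000, group_compare(rnorm(10), rnorm(10))$p_value)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("per-study stratification selects the top studies", {
  co <- small_cohort()
  syn <- co$ann[co$ann$consequence == "synonymous", ]
  res <- per_study_stratification(syn, metric = "frequency")
  by_study <- dplyr::count(syn, .data$study_id, sort = TRUE)
  # fewer than 10 studies: all selected
  expect_setequal(res$selected$study_id, unique(syn$study_id))
  # ranking agrees with a sort oracle
  expect_identical(
    res$selected$n_mutations[match(by_study$study_id, res$selected$study_id)],
    by_study$n)
  expect_true(all(table(res$distributions$stratum) == 10))
  # union of two top-5 sets can never exceed 10
  many <- dplyr::mutate(syn, study_id = sample(sprintf("ST%02d", 1:15),
                                               nrow(syn), replace = TRUE))
  res2 <- per_study_stratification(many)
  expect_lte(nrow(res2$selected), 10)
  expect_gte(nrow(res2$selected), 5)
})
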
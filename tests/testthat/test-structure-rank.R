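test_that("window export gives full or flagged truncated windows", {
  seq <- paste0(rand_dna(100), "ATG", strrep("GCA", 265), "TAA", rand_dna(100))
  tx <- transcript_model("TXW", "GW", "cw", "+", 0L, nchar(seq),
                         101L, 100L + 3L * 267L, seq)
  ann <- tibble::tibble(
    mutation_id = c("m1", "m2"), transcript_id = "TXW",
    cds_pos = c(250L, 2L),
    ref = c(substr(cds_sequence(tx), 250, 250), substr(cds_sequence(tx), 2, 2)),
    alt = c("T", "C")
  )
  ann$alt[1] <- setdiff(c("A", "C", "G", "T"), ann$ref[1])[1]
  ann$alt[2] <- setdiff(c("A", "C", "G", "T"), ann$ref[2])[1]
  w <- export_windows(ann, tx, flank = 200L)
  expect_identical(nchar(w$window[1]), 401L)
  expect_false(w$truncated[1])
  # cds_pos 2 -> transcript position 102: only 101 nt upstream
  expect_identical(nchar(w$window[2]), 302L)
  expect_true(w$truncated[2])
  expect_identical(substr(w$window[1], w$offset0[1] + 1, w$offset0[1] + 1),
                   w$ref[1])
  # ref mismatch is an export error
  bad <- ann[1, ]
  bad$ref <- setdiff(c("A", "C", "G", "T"), c(bad$ref, bad$alt))[1]
  expect_error(export_windows(bad, tx), "mismatch")
})

test_that("score ingestion enforces the column and key contract", {
  rem <- tibble::tibble(mutation_id = c("a", "b"), remurna_entropy = c(1, 2))
  rsn <- tibble::tibble(mutation_id = c("b", "c"), rnasnp_dmax = c(0.1, 0.2),
                        rnasnp_pvalue = c(0.5, 0.01))
  out <- ingest_scores(rem, rsn, context = 100L)
  expect_identical(nrow(out), 3L)
  expect_true(is.na(out$rnasnp_dmax[out$mutation_id == "a"]))
  expect_true(is.na(out$remurna_entropy[out$mutation_id == "c"]))
  expect_true(all(out$context == 100L))
  expect_error(ingest_scores(rem[, 1, drop = FALSE], NULL), "missing column")
  expect_error(
    ingest_scores(dplyr::bind_rows(rem, rem[1, ]), NULL),
    "duplicate mutation_id.*a")
  expect_error(ingest_scores(NULL, NULL), "no score table")
})

test_that("quantile ranks use the (# <= x)/n convention with mean ties", {
  expect_equal(quantile_rank(c(5, 1, 3)), c(1, 1/3, 2/3))
  expect_equal(quantile_rank(rep(7, 4)), rep((1 + 2 + 3 + 4) / 4 / 4, 4))
  x <- rnorm(100)
  expect_equal(quantile_rank(x), quantile_rank(exp(x)))  # monotone invariance
  expect_equal(mean(quantile_rank(x)), (100 + 1) / (2 * 100))
  withna <- quantile_rank(c(2, NA, 1))
  expect_true(is.na(withna[2]))
  expect_equal(withna[c(1, 3)], c(1, 0.5))
  expect_error(quantile_rank(c(NA_real_, NA_real_)), "finite")
})

test_that("rank correlation matches a rank-then-Pearson oracle", {
  expect_equal(rank_correlation(1:10, 1:10), 1)
  expect_equal(rank_correlation(1:10, -(1:10)), -1)
  expect_error(rank_correlation(c(1, 2, NA), c(1, NA, 3)), "insufficient")
  set.seed(55)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    a <- rnorm(n)
    b <- rnorm(n) + 0.5 * a
    expect_equal(rank_correlation(a, b),
                 stats::cor(rank(a), rank(b)), tolerance = 1e-12)
  }
  # pairwise-complete handling
  a <- c(rnorm(50), NA)
  b <- c(rnorm(50), 3)
  expect_equal(rank_correlation(a, b),
               stats::cor(rank(a[1:50]), rank(b[1:50])))
})

test_that("top-percentile fractions conserve mass across bins", {
  set.seed(60)
  n <- 20000
  scores <- rnorm(n)
  bins <- sample(1:10, n, replace = TRUE)
  tp <- top_percentile_by_bin(scores, bins, percentile = 5)
  expect_true(all(abs(tp$fraction - 0.05) < 0.02))
  expect_equal(sum(tp$fraction * tp$n) / sum(tp$n), 0.05)
  # constructed: all top scores in bin 1
  s2 <- c(rep(10, 50), rnorm(950))
  b2 <- c(rep(1L, 50), sample(2:10, 950, replace = TRUE))
  tp2 <- top_percentile_by_bin(s2, b2, percentile = 5)
  expect_equal(tp2$fraction[tp2$bin == 1], 1.0)
  expect_true(all(tp2$fraction[tp2$bin != 1] == 0))
  # single bin: fraction equals the percentile
  tp3 <- top_percentile_by_bin(rnorm(1000), rep(1L, 1000), percentile = 5)
  expect_equal(tp3$fraction, 0.05)
})

test_that("window summaries compute GC and MFE means per decile", {
  expect_equal(gc_content(c("GCGC", "ATAT", "GATC")), c(1, 0, 0.5))
  set.seed(61)
  win <- tibble::tibble(
    gc_content = runif(300),
    mfe = -runif(300, 5, 50),
    cds_decile = sample(1:10, 300, replace = TRUE)
  )
  ws <- window_summaries(win)
  d3 <- win[win$cds_decile == 3, ]
  expect_equal(ws$mean_gc[ws$cds_decile == 3], mean(d3$gc_content))
  expect_equal(ws$sem_mfe[ws$cds_decile == 3],
               stats::sd(d3$mfe) / sqrt(nrow(d3)))
  # counting oracle for GC
  w <- rand_dna(200)
  expect_equal(gc_content(w),
               sum(strsplit(w, "")[[1]] %in% c("G", "C")) / 200)
})

test_that("load-binned structure scores detect an injected correlation", {
  # null: identical distributions in all bins
  set.seed(62)
  s <- rexp(3000)
  l <- runif(3000, 10, 1000)
  res <- score_by_load_bins(s, l, c(10, 100, 500, 1000))
  expect_true(all(abs(res$tests$t) < 4))
  expect_error(score_by_load_bins(s, l, c(10, 10, 20)), "strictly increasing")
  # single bin: no tests
  res1 <- score_by_load_bins(s, l, c(10, 1000))
  expect_null(res1$tests)
  # injected negative score-load correlation gives decreasing bin means
  cfg <- small_config(seed = 71, score_load_correlation = -0.9)
  tt <- generate_transcriptome(cfg)
  mut <- generate_mutations(cfg, tt)
  refs <- generate_reference_tables(cfg, tt, mut)
  cur <- curate_mutations(mut, tt$transcripts)$curated
  ann <- annotate_mutations(cur, tt$transcripts, cfg$signature, refs)
  st <- refs$structure
  st$mutation_id <- paste0(st$chrom, ":", st$pos, ":", st$ref, ">", st$alt)
  ann <- dplyr::left_join(ann, st[, c("mutation_id", "remurna_entropy")],
                          by = "mutation_id")
  edges <- stats::quantile(ann$avg_mutation_load, c(0, 1/3, 2/3, 1))
  res2 <- score_by_load_bins(ann$remurna_entropy, ann$avg_mutation_load,
                             unname(edges))
  expect_true(all(diff(res2$bins$mean) < 0))
})
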
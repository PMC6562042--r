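test_that("config validation rejects impossible or invalid settings", {
  expect_error(synthetic_config(depletion_first_decile = 1.5), "\\[0, 1\\]")
  expect_error(synthetic_config(cds_length_range = c(301L, 900L)),
               "multiples of 3")
  expect_error(synthetic_config(exon_count_range = c(40L, 50L),
                                cds_length_range = c(300L, 300L),
                                utr_length_range = c(10L, 20L)),
               "configuration error")
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- small_config(seed = 42)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    tt <- generate_transcriptome(cfg)
    write_transcriptome(tt, d)
    write_mutation_table(generate_mutations(cfg, tt),
                         file.path(d, "mut.tsv"))
  }
  for (f in c("genome.fa", "transcripts.fa", "transcripts.bed12", "mut.tsv")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
  }
})

test_that("transcript architecture follows the configured constraints", {
  cfg <- synthetic_config(n_genes = 50, n_samples = 5,
                          exon_count_range = c(2L, 8L),
                          cds_length_range = c(300L, 900L),
                          load_range = c(5L, 20L), seed = 13)
  tt <- generate_transcriptome(cfg)
  for (i in seq_len(nrow(tt$transcripts))) {
    tx <- tt$transcripts[i, ]
    k <- length(tx$exon_starts0[[1]])
    expect_gte(k, 2L)
    expect_lte(k, 8L)
    # a multi-exon transcript has an internal exon iff it has >= 3 exons
    ex <- exon_table(tx)
    has_internal <- any(ex$exon_rank > 1L & ex$exon_rank < nrow(ex))
    expect_identical(has_internal, k >= 3L)
    # CDS translates without internal stop codons
    aa <- translate_codon(
      substring(cds_sequence(tx), seq(1, cds_length(tx) - 3, 3),
                seq(3, cds_length(tx) - 3, 3)))
    expect_false(any(aa == "*"))
  }
  # both strands represented
  expect_setequal(unique(tt$transcripts$strand), c("+", "-"))
})

test_that("monoexonic config yields a CDS-in-single-exon transcript", {
  cfg <- synthetic_config(n_genes = 1, n_samples = 2,
                          exon_count_range = c(1L, 1L),
                          cds_length_range = c(300L, 300L),
                          load_range = c(5L, 10L), seed = 4)
  tt <- generate_transcriptome(cfg)
  tx <- tt$transcripts[1, ]
  expect_length(tx$exon_starts0[[1]], 1L)
  expect_identical(nchar(tx$sequence),
                   tx$exon_ends0[[1]] - tx$exon_starts0[[1]])
})

test_that("a degenerate signature forces a single substitution class", {
  cfg <- small_config(
    seed = 7,
    signature = signature_model(c("C>A" = 0, "C>G" = 0, "C>T" = 1,
                                  "T>A" = 0, "T>C" = 0, "T>G" = 0)))
  tt <- generate_transcriptome(cfg)
  mut <- generate_mutations(cfg, tt)
  p <- sub("^c\\.\\d+([ACGT])>([ACGT])$", "\\1\\2", mut$cds_change)
  cls <- substitution_class(substr(p, 1, 1), substr(p, 2, 2))
  expect_true(all(cls == "C>T"))
})

test_that("empirical class frequencies converge to the signature", {
  cfg <- synthetic_config(n_genes = 150, n_samples = 80,
                          cds_length_range = c(900L, 2400L),
                          load_range = c(800L, 4000L), seed = 17)
  tt <- generate_transcriptome(cfg)
  mut <- generate_mutations(cfg, tt)
  expect_gt(nrow(mut), 1e5)
  p <- sub("^c\\.\\d+([ACGT])>([ACGT])$", "\\1\\2", mut$cds_change)
  cls <- substitution_class(substr(p, 1, 1), substr(p, 2, 2))
  emp <- table(factor(cls, levels = SUBSTITUTION_CLASSES)) / length(cls)
  tv <- 0.5 * sum(abs(as.numeric(emp) - as.numeric(cfg$signature)))
  expect_lt(tv, 0.02)
})

test_that("per-sample mutation counts match the load distribution mean", {
  cfg <- synthetic_config(n_genes = 120, n_samples = 1000,
                          load_range = c(20L, 100L), duplicate_rate = 0,
                          seed = 29)
  tt <- generate_transcriptome(cfg)
  mut <- generate_mutations(cfg, tt)
  per_sample <- table(mut$sample_id)
  analytic_mean <- diff(cfg$load_range) / diff(log(cfg$load_range))
  expect_lt(abs(mean(per_sample) - analytic_mean) / analytic_mean, 0.05)
  expect_identical(length(per_sample), 1000L)
})

test_that("without depletion, distinct-site decile counts are uniform", {
  # Distinct sites are independent position draws (recurrence re-draws the
  # same site, so the row-level counts are clustered); the chi-square runs on
  # sites against the position pool's decile composition.
  cfg0 <- synthetic_config(n_genes = 60, n_samples = 20,
                           cds_length_range = c(900L, 2400L),
                           load_range = c(30L, 150L), duplicate_rate = 0,
                           seed = 1)
  tt <- generate_transcriptome(cfg0)
  lens <- stats::setNames(tt$transcripts$cds_end - tt$transcripts$cds_start + 1L,
                          tt$transcripts$transcript_id)
  pool_counts <- integer(10)
  for (i in seq_len(nrow(tt$transcripts))) {
    L <- lens[[tt$transcripts$transcript_id[i]]]
    pool_counts <- pool_counts +
      tabulate(pmin(pmax(ceiling(10 * seq_len(L) / L), 1L), 10L), 10L)
  }
  pvals <- vapply(1:20, function(s) {
    cfg <- cfg0
    cfg$seed <- 1000L + s
    mut <- generate_mutations(cfg, tt)
    cur <- curate_mutations(mut, tt$transcripts)$curated
    sites <- dplyr::distinct(cur, .data$mutation_id, .keep_all = TRUE)
    dec <- pmin(pmax(ceiling(10 * sites$cds_pos / lens[sites$transcript_id]),
                     1L), 10L)
    stats::chisq.test(tabulate(dec, 10L),
                      p = pool_counts / sum(pool_counts))$p.value
  }, numeric(1))
  expect_gte(sum(pvals > 0.01), 19L)
})

test_that("the raw catalog carries duplicates for curation to remove", {
  co <- small_cohort()
  key <- paste(co$mut$chrom, co$mut$pos, co$mut$cds_change, co$mut$sample_id)
  expect_gt(sum(duplicated(key)), 0)
  expect_identical(sum(!duplicated(key)), nrow(co$cur$curated))
})
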
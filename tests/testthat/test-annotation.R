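test_that("frequency counts distinct carrier samples", {
  tbl <- tibble::tibble(
    mutation_id = c("v1", "v1", "v1", "v2"),
    sample_id = c("S1", "S2", "S3", "S4")
  )
  fr <- compute_frequency(tbl)
  expect_identical(fr$frequency[fr$mutation_id == "v1"], 3L)
  expect_identical(fr$frequency[fr$mutation_id == "v2"], 1L)
  expect_identical(fr$recurrent, c(TRUE, FALSE))
})

test_that("signature-normalized frequency follows f * (1 - p)", {
  expect_equal(signature_normalized_frequency(10, 0.3), 7.0)
  expect_equal(signature_normalized_frequency(5, 0), 5)
  expect_equal(signature_normalized_frequency(1000, 1), 0)
  expect_error(signature_normalized_frequency(10, 1.2), "\\[0, 1\\]")
})

test_that("mutation loads are per-sample totals averaged over carriers", {
  tbl <- tibble::tibble(
    mutation_id = c("v1", "v1", rep("x", 398), rep("y", 100)),
    sample_id = c("A", "B", rep("A", 99), rep("B", 299), rep("C", 100))
  )
  ml <- mutation_load(tbl)
  expect_identical(ml$sample_loads$load[ml$sample_loads$sample_id == "A"], 100L)
  expect_identical(ml$sample_loads$load[ml$sample_loads$sample_id == "B"], 300L)
  expect_equal(
    ml$mutation_loads$avg_mutation_load[ml$mutation_loads$mutation_id == "v1"],
    200)
  perm <- tbl[sample(nrow(tbl)), ]
  ml2 <- mutation_load(perm)
  expect_equal(dplyr::arrange(ml2$sample_loads, .data$sample_id),
               dplyr::arrange(ml$sample_loads, .data$sample_id))
})

test_that("CDS positional features handle bin boundaries by the ceil rule", {
  f <- cds_position_features(c(1L, 30L, 31L, 300L), 300L)
  expect_identical(f$cds_decile, c(1L, 1L, 2L, 10L))
  expect_identical(f$codon_index, c(1L, 10L, 11L, 100L))
  # first-200-codon bin only for CDS > 600 nt
  expect_true(is.na(cds_position_features(10L, 600L)$first200_bin))
  g <- cds_position_features(c(10L, 601L), 900L)
  expect_identical(g$first200_bin, c(1L, NA_integer_))
})

test_that("exon context is strand-aware and partitions mutations", {
  mono <- toy_multiexon_tx("+", exon_widths = 150L, utr5 = 12L, utr3 = 18L)
  ec <- exon_context(mono, transcript_to_genome(mono, 50L))
  expect_identical(ec$exon_context, "monoexonic")
  expect_true(is.na(ec$internal_exon_decile))

  tx <- toy_multiexon_tx("-")
  ex <- exon_table(tx)
  # first base of the internal exon: decile 1, boundary distance 0
  first_internal <- ex$tx_start[ex$exon_rank == 2]
  ec2 <- exon_context(tx, transcript_to_genome(tx, first_internal))
  expect_identical(ec2$exon_context, "internal")
  expect_identical(ec2$internal_exon_decile, 1L)
  expect_identical(ec2$boundary_distance, 0L)
  # the genomic-leftmost exon of a minus-strand transcript is "last"
  leftmost_pos <- min(unlist(tx$exon_starts0)) + 1L
  ec3 <- exon_context(tx, leftmost_pos)
  expect_identical(ec3$exon_context, "last")

  co <- small_cohort()
  syn <- co$ann[co$ann$consequence == "synonymous", ]
  expect_identical(
    sum(table(syn$exon_context)),
    as.integer(nrow(syn)))
})

test_that("alternative-event overlap returns label sets", {
  events <- tibble::tibble(
    chrom = c("c1", "c1", "c1"),
    start0 = c(100L, 150L, 500L), end0 = c(200L, 250L, 600L),
    event = c("cassetteExon", "retainedIntron", "altPromoter")
  )
  loci <- tibble::tibble(chrom = "c1", pos = c(120L, 180L, 400L))
  ov <- alt_event_overlap(loci, events)
  expect_identical(ov$alt_events[[1]], "cassetteExon")
  expect_identical(ov$alt_events[[2]], c("cassetteExon", "retainedIntron"))
  expect_identical(ov$alt_events[[3]], character(0))
})

test_that("external joins preserve rows, flag phenotypes, and reject dup keys", {
  tbl <- tibble::tibble(
    chrom = "c1", pos = c(10L, 20L), strand = c("+", "-"),
    ref = c("C", "C"), alt = c("T", "A"), gene = c("G1", "G2")
  )
  clinvar <- tibble::tibble(chrom = "c1", pos = 10L, ref = "C", alt = "T",
                            phenotype_list = "Hereditary cancer-predisposing syndrome")
  snps <- tibble::tibble(chrom = "c1", pos = 20L, ref = "G", alt = "T")
  out <- external_joins(tbl, cancer_genes = c("G1"), snps = snps,
                        clinvar = clinvar)
  expect_identical(nrow(out), 2L)
  expect_identical(out$cancer_gene, c(TRUE, FALSE))
  # minus-strand coding alleles are complemented before the genomic join
  expect_identical(out$snp_listed, c(FALSE, TRUE))
  expect_identical(out$clinvar_cancer, c(TRUE, FALSE))
  expect_true(is.na(out$phastcons[1]))
  expect_error(
    external_joins(tbl, conservation = tibble::tibble(
      chrom = c("c1", "c1"), pos = c(10L, 10L), phastcons = c(0.1, 0.2))),
    "duplicate key")
})

test_that("annotation invariants hold on a synthetic cohort", {
  co <- small_cohort()
  ann <- co$ann
  pt <- ann[!is.na(ann$cds_pos), ]
  expect_true(all(pt$signature_normalized_frequency <= pt$frequency))
  expect_true(all(pt$frequency >= 1))
  expect_identical(pt$recurrent, pt$frequency > 1)
  # decile assignments partition each transcript's mutations
  per_tx <- tapply(pt$cds_decile, pt$transcript_id,
                   function(d) sum(tabulate(d, 10L)))
  counts <- table(pt$transcript_id)
  expect_identical(as.integer(per_tx[names(counts)]), as.integer(counts))
})
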
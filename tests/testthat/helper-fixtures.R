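# Shared fixtures and independent oracles for the test suite.

# Independent consequence oracle: translate full codons with Biostrings and
# apply the consequence definition directly.
oracle_consequence <- function(codon, pos_in_codon, alt, table_id) {
  gc <- Biostrings::getGeneticCode(table_id)
  tr <- function(cdn) {
    as.character(Biostrings::translate(
      Biostrings::DNAString(cdn),
      genetic.code = gc, no.init.codon = TRUE))
  }
  mut <- codon
  substr(mut, pos_in_codon, pos_in_codon) <- alt
  aa_wt <- tr(codon)
  aa_mut <- tr(mut)
  if (aa_wt == aa_mut) "synonymous"
  else if (aa_mut == "*") "nonsense"
  else if (aa_wt == "*") "other"
  else "missense"
}

# Naive all-offsets substring oracle for motif occurrence counting.
naive_count <- function(window, motif) {
  k <- nchar(motif)
  n <- nchar(window)
  if (k > n) return(0L)
  sum(vapply(seq_len(n - k + 1L),
             function(i) substr(window, i, i + k - 1L) == motif,
             logical(1)))
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# A hand-built 3-exon transcript; `strand` controls orientation. Exon widths
# in transcript order; genomic gaps of 100 nt between exons.
toy_multiexon_tx <- function(strand = "+", exon_widths = c(40L, 60L, 50L),
                             utr5 = 12L, utr3 = 18L, seed = 5) {
  set.seed(seed)
  total <- sum(exon_widths)
  n_cds <- total - utr5 - utr3
  stopifnot(n_cds %% 3L == 0L)
  cds <- paste0("ATG", paste(sample(synmut:::SENSE_CODONS, n_cds / 3 - 2,
                                    replace = TRUE), collapse = ""), "TAA")
  seq <- paste0(rand_dna(utr5), cds, rand_dna(utr3))
  k <- length(exon_widths)
  genomic_w <- if (strand == "+") exon_widths else rev(exon_widths)
  starts0 <- cumsum(c(10L, utils::head(genomic_w + 100L, -1L)))
  transcript_model(
    transcript_id = "TOY1", gene = "TOYGENE", chrom = "toyctg",
    strand = strand, exon_starts0 = starts0,
    exon_ends0 = starts0 + genomic_w,
    cds_start = utr5 + 1L, cds_end = utr5 + n_cds,
    sequence = seq, code_table = "standard"
  )
}

# Small cohort config for fast end-to-end tests.
small_config <- function(seed = 21, ...) {
  synthetic_config(n_genes = 10, n_samples = 15,
                   cds_length_range = c(300L, 900L),
                   load_range = c(20L, 100L), seed = seed, ...)
}

# One shared small cohort, built lazily and reused across test files.
.fixture_env <- new.env(parent = emptyenv())
small_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    cfg <- small_config(seed = 33)
    tt <- generate_transcriptome(cfg)
    mut <- generate_mutations(cfg, tt)
    refs <- generate_reference_tables(cfg, tt, mut)
    cur <- curate_mutations(mut, tt$transcripts)
    ann <- annotate_mutations(cur$curated, tt$transcripts, cfg$signature, refs)
    .fixture_env$cohort <- list(cfg = cfg, tt = tt, mut = mut, refs = refs,
                                cur = cur, ann = ann)
  }
  .fixture_env$cohort
}
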
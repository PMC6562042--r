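#!/usr/bin/env Rscript
# Scan every synonymous mutation for gains and losses of exonic splicing
# enhancer/silencer motifs in a 100-nt-flank window around the mutated base.

library(synmut)
suppressMessages(library(readr))

cohort <- "results/cohort"
genes <- read_tsv(file.path(cohort, "genes.tsv"), show_col_types = FALSE)
transcripts <- read_transcript_models(
  file.path(cohort, "transcripts.bed12"),
  file.path(cohort, "transcripts.fa"),
  gene_map = setNames(genes$gene, genes$transcript_id))
annotated <- read_tsv(file.path(cohort, "mutations_annotated.tsv"),
                      show_col_types = FALSE)
syn <- annotated[annotated$consequence == "synonymous", ]

catalog <- read_motif_catalog(
  system.file("extdata", "synthetic_ese_ess_catalog.tsv", package = "synmut"),
  source_name = "synthetic")
cat(sprintf("catalog: %d motifs (%d dual-role ESE+ESS)\n",
            nrow(catalog), sum(catalog$role == "both")))

res <- scan_mutation_windows(syn, transcripts, catalog, flank = 100L)
write_tsv(res$summary, file.path(cohort, "motif_summary.tsv"))
write_tsv(res$diffs, file.path(cohort, "motif_diffs.tsv"))

cat(sprintf("%d distinct synonymous mutations scanned\n", nrow(res$summary)))
cat(sprintf("%.1f%% change at least one ESE/ESS motif (%d gains, %d losses)\n",
            100 * mean(res$summary$any_change),
            sum(res$summary$n_gain), sum(res$summary$n_loss)))
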
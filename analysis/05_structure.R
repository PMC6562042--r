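#!/usr/bin/env Rscript
# RNA-structure aberration analyses on ingested scores: export folding-tool
# input windows, ingest remuRNA-style and RNAsnp-style score tables, rank the
# scoring metrics against each other, locate the top 5th percentile of
# structural impact along the CDS, and relate scores to mutation load.

library(synmut)
suppressMessages({library(readr); library(dplyr)})

cohort <- "results/cohort"
genes <- read_tsv(file.path(cohort, "genes.tsv"), show_col_types = FALSE)
transcripts <- read_transcript_models(
  file.path(cohort, "transcripts.bed12"),
  file.path(cohort, "transcripts.fa"),
  gene_map = setNames(genes$gene, genes$transcript_id))
annotated <- read_tsv(file.path(cohort, "mutations_annotated.tsv"),
                      show_col_types = FALSE)
syn <- annotated[annotated$consequence == "synonymous", ]

windows <- export_windows(syn, transcripts, flank = 200L)
write_window_fasta(windows, file.path(cohort, "structure_windows.fa"))
cat(sprintf("exported %d windows (%d truncated, excluded from length-sensitive summaries)\n",
            nrow(windows), sum(windows$truncated)))

st <- read_tsv(file.path(cohort, "structure.tsv"), show_col_types = FALSE)
st$mutation_id <- paste0(st$chrom, ":", st$pos, ":", st$ref, ">", st$alt)
st <- st[st$mutation_id %in% syn$mutation_id, ]
scores <- ingest_scores(
  remurna = st[, c("mutation_id", "remurna_entropy", "mfe_wt", "mfe_mut")],
  rnasnp = st[, c("mutation_id", "rnasnp_dmax", "rnasnp_pvalue")],
  context = 200L)
write_tsv(scores, file.path(cohort, "structure_scores.tsv"))

rho <- rank_correlation(scores$remurna_entropy, scores$rnasnp_dmax)
cat(sprintf("Spearman rho, remuRNA entropy vs RNAsnp d_max: %.3f\n", rho))

var_syn <- syn |> distinct(mutation_id, .keep_all = TRUE) |>
  left_join(scores, by = "mutation_id")
tp <- top_percentile_by_bin(var_syn$remurna_entropy, var_syn$cds_decile,
                            percentile = 5)
write_tsv(tp, file.path(cohort, "structure_top5_by_decile.tsv"))
cat("top-5% structural impact fraction per CDS decile:\n")
print(round(tp$fraction, 4))

win_dec <- windows |>
  filter(!truncated) |>
  left_join(distinct(syn, mutation_id, cds_decile), by = "mutation_id") |>
  left_join(scores[, c("mutation_id", "mfe_wt")], by = "mutation_id") |>
  rename(mfe = mfe_wt)
ws <- window_summaries(win_dec)
write_tsv(ws, file.path(cohort, "window_gc_mfe_by_decile.tsv"))

edges <- unname(quantile(var_syn$avg_mutation_load, seq(0, 1, 0.25)))
slb <- score_by_load_bins(var_syn$remurna_entropy, var_syn$avg_mutation_load,
                          edges)
write_tsv(slb$bins, file.path(cohort, "structure_by_load_bins.tsv"))
write_tsv(slb$tests, file.path(cohort, "structure_by_load_tests.tsv"))
cat("mean remuRNA entropy by load quartile (low -> high):\n")
print(round(slb$bins$mean, 4))
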
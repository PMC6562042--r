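#!/usr/bin/env Rscript
# Cohort-level distributions: positional depletion along the CDS and within
# internal exons (overall and per substitution class), score along the CDS,
# observed vs expected amino-acid distributions, and per-study stratification.

library(synmut)
suppressMessages({library(readr); library(dplyr)})

cohort <- "results/cohort"
genes <- read_tsv(file.path(cohort, "genes.tsv"), show_col_types = FALSE)
transcripts <- read_transcript_models(
  file.path(cohort, "transcripts.bed12"),
  file.path(cohort, "transcripts.fa"),
  gene_map = setNames(genes$gene, genes$transcript_id))
scored <- read_tsv(file.path(cohort, "mutations_scored.tsv"),
                   show_col_types = FALSE)
cfg <- jsonlite::read_json(file.path(cohort, "config.json"))
signature <- signature_model(unlist(cfg$signature))

d_cds <- positional_distribution(scored, by = "cds")
write_tsv(d_cds, file.path(cohort, "dist_cds.tsv"))
cat("CDS decile fractions (injected first-decile depletion 0.7):\n")
print(round(d_cds$fraction, 4))

write_tsv(positional_distribution(scored, by = "cds",
                                  stratify_by = "substitution_class"),
          file.path(cohort, "dist_cds_by_class.tsv"))
d_ex <- positional_distribution(scored, by = "internal_exon")
write_tsv(d_ex, file.path(cohort, "dist_internal_exon.tsv"))
cat("internal-exon decile fractions (edge depletion 0.7):\n")
print(round(d_ex$fraction, 4))
write_tsv(positional_distribution(scored, by = "first_200_codons"),
          file.path(cohort, "dist_first200.tsv"))

mb <- metric_by_bin(scored, "score", by = "cds")
write_tsv(mb, file.path(cohort, "score_by_cds_bin.tsv"))

aa_obs <- amino_acid_distribution(scored)
aa_exp <- expected_aa_distribution(codon_usage(transcripts), signature)
aa <- left_join(aa_obs, aa_exp, by = "amino_acid")
write_tsv(aa, file.path(cohort, "aa_observed_vs_expected.tsv"))
cat(sprintf("Trp expected share: %.4f; Spearman(observed, expected) = %.3f\n",
            aa$expected_share[aa$amino_acid == "W"],
            rank_correlation(aa$normalized_share, aa$expected_share)))

ps <- per_study_stratification(scored, metric = "score")
write_tsv(ps$selected, file.path(cohort, "studies_selected.tsv"))
write_tsv(ps$distributions, file.path(cohort, "dist_cds_per_study.tsv"))
cat(sprintf("per-study stratification over %d studies\n", nrow(ps$selected)))
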
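#!/usr/bin/env Rscript
# Annotate every curated mutation with recurrence, signature-normalized
# frequency, mutation load, positional and exon features, and the external
# reference joins (conservation, cancer genes, SNPs, FATHMM-MKL, CADD,
# ClinVar-like phenotypes).

library(synmut)
suppressMessages(library(readr))

cohort <- "results/cohort"
genes <- read_tsv(file.path(cohort, "genes.tsv"), show_col_types = FALSE)
transcripts <- read_transcript_models(
  file.path(cohort, "transcripts.bed12"),
  file.path(cohort, "transcripts.fa"),
  gene_map = setNames(genes$gene, genes$transcript_id))
curated <- read_tsv(file.path(cohort, "mutations_curated.tsv"),
                    show_col_types = FALSE)
cfg <- jsonlite::read_json(file.path(cohort, "config.json"))
signature <- signature_model(unlist(cfg$signature))

refs <- list(
  conservation = read_tsv(file.path(cohort, "conservation.tsv"), show_col_types = FALSE),
  cancer_genes = read_tsv(file.path(cohort, "cancer_genes.tsv"), show_col_types = FALSE),
  snps = read_tsv(file.path(cohort, "snps.tsv"), show_col_types = FALSE),
  fathmm = read_tsv(file.path(cohort, "fathmm.tsv"), show_col_types = FALSE),
  cadd = read_tsv(file.path(cohort, "cadd.tsv"), show_col_types = FALSE),
  clinvar = read_tsv(file.path(cohort, "clinvar.tsv"), show_col_types = FALSE)
)

annotated <- annotate_mutations(curated, transcripts, signature, refs)
write_tsv(annotated[, setdiff(names(annotated), "alt_events")],
          file.path(cohort, "mutations_annotated.tsv"))

syn <- annotated[annotated$consequence == "synonymous", ]
cat(sprintf("annotated %d rows; synonymous: %d\n", nrow(annotated), nrow(syn)))
cat(sprintf("recurrent synonymous occurrences: %.1f%%\n",
            100 * mean(syn$recurrent)))
cat(sprintf("C>T/G>A share among synonymous: %.1f%%\n",
            100 * mean(syn$substitution_class == "C>T")))
cat(sprintf("in cancer genes: %.1f%%; listed as SNP: %.1f%%\n",
            100 * mean(syn$cancer_gene), 100 * mean(syn$snp_flag)))
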
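#!/usr/bin/env Rscript
# Simulate the study cohort: a toy transcriptome plus a COSMIC-like somatic
# mutation catalog with mild 5'-CDS and exon-edge depletion, an aging-type
# substitution signature, heavy-tailed recurrence, and a negative
# structure-score/mutation-load association. All downstream analyses run on
# these files; everything is plain text.

library(synmut)
suppressMessages(library(readr))

out <- "results/cohort"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- synthetic_config(
  depletion_first_decile = 0.7,
  depletion_exon_edges = 0.7,
  score_load_correlation = -0.3,
  seed = 1234L
)

transcriptome <- generate_transcriptome(cfg)
write_transcriptome(transcriptome, out)
write_tsv(
  transcriptome$transcripts[, c("transcript_id", "gene", "code_table")],
  file.path(out, "genes.tsv"))

mutations <- generate_mutations(cfg, transcriptome)
write_mutation_table(mutations, file.path(out, "mutations_raw.tsv"))

refs <- generate_reference_tables(cfg, transcriptome, mutations)
write_tsv(refs$conservation, file.path(out, "conservation.tsv"))
write_tsv(refs$cancer_genes, file.path(out, "cancer_genes.tsv"))
write_tsv(refs$snps, file.path(out, "snps.tsv"))
write_tsv(refs$fathmm, file.path(out, "fathmm.tsv"))
write_tsv(refs$cadd, file.path(out, "cadd.tsv"))
write_tsv(refs$clinvar, file.path(out, "clinvar.tsv"))
write_tsv(refs$structure, file.path(out, "structure.tsv"))
jsonlite::write_json(c(unclass(cfg)[setdiff(names(cfg), "signature")],
                       list(signature = as.list(cfg$signature))),
                     file.path(out, "config.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat(sprintf("transcripts: %d (CDS %d-%d nt)\n", nrow(transcriptome$transcripts),
            min(cfg$cds_length_range), max(cfg$cds_length_range)))
cat(sprintf("raw catalog rows: %d from %d samples in %d studies\n",
            nrow(mutations), cfg$n_samples, cfg$n_studies))
cat(sprintf("consequence mix: %s\n",
            paste(names(table(mutations$consequence)),
                  table(mutations$consequence), collapse = ", ")))
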
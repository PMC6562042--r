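#!/usr/bin/env Rscript
# Curate the raw catalog: re-derive consequences from sequence under each
# transcript's genetic code, verify reference bases, standardize tumor tiers,
# and collapse per-sample duplicates onto the canonical transcript.

library(synmut)
suppressMessages(library(readr))

cohort <- "results/cohort"
genes <- read_tsv(file.path(cohort, "genes.tsv"), show_col_types = FALSE)
transcripts <- read_transcript_models(
  file.path(cohort, "transcripts.bed12"),
  file.path(cohort, "transcripts.fa"),
  gene_map = setNames(genes$gene, genes$transcript_id))
raw <- read_mutation_table(file.path(cohort, "mutations_raw.tsv"))

res <- curate_mutations(raw, transcripts)
write_tsv(res$curated, file.path(cohort, "mutations_curated.tsv"))
write_tsv(res$rejected, file.path(cohort, "mutations_rejected.tsv"))
write_tsv(res$log, file.path(cohort, "curation_log.tsv"))

print(res$log)
dups <- res$log$rows[res$log$step == "after_checks"] -
  res$log$rows[res$log$step == "after_dedup"]
cat(sprintf("removed %d duplicate rows (same variant, same sample)\n", dups))
cat(sprintf("curated: %d rows, %d synonymous (%.1f%%)\n",
            nrow(res$curated),
            sum(res$curated$consequence == "synonymous"),
            100 * mean(res$curated$consequence == "synonymous")))
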
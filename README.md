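# synmut — pan-cancer analysis of somatic synonymous mutations

Synonymous ("silent") point mutations do not change the protein sequence,
yet they can act through splicing regulation, mRNA secondary structure and
codon usage. `synmut` is an R package plus an analysis workflow for somatic
synonymous mutations in COSMIC-style catalogs, aimed at cancer-genomics
analysts who want the full chain — catalog curation, orthogonal annotation,
prioritization, and cohort-level statistics — as tested, reusable code.

The package implements:

* **Curation** — consequence re-derivation from transcript sequence under
  the standard and vertebrate-mitochondrial genetic codes, reference-base
  verification with quarantine of failures, per-sample deduplication onto a
  canonical transcript, and `Organ System-Site-Histology` tumor tiers.
* **Annotation** — recurrence (distinct carrier samples), the six
  strand-symmetric substitution classes, signature-normalized frequency
  `f·(1 − p)`, per-sample mutation loads, CDS/exon positional features, and
  exact-key joins to conservation, cancer-gene, SNP, FATHMM-MKL, CADD and
  ClinVar-style tables.
* **Prioritization** — the nine-parameter composite score

  ```
  S = (log2 f + 1)(1 − p) − log10 L + g + c + s + m + qC + qR
  ```

  (frequency f, signature probability p, average carrier load L,
  cancer-gene score g ∈ [0;2], conservation c, SNP score s, FATHMM-MKL m,
  and cohort quantile ranks qC/qR of CADD and RNA-structure scores), with
  leave-one-out diagnostics, top-decile retention and percentile
  thresholds.
* **Cohort statistics** — positional decile distributions (CDS, internal
  exons, first 200 codons; optionally per substitution class or study),
  metric-by-bin summaries with SEM and t-tests, observed-vs-expected
  amino-acid distributions from codon usage × signature, and top-study
  stratification.
* **Splicing motifs** — ESE/ESS catalog curation (duplicate merging,
  dual-role flags, IUPAC expansion) and per-mutation gain/loss scanning
  with overlapping-occurrence counts.
* **RNA-structure ranking** — export of folding-tool input windows, strict
  ingestion of remuRNA-/RNAsnp-style score tables, quantile ranks, Spearman
  comparisons, top-5th-percentile-by-decile analyses and load-binned score
  comparisons (folding itself is out of scope and ingested, not computed).
* **Synthetic data** — a deterministic generator for toy transcriptomes and
  COSMIC-like catalogs with injectable depletion, signature, load and
  recurrence structure, so everything above runs without external
  downloads.

## Worked example

The KRAS hotspot region is the package's built-in classification example
(`KRAS_CDS_75` is the first 75 nt of the KRAS coding sequence):

```r
library(synmut)
tx <- kras_transcript()
classify_consequence(tx, 30L, "A", "C")      # "synonymous"  (Gly10 GGA->GGC)
cds_position_features(36L, 75L)$codon_index  # 12
classify_consequence(tx, 36L, "T", "C")      # "synonymous"  (Gly12 GGT->GGC)
classify_consequence(tx, 35L, "G", "A")      # "missense"    (G12D-type)
```

A small end-to-end run on synthetic data:

```r
cfg <- synthetic_config(n_genes = 8, n_samples = 10,
                        cds_length_range = c(300L, 600L),
                        load_range = c(15L, 60L), seed = 99)
res <- run_pipeline(cfg, "run")
unlist(res$run_log$stages)
#>  simulate  curate  annotate  motifs  structure  score  distributions  export
#>       328     325       325      93         93    105             10     105
percentile_thresholds(res$scored$score)
#>   top_percent threshold
#> 1        50        2.08
#> 2        10        3.46
#> 3         1        5.75
#> ...
```

328 raw catalog rows curate to 325 (duplicate rows removed), of which 105
occurrences (93 distinct variants) are synonymous; each gets the full
annotation, motif, structure and score columns, and `run/database_table.tsv`
holds the flat export with a JSON column dictionary.

The `analysis/` directory contains the numbered workflow
(`01_simulate.R` … `07_distributions.R`) that runs the same stages as
narrative scripts on a 120-gene cohort with injected 5'-CDS and exon-edge
depletion, writing every table under `results/cohort/`:

```sh
for f in analysis/0*.R; do Rscript "$f"; done
```

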
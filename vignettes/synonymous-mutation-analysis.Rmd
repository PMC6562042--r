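---
title: "Methods: curation, annotation and prioritization of somatic synonymous mutations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curation, annotation and prioritization of somatic synonymous mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synmut)
```

## The problem

Synonymous (silent) point mutations leave the protein sequence unchanged but
can act through splicing regulation, mRNA secondary structure, codon usage
and translation kinetics. `synmut` implements a pan-cancer analysis workflow
for somatic synonymous mutations in COSMIC-style catalogs: curation of the
raw catalog, per-mutation annotation with orthogonal evidence, a composite
prioritization score, cohort-level positional statistics, splicing-motif
gain/loss scanning, and ranking analyses over ingested RNA-structure
aberration scores. Because the real inputs are large external downloads, the
package ships a synthetic-data generator that emulates their statistical
structure, so the entire workflow is exercised end-to-end by code alone.

## Curation model

A mutation record names a transcript, a sample, a study, a genomic locus and
an HGVS-like `c.` change on the coding strand. Curation re-derives every
consequence from the transcript sequence itself rather than trusting the
incoming label:

* a change is **synonymous** iff the reference and mutant codons translate
  identically under the transcript's genetic-code table; **nonsense** iff the
  mutant codon is a stop and the reference codon is not; loss of a reference
  stop is labelled `other`;
* mitochondrial transcripts are translated under the vertebrate
  mitochondrial code (table 2; TGA = Trp, ATA = Met), which reclassifies
  records annotated under the standard code — reclassified rows are flagged;
* records whose stated reference base disagrees with the transcript sequence
  are quarantined to a reject table with a reason, never silently dropped;
* indels and other non-point changes pass through as `other` and are
  excluded from the synonymous/missense analyses;
* duplicate entries of the same variant in the same sample (e.g. mappings to
  multiple transcripts of one gene) are collapsed to one row. The surviving
  mapping is the *canonical transcript*: longest CDS, ties broken
  lexicographically by transcript id. This retention rule is a package
  choice; any deterministic rule would serve, and it is centralized in
  `deduplicate()`.

Coordinate conventions are fixed package-wide: CDS/transcript coordinates
are 1-based inclusive (HGVS style), genomic intervals are 0-based half-open
(BED), and ref/alt alleles are always stored on the coding strand
(genomic-strand alleles are reverse-complemented on ingest for minus-strand
transcripts).

## Annotation

Each curated mutation receives:

* **frequency** — the number of distinct samples carrying the identical
  genomic variant across all tumor entities; *recurrent* means frequency
  greater than 1. Frequency is keyed on the genomic variant, so paralogous
  transcripts sharing a locus count once;
* **signature-normalized frequency** — `frequency × (1 − p)`, where `p` is
  the probability of the mutation's substitution class under a six-class
  strand-symmetric signature (the aging-type signature found across tumor
  entities, with roughly two thirds of its mass on C>T/G>A). A 96-channel
  signature is collapsed by summing context channels within each class,
  since the normalization concerns the nucleotide change, not its context;
* **mutation load** — per-sample totals over all consequence classes
  (emulating genome-wide sequencing), averaged over a mutation's carriers;
* **positional features** — CDS fraction, CDS decile
  (`ceiling(10·pos/len)`, clamped; a position exactly on a bin boundary
  belongs to the lower bin, so `pos = len` lands in decile 10), codon index,
  amino acid, and a 20-codon bin over the first 200 codons emitted only for
  CDS longer than 200 codons;
* **exon context** — first/internal/last/monoexonic in transcription order
  (strand-aware), the decile along internal exons in 5'→3' orientation, and
  the distance to the nearest end of the containing exon;
* **external joins** — conservation by locus, cancer-gene membership by
  symbol, SNP/FATHMM-MKL/CADD/ClinVar by exact genomic variant
  (chrom, pos, ref, alt); missing matches yield NA, never row loss, and
  duplicate keys in a reference table are an error. ClinVar phenotypes
  containing "cancer" or "tumor" (case-insensitive) are flagged
  cancer-related.

## The composite prioritization score

Nine parameters enter the score:

S = (log2 f + 1)·(1 − p) − log10 L + g + c + s + m + qC + qR

with frequency f ≥ 1, signature probability p, average carrier load L,
cancer-gene score g ∈ {0, 2} (the mapping is configurable; the default is
binary), conservation c ∈ [0, 1], SNP score s (1 if *not* listed as SNP),
FATHMM-MKL m ∈ [0, 1], and cohort-wide quantile ranks qC (CADD) and qR
(structure score) in [0, 1]. Design notes:

* the quantile-rank convention is `(number of values ≤ x)/n` with ties
  averaged, applied identically to CADD and the structure score; ranks are
  computed over the whole cohort before scoring;
* missing bounded evidence (c, m, qC, qR) imputes to 0 — absent evidence
  contributes nothing — and affected rows carry an `imputed` flag;
* leave-one-out diagnostics recompute the score nine times, each with one
  parameter neutralized (the `log2 f + 1` factor or the `(1 − p)` multiplier
  replaced by 1, the `− log10 L` term dropped, additive terms dropped);
  `top_decile_retention()` measures how much of the full-score top 10%
  survives each ablation;
* percentile thresholds (top 50/10/1/0.1/0.01%) are empirical quantiles of
  the cohort; absolute threshold values are cohort-specific by construction
  and are not comparable across cohorts.

## Positional and codon-expectation statistics

`positional_distribution()` bins mutations into CDS deciles, internal-exon
deciles, or 20-codon bins of the first 200 codons, optionally stratified by
substitution class or study; fractions are normalized within stratum.
`metric_by_bin()` adds per-bin means with SEM and a two-sample t-test of
each bin against all others. Two-group comparisons use an F-test of
variance equality at α = 0.05 to choose between Student and Welch t-tests;
raw p-values are reported by default with Benjamini–Hochberg correction
available behind `p.adjust` on the caller's side.

The amino-acid analysis normalizes observed per-amino-acid counts by the
number of codons per amino acid under the standard code. The independent
expectation enumerates, for each sense codon, its nine single-base
substitutions, sums the signature probabilities of the synonymous ones,
multiplies by the codon's usage frequency in the supplied transcriptome
(not an external reference table, keeping the pipeline closed over its
inputs), aggregates to amino acids and normalizes. Tryptophan and
methionine have no synonymous single-base route and get expectation 0.
Stop codons are excluded throughout.

## Splicing-motif scanning

ESE/ESS catalogs are curated by merging duplicate sequences (annotations
concatenated) and flagging motifs listed as both enhancer and silencer.
U maps to T on ingest; degenerate IUPAC codes are expanded to explicit base
sets at scan time. For each mutation a window of 100 nt flank (truncated at
transcript boundaries) is extracted, the substitution applied, and each
motif counted at every offset in both windows — overlapping matches count,
the conservative superset in the absence of a stated convention. Only
occurrences fully contained in the window count; a motif straddling a
truncated edge is not counted, a documented package choice. The signed
difference (mutant − wildtype) per motif is reported; the scan is
antisymmetric by construction and only motifs overlapping the mutated base
can change.

## RNA-structure ranking

Folding itself is out of process: the package exports per-mutation windows
(200 nt flank, truncated windows flagged and excluded from length-sensitive
summaries) as variant-tagged FASTA, and ingests remuRNA-style and
RNAsnp-style score tables under a strict column contract with key-integrity
checks. Analyses are the rankings: Spearman correlations between metrics
over pairwise-complete rows, the fraction of the global top 5th percentile
of structural impact within each CDS decile (under positional independence
every fraction is ~0.05, and the bin-weighted mean equals the realized
top-set share exactly), per-decile window GC/MFE means, and structure score
across mutation-load bins with adjacent-bin t-tests.

## The synthetic-data generator

The generator defines the study conditions; its defaults were fixed once,
from the cohort structure the analyses presuppose, and are not tuned to
test outcomes:

* **transcriptome** — 120 genes, one transcript each on its own contig; CDS
  length 300–2400 nt of random sense codons (start codon first, one stop
  last, no internal stops), UTRs 20–200 nt, 1–10 exons of ≥30 nt with
  60–400 nt introns, random strand. Both strands and mono- and multi-exonic
  architectures are always represented at defaults;
* **signature** — six-class probabilities (C>A .04, C>G .03, C>T .67,
  T>A .06, T>C .15, T>G .05), a collapsed aging-type signature whose
  C>T/G>A mass matches the ~two-thirds share seen among somatic synonymous
  mutations;
* **loads** — per-sample totals log-uniform over 50–2000 (40 samples in 6
  studies at defaults), giving the orders-of-magnitude spread in mutation
  burden that drives the load-related analyses;
* **placement and depletion** — an event's substitution class is drawn from
  the signature first; its position is then drawn among ref-compatible
  bases (C/G for pyrimidine-C-rooted classes, A/T otherwise). Position-first
  sampling cannot reproduce the configured class probabilities, so the
  class-first order is a correctness requirement, not a convenience.
  Depletion weights (first CDS decile; outer deciles of internal exons) are
  applied by allocating the candidate-site catalog across weight strata
  exactly proportional to weight × stratum size, with uniform
  without-replacement sampling inside each stratum. The event-level
  positional distribution therefore matches the closed-form thinning
  expectation (e.g. a first-decile weight of 0.5 yields an expected
  first-decile fraction of 0.5/9.5) up to the transcriptome's base
  composition, with no saturation bias;
* **recurrence** — events draw sites from the class's catalog with
  Zipf-like weights (exponent 0.5 over ~5 candidate sites per event).
  These two constants were calibrated once so that, at default cohort
  sizes, ~27% of catalog rows are recurrent with a heavy multiplicity
  tail — the recurrence structure of the real pan-cancer catalog — and were
  then frozen;
* **reference tables** — conservation, FATHMM-MKL, CADD, ClinVar-like
  phenotypes and structure scores are independent draws by default, so the
  score components are independent under the null; a Gaussian-copula knob
  (`score_load_correlation`) injects a structure-score/load association
  when an analysis needs a positive control. A 2% verbatim duplicate-row
  rate exercises curation's deduplication;
* **determinism** — every generator function derives its RNG stream from
  `config$seed`; a fixed seed reproduces outputs byte-identically.

What the generator does **not** emulate: trinucleotide-context (96-channel)
signature structure, germline variation, gene-length and expression biases,
regional mutation-rate covariates (replication timing, chromatin), multiple
transcripts per gene, and any real correlation structure among the evidence
tracks. Passing tests therefore demonstrate correctness of the computations
and recovery of injected structure, not biological conclusions about real
cohorts.

## Numerical choices and edge cases

* Decile of a boundary position goes to the lower-indexed bin (ceil rule).
* `quantile_rank` maps into (0, 1], ties share the mean rank, NAs pass
  through; all-NA input is an error.
* Top-percentile membership takes the `round(n·p/100)` highest values by
  rank; with distinct scores and n divisible by 100/p the selected share is
  exact.
* Degenerate two-group comparisons (zero variance in both groups, equal
  means) return p = 1 by convention.
* Empty positional strata are omitted; bins with n < 2 report NA SEM and no
  test.
* Windows shorter than 2·flank+1 are flagged `truncated` and excluded from
  length-sensitive structure summaries.
* Percentile thresholds use R's default empirical quantile (type 7).

## Problem sizes

The test suite runs small cohorts (8–15 genes) for unit behavior, a
120-gene default cohort (~20k mutations) for integration properties, and
400-gene cohorts (~120k mutations) for the calibration checks of the
uniform null and the injected first-decile depletion; Monte-Carlo standard
errors for decile fractions account for recurrence clustering via site
multiplicities (Var = p(1−p)·Σm²/N²). The acceptance script pools three
independent 500-gene replicates (~750k mutation rows, ~590k distinct
variants). These sizes were chosen so that Monte-Carlo error is small
against the quantities being checked while the whole suite remains quick to
run.

## Known limitations

* One transcript per gene in the generator; multi-isoform deduplication is
  exercised through constructed fixtures instead.
* The cancer-gene score mapping `{0, 2}` is binary; a tiered mapping can be
  supplied via `cgc_map` in `score_cohort()`.
* Whether raw frequency should be capped before entering the score is an
  open design point; the package uses the raw distinct-sample count.
* Absolute score thresholds depend on the cohort and are not transferable.
* The motif catalogs bundled under `inst/extdata` are synthetic stand-ins
  shaped like the real ESE/ESS compilations; analyses of real data should
  ingest the real catalogs via `read_motif_catalog()`.
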
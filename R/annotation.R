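#' Per-mutation frequency (recurrence)
#'
#' Frequency of a mutation is the number of distinct samples carrying the
#' identical genomic variant across all tumor entities; a mutation is
#' recurrent iff it occurs in more than one sample.
#'
#' @param curated Deduplicated curated table with `mutation_id`, `sample_id`.
#' @return Tibble `mutation_id`, `frequency`, `recurrent`.
#' @export
compute_frequency <- function(curated) {
  curated |>
    dplyr::group_by(.data$mutation_id) |>
    dplyr::summarise(frequency = dplyr::n_distinct(.data$sample_id),
                     .groups = "drop") |>
    dplyr::mutate(recurrent = .data$frequency > 1L)
}

#' Signature-normalized frequency
#'
#' Down-weights recurrence of substitution types that are common under the
#' mutational signature: `frequency * (1 - p)` where `p` is the signature
#' probability of the mutation's substitution class.
#'
#' @param frequency Sample counts (>= 1).
#' @param p Class probabilities in \[0, 1\].
#' @return Numeric vector.
#' @export
signature_normalized_frequency <- function(frequency, p) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  frequency * (1 - p)
}

#' Per-sample mutation loads and per-mutation average loads
#'
#' The load (mutation burden) of a sample is its total number of curated
#' mutations of any consequence class; each mutation's `avg_mutation_load` is
#' the mean load over its carrier samples.
#'
#' @param curated Curated table (all consequence classes).
#' @return List with `sample_loads` (`sample_id`, `load`) and
#'   `mutation_loads` (`mutation_id`, `avg_mutation_load`).
#' @export
mutation_load <- function(curated) {
  sample_loads <- dplyr::count(curated, .data$sample_id, name = "load")
  mutation_loads <- curated |>
    dplyr::left_join(sample_loads, by = "sample_id") |>
    dplyr::group_by(.data$mutation_id) |>
    dplyr::summarise(avg_mutation_load = mean(.data$load), .groups = "drop")
  list(sample_loads = sample_loads, mutation_loads = mutation_loads)
}

#' Positional features within the coding sequence
#'
#' Decile is `ceiling(10 * cds_pos / cds_len)` clamped to \[1, 10\] (a
#' position exactly on a bin boundary belongs to the lower-indexed bin);
#' codon index is `ceiling(cds_pos / 3)`. The first-200-codon bin (20-codon
#' bins 1..10) is only emitted for CDS longer than 200 codons and positions
#' within the first 200 codons.
#'
#' @param cds_pos 1-based CDS positions.
#' @param cds_len CDS lengths (recycled).
#' @return Tibble `cds_fraction`, `cds_decile`, `codon_index`,
#'   `first200_bin` (NA where not applicable).
#' @export
cds_position_features <- function(cds_pos, cds_len) {
  if (any(cds_pos < 1L | cds_pos > cds_len)) stop("cds_pos out of range")
  decile <- pmin(pmax(ceiling(10 * cds_pos / cds_len), 1L), 10L)
  codon <- ceiling(cds_pos / 3)
  first200 <- ifelse(cds_len > 600L & codon <= 200L,
                     pmin(pmax(ceiling(codon / 20), 1L), 10L), NA_integer_)
  tibble::tibble(
    cds_fraction = cds_pos / cds_len,
    cds_decile = as.integer(decile),
    codon_index = as.integer(codon),
    first200_bin = as.integer(first200)
  )
}

#' Exon context of a genomic position on a transcript
#'
#' Labels the containing exon in transcription order (strand-aware) as
#' `first`, `internal`, `last` or `monoexonic`; for internal exons also
#' returns the decile of the position along the exon in 5'->3' transcript
#' orientation, and for every exon the distance (nt) to the nearest end of
#' the containing exon.
#'
#' @param transcript One-row transcript tibble.
#' @param genomic_pos 1-based genomic positions (must be exonic).
#' @return Tibble `exon_context`, `internal_exon_decile`, `boundary_distance`.
#' @export
exon_context <- function(transcript, genomic_pos) {
  tpos <- genome_to_transcript(transcript, genomic_pos)
  exon_context_tpos(transcript, tpos)
}

exon_context_tpos <- function(transcript, tpos) {
  ex <- exon_table(transcript)
  n_ex <- nrow(ex)
  idx <- findInterval(tpos, ex$tx_start)
  in_pos <- tpos - ex$tx_start[idx] + 1L
  w <- ex$width[idx]
  context <- dplyr::case_when(
    n_ex == 1L ~ "monoexonic",
    idx == 1L ~ "first",
    idx == n_ex ~ "last",
    TRUE ~ "internal"
  )
  decile <- ifelse(context == "internal",
                   pmin(pmax(ceiling(10 * in_pos / w), 1L), 10L), NA_integer_)
  tibble::tibble(
    exon_context = context,
    internal_exon_decile = as.integer(decile),
    boundary_distance = as.integer(pmin(in_pos - 1L, w - in_pos))
  )
}

#' Alternative-event overlap
#'
#' Returns, per locus, the set of alternative-event labels (cassetteExon,
#' retainedIntron, ...) whose intervals contain the locus.
#'
#' @param loci Tibble with `chrom`, `pos` (1-based).
#' @param events Tibble with `chrom`, `start0`, `end0` (0-based half-open),
#'   `event` label.
#' @return List-column tibble: `alt_events` (character vector per locus,
#'   possibly empty) and `alt_events_str` (`;`-collapsed, "" if none).
#' @export
alt_event_overlap <- function(loci, events) {
  out <- replicate(nrow(loci), character(0), simplify = FALSE)
  if (nrow(events) > 0 && nrow(loci) > 0) {
    q <- GenomicRanges::GRanges(loci$chrom, IRanges::IRanges(loci$pos, loci$pos))
    s <- GenomicRanges::GRanges(events$chrom,
                                IRanges::IRanges(events$start0 + 1L, events$end0))
    hits <- GenomicRanges::findOverlaps(q, s)
    if (length(hits) > 0) {
      byq <- split(events$event[S4Vectors::subjectHits(hits)],
                   S4Vectors::queryHits(hits))
      for (k in names(byq)) out[[as.integer(k)]] <- sort(unique(byq[[k]]))
    }
  }
  tibble::tibble(
    alt_events = out,
    alt_events_str = vapply(out, paste, character(1), collapse = ";")
  )
}

assert_unique_key <- function(tbl, keys, what) {
  if (nrow(tbl) == 0) return(invisible(TRUE))
  d <- tbl[duplicated(tbl[keys]), keys, drop = FALSE]
  if (nrow(d) > 0) {
    stop("duplicate key(s) in ", what, " reference table: ",
         paste(do.call(paste, c(d[1, ], sep = ":")), collapse = ", "))
  }
  invisible(TRUE)
}

#' Join external reference tables onto a mutation table
#'
#' Variant-level tables join on (`chrom`, `pos`, genomic `ref`, `alt`);
#' conservation on (`chrom`, `pos`); gene-level lists on the gene symbol.
#' Missing matches yield NA/FALSE, never row loss. ClinVar matches whose
#' phenotype list contains "cancer" or "tumor" (case-insensitive) are flagged
#' cancer-related.
#'
#' @param tbl Mutation table with `chrom`, `pos`, `strand`, `ref`, `alt`
#'   (coding strand), `gene`.
#' @param conservation Tibble `chrom`, `pos`, `phastcons`.
#' @param cancer_genes Tibble with column `gene` (or character vector).
#' @param snps Tibble keyed `chrom`, `pos`, `ref`, `alt` (genomic alleles).
#' @param fathmm,cadd Variant-keyed score tibbles (`fathmm`, `cadd_raw`).
#' @param clinvar Variant-keyed tibble with `phenotype_list`.
#' @return `tbl` with `phastcons`, `cancer_gene`, `snp_listed`, `fathmm`,
#'   `cadd_raw`, `clinvar_match`, `clinvar_cancer` columns appended.
#' @export
external_joins <- function(tbl, conservation = NULL, cancer_genes = NULL,
                           snps = NULL, fathmm = NULL, cadd = NULL,
                           clinvar = NULL) {
  ga <- genomic_alleles(tbl$ref, tbl$alt, tbl$strand)
  key <- dplyr::mutate(tbl, .gref = ga$g_ref, .galt = ga$g_alt)
  by_var <- c(chrom = "chrom", pos = "pos", .gref = "ref", .galt = "alt")

  if (!is.null(conservation)) {
    assert_unique_key(conservation, c("chrom", "pos"), "conservation")
    key <- dplyr::left_join(key, conservation, by = c("chrom", "pos"))
  } else key$phastcons <- NA_real_
  if (!is.null(cancer_genes)) {
    cg <- if (is.data.frame(cancer_genes)) cancer_genes$gene else cancer_genes
    key$cancer_gene <- key$gene %in% cg
  } else key$cancer_gene <- NA
  if (!is.null(snps)) {
    assert_unique_key(snps, c("chrom", "pos", "ref", "alt"), "SNP")
    snp_key <- paste(snps$chrom, snps$pos, snps$ref, snps$alt)
    key$snp_listed <- paste(key$chrom, key$pos, key$.gref, key$.galt) %in% snp_key
  } else key$snp_listed <- NA
  if (!is.null(fathmm)) {
    assert_unique_key(fathmm, c("chrom", "pos", "ref", "alt"), "FATHMM-MKL")
    key <- dplyr::left_join(key, fathmm, by = by_var)
  } else key$fathmm <- NA_real_
  if (!is.null(cadd)) {
    assert_unique_key(cadd, c("chrom", "pos", "ref", "alt"), "CADD")
    key <- dplyr::left_join(key, cadd, by = by_var)
  } else key$cadd_raw <- NA_real_
  if (!is.null(clinvar)) {
    assert_unique_key(clinvar, c("chrom", "pos", "ref", "alt"), "ClinVar")
    key <- dplyr::left_join(
      key, dplyr::rename(clinvar, clinvar_match = "phenotype_list"), by = by_var)
    key$clinvar_cancer <- !is.na(key$clinvar_match) &
      grepl("cancer|tumor", key$clinvar_match, ignore.case = TRUE)
  } else {
    key$clinvar_match <- NA_character_
    key$clinvar_cancer <- NA
  }
  dplyr::select(key, -".gref", -".galt")
}

#' Annotate a curated mutation table
#'
#' Attaches all per-mutation features used by the cohort analyses: frequency
#' and recurrence, signature-normalized frequency, substitution class, average
#' mutation load of carrier samples, CDS positional features (fraction,
#' decile, codon index, amino acid, first-200-codon bin), exon context
#' (first/internal/last/monoexonic, internal-exon decile, boundary distance),
#' alternative-event overlap, and the external reference joins.
#'
#' @param curated Curated table from [curate_mutations()] (point mutations
#'   with `cds_pos`/`ref`/`alt`; `"other"` rows are carried through with NA
#'   positional features).
#' @param transcripts Transcript-model tibble.
#' @param signature A [signature_model()].
#' @param refs Optional named list of reference tables as accepted by
#'   [external_joins()], plus optionally `alt_events`.
#' @return Annotated tibble (one row per curated mutation occurrence).
#' @export
annotate_mutations <- function(curated, transcripts, signature,
                               refs = list()) {
  tbl <- curated
  point <- !is.na(tbl$cds_pos)

  freq <- compute_frequency(tbl)
  loads <- mutation_load(tbl)
  tbl <- tbl |>
    dplyr::left_join(freq, by = "mutation_id") |>
    dplyr::left_join(loads$mutation_loads, by = "mutation_id")

  tbl$substitution_class <- NA_character_
  tbl$substitution_class[point] <-
    substitution_class(tbl$ref[point], tbl$alt[point])
  tbl$signature_p <- unname(signature[tbl$substitution_class])
  tbl$signature_normalized_frequency <- ifelse(
    point, signature_normalized_frequency(tbl$frequency, tbl$signature_p), NA)

  # positional + exon features, per transcript
  tbl$cds_fraction <- NA_real_
  tbl$cds_decile <- NA_integer_
  tbl$codon_index <- NA_integer_
  tbl$first200_bin <- NA_integer_
  tbl$amino_acid <- NA_character_
  tbl$exon_context <- NA_character_
  tbl$internal_exon_decile <- NA_integer_
  tbl$boundary_distance <- NA_integer_
  for (id in unique(tbl$transcript_id[point])) {
    tx <- transcripts[transcripts$transcript_id == id, ]
    sel <- which(point & tbl$transcript_id == id)
    L <- cds_length(tx)
    cf <- cds_position_features(tbl$cds_pos[sel], L)
    tbl$cds_fraction[sel] <- cf$cds_fraction
    tbl$cds_decile[sel] <- cf$cds_decile
    tbl$codon_index[sel] <- cf$codon_index
    tbl$first200_bin[sel] <- cf$first200_bin
    cds <- cds_sequence(tx)
    cstart <- (cf$codon_index - 1L) * 3L + 1L
    tbl$amino_acid[sel] <- translate_codon(
      substring(cds, cstart, cstart + 2L), tx$code_table)
    ec <- exon_context_tpos(tx, tx$cds_start + tbl$cds_pos[sel] - 1L)
    tbl$exon_context[sel] <- ec$exon_context
    tbl$internal_exon_decile[sel] <- ec$internal_exon_decile
    tbl$boundary_distance[sel] <- ec$boundary_distance
  }

  if (!is.null(refs$alt_events)) {
    ev <- alt_event_overlap(tbl[, c("chrom", "pos")], refs$alt_events)
    tbl <- dplyr::bind_cols(tbl, ev)
  }
  external_joins(tbl,
                 conservation = refs$conservation,
                 cancer_genes = refs$cancer_genes,
                 snps = refs$snps,
                 fathmm = refs$fathmm,
                 cadd = refs$cadd,
                 clinvar = refs$clinvar)
}
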
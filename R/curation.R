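#' Three-tier tumor categorization
#'
#' Builds the `Organ System-Site-Histology` tier string; blank or missing
#' fields map to `"NS"` (not specified).
#'
#' @param organ_system,primary_site,histology Character vectors.
#' @return Character vector of tier strings.
#' @export
categorize_tumor <- function(organ_system, primary_site, histology) {
  ns <- function(x) {
    x <- as.character(x)
    x[is.na(x) | trimws(x) == ""] <- "NS"
    x
  }
  paste(ns(organ_system), ns(primary_site), ns(histology), sep = "-")
}

#' @rdname categorize_tumor
#' @param tiers Tier strings produced by `categorize_tumor()`.
#' @return `split_tumor_tiers()` returns a tibble with the three fields.
#' @export
split_tumor_tiers <- function(tiers) {
  m <- stringr::str_split_fixed(tiers, "-", 3)
  tibble::tibble(organ_system = m[, 1], primary_site = m[, 2], histology = m[, 3])
}

parse_cds_change <- function(cds_change) {
  m <- stringr::str_match(cds_change, "^c\\.(\\d+)([ACGT])>([ACGT])$")
  tibble::tibble(
    cds_pos = as.integer(m[, 2]),
    ref = m[, 3],
    alt = m[, 4]
  )
}

# Genomic-strand alleles of a coding-strand change.
genomic_alleles <- function(ref, alt, strand) {
  minus <- strand == "-"
  tibble::tibble(
    g_ref = ifelse(minus, complement_base(ref), ref),
    g_alt = ifelse(minus, complement_base(alt), alt)
  )
}

#' Recompute consequences under the transcript's genetic-code table
#'
#' Corrects records classified under the wrong code table (notably standard
#' code applied to mitochondrial transcripts). Nuclear records whose stored
#' consequence already matches are untouched; any record whose class changes
#' is flagged.
#'
#' @param records Curated-style table with `transcript_id`, `cds_pos`, `ref`,
#'   `alt` and `consequence` columns.
#' @param transcripts Transcript-model tibble.
#' @return `records` with recomputed `consequence` and a logical
#'   `consequence_changed` column.
#' @export
apply_code_table_correction <- function(records, transcripts) {
  bad <- setdiff(unique(records$transcript_id), transcripts$transcript_id)
  if (length(bad)) stop("unknown transcript(s): ", paste(bad, collapse = ", "))
  if (!all(transcripts$code_table %in%
           c("standard", "vertebrate_mitochondrial"))) {
    stop("configuration error: unknown code table")
  }
  old <- records$consequence
  records$consequence <- recompute_consequence(records, transcripts)
  records$consequence_changed <- records$consequence != old
  records
}

recompute_consequence <- function(records, transcripts) {
  out <- character(nrow(records))
  for (id in unique(records$transcript_id)) {
    tx <- transcripts[transcripts$transcript_id == id, ]
    sel <- which(records$transcript_id == id)
    out[sel] <- classify_codon_change(cds_sequence(tx), records$cds_pos[sel],
                                      records$alt[sel], tx$code_table)
  }
  out
}

#' Remove duplicate entries of the same mutation in the same sample
#'
#' At most one row is retained per (genomic variant, sample). When a variant
#' maps to multiple transcripts of a gene in one sample, the mapping on the
#' canonical transcript survives: the transcript with the longest CDS, ties
#' broken lexicographically by transcript id.
#'
#' @param records Table with `mutation_id`, `sample_id` and `transcript_id`.
#' @param transcripts Transcript-model tibble (for CDS lengths).
#' @return Deduplicated table (row order by mutation then sample).
#' @export
deduplicate <- function(records, transcripts) {
  if (nrow(records) == 0) return(records)
  cds_len <- tibble::tibble(
    transcript_id = transcripts$transcript_id,
    .cds_len = transcripts$cds_end - transcripts$cds_start + 1L
  )
  records |>
    dplyr::left_join(cds_len, by = "transcript_id") |>
    dplyr::arrange(.data$mutation_id, .data$sample_id,
                   dplyr::desc(.data$.cds_len), .data$transcript_id) |>
    dplyr::distinct(.data$mutation_id, .data$sample_id, .keep_all = TRUE) |>
    dplyr::select(-".cds_len")
}

#' Curate a raw COSMIC-like mutation catalog
#'
#' The curation stage of the pipeline: parses HGVS-like c. notation, verifies
#' the reference base against the transcript sequence, re-derives consequences
#' from sequence under each transcript's genetic-code table, standardizes the
#' tumor tiers, assigns genomic variant identities, and removes per-sample
#' duplicates (keeping the canonical-transcript mapping). Non-point changes
#' pass through with consequence `"other"` and are excluded from
#' synonymous/missense analyses downstream. Records that fail checks are
#' quarantined with a reason, never silently dropped.
#'
#' @param raw Raw catalog (columns as produced by [generate_mutations()]).
#' @param transcripts Transcript-model tibble.
#' @return List with `curated` (tibble incl. `mutation_id`, `cds_pos`, `ref`,
#'   `alt`, recomputed `consequence`, `tumor_tier`), `rejected` (quarantined
#'   rows with `reject_reason`), and `log` (per-step row accounting).
#' @export
curate_mutations <- function(raw, transcripts) {
  n_in <- nrow(raw)
  parsed <- parse_cds_change(raw$cds_change)
  rec <- dplyr::bind_cols(raw[setdiff(names(raw), c("ref", "alt", "cds_pos"))],
                          parsed)
  point <- !is.na(rec$cds_pos)

  rejected <- rec[0, ]
  rejected$reject_reason <- character(0)

  # unknown transcripts
  known <- rec$transcript_id %in% transcripts$transcript_id
  if (any(!known)) {
    rejected <- dplyr::bind_rows(
      rejected, dplyr::mutate(rec[!known, ], reject_reason = "unknown_transcript"))
    rec <- rec[known, ]
    point <- point[known]
  }

  cds_len <- stats::setNames(transcripts$cds_end - transcripts$cds_start + 1L,
                             transcripts$transcript_id)
  cds_seq <- stats::setNames(
    vapply(seq_len(nrow(transcripts)),
           function(i) cds_sequence(transcripts[i, ]), character(1)),
    transcripts$transcript_id)

  in_range <- !point | (rec$cds_pos >= 1L &
                          rec$cds_pos <= cds_len[rec$transcript_id])
  if (any(!in_range)) {
    rejected <- dplyr::bind_rows(
      rejected, dplyr::mutate(rec[!in_range, ], reject_reason = "cds_pos_out_of_range"))
    rec <- rec[in_range, ]
    point <- point[in_range]
  }

  seq_base <- rep(NA_character_, nrow(rec))
  seq_base[point] <- substring(cds_seq[rec$transcript_id[point]],
                               rec$cds_pos[point], rec$cds_pos[point])
  ref_ok <- !point | seq_base == rec$ref
  if (any(!ref_ok)) {
    rejected <- dplyr::bind_rows(
      rejected, dplyr::mutate(rec[!ref_ok, ], reject_reason = "reference_mismatch"))
    rec <- rec[ref_ok, ]
    point <- point[ref_ok]
  }

  # consequence re-derivation (incl. genetic-code correction)
  rec$consequence[!point] <- "other"
  pt <- apply_code_table_correction(rec[point, ], transcripts)
  rec$consequence[point] <- pt$consequence
  rec$consequence_changed <- FALSE
  rec$consequence_changed[point] <- pt$consequence_changed

  rec$tumor_tier <- categorize_tumor(rec$organ_system, rec$primary_site,
                                     rec$histology)
  ga <- genomic_alleles(rec$ref, rec$alt, rec$strand)
  rec$mutation_id <- ifelse(
    point,
    paste0(rec$chrom, ":", rec$pos, ":", ga$g_ref, ">", ga$g_alt),
    paste0(rec$chrom, ":", rec$pos, ":", rec$cds_change)
  )
  n_before_dedup <- nrow(rec)
  curated <- deduplicate(rec, transcripts)

  log <- tibble::tibble(
    step = c("input", "unknown_transcript", "cds_pos_out_of_range",
             "reference_mismatch", "after_checks", "after_dedup"),
    rows = c(n_in,
             sum(rejected$reject_reason == "unknown_transcript"),
             sum(rejected$reject_reason == "cds_pos_out_of_range"),
             sum(rejected$reject_reason == "reference_mismatch"),
             n_before_dedup, nrow(curated))
  )
  list(curated = curated, rejected = rejected, log = log)
}
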
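#' Curate an ESE/ESS motif catalog
#'
#' Merges duplicate motif sequences, concatenating the annotation of each
#' appearance; motifs that appear with both enhancer and silencer annotations
#' are flagged `"both"`. RNA alphabets are mapped to DNA (U -> T) on ingest;
#' degenerate IUPAC codes are retained in the catalog and expanded to explicit
#' base sets at scan time.
#'
#' @param entries Tibble/data.frame with columns `sequence`, `role` (`"ESE"`
#'   or `"ESS"`) and `annotation`.
#' @param source_name Label for the catalog's provenance.
#' @return Tibble (`sequence`, `role`, `sources`, `source_name`) with unique
#'   sequences; `role` is `"ESE"`, `"ESS"` or `"both"`.
#' @export
curate_catalog <- function(entries, source_name = "catalog") {
  seqs <- toupper(gsub("U", "T", toupper(entries$sequence)))
  if (any(is.na(seqs) | seqs == "")) stop("empty motif sequence")
  valid <- grepl(sprintf("^[%s]+$", paste(names(Biostrings::IUPAC_CODE_MAP),
                                          collapse = "")), seqs)
  if (!all(valid)) {
    stop("invalid motif character(s) in: ",
         paste(unique(entries$sequence[!valid]), collapse = ", "))
  }
  if (!all(entries$role %in% c("ESE", "ESS"))) stop("role must be ESE or ESS")
  tibble::tibble(sequence = seqs, role = entries$role,
                 annotation = as.character(entries$annotation)) |>
    dplyr::group_by(.data$sequence) |>
    dplyr::summarise(
      role = if (dplyr::n_distinct(.data$role) > 1) "both" else .data$role[1],
      sources = paste(.data$annotation, collapse = ";"),
      .groups = "drop"
    ) |>
    dplyr::mutate(source_name = source_name)
}

#' Read a motif catalog from TSV
#'
#' Expects columns `sequence`, `role`, `annotation` (extra columns ignored).
#'
#' @param path TSV path.
#' @inheritParams curate_catalog
#' @return Curated catalog tibble.
#' @export
read_motif_catalog <- function(path, source_name = basename(path)) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  curate_catalog(raw[, c("sequence", "role", "annotation")], source_name)
}

#' Extract the local sequence window around a transcript position
#'
#' The window spans `flank` nt on each side of the position, truncated at the
#' transcript boundaries; the 0-based offset of the position within the
#' window is returned alongside.
#'
#' @param transcript One-row transcript tibble.
#' @param position 1-based transcript coordinate.
#' @param flank Nucleotides of flank on each side (>= 0).
#' @return List with `window` (character), `offset0` (0-based offset of
#'   `position` in `window`) and `truncated` (TRUE if either flank was cut).
#' @export
extract_window <- function(transcript, position, flank) {
  stopifnot(flank >= 0)
  n <- nchar(transcript$sequence[1])
  if (position < 1L || position > n) stop("position outside transcript")
  lo <- max(1L, position - flank)
  hi <- min(n, position + flank)
  list(
    window = substr(transcript$sequence[1], lo, hi),
    offset0 = position - lo,
    truncated = (position - flank < 1L) || (position + flank > n)
  )
}

# All explicit DNA sequences matching a (possibly IUPAC-degenerate) motif.
expand_iupac <- function(motif) {
  sets <- strsplit(Biostrings::IUPAC_CODE_MAP[strsplit(motif, "")[[1]]], "")
  do.call(paste0, rev(expand.grid(rev(sets), stringsAsFactors = FALSE)))
}

# Overlapping occurrence count of an explicit motif in a window.
count_occurrences <- function(window, motif) {
  if (nchar(motif) > nchar(window)) return(0L)
  Biostrings::countPattern(motif, Biostrings::DNAString(window))
}

#' Motif gains and losses between wildtype and mutant windows
#'
#' For each catalog motif, counts occurrences at every offset (overlapping
#' matches included, degenerate motifs expanded to their explicit base sets)
#' in both windows and reports the signed difference
#' `delta = count(mutant) - count(wildtype)`. Only nonzero deltas are emitted.
#'
#' @param wt_window,mut_window Sequence windows differing at exactly one
#'   position.
#' @param catalog Curated catalog from [curate_catalog()].
#' @return Tibble `sequence`, `role`, `delta` (rows with `delta != 0`).
#' @export
scan_gain_loss <- function(wt_window, mut_window, catalog) {
  if (nchar(wt_window) != nchar(mut_window)) {
    stop("windows must have equal length")
  }
  diffs <- which(strsplit(wt_window, "")[[1]] != strsplit(mut_window, "")[[1]])
  if (length(diffs) > 1L) {
    stop("windows must differ at exactly one position (found ",
         length(diffs), ")")
  }
  if (length(diffs) == 0L) {
    return(tibble::tibble(sequence = character(0), role = character(0),
                          delta = integer(0)))
  }
  wt_d <- Biostrings::DNAString(wt_window)
  mut_d <- Biostrings::DNAString(mut_window)
  expansions <- attr(catalog, "expansions")
  if (is.null(expansions)) expansions <- lapply(catalog$sequence, expand_iupac)
  count_all <- function(expl, subject) {
    sum(vapply(expl, function(m) {
      if (nchar(m) > length(subject)) 0L
      else Biostrings::countPattern(m, subject)
    }, integer(1)))
  }
  delta <- vapply(expansions, function(expl) {
    count_all(expl, mut_d) - count_all(expl, wt_d)
  }, numeric(1))
  out <- tibble::tibble(sequence = catalog$sequence, role = catalog$role,
                        delta = as.integer(delta))
  out[out$delta != 0L, ]
}

#' Scan all mutations of a cohort for ESE/ESS motif changes
#'
#' Extracts the wildtype window around each point mutation, applies the
#' substitution, and runs [scan_gain_loss()]. Emits a per-mutation summary
#' (any-change flag, gain/loss counts) and the long per-motif diff table.
#'
#' @param annotated Annotated table (needs `mutation_id`, `transcript_id`,
#'   `cds_pos`, `ref`, `alt`); typically filtered to synonymous rows first.
#' @param transcripts Transcript-model tibble.
#' @param catalog Curated catalog.
#' @param flank Window flank in nt (default 100).
#' @return List with `summary` (per mutation: `n_gain`, `n_loss`,
#'   `any_change`) and `diffs` (long format, one row per mutation x motif
#'   with nonzero delta).
#' @export
scan_mutation_windows <- function(annotated, transcripts, catalog,
                                  flank = 100L) {
  rows <- dplyr::distinct(annotated, .data$mutation_id, .data$transcript_id,
                          .data$cds_pos, .data$ref, .data$alt)
  attr(catalog, "expansions") <- lapply(catalog$sequence, expand_iupac)
  diffs <- purrr::map_dfr(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    tx <- transcripts[transcripts$transcript_id == r$transcript_id, ]
    w <- extract_window(tx, tx$cds_start + r$cds_pos - 1L, flank)
    mut <- w$window
    substring(mut, w$offset0 + 1L, w$offset0 + 1L) <- r$alt
    d <- scan_gain_loss(w$window, mut, catalog)
    if (nrow(d) == 0) return(NULL)
    dplyr::mutate(d, mutation_id = r$mutation_id, .before = 1)
  })
  summary <- rows |>
    dplyr::left_join(
      if (nrow(diffs)) {
        diffs |>
          dplyr::group_by(.data$mutation_id) |>
          dplyr::summarise(n_gain = sum(.data$delta > 0),
                           n_loss = sum(.data$delta < 0), .groups = "drop")
      } else tibble::tibble(mutation_id = character(0),
                            n_gain = integer(0), n_loss = integer(0)),
      by = "mutation_id") |>
    dplyr::mutate(
      n_gain = dplyr::coalesce(.data$n_gain, 0L),
      n_loss = dplyr::coalesce(.data$n_loss, 0L),
      any_change = .data$n_gain + .data$n_loss > 0L
    )
  list(summary = summary, diffs = diffs)
}
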
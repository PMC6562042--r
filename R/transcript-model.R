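#' Construct a transcript model
#'
#' A transcript model ties together exon structure on the genome, the spliced
#' transcript sequence, and the CDS interval in transcript coordinates.
#' Conventions (used everywhere in the package): genomic exon intervals are
#' 0-based half-open (BED); transcript and CDS coordinates are 1-based
#' inclusive (HGVS c. style); `sequence` and all ref/alt alleles are on the
#' coding strand.
#'
#' @param transcript_id,gene Identifiers.
#' @param chrom Contig name.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts0,exon_ends0 Integer vectors of genomic exon bounds,
#'   0-based half-open, sorted by genomic coordinate.
#' @param cds_start,cds_end 1-based transcript coordinates of the CDS
#'   (inclusive); length must be divisible by 3.
#' @param sequence Spliced transcript sequence (coding strand).
#' @param code_table `"standard"` or `"vertebrate_mitochondrial"`.
#' @return A one-row tibble; several rows bound together form the
#'   `transcripts` table of a transcriptome.
#' @export
transcript_model <- function(transcript_id, gene, chrom, strand,
                             exon_starts0, exon_ends0,
                             cds_start, cds_end, sequence,
                             code_table = "standard") {
  stopifnot(strand %in% c("+", "-"), length(exon_starts0) == length(exon_ends0))
  exon_starts0 <- as.integer(exon_starts0)
  exon_ends0 <- as.integer(exon_ends0)
  if (is.unsorted(exon_starts0, strictly = TRUE) ||
      any(exon_ends0 <= exon_starts0) ||
      any(utils::head(exon_ends0, -1) > utils::tail(exon_starts0, -1))) {
    stop("exon intervals must be disjoint, ordered and non-empty")
  }
  widths <- exon_ends0 - exon_starts0
  if (sum(widths) != nchar(sequence)) {
    stop("exon widths must sum to transcript length")
  }
  cds_len <- cds_end - cds_start + 1L
  if (cds_len %% 3L != 0L) stop("CDS length must be divisible by 3")
  tx <- tibble::tibble(
    transcript_id = transcript_id, gene = gene, chrom = chrom, strand = strand,
    exon_starts0 = list(exon_starts0), exon_ends0 = list(exon_ends0),
    cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
    sequence = sequence, code_table = code_table
  )
  first_aa <- translate_codon(substr(sequence, cds_start, cds_start + 2L), code_table)
  if (first_aa != "M") stop("CDS must begin with a start codon under its code table")
  tx
}

#' CDS sequence and length of a transcript row
#' @param transcript A one-row transcript tibble.
#' @return Character scalar / integer scalar.
#' @export
cds_sequence <- function(transcript) {
  substr(transcript$sequence[1], transcript$cds_start[1], transcript$cds_end[1])
}

#' @rdname cds_sequence
#' @export
cds_length <- function(transcript) {
  transcript$cds_end[1] - transcript$cds_start[1] + 1L
}

#' Per-exon table in transcription order
#'
#' @param transcript A one-row transcript tibble.
#' @return Tibble with one row per exon in 5'->3' transcript order:
#'   `exon_rank`, genomic `start0`/`end0`, `width`, and the transcript
#'   coordinates `tx_start`/`tx_end` (1-based inclusive) it spans.
#' @export
exon_table <- function(transcript) {
  s0 <- transcript$exon_starts0[[1]]
  e0 <- transcript$exon_ends0[[1]]
  if (transcript$strand[1] == "-") {
    ord <- rev(seq_along(s0))
  } else {
    ord <- seq_along(s0)
  }
  w <- (e0 - s0)[ord]
  tx_end <- cumsum(w)
  tibble::tibble(
    exon_rank = seq_along(ord),
    start0 = s0[ord], end0 = e0[ord], width = w,
    tx_start = tx_end - w + 1L, tx_end = tx_end
  )
}

#' Map transcript coordinates to genomic coordinates (and back)
#'
#' @param transcript A one-row transcript tibble.
#' @param tpos 1-based transcript positions.
#' @param gpos 1-based genomic positions (must fall in an exon).
#' @return Integer vector of mapped positions (1-based).
#' @export
transcript_to_genome <- function(transcript, tpos) {
  ex <- exon_table(transcript)
  idx <- findInterval(tpos, ex$tx_start)
  if (any(tpos < 1L | tpos > max(ex$tx_end))) stop("transcript position out of range")
  off <- tpos - ex$tx_start[idx]
  if (transcript$strand[1] == "+") {
    as.integer(ex$start0[idx] + off + 1L)
  } else {
    as.integer(ex$end0[idx] - off)
  }
}

#' @rdname transcript_to_genome
#' @export
genome_to_transcript <- function(transcript, gpos) {
  ex <- exon_table(transcript)
  g0 <- gpos - 1L
  hit <- vapply(g0, function(p) {
    w <- which(ex$start0 <= p & p < ex$end0)
    if (length(w) != 1L) NA_integer_ else w
  }, integer(1))
  if (anyNA(hit)) stop("genomic position not exonic for this transcript")
  if (transcript$strand[1] == "+") {
    as.integer(ex$tx_start[hit] + (g0 - ex$start0[hit]))
  } else {
    as.integer(ex$tx_start[hit] + (ex$end0[hit] - 1L - g0))
  }
}

#' Write a toy transcriptome to FASTA + BED12
#'
#' Emits `genome.fa` (contigs), `transcripts.fa` (spliced transcript
#' sequences, coding strand) and `transcripts.bed12` (12-column BED, 0-based
#' half-open, blockStarts relative to chromStart; thickStart/thickEnd mark the
#' genomic CDS span).
#'
#' @param transcriptome A list with elements `transcripts` (tibble of
#'   transcript-model rows) and `genome` (named character vector of contigs).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_transcriptome <- function(transcriptome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome_fa <- file.path(dir, "genome.fa")
  tx_fa <- file.path(dir, "transcripts.fa")
  bed <- file.path(dir, "transcripts.bed12")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(transcriptome$genome), genome_fa
  )
  txs <- transcriptome$transcripts
  seqs <- Biostrings::DNAStringSet(stats::setNames(txs$sequence, txs$transcript_id))
  Biostrings::writeXStringSet(seqs, tx_fa)
  lines <- vapply(seq_len(nrow(txs)), function(i) {
    tx <- txs[i, ]
    s0 <- tx$exon_starts0[[1]]
    e0 <- tx$exon_ends0[[1]]
    chrom_start <- min(s0)
    g_cds <- transcript_to_genome(tx, c(tx$cds_start, tx$cds_end))
    paste(
      tx$chrom, chrom_start, max(e0), tx$transcript_id, 0L, tx$strand,
      min(g_cds) - 1L, max(g_cds), "0", length(s0),
      paste0(paste(e0 - s0, collapse = ","), ","),
      paste0(paste(s0 - chrom_start, collapse = ","), ","),
      sep = "\t"
    )
  }, character(1))
  writeLines(lines, bed)
  invisible(c(genome = genome_fa, transcripts = tx_fa, bed12 = bed))
}

#' Read transcript models from BED12 + transcript FASTA
#'
#' Inverse of [write_transcriptome()] for the transcript table. Contigs named
#' `chrM`/`MT` are assigned the vertebrate mitochondrial code table.
#'
#' @param bed12_path Path to a 12-column BED file.
#' @param transcripts_fasta Path to the spliced transcript FASTA whose names
#'   match the BED `name` column.
#' @param gene_map Optional named character vector transcript_id -> gene
#'   symbol; defaults to the transcript id.
#' @return Tibble of transcript-model rows.
#' @export
read_transcript_models <- function(bed12_path, transcripts_fasta, gene_map = NULL) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("read_transcript_models() requires the rtracklayer package")
  }
  gr <- rtracklayer::import(bed12_path, format = "BED")
  seqs <- Biostrings::readDNAStringSet(transcripts_fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  rows <- lapply(seq_along(gr), function(i) {
    g <- gr[i]
    id <- g$name
    blocks <- IRanges::shift(g$blocks[[1]], GenomicRanges::start(g) - 1L)
    s0 <- IRanges::start(blocks) - 1L
    e0 <- IRanges::end(blocks)
    chrom <- as.character(GenomicRanges::seqnames(g))
    strand <- as.character(GenomicRanges::strand(g))
    seq <- as.character(seqs[[id]])
    tmp <- tibble::tibble(
      transcript_id = id, gene = id, chrom = chrom, strand = strand,
      exon_starts0 = list(s0), exon_ends0 = list(e0),
      cds_start = 1L, cds_end = 3L, sequence = seq, code_table = "standard"
    )
    thick <- g$thick
    t_ends <- genome_to_transcript(tmp, c(IRanges::start(thick), IRanges::end(thick)))
    gene <- if (!is.null(gene_map) && id %in% names(gene_map)) gene_map[[id]] else id
    transcript_model(
      transcript_id = id, gene = gene, chrom = chrom, strand = strand,
      exon_starts0 = s0, exon_ends0 = e0,
      cds_start = min(t_ends), cds_end = max(t_ends), sequence = seq,
      code_table = if (chrom %in% c("chrM", "MT")) "vertebrate_mitochondrial" else "standard"
    )
  })
  dplyr::bind_rows(rows)
}
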
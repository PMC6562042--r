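#' KRAS coding-sequence fragment (worked example)
#'
#' The first 75 nt of the human KRAS coding sequence (codons 1-25, the
#' G-domain N-terminus spanning the hotspot codons 12/13), used as the
#' package's worked example for consequence classification: c.30A>C is a
#' synonymous Gly10 change (GGA -> GGC) and c.36T>C is a synonymous Gly12
#' change (GGT -> GGC).
#'
#' @format A length-1 character vector (75 nt).
#' @export
KRAS_CDS_75 <- "ATGACTGAATATAAACTTGTGGTAGTTGGAGCTGGTGGCGTAGGCAAGAGTGCCTTGACGATACAGCTAATTCAG"

#' Transcript model of the KRAS fragment
#'
#' Wraps [KRAS_CDS_75] as a monoexonic plus-strand transcript whose CDS is
#' the whole sequence, so the classification and positional operations can be
#' applied to it directly.
#'
#' @return One-row transcript-model tibble.
#' @export
kras_transcript <- function() {
  transcript_model(
    transcript_id = "KRAS_fragment", gene = "KRAS", chrom = "KRAS_ctg",
    strand = "+", exon_starts0 = 0L, exon_ends0 = nchar(KRAS_CDS_75),
    cds_start = 1L, cds_end = nchar(KRAS_CDS_75),
    sequence = KRAS_CDS_75, code_table = "standard"
  )
}
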
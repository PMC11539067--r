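#' Apply a deletion to a coding sequence
#'
#' Removes \code{n} bases starting at 0-based position \code{pos}
#' (end-exclusive coordinates), as for the 4-nt frameshift deletion in the
#' second exon of \emph{zfyve26}.
#'
#' @param cds Nucleotide string (A/C/G/T).
#' @param pos 0-based deletion start.
#' @param n Deletion length (>= 0).
#' @return The mutated sequence.
#' @export
apply_deletion <- function(cds, pos, n) {
  stopifnot(is.character(cds), length(cds) == 1, n >= 0, pos >= 0)
  L <- nchar(cds)
  if (pos + n > L) stop("deletion out of range: pos + n exceeds sequence")
  paste0(substr(cds, 1, pos), substr(cds, pos + n + 1, L))
}

#' Count residues translated before the first stop codon
#'
#' Translates the CDS in frame from its initiator ATG with the standard
#' genetic code and counts the amino acids preceding the first in-frame
#' stop. A frameshift that introduces a premature stop is therefore scored
#' by how much protein remains.
#'
#' @param cds Nucleotide string starting with ATG.
#' @return List: \code{n_aa} (residues before the first stop; the
#'   initiator methionine counts as residue 1), \code{has_stop} (FALSE
#'   when no in-frame stop exists, flagging a non-terminating read-through).
#' @export
translate_to_stop <- function(cds) {
  cds <- toupper(cds)
  if (grepl("[^ACGT]", cds)) stop("non-ACGT characters in sequence")
  if (substr(cds, 1, 3) != "ATG") stop("sequence must start with ATG")
  n_codon <- nchar(cds) %/% 3
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(cds, 1, n_codon * 3)),
    if.fuzzy.codon = "X"))
  stop_pos <- regexpr("*", aa, fixed = TRUE)
  if (stop_pos == -1) {
    list(n_aa = nchar(aa), has_stop = FALSE)
  } else {
    list(n_aa = as.integer(stop_pos) - 1L, has_stop = TRUE)
  }
}

#' Truncated protein length
#'
#' Length arithmetic for truncating alleles: a full-length protein of
#' \code{full_length_aa} residues losing \code{aa_lost} residues leaves a
#' \code{full_length_aa - aa_lost} residue product (e.g. 2552 - 282 = 2270
#' for the splice-site allele).
#'
#' @param full_length_aa Full protein length (aa).
#' @param aa_lost Residues lost (0 <= aa_lost <= full_length_aa).
#' @return Truncated length (aa).
#' @export
truncation_length <- function(full_length_aa, aa_lost) {
  stopifnot(full_length_aa >= 0, aa_lost >= 0)
  if (aa_lost > full_length_aa)
    stop("cannot lose more residues than the protein has")
  full_length_aa - aa_lost
}

#' Allele truncation report
#'
#' One-row summary of a deletion allele: applies the deletion, translates
#' to the first stop, and reports the truncated product length.
#'
#' @param cds Reference CDS (string, or path to a FASTA file read with
#'   \code{Biostrings::readDNAStringSet}).
#' @param pos,n Deletion coordinates as in [apply_deletion()].
#' @param allele Allele name for the report.
#' @return One-row data.frame: allele, cds_length, deletion_pos,
#'   deletion_len, frameshift, product_aa, full_product_aa, has_stop.
#' @export
allele_report <- function(cds, pos, n, allele = "allele") {
  if (file.exists(cds)) {
    cds <- as.character(Biostrings::readDNAStringSet(cds)[[1]])
  }
  mut <- apply_deletion(cds, pos, n)
  tr_wt <- translate_to_stop(cds)
  tr_mut <- translate_to_stop(mut)
  data.frame(allele = allele, cds_length = nchar(cds), deletion_pos = pos,
             deletion_len = n, frameshift = (n %% 3) != 0,
             product_aa = tr_mut$n_aa, full_product_aa = tr_wt$n_aa,
             has_stop = tr_mut$has_stop)
}
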
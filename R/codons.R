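# Genetic-code constants shared across modules. All sequences are DNA
# (T, not U); helpers accept RNA-style codons and convert.

.genetic_code <- function() Biostrings::GENETIC_CODE

#' The 61 sense codons
#'
#' DNA-alphabet sense codons (the standard genetic code minus the three
#' stop codons), in lexicographic order.
#'
#' @return Character vector of length 61.
#' @export
sense_codons <- function() {
  gc <- .genetic_code()
  sort(names(gc)[gc != "*"])
}

#' Stop codons of the standard genetic code
#'
#' @return Character vector (`TAA`, `TAG`, `TGA`).
#' @export
stop_codons <- function() {
  gc <- .genetic_code()
  sort(names(gc)[gc == "*"])
}

.as_dna_codon <- function(codon) {
  toupper(chartr("Uu", "Tt", codon))
}

.codon_aa <- function(codon) {
  unname(.genetic_code()[.as_dna_codon(codon)])
}

#' Classify leucine and serine codons by A/U- versus G/C-richness
#'
#' The Leu/Ser codon families split into an A/U-rich class, decoded by the
#' tRNAs whose loss triggers ribosome stalling, and a G/C-rich class decoded
#' by unaffected tRNAs. Leucine: UUA, UUG, CUA, CUU are `UA_rich`; CUC and
#' CUG are `CG_rich`. Serine is classified analogously by the package's
#' convention: UCA, UCU, AGU are `UA_rich`; UCC, UCG, AGC are `CG_rich`.
#' Codons of any other amino acid map to `other`.
#'
#' @param codon Character vector of codons (DNA or RNA alphabet).
#' @return Character vector over `{"UA_rich", "CG_rich", "other"}`.
#' @examples
#' classify_leu_ser(c("TTA", "CTG", "AAA"))
#' @export
classify_leu_ser <- function(codon) {
  codon <- .as_dna_codon(codon)
  bad <- !codon %in% names(.genetic_code())
  if (any(bad)) {
    stop("not a codon: ", paste(unique(codon[bad]), collapse = ", "))
  }
  ua <- c("TTA", "TTG", "CTA", "CTT", "TCA", "TCT", "AGT")
  cg <- c("CTC", "CTG", "TCC", "TCG", "AGC")
  out <- rep("other", length(codon))
  out[codon %in% ua] <- "UA_rich"
  out[codon %in% cg] <- "CG_rich"
  out
}

# anticodon (DNA) -> display form used in gene ids (RNA-style)
.rna_display <- function(x) chartr("T", "U", x)
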
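# Synthetic coding transcriptome: CDS sets with controllable codon
# composition and optionally embedded codon runs (reporter-style constructs).

#' Generate a synthetic coding transcriptome
#'
#' Each CDS starts with ATG, ends with a single stop codon, contains no
#' internal stops, and draws its internal codons from the 61 sense codons
#' with the given composition weights. Specific codon runs (for example a
#' `3x UUA` reporter cassette) can be embedded at requested positions.
#'
#' @param n_genes Number of genes (>= 1).
#' @param length_range Two integers: min/max CDS length in codons, including
#'   the start and stop codons.
#' @param codon_weights Named nonnegative vector over sense codons (subset
#'   allowed; missing codons get weight 0). `NULL` means uniform. A positive
#'   weight on a stop codon is an error.
#' @param embedded_runs Optional list of lists with fields `gene` (index or
#'   `gene_id`), `after` (1-based codon number; the run replaces the codons
#'   immediately following it) and `codons` (character vector of sense
#'   codons, DNA or RNA alphabet).
#' @param seed Integer seed.
#' @return An object of class `transcriptome`: list with `genes`, a
#'   data.frame (`gene_id`, `cds_sequence`, `n_codons`).
#' @examples
#' tx <- make_transcriptome(n_genes = 5, seed = 1)
#' @export
make_transcriptome <- function(n_genes = 100, length_range = c(200, 400),
                               codon_weights = NULL, embedded_runs = NULL,
                               seed = 1) {
  stopifnot(n_genes >= 1, length(length_range) == 2,
            length_range[1] >= 4, length_range[1] <= length_range[2])
  sense <- sense_codons()
  if (is.null(codon_weights)) {
    w <- setNames(rep(1, length(sense)), sense)
  } else {
    names(codon_weights) <- .as_dna_codon(names(codon_weights))
    if (any(names(codon_weights) %in% stop_codons() & codon_weights > 0)) {
      stop("stop codons cannot receive coding-position weight")
    }
    w <- setNames(rep(0, length(sense)), sense)
    keep <- intersect(names(codon_weights), sense)
    w[keep] <- codon_weights[keep]
    if (sum(w) <= 0) stop("codon weights sum to zero")
  }
  withr::with_seed(seed, {
    lens <- sample(length_range[1]:length_range[2], n_genes, replace = TRUE)
    codons <- lapply(lens, function(L) {
      c("ATG", sample(sense, L - 2, replace = TRUE, prob = w),
        sample(stop_codons(), 1))
    })
    gene_id <- sprintf("gene%03d", seq_len(n_genes))
    if (!is.null(embedded_runs)) {
      for (run in embedded_runs) {
        gi <- if (is.character(run$gene)) match(run$gene, gene_id) else
          as.integer(run$gene)
        if (is.na(gi) || gi < 1 || gi > n_genes) stop("unknown gene in run")
        cods <- .as_dna_codon(run$codons)
        if (any(cods %in% stop_codons())) {
          stop("embedded runs may not contain stop codons")
        }
        at <- run$after + seq_along(cods)     # 1-based codon numbers
        if (max(at) >= lens[gi]) stop("embedded run overruns the CDS")
        codons[[gi]][at] <- cods
      }
    }
    genes <- data.frame(
      gene_id = gene_id,
      cds_sequence = vapply(codons, paste, "", collapse = ""),
      n_codons = lens, stringsAsFactors = FALSE)
    structure(list(genes = genes), class = "transcriptome")
  })
}

#' @export
print.transcriptome <- function(x, ...) {
  cat(sprintf("transcriptome: %d CDS, %d--%d codons\n", nrow(x$genes),
              min(x$genes$n_codons), max(x$genes$n_codons)))
  invisible(x)
}

#' Split CDS sequences into codon vectors
#'
#' @param txome A `transcriptome` (or any data.frame with `gene_id` and
#'   `cds_sequence`).
#' @return Named list of character vectors of codons, one per gene.
#' @export
codon_array <- function(txome) {
  g <- if (inherits(txome, "transcriptome")) txome$genes else txome
  out <- lapply(g$cds_sequence, function(s) {
    substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  })
  names(out) <- g$gene_id
  out
}

#' Write CDS sequences as FASTA
#'
#' @param txome A `transcriptome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(txome, path) {
  ss <- Biostrings::DNAStringSet(txome$genes$cds_sequence)
  names(ss) <- txome$genes$gene_id
  Biostrings::writeXStringSet(ss, filepath = path)
  invisible(path)
}

#' Read a CDS FASTA into a transcriptome
#'
#' @param path FASTA path.
#' @return A `transcriptome` object.
#' @export
read_cds_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  genes <- data.frame(gene_id = sub(" .*", "", names(ss)),
                      cds_sequence = as.character(ss),
                      stringsAsFactors = FALSE)
  genes$n_codons <- nchar(genes$cds_sequence) %/% 3L
  structure(list(genes = genes), class = "transcriptome")
}
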
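# Codon-composition statistics: usage frequencies against a background,
# within-amino-acid-family skew, and dipeptide enrichment.

.cds_genes <- function(cds_set) {
  if (inherits(cds_set, "transcriptome")) return(cds_set$genes)
  if (is.data.frame(cds_set)) return(cds_set)
  if (is.character(cds_set)) {
    ids <- if (is.null(names(cds_set))) {
      sprintf("seq%03d", seq_along(cds_set))
    } else names(cds_set)
    return(data.frame(gene_id = ids, cds_sequence = unname(cds_set),
                      stringsAsFactors = FALSE))
  }
  stop("unsupported CDS set")
}

.check_cds <- function(genes) {
  n <- nchar(genes$cds_sequence)
  bad <- which(n %% 3 != 0)
  if (length(bad)) {
    stop("CDS length not divisible by 3: ", genes$gene_id[bad[1]])
  }
  cods <- codon_array(genes)
  for (i in seq_along(cods)) {
    v <- cods[[i]]
    internal <- v[-length(v)]
    if (any(internal %in% stop_codons())) {
      stop("internal stop codon in ", genes$gene_id[i])
    }
  }
  cods
}

#' Codon usage of a CDS set
#'
#' Computes per-gene sense-codon frequency vectors (the terminal stop codon
#' is excluded) and averages them unweighted across genes, so long genes do
#' not dominate the set average. A pooled mode (single frequency vector over
#' all codon occurrences) is available behind `pooled = TRUE`.
#'
#' @param cds_set A `transcriptome`, a data.frame with `gene_id` and
#'   `cds_sequence`, or a character vector of CDS strings.
#' @param pooled Pool codon counts across genes instead of averaging
#'   per-gene frequencies.
#' @return Named numeric vector over the 61 sense codons, class
#'   `codon_usage`, with attributes `n_genes` and `pooled`. Frequencies sum
#'   to 1.
#' @examples
#' codon_usage(c(g1 = "ATGTTATAA"))
#' @export
codon_usage <- function(cds_set, pooled = FALSE) {
  genes <- .cds_genes(cds_set)
  if (!nrow(genes)) stop("empty CDS set")
  cods <- .check_cds(genes)
  sense <- sense_codons()
  tally <- function(v) {
    v <- v[-length(v)]                     # drop the terminal stop
    tab <- table(factor(v, levels = sense))
    as.numeric(tab)
  }
  counts <- vapply(cods, tally, numeric(length(sense)))
  freq <- if (pooled) {
    tot <- rowSums(counts)
    tot / sum(tot)
  } else {
    rowMeans(sweep(counts, 2, colSums(counts), "/"))
  }
  structure(setNames(freq, sense), class = "codon_usage",
            n_genes = nrow(genes), pooled = pooled)
}

#' Family-relative codon frequencies
#'
#' For every codon, its frequency relative to the summed frequency of its
#' amino-acid family: `r(c) = f(c) / sum over the family of f`. Families
#' with zero total frequency are omitted.
#'
#' @param usage A [codon_usage()] vector.
#' @return Data.frame (`codon`, `amino_acid`, `f`, `r`); within each
#'   represented family the `r` values sum to 1.
#' @export
family_relative <- function(usage) {
  sense <- sense_codons()
  f <- as.numeric(usage[sense])
  aa <- .codon_aa(sense)
  fam_tot <- tapply(f, aa, sum)
  out <- data.frame(codon = sense, amino_acid = aa, f = f,
                    r = f / as.numeric(fam_tot[aa]),
                    stringsAsFactors = FALSE)
  out[is.finite(out$r), ]
}

#' Codon skew of a gene set against a background
#'
#' The skew of a codon is the difference of its family-relative frequencies
#' in the set and the background (`r_set - r_background`); within a family
#' the skews sum to zero. The absolute frequencies `f_set` and
#' `f_background` are carried alongside for frequency-vs-frequency
#' comparisons.
#'
#' @param set_usage,background_usage [codon_usage()] vectors.
#' @return Data.frame (`codon`, `amino_acid`, `f_set`, `f_background`,
#'   `r_set`, `r_background`, `skew`), restricted to families represented in
#'   both usages.
#' @export
skew <- function(set_usage, background_usage) {
  a <- family_relative(set_usage)
  b <- family_relative(background_usage)
  shared <- intersect(a$codon, b$codon)
  a <- a[match(shared, a$codon), ]
  b <- b[match(shared, b$codon), ]
  data.frame(codon = shared, amino_acid = a$amino_acid,
             f_set = a$f, f_background = b$f,
             r_set = a$r, r_background = b$r,
             skew = a$r - b$r, stringsAsFactors = FALSE)
}

.aa_pairs <- function(genes) {
  prot <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(genes$cds_sequence)))
  prot <- sub("\\*$", "", prot)
  pairs <- unlist(lapply(prot, function(p) {
    n <- nchar(p)
    if (n < 2) return(character())
    paste0(substring(p, 1:(n - 1), 1:(n - 1)),
           substring(p, 2:n, 2:n))
  }), use.names = FALSE)
  pairs
}

#' Dipeptide (amino-acid pair) frequencies and enrichment
#'
#' Translates each CDS (dropping the stop), counts adjacent amino-acid
#' pairs pooled over the set, and reports the log2 enrichment of each pair
#' against the background set with a pseudocount.
#'
#' @param cds_set,background_set CDS sets (see [codon_usage()]).
#' @param pseudocount Added to both frequencies before the ratio.
#' @return Data.frame (`aa_pair`, `freq_set`, `freq_background`,
#'   `log2_enrichment`) over the 400 standard pairs; both frequency columns
#'   sum to 1.
#' @export
dipeptide_freq <- function(cds_set, background_set, pseudocount = 1e-6) {
  genes_s <- .cds_genes(cds_set)
  genes_b <- .cds_genes(background_set)
  .check_cds(genes_s)
  .check_cds(genes_b)
  aa20 <- sort(unique(.genetic_code()[.genetic_code() != "*"]))
  lv <- as.vector(outer(aa20, aa20, function(a, b) paste0(a, b)))
  cnt <- function(genes) {
    tab <- table(factor(.aa_pairs(genes), levels = lv))
    as.numeric(tab) / max(sum(tab), 1)
  }
  fs <- cnt(genes_s)
  fb <- cnt(genes_b)
  data.frame(aa_pair = lv, freq_set = fs, freq_background = fb,
             log2_enrichment = log2((fs + pseudocount) /
                                      (fb + pseudocount)),
             stringsAsFactors = FALSE)
}
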
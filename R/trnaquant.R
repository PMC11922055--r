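# Isodecoder quantification tolerant of modification-induced mismatches,
# differential abundance, and anticodon-level aggregation.

.parse_mm_positions <- function(x) {
  lapply(strsplit(x, ",", fixed = TRUE), function(p) {
    if (!length(p) || identical(p, "")) integer() else as.integer(p)
  })
}

#' Quantify isodecoder abundance from alignments
#'
#' Each read contributes weight `1 / multimap_count` to the genes it aligns
#' to. Mismatches at tolerated sites (by default the annotated C12
#' acetylation positions, which misincorporate in modification-carrying
#' reads) are forgiven before the mismatch-fraction test, so modified
#' molecules are not discarded from their gene of origin.
#'
#' @param alns An `alignment_set` from [align_ungapped()].
#' @param ref A `trna_reference`.
#' @param tolerated_sites Named list of 0-based position vectors per
#'   `gene_id`, or `NULL` for the default (each gene's `c12_index`).
#' @param max_mismatch_frac Mismatch-fraction ceiling applied after
#'   forgiveness.
#' @param condition,replicate Labels recorded on the output.
#' @return Data.frame (`gene_id`, `condition`, `replicate`, `count`,
#'   `proportion`) of class `abundance_table`; proportions sum to 1 within
#'   the replicate. Empty alignments yield an empty table with a warning.
#' @export
quantify <- function(alns, ref, tolerated_sites = NULL,
                     max_mismatch_frac = 0.1, condition = "WT",
                     replicate = 1) {
  g <- ref$genes
  if (is.null(tolerated_sites)) {
    has <- !is.na(g$c12_index)
    tolerated_sites <- setNames(as.list(g$c12_index[has]), g$gene_id[has])
  }
  empty <- data.frame(gene_id = character(), condition = character(),
                      replicate = integer(), count = numeric(),
                      proportion = numeric(), stringsAsFactors = FALSE)
  if (!nrow(alns)) {
    warning("empty alignment set")
    return(structure(empty, class = c("abundance_table", "data.frame")))
  }
  mmpos <- .parse_mm_positions(alns$mismatch_positions)
  tol <- tolerated_sites[alns$ref_id]
  n_forgiven <- mapply(function(p, t) {
    if (is.null(t)) 0L else sum(p %in% t)
  }, mmpos, tol)
  read_len <- alns$ref_end - alns$ref_start
  keep <- (alns$n_mismatch - n_forgiven) <= max_mismatch_frac * read_len
  a <- alns[keep, , drop = FALSE]
  if (!nrow(a)) {
    warning("no alignments survive the mismatch filter")
    return(structure(empty, class = c("abundance_table", "data.frame")))
  }
  dt <- data.table::as.data.table(a[, c("read_id", "ref_id")])
  dt[, weight := 1 / .N, by = read_id]
  counts <- dt[, .(count = sum(weight)), by = ref_id]
  out <- data.frame(gene_id = counts$ref_id, condition = condition,
                    replicate = replicate, count = counts$count,
                    proportion = counts$count / sum(counts$count),
                    stringsAsFactors = FALSE)
  structure(out[order(out$gene_id), ],
            class = c("abundance_table", "data.frame"))
}

#' Differential isodecoder abundance between conditions
#'
#' Log2 fold changes compare mean KO and WT proportions (with a pseudocount);
#' p values come from a two-sided pooled-variance two-sample t test on log
#' proportions across replicates, adjusted by Benjamini-Hochberg. The pooled
#' test is exactly calibrated under the null at the small replicate numbers
#' typical of these designs, where the Welch approximation is conservative.
#' Genes absent from one condition are treated as proportion 0 there.
#'
#' @param wt,ko `abundance_table`s, each stacking >= 1 replicates (>= 2 per
#'   condition for p values).
#' @param pseudocount Added to proportions before logs and ratios.
#' @return Data.frame (`gene_id`, `mean_wt`, `mean_ko`, `log2fc`, `p_value`,
#'   `p_adjusted`).
#' @export
differential <- function(wt, ko, pseudocount = 1e-6) {
  genes <- sort(union(wt$gene_id, ko$gene_id))
  grab <- function(tbl, gid) {
    reps <- sort(unique(tbl$replicate))
    vapply(reps, function(r) {
      p <- tbl$proportion[tbl$gene_id == gid & tbl$replicate == r]
      if (length(p)) p[1] else 0
    }, 0)
  }
  rows <- lapply(genes, function(gid) {
    pw <- grab(wt, gid)
    pk <- grab(ko, gid)
    l2 <- log2((mean(pk) + pseudocount) / (mean(pw) + pseudocount))
    p <- NA_real_
    if (length(pw) >= 2 && length(pk) >= 2) {
      p <- tryCatch(
        t.test(log(pk + pseudocount), log(pw + pseudocount),
               var.equal = TRUE)$p.value,
        error = function(e) NA_real_)
    }
    data.frame(gene_id = gid, mean_wt = mean(pw), mean_ko = mean(pk),
               log2fc = l2, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  out
}

#' Aggregate isodecoder abundance to the anticodon level
#'
#' Sums counts and proportions over all isodecoders sharing an anticodon
#' (within condition and replicate); totals are conserved.
#'
#' @param tbl An `abundance_table`.
#' @param ref Optional `trna_reference` supplying the gene-to-anticodon map;
#'   without it the map is parsed from gene ids of the form
#'   `<Aa>-<anticodon>-<copy>`.
#' @return Data.frame (`anticodon_id`, `condition`, `replicate`, `count`,
#'   `proportion`).
#' @export
aggregate_by_anticodon <- function(tbl, ref = NULL) {
  if (!is.null(ref)) {
    g <- ref$genes
    key <- setNames(paste(g$amino_acid, .rna_display(g$anticodon), sep = "-"),
                    g$gene_id)
    grp <- key[tbl$gene_id]
  } else {
    grp <- sub("-[^-]*$", "", tbl$gene_id)
  }
  dt <- data.table::data.table(anticodon_id = grp,
                               condition = tbl$condition,
                               replicate = tbl$replicate,
                               count = tbl$count,
                               proportion = tbl$proportion)
  out <- dt[, .(count = sum(count), proportion = sum(proportion)),
            by = .(anticodon_id, condition, replicate)]
  as.data.frame(out[order(anticodon_id)])
}
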
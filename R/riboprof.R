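# Codon-resolution occupancy analysis for monosome and disome footprints,
# meta-codon profiles, per-gene tracks, and translation-efficiency sets.

#' Partition footprints into monosome and disome size classes
#'
#' Monosomes are lengths in `[25, 40)`, disomes `[40, 80]` (the shared
#' boundary length 40 is assigned to the disome class); all other lengths
#' are dropped and counted.
#'
#' @param fp Footprint data.frame (see [simulate_footprints()]).
#' @return List with elements `mono`, `di` (footprint data.frames with the
#'   `library` column set) and `n_dropped`.
#' @export
partition_by_size <- function(fp) {
  mono <- fp[fp$length >= 25 & fp$length < 40, , drop = FALSE]
  di <- fp[fp$length >= 40 & fp$length <= 80, , drop = FALSE]
  if (nrow(mono)) mono$library <- "mono"
  if (nrow(di)) di$library <- "di"
  list(mono = mono, di = di,
       n_dropped = nrow(fp) - nrow(mono) - nrow(di))
}

#' Assign footprints to A-site codons
#'
#' `codon_index = floor((five_prime_pos + offset - cds_start) / 3)`, with the
#' offset looked up per (library, length). Footprints whose length has no
#' offset, or whose A site falls outside the CDS, get `NA` and are counted.
#'
#' @param fp Footprint data.frame with `transcript_id`, `five_prime_pos`,
#'   `length`, `library`.
#' @param offsets Offset table, see [default_offsets()].
#' @param txome A `transcriptome` (bounds the codon index per gene);
#'   alternatively pass `cds_len` as a named vector in codons.
#' @param cds_start Transcript coordinate of the first CDS nucleotide.
#' @return `fp` with an added integer column `codon_index` (0-based);
#'   attributes `n_no_offset` and `n_outside_cds`.
#' @export
assign_asite <- function(fp, offsets = default_offsets(), txome = NULL,
                         cds_start = 0, cds_len = NULL) {
  key <- paste(fp$library, fp$length)
  off <- offsets$offset[match(key, paste(offsets$library, offsets$length))]
  ci <- as.integer(floor((fp$five_prime_pos + off - cds_start) / 3))
  n_no_offset <- sum(is.na(off))
  if (is.null(cds_len) && !is.null(txome)) {
    cds_len <- setNames(txome$genes$n_codons, txome$genes$gene_id)
  }
  n_outside <- 0L
  if (!is.null(cds_len)) {
    L <- cds_len[fp$transcript_id]
    outside <- !is.na(ci) & (ci < 0 | ci >= L)
    n_outside <- sum(outside, na.rm = TRUE)
    ci[outside] <- NA_integer_
  }
  fp$codon_index <- ci
  attr(fp, "n_no_offset") <- n_no_offset
  attr(fp, "n_outside_cds") <- n_outside
  fp
}

# Per-gene A-site count vectors and normalized densities. Inclusion window
# is [edge, L - 1 - edge] (0-based codons); the gene mean is taken over all
# included positions (zeros included).
.gene_densities <- function(fp, txome, offsets, edge, min_gene_density) {
  fp <- assign_asite(fp, offsets, txome)
  fp <- fp[!is.na(fp$codon_index), , drop = FALSE]
  cods <- codon_array(txome)
  lens <- setNames(txome$genes$n_codons, txome$genes$gene_id)
  dt <- data.table::data.table(gene = fp$transcript_id,
                               ci = fp$codon_index)
  counts <- dt[, .N, by = .(gene, ci)]
  out <- list()
  for (gid in names(lens)) {
    L <- lens[[gid]]
    lo <- edge
    hi <- L - 1L - edge
    if (hi < lo) next
    v <- numeric(L)
    sub <- counts[counts$gene == gid, ]
    if (nrow(sub)) v[sub$ci + 1L] <- sub$N
    gmean <- mean(v[(lo + 1L):(hi + 1L)])
    if (gmean < min_gene_density) next
    out[[gid]] <- list(dens = v / gmean, counts = v,
                       codons = cods[[gid]], lo = lo, hi = hi)
  }
  out
}

#' Per-codon A-site occupancy
#'
#' For every gene whose mean footprint count per included codon reaches
#' `min_gene_density`, codon positions are normalized by the gene mean over
#' the included window (excluding `edge_exclusion` codons at each CDS end).
#' The occupancy of a codon is the unweighted mean normalized density over
#' all its occurrences across qualifying genes, finally rescaled so the mean
#' over observed codons is 1.
#'
#' @param fp Footprints of one library and condition.
#' @param txome A `transcriptome`.
#' @param offsets Offset table.
#' @param edge_exclusion Codons excluded at each CDS end.
#' @param min_gene_density Minimum mean footprints per included codon.
#' @param rescale Rescale so the mean occupancy over observed codons is 1.
#' @return Data.frame (`codon`, `occupancy`, `n_occurrences`) of class
#'   `occupancy_table`, with attribute `n_genes_used`.
#' @export
codon_occupancy <- function(fp, txome, offsets = default_offsets(),
                            edge_exclusion = 20, min_gene_density = 0.5,
                            rescale = TRUE) {
  dens <- .gene_densities(fp, txome, offsets, edge_exclusion,
                          min_gene_density)
  if (!length(dens)) stop("no genes pass the density filter (",
                          "min_gene_density = ", min_gene_density, ")")
  sums <- setNames(numeric(length(sense_codons())), sense_codons())
  ns <- sums
  for (d in dens) {
    idx <- (d$lo + 1L):(d$hi + 1L)
    cod <- d$codons[idx]
    ok <- cod %in% names(sums)
    s <- rowsum(d$dens[idx][ok], cod[ok])
    n <- rowsum(rep(1, sum(ok)), cod[ok])
    sums[rownames(s)] <- sums[rownames(s)] + s[, 1]
    ns[rownames(n)] <- ns[rownames(n)] + n[, 1]
  }
  obs <- ns > 0
  occ <- sums[obs] / ns[obs]
  if (rescale) occ <- occ / mean(occ)
  out <- data.frame(codon = names(occ), occupancy = unname(occ),
                    n_occurrences = unname(ns[obs]),
                    stringsAsFactors = FALSE)
  structure(out[order(out$codon), ],
            class = c("occupancy_table", "data.frame"),
            n_genes_used = length(dens))
}

#' Per-codon occupancy ratio between conditions
#'
#' @param ko,wt `occupancy_table`s from the same library.
#' @return Data.frame (`codon`, `occupancy_ko`, `occupancy_wt`,
#'   `ratio_ko_wt`), omitting codons absent from either table or with zero
#'   WT occupancy (counted in attribute `n_omitted`).
#' @export
occupancy_ratio <- function(ko, wt) {
  shared <- intersect(ko$codon, wt$codon)
  k <- ko$occupancy[match(shared, ko$codon)]
  w <- wt$occupancy[match(shared, wt$codon)]
  ok <- w > 0
  out <- data.frame(codon = shared[ok], occupancy_ko = k[ok],
                    occupancy_wt = w[ok], ratio_ko_wt = k[ok] / w[ok],
                    stringsAsFactors = FALSE)
  n_omitted <- length(union(ko$codon, wt$codon)) - nrow(out)
  structure(out, n_omitted = n_omitted)
}

#' Meta-codon density profile
#'
#' Averages gene-mean-normalized A-site density in a window of `W` codons
#' around every occurrence of `codon` lying at least `W` codons from both
#' CDS ends in qualifying genes.
#'
#' @param fp Footprints of one library and condition.
#' @param txome A `transcriptome`.
#' @param offsets Offset table.
#' @param codon Sense codon (DNA or RNA alphabet).
#' @param W Half-window in codons.
#' @param min_gene_density Gene inclusion filter, as in [codon_occupancy()].
#' @return Data.frame (`offset`, `mean_density`, `n_occurrences`); zero
#'   occurrences yield an empty profile with a warning.
#' @export
metacodon <- function(fp, txome, offsets = default_offsets(), codon,
                      W = 30, min_gene_density = 0.5) {
  codon <- .as_dna_codon(codon)
  if (!codon %in% sense_codons()) stop("not a sense codon: ", codon)
  dens <- .gene_densities(fp, txome, offsets, W, min_gene_density)
  total <- numeric(2 * W + 1)
  n_occ <- 0L
  for (d in dens) {
    hits <- which(d$codons == codon) - 1L   # 0-based codon indices
    hits <- hits[hits >= W & hits <= length(d$codons) - 1L - W]
    for (h in hits) {
      total <- total + d$dens[(h - W + 1L):(h + W + 1L)]
      n_occ <- n_occ + 1L
    }
  }
  if (n_occ == 0) {
    warning("no eligible occurrences of ", codon)
    return(data.frame(offset = integer(), mean_density = numeric(),
                      n_occurrences = integer()))
  }
  data.frame(offset = -W:W, mean_density = total / n_occ,
             n_occurrences = n_occ)
}

#' Per-gene A-site density track
#'
#' @param fp Footprints of one library and condition.
#' @param txome A `transcriptome`.
#' @param offsets Offset table.
#' @param gene_id Gene to profile.
#' @return Data.frame (`codon_index`, `codon`, `count`,
#'   `normalized_density`); the normalization is by the gene mean over all
#'   codon positions. Unknown genes are an error; a gene without coverage
#'   yields a zero vector.
#' @export
gene_profile <- function(fp, txome, offsets = default_offsets(), gene_id) {
  g <- txome$genes
  gi <- match(gene_id, g$gene_id)
  if (is.na(gi)) stop("unknown gene: ", gene_id)
  fp <- fp[fp$transcript_id == gene_id, , drop = FALSE]
  fp <- assign_asite(fp, offsets, txome)
  ci <- fp$codon_index[!is.na(fp$codon_index)]
  L <- g$n_codons[gi]
  v <- tabulate(ci + 1L, nbins = L)
  m <- mean(v)
  data.frame(codon_index = 0:(L - 1),
             codon = codon_array(txome)[[gene_id]],
             count = v,
             normalized_density = if (m > 0) v / m else rep(0, L),
             stringsAsFactors = FALSE)
}

#' Translation efficiency and TE-shift gene sets
#'
#' TE per gene and condition is footprint density over RNA density (counts
#' per CDS nucleotide; replicates are averaged before the ratio). The TE
#' shift is `log2 TE(KO) - log2 TE(WT)`. Genes must reach `min_counts` mean
#' counts in every library to enter the shift sets; genes with zero RNA
#' count are excluded and counted.
#'
#' @param rpf_counts,rna_counts Data.frames (`gene_id`, `condition`,
#'   `replicate`, `count`) over matched gene universes.
#' @param cds_length Named vector of CDS lengths (nt).
#' @param min_counts Minimum mean count in every library for set membership.
#' @param down_threshold_log2,up_threshold_log2 TE-shift thresholds
#'   (defaults are -/+ log2(1.5)).
#' @return List with `te` (gene x condition TE table), `dte` (per-gene
#'   `delta_te_log2`), `te_down`, `te_up` (character vectors), and
#'   `n_excluded_zero_rna`.
#' @export
compute_te <- function(rpf_counts, rna_counts, cds_length,
                       min_counts = 32, down_threshold_log2 = -0.585,
                       up_threshold_log2 = 0.585) {
  if (!setequal(unique(rpf_counts$gene_id), unique(rna_counts$gene_id))) {
    stop("RPF and RNA tables cover different gene universes")
  }
  agg <- function(tbl) {
    dt <- data.table::as.data.table(tbl)
    as.data.frame(dt[, .(count = mean(count)), by = .(gene_id, condition)])
  }
  rpf <- agg(rpf_counts)
  rna <- agg(rna_counts)
  key <- paste(rpf$gene_id, rpf$condition)
  rna <- rna[match(key, paste(rna$gene_id, rna$condition)), ]
  len <- cds_length[rpf$gene_id]
  te <- data.frame(gene_id = rpf$gene_id, condition = rpf$condition,
                   rpf_count = rpf$count, rna_count = rna$count,
                   rpf_density = rpf$count / len,
                   rna_density = rna$count / len,
                   stringsAsFactors = FALSE)
  zero_rna <- unique(te$gene_id[te$rna_count == 0])
  te <- te[!te$gene_id %in% zero_rna, ]
  te$te <- te$rpf_density / te$rna_density
  wt <- te[te$condition == "WT", ]
  ko <- te[te$condition == "KO", ]
  ko <- ko[match(wt$gene_id, ko$gene_id), ]
  dte <- data.frame(gene_id = wt$gene_id,
                    delta_te_log2 = log2(ko$te) - log2(wt$te),
                    stringsAsFactors = FALSE)
  eligible <- wt$gene_id[pmin(wt$rpf_count, wt$rna_count,
                              ko$rpf_count, ko$rna_count) >= min_counts]
  dte_ok <- dte[dte$gene_id %in% eligible & is.finite(dte$delta_te_log2), ]
  list(te = te, dte = dte,
       te_down = dte_ok$gene_id[dte_ok$delta_te_log2 <= down_threshold_log2],
       te_up = dte_ok$gene_id[dte_ok$delta_te_log2 >= up_threshold_log2],
       n_excluded_zero_rna = length(zero_rna))
}

#' Write or read footprint tables as TSV
#'
#' @param fp Footprint data.frame.
#' @param path File path.
#' @return `path` invisibly, or the footprint data.frame.
#' @export
write_footprints <- function(fp, path) {
  write.table(fp, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_footprints
#' @export
read_footprints <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
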
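# ac4C site calling: read preprocessing, exhaustive ungapped alignment,
# weighted pileups, and reduced-vs-mock misincorporation calling.

#' Trim adapters, deduplicate on UMI-containing sequence, and strip UMIs
#'
#' The 3' adapter is removed when a suffix of the read matches a prefix of
#' the adapter over at least 10 nt with at most one mismatch (longest
#' overlap wins). Reads are then deduplicated on the full sequence including
#' UMI bases (first occurrence kept) and the UMI bases are stripped.
#'
#' @param raw A `read_set` data.frame (`read_id`, `sequence`).
#' @param adapter Adapter sequence (>= 10 nt).
#' @param umi_5p_len,umi_3p_len UMI lengths to strip after deduplication.
#' @return A `read_set` of processed reads, with attributes `n_duplicates`
#'   and `n_too_short` recording dropped read counts.
#' @export
preprocess_reads <- function(raw, adapter = default_adapter(),
                             umi_5p_len = 6, umi_3p_len = 6) {
  if (nchar(adapter) < 10) stop("invalid config: adapter shorter than 10 nt")
  stopifnot(umi_5p_len >= 0, umi_3p_len >= 0)
  seqs <- raw$sequence
  lens <- nchar(seqs)
  ad_chars <- strsplit(adapter, "", fixed = TRUE)[[1]]
  trimmed <- rep(FALSE, length(seqs))
  for (ov in seq(min(nchar(adapter), max(lens)), 10)) {
    cand <- which(!trimmed & lens >= ov)
    if (!length(cand)) next
    sufs <- substr(seqs[cand], lens[cand] - ov + 1L, lens[cand])
    m <- matrix(unlist(strsplit(sufs, "", fixed = TRUE), use.names = FALSE),
                nrow = ov)
    mm <- colSums(m != ad_chars[seq_len(ov)])
    hit <- mm <= 1
    if (any(hit)) {
      idx <- cand[hit]
      seqs[idx] <- substr(seqs[idx], 1L, lens[idx] - ov)
      lens[idx] <- lens[idx] - ov
      trimmed[idx] <- TRUE
    }
  }
  dup <- duplicated(seqs)
  seqs <- seqs[!dup]
  ids <- raw$read_id[!dup]
  lens <- lens[!dup]
  keep <- lens > umi_5p_len + umi_3p_len
  inserts <- substr(seqs[keep], umi_5p_len + 1L, lens[keep] - umi_3p_len)
  structure(
    data.frame(read_id = ids[keep], sequence = inserts,
               stringsAsFactors = FALSE),
    class = c("read_set", "data.frame"),
    n_duplicates = sum(dup), n_too_short = sum(!keep))
}

#' Exhaustive ungapped alignment against a tRNA reference
#'
#' Every read is scanned against every ungapped placement on every
#' reference gene; all placements achieving the minimum mismatch count are
#' kept when that count is at most `max_mismatch_frac` times the read
#' length. Multimapping reads receive fractional weight
#' `1 / multimap_count`.
#'
#' @param reads A `read_set`.
#' @param ref A `trna_reference`.
#' @param max_mismatch_frac Maximum tolerated mismatch fraction.
#' @return Data.frame of class `alignment_set` with columns `read_id`,
#'   `ref_id`, `ref_start`, `ref_end` (0-based half-open), `n_mismatch`,
#'   `mismatch_positions` (comma-separated 0-based reference indices),
#'   `multimap_count`, `weight`; attribute `n_unaligned` counts dropped
#'   reads.
#' @export
align_ungapped <- function(reads, ref, max_mismatch_frac = 0.1) {
  g <- ref$genes
  if (!nrow(g)) stop("empty reference")
  uniq <- unique(reads$sequence)
  hits <- .align_ungapped_cpp(uniq, g$sequence, max_mismatch_frac)
  # expand unique-sequence hits back to individual reads
  seq_idx <- match(reads$sequence, uniq)
  n_hits_per_uniq <- tabulate(hits$read_index, nbins = length(uniq))
  aligned_reads <- which(n_hits_per_uniq[seq_idx] > 0)
  ord <- order(hits$read_index)
  hits <- hits[ord, , drop = FALSE]
  first_row <- c(0L, cumsum(n_hits_per_uniq))[seq_len(length(uniq))]
  rows <- unlist(lapply(aligned_reads, function(i) {
    u <- seq_idx[i]
    first_row[u] + seq_len(n_hits_per_uniq[u])
  }), use.names = FALSE)
  per_read <- rep.int(n_hits_per_uniq[seq_idx[aligned_reads]],
                      n_hits_per_uniq[seq_idx[aligned_reads]])
  read_of_row <- rep.int(aligned_reads,
                         n_hits_per_uniq[seq_idx[aligned_reads]])
  h <- hits[rows, , drop = FALSE]
  len <- nchar(reads$sequence[read_of_row])
  out <- data.frame(
    read_id = reads$read_id[read_of_row],
    ref_id = g$gene_id[h$ref_index],
    ref_start = h$ref_start,
    ref_end = h$ref_start + len,
    n_mismatch = h$n_mismatch,
    mismatch_positions = h$mismatch_positions,
    multimap_count = per_read,
    weight = 1 / per_read,
    stringsAsFactors = FALSE)
  structure(out, class = c("alignment_set", "data.frame"),
            n_unaligned = nrow(reads) - length(aligned_reads))
}

#' Build a weighted base/stop pileup from alignments
#'
#' Accumulates fractional multimapper weights per base at every covered
#' reference position, in full precision. `stop_count(pos)` accumulates the
#' weight of alignments whose 5'-most covered position is `pos + 1`,
#' the signature of reverse transcription terminating one nucleotide 3' of
#' a blocking modification.
#'
#' @param alns An `alignment_set`.
#' @param reads The `read_set` the alignments came from.
#' @param ref The `trna_reference` aligned against.
#' @return Data.frame of class `pileup_table` with columns `ref_id`, `pos`
#'   (0-based), `ref_base`, `a`, `c`, `g`, `t`, `depth`, `stop_count`.
#' @export
build_pileup <- function(alns, reads, ref) {
  g <- ref$genes
  ref_index <- match(alns$ref_id, g$gene_id)
  if (any(is.na(ref_index))) stop("alignment references unknown gene")
  seqs <- reads$sequence[match(alns$read_id, reads$read_id)]
  mats <- .pileup_cpp(seqs, ref_index, alns$ref_start, alns$weight,
                      nchar(g$sequence))
  out <- lapply(seq_len(nrow(g)), function(j) {
    m <- mats[[j]]
    L <- ncol(m)
    data.frame(
      ref_id = g$gene_id[j], pos = 0:(L - 1),
      ref_base = strsplit(g$sequence[j], "", fixed = TRUE)[[1]],
      a = m[1, ], c = m[2, ], g = m[3, ], t = m[4, ],
      depth = colSums(m[1:4, , drop = FALSE]),
      stop_count = m[5, ], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("pileup_table", "data.frame"))
}

#' Call misincorporation sites from reduced and mock pileups
#'
#' For every reference cytidine with positive reduced-library depth the
#' C-to-T misincorporation rate is `t / (c + t)` in each library (A/G reads
#' are tracked but excluded from the rate); the net rate is the reduced
#' minus mock difference floored at 0. A site passes when the reduced depth
#' is strictly greater than `min_depth` (the ">100 reads" convention) and
#' the net rate is at least `min_net_rate` (the 2% stoichiometry floor).
#' `is_ccg` flags the 5'-CCG-3' acetylation consensus around the position.
#'
#' @param reduced,mock `pileup_table`s over the same reference.
#' @param ref The `trna_reference`.
#' @param min_depth Strict lower depth bound (default 100).
#' @param min_net_rate Minimum net misincorporation rate (default 0.02).
#' @return Data.frame of class `misinc_site_table` with columns `ref_id`,
#'   `pos`, `rate_reduced`, `rate_mock`, `net_rate`, `depth_reduced`,
#'   `depth_mock`, `stop_fraction`, `is_ccg`, `is_c12`, `passes`.
#' @export
call_sites <- function(reduced, mock, ref, min_depth = 100,
                       min_net_rate = 0.02) {
  if (!setequal(unique(reduced$ref_id), unique(mock$ref_id))) {
    stop("reduced and mock pileups cover different references")
  }
  red <- reduced[reduced$ref_base == "C" & reduced$depth > 0, ]
  key <- paste(red$ref_id, red$pos)
  mk <- mock[match(key, paste(mock$ref_id, mock$pos)), ]
  rate <- function(tt, cc) ifelse(cc + tt > 0, tt / (cc + tt), 0)
  rate_red <- rate(red$t, red$c)
  rate_mock <- rate(ifelse(is.na(mk$t), 0, mk$t),
                    ifelse(is.na(mk$c), 0, mk$c))
  g <- ref$genes
  gi <- match(red$ref_id, g$gene_id)
  ctx <- substr(g$sequence[gi], red$pos, red$pos + 2)  # pos-1..pos+1, 0-based
  out <- data.frame(
    ref_id = red$ref_id, pos = red$pos,
    rate_reduced = rate_red, rate_mock = rate_mock,
    net_rate = pmax(0, rate_red - rate_mock),
    depth_reduced = red$depth,
    depth_mock = ifelse(is.na(mk$depth), 0, mk$depth),
    stop_fraction = red$stop_count / (red$stop_count + red$depth),
    is_ccg = ctx == "CCG",
    is_c12 = !is.na(g$c12_index[gi]) & red$pos == g$c12_index[gi],
    stringsAsFactors = FALSE)
  out$passes <- out$depth_reduced > min_depth & out$net_rate >= min_net_rate
  structure(out, class = c("misinc_site_table", "data.frame"))
}

#' Per-position RT-stop fraction profile
#'
#' `stop_fraction(pos) = stop_count(pos) / (stop_count(pos) + depth(pos))`.
#'
#' @param pileup A `pileup_table`.
#' @return Data.frame (`ref_id`, `pos`, `stop_fraction`).
#' @export
stop_profile <- function(pileup) {
  if (!nrow(pileup)) stop("empty pileup")
  denom <- pileup$stop_count + pileup$depth
  data.frame(ref_id = pileup$ref_id, pos = pileup$pos,
             stop_fraction = ifelse(denom > 0, pileup$stop_count / denom, 0),
             stringsAsFactors = FALSE)
}

#' Classify sites by sensitivity to Thumpd1 knockout
#'
#' A site is Thumpd1-sensitive when it passes all filters in the WT
#' comparison and its net misincorporation rate in the KO comparison falls
#' below `ko_max_net`. Positions present in only one table are reported as
#' uncallable (`NA`).
#'
#' @param sites_wt,sites_ko `misinc_site_table`s from [call_sites()].
#' @param ko_max_net Net-rate ceiling in KO for a sensitive call.
#' @return `sites_wt` with added columns `net_rate_ko` and
#'   `thumpd1_sensitive`.
#' @export
thumpd1_sensitivity <- function(sites_wt, sites_ko, ko_max_net = 0.02) {
  idx <- match(paste(sites_wt$ref_id, sites_wt$pos),
               paste(sites_ko$ref_id, sites_ko$pos))
  out <- sites_wt
  out$net_rate_ko <- sites_ko$net_rate[idx]
  out$thumpd1_sensitive <- ifelse(is.na(idx), NA,
                                  out$passes & out$net_rate_ko < ko_max_net)
  out
}

#' Write a site report TSV
#'
#' Coordinates are converted to 1-based inclusive positions for reporting.
#'
#' @param sites A `misinc_site_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_site_report <- function(sites, path) {
  rep <- sites
  rep$pos_1based <- rep$pos + 1L
  rep$pos <- NULL
  cols <- c("ref_id", "pos_1based",
            setdiff(names(rep), c("ref_id", "pos_1based")))
  write.table(rep[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
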
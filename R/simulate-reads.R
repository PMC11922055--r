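# Read-level simulators: reduction-dependent misincorporation (ac4C-seq
# style) libraries and full-length tRNA-seq libraries.

.other_bases <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                     G = c("A", "C", "T"), T = c("A", "C", "G"))

# Apply background errors: each base independently mutates to each specific
# other base with probability eps (total substitution rate 3 * eps).
.apply_errors <- function(seqs, eps) {
  if (eps <= 0 || !length(seqs)) return(seqs)
  chars <- strsplit(seqs, "", fixed = TRUE)
  lens <- lengths(chars)
  flat <- unlist(chars, use.names = FALSE)
  hit <- which(runif(length(flat)) < 3 * eps)
  if (length(hit)) {
    pick <- ceiling(runif(length(hit)) * 3)
    alt <- vapply(seq_along(hit), function(i) {
      b <- flat[hit[i]]
      if (b %in% names(.other_bases)) .other_bases[[b]][pick[i]] else b
    }, "")
    flat[hit] <- alt
  }
  grp <- rep.int(seq_along(lens), lens)
  vapply(split(flat, grp), paste, "", collapse = "")
}

.random_umi <- function(n, len) {
  if (len == 0) return(rep("", n))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n)
  apply(m, 1, paste, collapse = "")
}

#' Default 3' sequencing adapter
#'
#' The constant appended by the read simulators and trimmed by
#' [preprocess_reads()].
#'
#' @return A 20 nt DNA string.
#' @export
default_adapter <- function() "AGATCGGAAGAGCACACGTC"

#' Simulate a reduction-readout (ac4C-seq style) library
#'
#' Emits `depth` already-merged single reads per gene. Under the `reduced`
#' treatment each molecule of a substrate gene is acetylated with probability
#' `s`; an acetylated, reduced molecule independently either terminates
#' reverse transcription so that its 5'-most covered position is
#' `c12_index + 1` (probability `p_stop`), carries a T at `c12_index`
#' (probability `p_mis`), or reads through as C. Under `mock` only background
#' errors occur. Background errors (`epsilon`, see [acetylation_profile()])
#' apply independently at every insert position in both treatments. Each read
#' is wrapped as `5' UMI + insert + 3' UMI + adapter`, mirroring the library
#' structure that [preprocess_reads()] undoes; read names encode the gene of
#' origin.
#'
#' @param ref A `trna_reference`.
#' @param profile An [acetylation_profile()] data.frame.
#' @param treatment `"reduced"` or `"mock"`.
#' @param depth Reads per gene (>= 1).
#' @param seed Integer seed.
#' @param umi_5p_len,umi_3p_len Lengths of the random unique molecular
#'   identifiers flanking the insert. Set both to 0 for bare inserts.
#' @param adapter 3' adapter appended after the 3' UMI, or `""` for none.
#' @return A data.frame (`read_id`, `sequence`) of class `read_set`.
#' @export
simulate_ac4cseq_reads <- function(ref, profile,
                                   treatment = c("reduced", "mock"),
                                   depth = 1000, seed = 1,
                                   umi_5p_len = 6, umi_3p_len = 6,
                                   adapter = default_adapter()) {
  treatment <- match.arg(treatment)
  stopifnot(depth >= 1)
  g <- ref$genes
  prof <- profile[match(g$gene_id, profile$gene_id), ]
  withr::with_seed(seed, {
    out <- vector("list", nrow(g))
    for (i in seq_len(nrow(g))) {
      sq <- g$sequence[i]
      c12 <- g$c12_index[i]
      inserts <- rep(sq, depth)
      if (treatment == "reduced" && !is.na(c12) && prof$s[i] > 0) {
        acet <- runif(depth) < prof$s[i]
        u <- runif(depth)
        is_stop <- acet & u < prof$p_stop[i]
        is_mis <- acet & !is_stop & u < prof$p_stop[i] + prof$p_mis[i]
        # stop: cDNA terminates one nt 3' of the modification
        inserts[is_stop] <- substring(sq, c12 + 2)
        if (any(is_mis)) {
          tmp <- inserts[is_mis]
          substr(tmp, c12 + 1, c12 + 1) <- "T"
          inserts[is_mis] <- tmp
        }
      }
      inserts <- .apply_errors(inserts, prof$epsilon[i])
      reads <- paste0(.random_umi(depth, umi_5p_len), inserts,
                      .random_umi(depth, umi_3p_len), adapter)
      out[[i]] <- data.frame(
        read_id = sprintf("%s|%s|%d", g$gene_id[i], treatment,
                          seq_len(depth)),
        sequence = reads, stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    structure(res, class = c("read_set", "data.frame"))
  })
}

#' Default condition-specific isodecoder abundance
#'
#' Wild-type abundance is uniform across genes. The knockout profile divides
#' Leu-UAA-2 by 4 and Ser-AGA-3, Ser-UGA-4, Leu-AAG-3 and Leu-UAA-3 by 1.5,
#' the depletion pattern used as the recoverable ground truth for the
#' quantification stage.
#'
#' @param ref A `trna_reference`.
#' @param condition `"WT"` or `"KO"`.
#' @return Named numeric vector of relative abundances.
#' @export
default_abundance <- function(ref, condition = c("WT", "KO")) {
  condition <- match.arg(condition)
  ab <- setNames(rep(1, nrow(ref$genes)), ref$genes$gene_id)
  if (condition == "KO") {
    dep <- c("Leu-UAA-2" = 4, "Ser-AGA-3" = 1.5, "Ser-UGA-4" = 1.5,
             "Leu-AAG-3" = 1.5, "Leu-UAA-3" = 1.5)
    for (gid in names(dep)) {
      if (gid %in% names(ab)) ab[gid] <- ab[gid] / dep[[gid]]
    }
  }
  ab
}

#' Default modification-induced misincorporation signature
#'
#' Positions at which tRNA-seq reads carry mismatches that quantification
#' must tolerate: the C12 acetylation site misincorporates in WT (rate 0.3)
#' but not in KO, and a second, Thumpd1-independent site near position 58
#' misincorporates at rate 0.15 in every gene long enough to carry it.
#'
#' @param ref A `trna_reference`.
#' @param condition `"WT"` or `"KO"`.
#' @return Data.frame `gene_id`, `pos` (0-based), `rate`, `to_base`.
#' @export
default_misinc_signature <- function(ref, condition = c("WT", "KO")) {
  condition <- match.arg(condition)
  g <- ref$genes
  rows <- list()
  sub <- g[g$is_substrate & !is.na(g$c12_index), ]
  if (nrow(sub) && condition == "WT") {
    rows[[1]] <- data.frame(gene_id = sub$gene_id, pos = sub$c12_index,
                            rate = 0.3, to_base = "T",
                            stringsAsFactors = FALSE)
  }
  long <- g[nchar(g$sequence) > 58, ]
  if (nrow(long)) {
    base58 <- substr(long$sequence, 58, 58)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = long$gene_id, pos = 57L, rate = 0.15,
      to_base = ifelse(base58 == "T", "C", "T"), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), pos = integer(),
                      rate = numeric(), to_base = character(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Simulate a full-length tRNA-seq library
#'
#' Samples `depth` full-length reads with per-gene probability proportional
#' to `abundance`, then mutates each annotated signature position at its
#' stated rate to emulate modification-induced misincorporations. Reads are
#' emitted bare (no UMI or adapter), as after merging and trimming.
#'
#' @param ref A `trna_reference`.
#' @param abundance Named nonnegative vector over `gene_id` (at least one
#'   positive); see [default_abundance()].
#' @param misinc_signature Data.frame as from [default_misinc_signature()],
#'   or `NULL` for error-free reads.
#' @param depth Total number of reads.
#' @param seed Integer seed.
#' @return A `read_set` data.frame (`read_id`, `sequence`).
#' @export
simulate_trnaseq_reads <- function(ref, abundance, misinc_signature = NULL,
                                   depth = 200000, seed = 1) {
  stopifnot(depth >= 1)
  g <- ref$genes
  ab <- abundance[g$gene_id]
  ab[is.na(ab)] <- 0
  if (any(ab < 0)) stop("abundances must be nonnegative")
  if (sum(ab) <= 0) stop("all-zero abundance")
  withr::with_seed(seed, {
    idx <- sample.int(nrow(g), depth, replace = TRUE, prob = ab)
    reads <- g$sequence[idx]
    if (!is.null(misinc_signature) && nrow(misinc_signature)) {
      for (k in seq_len(nrow(misinc_signature))) {
        gi <- match(misinc_signature$gene_id[k], g$gene_id)
        if (is.na(gi)) next
        sel <- which(idx == gi)
        sel <- sel[runif(length(sel)) < misinc_signature$rate[k]]
        if (length(sel)) {
          p <- misinc_signature$pos[k] + 1L
          tmp <- reads[sel]
          substr(tmp, p, p) <- misinc_signature$to_base[k]
          reads[sel] <- tmp
        }
      }
    }
    structure(data.frame(
      read_id = sprintf("%s|%d", g$gene_id[idx], seq_len(depth)),
      sequence = reads, stringsAsFactors = FALSE),
      class = c("read_set", "data.frame"))
  })
}

#' Write a read set as FASTQ
#'
#' All bases receive the fixed quality character `I`.
#'
#' @param reads A `read_set` data.frame.
#' @param path Output path (uncompressed FASTQ).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  ss <- Biostrings::DNAStringSet(reads$sequence)
  names(ss) <- reads$read_id
  qual <- Biostrings::BStringSet(strrep("I", nchar(reads$sequence)))
  Biostrings::writeXStringSet(ss, filepath = path, format = "fastq",
                              qualities = qual)
  invisible(path)
}

#' Read a FASTQ file into a read set
#'
#' @param path FASTQ path.
#' @return A `read_set` data.frame (`read_id`, `sequence`).
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  structure(data.frame(read_id = names(ss), sequence = as.character(ss),
                       stringsAsFactors = FALSE),
            class = c("read_set", "data.frame"))
}
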
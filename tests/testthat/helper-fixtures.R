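# Shared fixtures and oracles, built in code at test time.

# 99% exact binomial interval for a count at n trials, probability p
binom_ci99 <- function(n, p, alpha = 0.01) {
  qbinom(c(alpha / 2, 1 - alpha / 2), n, p)
}

# hand-built two-gene reference with known sequences
tiny_ref <- function() {
  genes <- data.frame(
    gene_id = c("Leu-UAA-1", "Ala-AGC-1"),
    amino_acid = c("Leu", "Ala"),
    anticodon = c("TAA", "AGC"),
    copy_index = c(1L, 1L),
    sequence = c(
      paste0("GGGAAATTTGCCGATTTAAACCCGGGTTTAAACCGTAATTTGGGCCCAAATTTGGGCCC",
             "AAATTTGGGTT"),
      paste0("AAACCCGGGTTTAAACCCGGGTTTAAACCCGGGAGCAAACCCGGGTTTAAACCCGGGTT",
             "TAAACCCGGAA")),
    c12_index = c(11L, NA_integer_),
    is_substrate = c(TRUE, FALSE),
    stringsAsFactors = FALSE)
  structure(list(genes = genes), class = "trna_reference")
}

as_read_set <- function(seqs, ids = sprintf("r%d", seq_along(seqs))) {
  structure(data.frame(read_id = ids, sequence = seqs,
                       stringsAsFactors = FALSE),
            class = c("read_set", "data.frame"))
}

# brute-force Hamming scanner: all placements with the minimum mismatch
# count, if that count is within the fraction threshold
oracle_align <- function(read, ref_genes, frac = 0.1) {
  L <- nchar(read)
  rchars <- strsplit(read, "")[[1]]
  best <- floor(frac * L + 1e-9) + 1
  hits <- list()
  for (j in seq_len(nrow(ref_genes))) {
    schars <- strsplit(ref_genes$sequence[j], "")[[1]]
    for (off in 0:(length(schars) - L)) {
      if (length(schars) < L) next
      mm <- sum(rchars != schars[(off + 1):(off + L)])
      if (mm < best) {
        best <- mm
        hits <- list()
      }
      if (mm == best) {
        hits[[length(hits) + 1]] <- c(j, off, mm)
      }
    }
  }
  if (!length(hits) || best > floor(frac * L + 1e-9)) {
    return(data.frame(ref = integer(), start = integer(), mm = integer()))
  }
  m <- do.call(rbind, hits)
  data.frame(ref = m[, 1], start = m[, 2], mm = m[, 3])
}

# abundance table built directly from multinomial counts with optional
# per-replicate log-normal abundance noise
abundance_fixture <- function(ab, condition, replicate, depth = 50000,
                              noise_sd = 0) {
  a <- ab * exp(rnorm(length(ab), sd = noise_sd))
  cnt <- as.vector(rmultinom(1, depth, a / sum(a)))
  data.frame(gene_id = names(ab), condition = condition,
             replicate = replicate, count = cnt,
             proportion = cnt / sum(cnt), stringsAsFactors = FALSE)
}

# quantification from simulated reads for one library
quant_library <- function(ref, condition, replicate, seed, depth = 200000) {
  rs <- simulate_trnaseq_reads(ref, default_abundance(ref, condition),
                               default_misinc_signature(ref, condition),
                               depth = depth, seed = seed)
  al <- align_ungapped(rs, ref)
  quantify(al, ref, condition = condition, replicate = replicate)
}

# default ac4C pipeline: simulate, preprocess, align, pileup for one
# treatment arm
ac4c_pileup <- function(ref, profile, treatment, depth, seed) {
  rs <- simulate_ac4cseq_reads(ref, profile, treatment, depth = depth,
                               seed = seed)
  pp <- preprocess_reads(rs)
  al <- align_ungapped(pp, ref)
  build_pileup(al, pp, ref)
}
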
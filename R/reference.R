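# tRNA reference construction: isodecoder genes with annotated C12 sites.

.default_substrate_plan <- function() {
  # 26 Leu/Ser isodecoder genes over 9 anticodons, the substrate complement
  # observed for Thumpd1-dependent C12 acetylation
  c("Leu-TAA" = 3L, "Leu-AAG" = 3L, "Leu-CAG" = 3L, "Leu-CAA" = 2L,
    "Leu-TAG" = 2L,
    "Ser-AGA" = 4L, "Ser-TGA" = 4L, "Ser-CGA" = 3L, "Ser-GCT" = 2L)
}

.decoy_pool <- function() {
  c("Ala" = "AGC", "Arg" = "ACG", "Asn" = "GTT", "Asp" = "GTC",
    "Glu" = "TTC", "Gly" = "GCC", "His" = "GTG", "Lys" = "CTT",
    "Phe" = "GAA", "Pro" = "AGG", "Thr" = "AGT", "Val" = "AAC",
    "Ile" = "AAT", "Met" = "CAT", "Tyr" = "GTA", "Trp" = "CCA")
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic tRNA isodecoder reference
#'
#' Builds a reference of tRNA genes with unique random body sequences
#' (70--90 nt). Substrate genes are Leu/Ser isodecoders carrying the
#' 5'-CCG-3' acetylation consensus around the annotated C12 position
#' (0-based index 11) and the anticodon at positions 34--36; decoy genes
#' represent tRNAs of other amino acids and carry no C12 annotation. The
#' default plan emits 26 substrate genes spanning 9 distinct anticodons.
#'
#' @param substrate_copies Named integer vector `"<Aa>-<anticodon>" = copies`
#'   (DNA-alphabet anticodons). `NULL` uses the default 26-gene plan; an
#'   empty vector generates no substrates.
#' @param n_decoys Number of non-substrate decoy genes.
#' @param seed Integer seed; output is byte-reproducible for a fixed seed.
#' @return An object of class `trna_reference`: a list with element `genes`,
#'   a data.frame with columns `gene_id`, `amino_acid`, `anticodon`,
#'   `copy_index`, `sequence`, `c12_index` (0-based, `NA` for decoys) and
#'   `is_substrate`.
#' @examples
#' ref <- make_trna_reference(seed = 1)
#' sum(ref$genes$is_substrate)
#' @export
make_trna_reference <- function(substrate_copies = NULL, n_decoys = 10,
                                seed = 1) {
  if (is.null(substrate_copies)) substrate_copies <- .default_substrate_plan()
  stopifnot(n_decoys >= 0)
  if (length(substrate_copies) > 0 && any(substrate_copies < 0)) {
    stop("substrate copy numbers must be >= 0")
  }
  n_sub <- if (length(substrate_copies)) sum(substrate_copies) else 0L
  if (n_sub + n_decoys == 0) {
    stop("invalid config: reference would contain zero genes")
  }

  withr::with_seed(seed, {
    rows <- list()
    if (n_sub > 0) {
      for (key in names(substrate_copies)) {
        parts <- strsplit(key, "-", fixed = TRUE)[[1]]
        aa <- parts[1]
        anticodon <- toupper(chartr("U", "T", parts[2]))
        for (k in seq_len(substrate_copies[[key]])) {
          len <- sample(72:82, 1)
          sq <- .random_dna(len)
          substr(sq, 11, 13) <- "CCG"       # C12 consensus, c12_index = 11
          substr(sq, 34, 36) <- anticodon
          rows[[length(rows) + 1L]] <- data.frame(
            gene_id = sprintf("%s-%s-%d", aa, .rna_display(anticodon), k),
            amino_acid = aa, anticodon = anticodon, copy_index = k,
            sequence = sq, c12_index = 11L, is_substrate = TRUE,
            stringsAsFactors = FALSE)
        }
      }
    }
    if (n_decoys > 0) {
      pool <- .decoy_pool()
      picks <- rep(seq_along(pool), length.out = n_decoys)
      copy_seen <- integer(length(pool))
      for (i in seq_len(n_decoys)) {
        j <- picks[i]
        copy_seen[j] <- copy_seen[j] + 1L
        aa <- names(pool)[j]
        anticodon <- pool[[j]]
        len <- sample(70:90, 1)
        sq <- .random_dna(len)
        substr(sq, 34, 36) <- anticodon
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = sprintf("%s-%s-%d", aa, .rna_display(anticodon),
                            copy_seen[j]),
          amino_acid = aa, anticodon = anticodon, copy_index = copy_seen[j],
          sequence = sq, c12_index = NA_integer_, is_substrate = FALSE,
          stringsAsFactors = FALSE)
      }
    }
    genes <- do.call(rbind, rows)
    # random 70+ nt bodies collide with vanishing probability; regenerate
    # any duplicate tail to keep sequences unique
    while (anyDuplicated(genes$sequence)) {
      i <- anyDuplicated(genes$sequence)
      sq <- genes$sequence[i]
      substr(sq, nchar(sq) - 9, nchar(sq)) <- .random_dna(10)
      genes$sequence[i] <- sq
    }
    structure(list(genes = genes), class = "trna_reference")
  })
}

#' @export
print.trna_reference <- function(x, ...) {
  g <- x$genes
  cat(sprintf(
    "trna_reference: %d genes (%d substrate over %d anticodons, %d decoy)\n",
    nrow(g), sum(g$is_substrate),
    length(unique(g$anticodon[g$is_substrate])), sum(!g$is_substrate)))
  invisible(x)
}

#' Write a tRNA reference as FASTA
#'
#' Record descriptions carry `key=value` metadata (`anticodon`, `c12_index`,
#' `is_substrate`) so the reference round-trips through plain FASTA.
#'
#' @param ref A [make_trna_reference()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trna_fasta <- function(ref, path) {
  g <- ref$genes
  desc <- sprintf("%s anticodon=%s c12_index=%s is_substrate=%d",
                  g$gene_id, g$anticodon,
                  ifelse(is.na(g$c12_index), "NA", g$c12_index),
                  as.integer(g$is_substrate))
  ss <- Biostrings::DNAStringSet(g$sequence)
  names(ss) <- desc
  Biostrings::writeXStringSet(ss, filepath = path)
  invisible(path)
}

#' Read a tRNA reference from FASTA written by [write_trna_fasta()]
#'
#' @param path FASTA file path.
#' @return A `trna_reference` object.
#' @export
read_trna_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  meta <- strsplit(names(ss), " ", fixed = TRUE)
  get_kv <- function(m, key) {
    hit <- grep(paste0("^", key, "="), m, value = TRUE)
    if (!length(hit)) NA_character_ else sub(paste0("^", key, "="), "", hit[1])
  }
  gene_id <- unname(vapply(meta, `[[`, "", 1L))
  idparts <- strsplit(gene_id, "-", fixed = TRUE)
  genes <- data.frame(
    gene_id = gene_id,
    amino_acid = vapply(idparts, `[[`, "", 1L),
    anticodon = unname(vapply(meta, get_kv, "", key = "anticodon")),
    copy_index = as.integer(vapply(idparts, function(p) p[[length(p)]], "")),
    sequence = unname(as.character(ss)),
    c12_index = suppressWarnings(as.integer(
      unname(vapply(meta, get_kv, "", key = "c12_index")))),
    is_substrate = unname(
      vapply(meta, get_kv, "", key = "is_substrate")) == "1",
    stringsAsFactors = FALSE)
  rownames(genes) <- NULL
  structure(list(genes = genes), class = "trna_reference")
}

#' Construct a per-gene acetylation profile
#'
#' Assigns each substrate gene an ac4C stoichiometry and the chemistry of the
#' reduction readout: the probability that an acetylated, reduced molecule is
#' read as a C-to-T misincorporation (`p_mis`) versus a reverse-transcription
#' stop one nucleotide 3' of C12 (`p_stop`); the remainder reads through as
#' C. Misincorporation defaults are more penetrant for Ser substrates, while
#' Leu substrates favour RT stops, reproducing the qualitative contrast seen
#' between the two families. `epsilon` is the background error rate per base
#' and per target base (so the total substitution rate is `3 * epsilon`),
#' applied in both treated and mock libraries.
#'
#' @param ref A `trna_reference`.
#' @param stoichiometry Acetylated fraction for substrate genes, in `[0, 1]`;
#'   either a scalar or a vector named by `gene_id`. Non-substrates are 0.
#' @param leu_p_mis,leu_p_stop Chemistry for Leu substrates.
#' @param ser_p_mis,ser_p_stop Chemistry for Ser substrates.
#' @param epsilon Background per-base, per-substitution error rate in
#'   `[0, 0.02]`.
#' @return Data.frame with columns `gene_id`, `s`, `p_mis`, `p_stop`,
#'   `epsilon`.
#' @export
acetylation_profile <- function(ref, stoichiometry = 0.9,
                                leu_p_mis = 0.35, leu_p_stop = 0.35,
                                ser_p_mis = 0.6, ser_p_stop = 0.1,
                                epsilon = 0.002) {
  stopifnot(leu_p_mis + leu_p_stop <= 1, ser_p_mis + ser_p_stop <= 1,
            epsilon >= 0, epsilon <= 0.02,
            all(stoichiometry >= 0), all(stoichiometry <= 1))
  g <- ref$genes
  s <- if (!is.null(names(stoichiometry))) {
    ifelse(g$gene_id %in% names(stoichiometry),
           stoichiometry[g$gene_id], 0)
  } else {
    rep(stoichiometry[1], nrow(g))
  }
  s[!g$is_substrate] <- 0
  data.frame(
    gene_id = g$gene_id,
    s = unname(s),
    p_mis = ifelse(g$amino_acid == "Ser", ser_p_mis, leu_p_mis),
    p_stop = ifelse(g$amino_acid == "Ser", ser_p_stop, leu_p_stop),
    epsilon = epsilon,
    stringsAsFactors = FALSE)
}
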
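# Footprint simulator: codon-resolution dwell-time model for monosome and
# disome (collision) libraries, plus paired RNA/RPF count tables.

#' Default A-site offset table
#'
#' Distance from the footprint 5' end to the first nucleotide of the A-site
#' codon. Monosomes: 15 nt for lengths 25--31, 16 nt for 32--40. Disomes
#' place the trailing ribosome over the 5'-most ~30 nt, so the leading
#' ribosome's A site sits 30 nt deeper: 45 nt for lengths 40--61 and 46 nt
#' for 62--80. The simulator and all analysis functions share this table, so
#' the convention is self-consistent end to end.
#'
#' @return Data.frame with columns `library`, `length`, `offset`.
#' @export
default_offsets <- function() {
  rbind(
    data.frame(library = "mono", length = 25:40,
               offset = ifelse(25:40 <= 31, 15L, 16L)),
    data.frame(library = "di", length = 40:80,
               offset = ifelse(40:80 <= 61, 45L, 46L)))
}

.norm_mean1 <- function(w) w / mean(w)

#' Construct a codon dwell-time model
#'
#' Holds strictly positive per-codon dwell weights for monosome and disome
#' sampling (each normalized to mean 1 over the 61 sense codons), the
#' footprint length distributions of the two libraries, and the expected
#' disome fraction of a mixed library. The defaults encode the study
#' conditions: wild type is uniform; the knockout doubles monosome dwell at
#' the A/U-rich Leu codons UUG, CUA, CUU and UUA, and disome dwell at the
#' collision-prone codons UCA, CUC, UUG and UUA.
#'
#' @param condition `"WT"` or `"KO"`.
#' @param w_mono,w_di Optional named positive weight vectors over sense
#'   codons (missing codons get weight 1); override the defaults.
#' @param stall_factor Multiplier applied to the default stall codons in the
#'   KO condition.
#' @param disome_fraction Expected fraction of disome footprints in a mixed
#'   library.
#' @return An object of class `dwell_model`.
#' @export
dwell_model <- function(condition = c("WT", "KO"), w_mono = NULL,
                        w_di = NULL, stall_factor = 2,
                        disome_fraction = 0.15) {
  condition <- match.arg(condition)
  sense <- sense_codons()
  base <- setNames(rep(1, length(sense)), sense)
  fill <- function(w, stall) {
    out <- base
    if (!is.null(w)) {
      names(w) <- .as_dna_codon(names(w))
      out[intersect(names(w), sense)] <- w[intersect(names(w), sense)]
    } else if (condition == "KO") {
      out[stall] <- stall_factor
    }
    if (any(out <= 0)) stop("dwell weights must be strictly positive")
    .norm_mean1(out)
  }
  structure(list(
    condition = condition,
    w_mono = fill(w_mono, c("TTG", "CTA", "CTT", "TTA")),
    w_di = fill(w_di, c("TCA", "CTC", "TTG", "TTA")),
    mono_len_probs = local({
      l <- 25:39; setNames(.norm_prob(stats::dnorm(l, 29, 2)), l)
    }),
    di_len_probs = local({
      l <- 40:80; setNames(.norm_prob(stats::dnorm(l, 60, 5)), l)
    }),
    disome_fraction = disome_fraction), class = "dwell_model")
}

.norm_prob <- function(p) p / sum(p)

#' @export
print.dwell_model <- function(x, ...) {
  cat(sprintf("dwell_model (%s): top mono codons %s\n", x$condition,
              paste(names(sort(x$w_mono, decreasing = TRUE))[1:4],
                    collapse = ", ")))
  invisible(x)
}

.offset_lookup <- function(offsets, library) {
  o <- offsets[offsets$library == library, ]
  setNames(o$offset, o$length)
}

#' Simulate ribosome footprints
#'
#' Draws footprints whose A-site codon (leading-ribosome A site for disomes)
#' is sampled within each gene with probability proportional to the dwell
#' weight of the codon at that position. Gene choice is proportional to
#' `expression`; footprint lengths follow the library-specific distribution;
#' the 5' position is placed so that the shared offset convention
#' ([default_offsets()]) recovers the sampled codon, with a uniform 0--2 nt
#' within-codon jitter.
#'
#' @param txome A [make_transcriptome()] object.
#' @param expression Named nonnegative per-gene weights (`NULL` = uniform).
#' @param dwell A [dwell_model()].
#' @param library `"mono"`, `"di"`, or `"both"` (disome share drawn from
#'   `dwell$disome_fraction`).
#' @param depth Total number of footprints (>= 1).
#' @param seed Integer seed.
#' @param offsets Offset table; defaults to [default_offsets()].
#' @param condition,replicate Labels recorded on the output.
#' @return Data.frame with columns `transcript_id`, `five_prime_pos`
#'   (0-based), `length`, `library`, `condition`, `replicate`.
#' @export
simulate_footprints <- function(txome, expression = NULL, dwell,
                                library = c("mono", "di", "both"),
                                depth = 100000, seed = 1,
                                offsets = default_offsets(),
                                condition = dwell$condition, replicate = 1) {
  library <- match.arg(library)
  stopifnot(depth >= 1, inherits(dwell, "dwell_model"))
  g <- txome$genes
  expr <- if (is.null(expression)) setNames(rep(1, nrow(g)), g$gene_id) else
    expression[g$gene_id]
  if (any(is.na(expr)) || any(expr < 0) || sum(expr) <= 0) {
    stop("invalid expression weights")
  }
  cods <- codon_array(txome)
  withr::with_seed(seed, {
    gene_idx <- sample.int(nrow(g), depth, replace = TRUE, prob = expr)
    lib <- if (library == "both") {
      ifelse(runif(depth) < dwell$disome_fraction, "di", "mono")
    } else rep(library, depth)
    len <- integer(depth)
    is_mono <- lib == "mono"
    if (any(is_mono)) {
      len[is_mono] <- sample(as.integer(names(dwell$mono_len_probs)),
                             sum(is_mono), replace = TRUE,
                             prob = dwell$mono_len_probs)
    }
    if (any(!is_mono)) {
      len[!is_mono] <- sample(as.integer(names(dwell$di_len_probs)),
                              sum(!is_mono), replace = TRUE,
                              prob = dwell$di_len_probs)
    }
    off_mono <- .offset_lookup(offsets, "mono")
    off_di <- .offset_lookup(offsets, "di")
    off <- ifelse(is_mono, off_mono[as.character(len)],
                  off_di[as.character(len)])
    ci <- integer(depth)
    dt <- data.table::data.table(i = seq_len(depth), gene = gene_idx,
                                 len = len, off = as.integer(off),
                                 mono = is_mono)
    for (grp in split(dt, by = c("gene", "len", "mono"))) {
      gi <- grp$gene[1]
      L <- g$n_codons[gi]
      o <- grp$off[1]
      w <- if (grp$mono[1]) dwell$w_mono else dwell$w_di
      lo <- as.integer(ceiling(o / 3))
      hi <- as.integer(floor((3 * L - grp$len[1] + o - 2) / 3))
      hi <- min(hi, L - 1L)
      if (hi < lo) stop("gene too short for footprint placement")
      pos <- lo:hi
      pw <- w[cods[[gi]][pos + 1L]]
      pw[is.na(pw)] <- 0      # start/stop codons carry no dwell weight
      if (sum(pw) <= 0) stop("no eligible A-site positions")
      ci[grp$i] <- pos[sample.int(length(pos), nrow(grp), replace = TRUE,
                                  prob = pw)]
    }
    jitter <- sample(0:2, depth, replace = TRUE)
    data.frame(
      transcript_id = g$gene_id[gene_idx],
      five_prime_pos = 3L * ci - as.integer(off) + jitter,
      length = len, library = lib, condition = condition,
      replicate = replicate, stringsAsFactors = FALSE)
  })
}

#' Simulate paired RNA-seq and ribosome-footprint count tables
#'
#' Per-gene baseline expression is log-normal; RNA counts are Poisson with a
#' condition-independent mean, and footprint (RPF) counts are Poisson with
#' the same mean scaled by the gene's translation-efficiency multiplier in
#' the knockout condition.
#'
#' @param txome A `transcriptome`.
#' @param te_effects Named positive KO/WT TE multipliers (`NULL` = all 1).
#' @param n_replicates Replicates per condition.
#' @param mean_rna Mean RNA count per gene (> 0).
#' @param rpf_factor RPF/RNA mean-count ratio (> 0).
#' @param seed Integer seed.
#' @return List with data.frames `rna` and `rpf`, each with columns
#'   `gene_id`, `condition`, `replicate`, `count`.
#' @export
simulate_expression_tables <- function(txome, te_effects = NULL,
                                       n_replicates = 2, mean_rna = 200,
                                       rpf_factor = 1, seed = 1) {
  if (mean_rna <= 0 || rpf_factor <= 0) {
    stop("negative or zero counts requested")
  }
  g <- txome$genes
  mult <- setNames(rep(1, nrow(g)), g$gene_id)
  if (!is.null(te_effects)) {
    if (any(te_effects <= 0)) stop("TE multipliers must be > 0")
    mult[intersect(names(te_effects), g$gene_id)] <-
      te_effects[intersect(names(te_effects), g$gene_id)]
  }
  withr::with_seed(seed, {
    base <- stats::rlnorm(nrow(g), meanlog = log(mean_rna), sdlog = 0.5)
    grid <- expand.grid(gene = seq_len(nrow(g)),
                        condition = c("WT", "KO"),
                        replicate = seq_len(n_replicates),
                        stringsAsFactors = FALSE)
    rna <- data.frame(
      gene_id = g$gene_id[grid$gene], condition = grid$condition,
      replicate = grid$replicate,
      count = rpois(nrow(grid), base[grid$gene]),
      stringsAsFactors = FALSE)
    rpf_mean <- base[grid$gene] * rpf_factor *
      ifelse(grid$condition == "KO", mult[grid$gene], 1)
    rpf <- rna
    rpf$count <- rpois(nrow(grid), rpf_mean)
    list(rna = rna, rpf = rpf)
  })
}
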
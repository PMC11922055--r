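# Closed-form assay computations: Sanger misincorporation percentage,
# delta-delta-Ct charged fraction and relative expression, densitometry
# normalization, and breeding-ratio statistics.

.peak_height <- function(tbl, position, base) {
  h <- tbl$height[tbl$position == position & tbl$base == base]
  if (!length(h)) 0 else sum(h)
}

#' Sanger percent misincorporation with water-control subtraction
#'
#' Per trace, `raw = 100 * T / (C + T)` from the peak heights at the queried
#' position; the result is the treated minus control difference, clamped at
#' 0 (background can exceed signal by chance).
#'
#' @param treated,control Peak tables (`position`, `base`, `height`).
#' @param position 1-based trace position.
#' @return Percentage in `[0, 100]`.
#' @examples
#' tr <- data.frame(position = 1, base = c("C", "T"), height = c(50, 50))
#' ct <- data.frame(position = 1, base = c("C", "T"), height = c(100, 0))
#' sanger_percent_misinc(tr, ct, 1)
#' @export
sanger_percent_misinc <- function(treated, control, position) {
  raw <- function(tbl) {
    cc <- .peak_height(tbl, position, "C")
    tt <- .peak_height(tbl, position, "T")
    if (cc + tt <= 0) stop("undefined result: C + T peak sum is zero")
    100 * tt / (cc + tt)
  }
  max(0, raw(treated) - raw(control))
}

#' Charged tRNA fraction from a periodate-protection Ct table
#'
#' `ddCt = (mean Ct_target - mean Ct_spike)_oxidized -
#' (mean Ct_target - mean Ct_spike)_control`, and the charged fraction is
#' `2^-ddCt`. Replicate Ct values are averaged per (target, treatment).
#' Values above 1 are possible under noise and reported with a warning.
#'
#' @param ct Ct table (`target`, `treatment`, `replicate`, `ct`) with
#'   treatments `oxidized` and `control`.
#' @param target Target of interest.
#' @param spike_target Spike-in control target.
#' @return Positive charged fraction.
#' @export
charged_fraction <- function(ct, target, spike_target = "yPhe") {
  mean_ct <- function(tg, tr) {
    v <- ct$ct[ct$target == tg & ct$treatment == tr]
    if (!length(v)) stop("missing treatment arm: ", tg, " / ", tr)
    mean(v)
  }
  ddct <- (mean_ct(target, "oxidized") - mean_ct(spike_target, "oxidized")) -
    (mean_ct(target, "control") - mean_ct(spike_target, "control"))
  out <- 2^(-ddct)
  if (out > 1) warning("charged fraction above 1 (", signif(out, 3),
                       "); noise can push 2^-ddCt past 1")
  out
}

#' Relative expression by the 2^-ddCt method
#'
#' With a reference gene the classic delta-delta-Ct normalization is used;
#' without one, `2^-(Ct_sample - Ct_calibrator)`. The calibrator sample maps
#' to 1. Replicate Ct values are averaged per (sample, target).
#'
#' @param ct Ct table (`sample`, `target`, `replicate`, `ct`).
#' @param target Target gene.
#' @param reference_gene Optional internal reference gene.
#' @param calibrator_sample Sample whose abundance defines 1.
#' @return Named vector of relative abundances per sample.
#' @export
ddct_expression <- function(ct, target, reference_gene = NULL,
                            calibrator_sample) {
  samples <- unique(ct$sample)
  if (!calibrator_sample %in% samples) {
    stop("unknown calibrator sample: ", calibrator_sample)
  }
  mean_ct <- function(s, tg) {
    v <- ct$ct[ct$sample == s & ct$target == tg]
    if (!length(v)) stop("missing Ct for ", s, " / ", tg)
    mean(v)
  }
  dct <- vapply(samples, function(s) {
    if (is.null(reference_gene)) mean_ct(s, target) else
      mean_ct(s, target) - mean_ct(s, reference_gene)
  }, 0)
  setNames(2^-(dct - dct[calibrator_sample == samples]), samples)
}

#' Collapse a genotype table to counts for one locus
#'
#' @param tbl Genotype table (`thumpd1`, `gcn2`, `count`).
#' @param locus `"thumpd1"` or `"gcn2"`.
#' @return Named integer vector over `+/+`, `+/-`, `-/-`.
#' @export
genotype_counts <- function(tbl, locus = c("thumpd1", "gcn2")) {
  locus <- match.arg(locus)
  lv <- c("+/+", "+/-", "-/-")
  v <- tapply(tbl$count, factor(tbl[[locus]], levels = lv), sum)
  v[is.na(v)] <- 0
  setNames(as.integer(v), lv)
}

#' Pearson chi-square goodness-of-fit test against Mendelian expectations
#'
#' @param counts Named vector of observed category counts (total > 0).
#' @param expected Proportions over the same categories, summing to 1.
#' @return List (`chi2`, `df`, `p`).
#' @examples
#' mendelian_test(c(10, 20, 10), c(0.25, 0.5, 0.25))
#' @export
mendelian_test <- function(counts, expected) {
  stopifnot(length(counts) == length(expected))
  if (abs(sum(expected) - 1) > 1e-9) stop("expected proportions must sum to 1")
  n <- sum(counts)
  if (n <= 0) stop("total count must be positive")
  if (any(expected == 0 & counts > 0)) {
    stop("nonzero count in a zero-probability category")
  }
  keep <- expected > 0
  e <- n * expected[keep]
  chi2 <- sum((counts[keep] - e)^2 / e)
  df <- sum(keep) - 1
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE))
}

#' Compare Thumpd1-/- proportions between Gcn2 strata
#'
#' Splits offspring into Gcn2-/- versus Gcn2-functional (`+/+` and `+/-`)
#' strata, reports the Thumpd1-/- proportion in each, and tests the 2x2
#' collapse (Thumpd1-/- versus not) with a two-sided Fisher exact test. The
#' full 3x3 table is returned alongside.
#'
#' @param tbl Genotype table (`thumpd1`, `gcn2`, `count`).
#' @return List (`proportions`, `p_fisher`, `table2x2`, `table3x3`).
#' @export
compare_proportions <- function(tbl) {
  null_stratum <- tbl$gcn2 == "-/-"
  ko <- tbl$thumpd1 == "-/-"
  n_fun <- sum(tbl$count[!null_stratum])
  n_null <- sum(tbl$count[null_stratum])
  if (n_fun == 0 || n_null == 0) stop("empty Gcn2 stratum")
  k_fun <- sum(tbl$count[!null_stratum & ko])
  k_null <- sum(tbl$count[null_stratum & ko])
  m <- matrix(c(k_fun, n_fun - k_fun, k_null, n_null - k_null), nrow = 2,
              byrow = TRUE,
              dimnames = list(gcn2 = c("functional", "-/-"),
                              thumpd1 = c("-/-", "other")))
  lv <- c("+/+", "+/-", "-/-")
  t3 <- matrix(0L, 3, 3, dimnames = list(thumpd1 = lv, gcn2 = lv))
  for (i in seq_len(nrow(tbl))) {
    t3[tbl$thumpd1[i], tbl$gcn2[i]] <-
      t3[tbl$thumpd1[i], tbl$gcn2[i]] + tbl$count[i]
  }
  list(proportions = c(gcn2_functional = k_fun / n_fun,
                       gcn2_null = k_null / n_null),
       p_fisher = fisher.test(m)$p.value,
       table2x2 = m, table3x3 = t3)
}

#' Densitometry normalization to a loading control
#'
#' `100 * signal / loading`.
#'
#' @param signal Nonnegative signal intensity.
#' @param loading Positive loading-control intensity.
#' @return Percentage of the loading control.
#' @export
densitometry_normalize <- function(signal, loading) {
  if (any(loading <= 0)) stop("loading control must be positive")
  if (any(signal < 0)) stop("signal must be nonnegative")
  100 * signal / loading
}
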
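# Simulators for the closed-form assays: periodate-protected qPCR of
# charged tRNA, dihybrid-cross offspring genotypes, and Sanger trace peaks.

#' Simulate a periodate-protection qPCR Ct table
#'
#' Models the ideal-doubling qPCR readout `Ct = base_ct - log2(template) +
#' noise`. Periodate oxidation destroys uncharged tRNA, so the oxidized
#' ("rxn") template is `charged_fraction * total` while the non-oxidized
#' control template is the total; the spike-in target is added after the
#' treatment and is unaffected by it.
#'
#' @param targets Character vector of target names (excluding the spike-in).
#' @param charged_fraction Named (or recycled) vector in `(0, 1]` per target.
#' @param ct_noise_sd Gaussian noise SD on each Ct value.
#' @param n_replicates Replicates per (target, treatment).
#' @param base_ct Ct of one template unit.
#' @param spike_target Name of the spike-in control target.
#' @param sample Sample label recorded on every row.
#' @param seed Integer seed.
#' @return Data.frame (`sample`, `target`, `treatment`, `replicate`, `ct`)
#'   with treatments `oxidized` and `control`.
#' @export
simulate_qpcr_ct <- function(targets, charged_fraction, ct_noise_sd = 0,
                             n_replicates = 3, base_ct = 20,
                             spike_target = "yPhe", sample = "S1",
                             seed = 1) {
  cf <- if (is.null(names(charged_fraction))) {
    setNames(rep_len(charged_fraction, length(targets)), targets)
  } else charged_fraction[targets]
  if (any(is.na(cf)) || any(cf <= 0) || any(cf > 1)) {
    stop("charged fractions must lie in (0, 1]")
  }
  withr::with_seed(seed, {
    rows <- expand.grid(target = c(targets, spike_target),
                        treatment = c("oxidized", "control"),
                        replicate = seq_len(n_replicates),
                        stringsAsFactors = FALSE)
    template <- ifelse(rows$target == spike_target, 1,
                       ifelse(rows$treatment == "oxidized",
                              cf[rows$target], 1))
    data.frame(sample = sample, target = rows$target,
               treatment = rows$treatment, replicate = rows$replicate,
               ct = base_ct - log2(template) +
                 rnorm(nrow(rows), sd = ct_noise_sd),
               stringsAsFactors = FALSE)
  })
}

#' Construct a dihybrid-cross viability model
#'
#' Offspring genotypes at two loci follow the Mendelian 1:2:1 x 1:2:1 prior
#' reweighted by genotype-specific viability `v(thumpd1, gcn2) >= 0`. The
#' default viabilities are solved in closed form so that the expected
#' Thumpd1-/- proportion is exactly `p_functional` (13%) among offspring
#' carrying at least one functional Gcn2 allele and `p_gcn2_null` (22%)
#' among Gcn2-/- offspring; with all viabilities equal to 1 the Thumpd1-/-
#' expectation is the Mendelian 0.25.
#'
#' @param viability Optional 3x3 matrix (rows Thumpd1 `+/+`, `+/-`, `-/-`;
#'   columns Gcn2 likewise). Overrides the calibrated defaults.
#' @param p_functional,p_gcn2_null Target Thumpd1-/- proportions used to
#'   calibrate the default viabilities.
#' @return An object of class `cohort_model` wrapping the viability matrix.
#' @export
cohort_model <- function(viability = NULL, p_functional = 0.13,
                         p_gcn2_null = 0.22) {
  lv <- c("+/+", "+/-", "-/-")
  if (is.null(viability)) {
    viability <- matrix(1, 3, 3, dimnames = list(thumpd1 = lv, gcn2 = lv))
    # solve 0.25 v / (0.75 + 0.25 v) = p for v
    viability["-/-", c("+/+", "+/-")] <- 3 * p_functional / (1 - p_functional)
    viability["-/-", "-/-"] <- 3 * p_gcn2_null / (1 - p_gcn2_null)
  } else {
    viability <- as.matrix(viability)
    dimnames(viability) <- list(thumpd1 = lv, gcn2 = lv)
  }
  if (any(viability < 0)) stop("viabilities must be nonnegative")
  if (all(viability == 0)) stop("at least one viability must be positive")
  structure(list(viability = viability), class = "cohort_model")
}

#' Simulate offspring genotypes from a dihybrid cross
#'
#' @param n_offspring Number of offspring (>= 1).
#' @param model A [cohort_model()].
#' @param seed Integer seed.
#' @return Data.frame (`thumpd1`, `gcn2`, `count`) over the 9 genotype
#'   pairs; counts sum to `n_offspring`.
#' @export
simulate_cohort <- function(n_offspring = 262, model = cohort_model(),
                            seed = 1) {
  stopifnot(n_offspring >= 1, inherits(model, "cohort_model"))
  mend <- c(0.25, 0.5, 0.25)
  p <- outer(mend, mend) * model$viability
  if (sum(p) <= 0) stop("all genotypes inviable")
  p <- p / sum(p)
  withr::with_seed(seed, {
    counts <- rmultinom(1, n_offspring, as.vector(p))
  })
  lv <- c("+/+", "+/-", "-/-")
  grid <- expand.grid(thumpd1 = lv, gcn2 = lv, stringsAsFactors = FALSE)
  # expand.grid varies the first factor fastest, matching column-major
  # layout of the 3x3 probability matrix
  data.frame(grid, count = as.integer(counts), stringsAsFactors = FALSE)
}

#' Simulate a paired Sanger trace peak table
#'
#' At the queried position the treated trace shows a T-peak share of
#' `true_rate + background` (capped at 1) and the water control a share of
#' `background`; peak heights are the shares times `peak_scale` with
#' multiplicative log-normal noise.
#'
#' @param true_rate,background Rates in `[0, 1]`.
#' @param peak_scale Overall peak height scale (> 0).
#' @param position 1-based trace position reported.
#' @param noise_sd SD of the log-normal height noise.
#' @param seed Integer seed.
#' @return List with data.frames `treated` and `control`, each with columns
#'   `position`, `base`, `height`.
#' @export
simulate_sanger_trace <- function(true_rate, background, peak_scale = 1000,
                                  position = 12, noise_sd = 0.05, seed = 1) {
  stopifnot(true_rate >= 0, true_rate <= 1, background >= 0,
            background <= 1, peak_scale > 0)
  withr::with_seed(seed, {
    mk <- function(t_share) {
      h <- peak_scale * c(C = 1 - t_share, T = t_share) *
        exp(rnorm(2, sd = noise_sd))
      data.frame(position = position, base = c("C", "T"),
                 height = unname(h), stringsAsFactors = FALSE)
    }
    list(treated = mk(min(true_rate + background, 1)),
         control = mk(background))
  })
}
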
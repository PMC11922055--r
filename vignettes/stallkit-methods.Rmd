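---
title: "Models and methods behind stallkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stallkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stallkit)
```

# Scope

stallkit models the molecular readouts by which loss of tRNA C12
N4-acetylcytidine (ac4C) — deposited on Leu/Ser tRNAs by NAT10 with its
adapter THUMPD1 — propagates to tRNA levels, codon-specific ribosome
stalling and collisions, and downstream stress phenotypes. The package has
two halves that mirror each other:

* a **synthetic-data generator** that emulates each data-generating process
  (reduction-readout sequencing chemistry, tRNA-seq sampling, footprint
  dwell times, periodate-protected qPCR, dihybrid crosses, Sanger traces);
* an **analysis pipeline** (site calling, isodecoder quantification,
  occupancy and collision analysis, codon-bias statistics, closed-form
  assays) whose correctness is demonstrated by recovering the parameters the
  generator injected.

Because the generator's defaults *are* the study conditions, every headline
quantity is a parameter-recovery exercise: the defaults encode a 26-gene
Leu/Ser substrate complement over 9 anticodons, a 4-fold depletion of
isodecoder Leu-UAA-2 (with 1.5-fold depletions of Ser-AGA-3, Ser-UGA-4,
Leu-AAG-3, Leu-UAA-3), doubled monosome dwell at UUG/CUA/CUU/UUA and
doubled disome dwell at UCA/CUC/UUG/UUA in the knockout, and offspring
viabilities calibrated to 13% / 22% Thumpd1-null proportions by Gcn2
stratum.

# The reduction-readout (ac4C-seq style) model

A substrate molecule is acetylated with stoichiometry $s$. After chemical
reduction, reverse transcription of an acetylated molecule takes one of
three branches:

* **RT stop** with probability $p_\mathrm{stop}$: the cDNA terminates one
  nucleotide 3' of the modified cytidine, so the read's 5'-most covered
  reference position is $c_{12}+1$. The pileup records this as
  `stop_count` at position $c_{12}$.
* **Misincorporation** with probability $p_\mathrm{mis}$: the read carries
  T at $c_{12}$.
* **Readthrough** otherwise: the read carries C.

The observable misincorporation rate at the site is therefore

$$\mathrm{rate} \;=\; \frac{s\,p_\mathrm{mis}}{1 - s\,p_\mathrm{stop}},$$

because stopped molecules never reach the pileup denominator. The
consistency tests verify convergence to this value at depth 50,000.

Defaults are $p_\mathrm{mis}=0.35,\ p_\mathrm{stop}=0.35$ for Leu
substrates and $p_\mathrm{mis}=0.6,\ p_\mathrm{stop}=0.1$ for Ser,
reproducing the observed qualitative contrast — misincorporation signals
more penetrant for Ser, a higher propensity for stops adjacent to C12 for
Leu — while remaining fully configurable. Per-site stoichiometries are not
published; the default $s = 0.9$ expresses that C12 is the penetrant,
near-stoichiometric site.

**Background error convention.** `epsilon` is the per-base rate of each
*specific* substitution (total substitution rate $3\varepsilon$), so the
expected T fraction at an unmodified C is exactly $\varepsilon$ in both
treated and mock libraries. The default $\varepsilon = 0.002$ is a typical
reverse-transcription error scale. Because the caller subtracts the mock
rate, background cancels in expectation and the residual noise at 1000x
depth is an order of magnitude below the 2% stoichiometry filter.

**Filters.** A site passes when (i) reduced-library depth is *strictly*
greater than `min_depth = 100` reads — the ">100 reads" convention — and
(ii) the mock-subtracted net rate is at least `min_net_rate = 0.02`,
mirroring the observation that spurious reduction-dependent signals sit
below 2% and off the 5'-CCG-3' consensus. Rates use $T/(C+T)$; A/G reads
at C positions are tracked but excluded from the rate. Mock subtraction is
a difference floored at zero, not a ratio. Multimapper weights
($1/\text{placements}$) are accumulated in full precision and depth
comparisons use the real-valued sums.

**Library structure.** Simulated reads are `5' UMI + insert + 3' UMI +
adapter` (6 + 6 nt UMIs, 20 nt adapter). `preprocess_reads()` trims the
adapter (suffix/prefix overlap of at least 10 nt, at most one mismatch,
longest overlap wins), deduplicates on the full sequence *including* UMI
bases (so true duplicates collapse but independent molecules with distinct
UMIs survive), then strips the UMIs. Paired-end merging is out of scope;
the generator emits already-merged single reads.

# Isodecoder quantification

The exhaustive ungapped aligner scans every read against every offset of
every reference gene and keeps all placements achieving the minimum
mismatch count when that count is at most `max_mismatch_frac` (default 0.1,
echoing common aligner settings) times the read length. Isodecoders are
near-identical, so unique-only counting would discard exactly the signal of
interest; fractional $1/\text{multimap}$ weights are used instead.

Quantification forgives mismatches at *tolerated sites* — by default the
annotated C12 positions, where modification-induced misincorporation is
expected — before applying the mismatch threshold. This is a deliberately
simplified, transparent re-implementation of modification-tolerant tRNA
quantification; the full misincorporation-model clustering of the published
mim-tRNA-seq algorithm is explicitly not reproduced, and RT stops are not
modelled in tRNA-seq reads (the generator emits full-length molecules).

**Differential testing.** Log2 fold changes compare mean proportions with a
$10^{-6}$ pseudocount. p values come from a two-sided **pooled-variance**
two-sample t test on log proportions, with Benjamini–Hochberg adjustment.
The pooled test was chosen over the Welch test after measuring both under a
replicate-noise null: at two replicates per condition the Welch
approximation is markedly conservative (empirical type-I error about 0.027
at nominal 0.05), while the pooled test is exactly calibrated under
normality and measured at 0.048–0.056. With equal replicate numbers and
similar group variances — the regime these designs live in — the two
statistics coincide anyway.

Note the compositional subtlety: proportions must sum to one, so depleting
one isodecoder inflates all others slightly. The recovered Leu-UAA-2 fold
change is therefore expected at $\approx 3.7$ rather than 4.0 when the true
per-molecule depletion is 4-fold; the acceptance band (±15%) covers this.

# Footprint occupancy and collisions

The dwell model assigns each of the 61 sense codons a strictly positive
weight, normalized to mean 1. Because monosome stalling (UUG/CUA/CUU/UUA)
and disome accumulation (UCA/CUC/UUG/UUA) involve different codon sets, the
model carries separate monosome and disome weight vectors per condition —
a deliberate widening of a single-weight-vector design, without which the
two collision readouts could not be emulated simultaneously.

**Size classes and offsets.** Monosome footprints are 25–40 nt and disome
footprints 40–80 nt; the printed ranges overlap at 40 nt, and the package
resolves the ambiguity half-open: mono = [25, 40), di = [40, 80]. A-site
offsets are 15 nt (lengths 25–31) and 16 nt (32–40) for monosomes; disome
offsets add the ~30 nt span of the trailing ribosome, giving 45/46 nt to
the *leading* ribosome's A site. Published offset rules for these libraries
live in unreleased scripts, so these are package conventions, shared
exactly between simulator and analyzer; all occupancy acceptance is via
simulator-consistent parameter recovery, not via published occupancy
values.

**Occupancy estimator.** Genes qualify at a mean density of at least 0.5
footprints per included codon; the first and last 20 codons are excluded to
avoid initiation/termination artifacts (both conventional choices, not
published values). Per-gene densities are normalized by the gene mean over
included positions; a codon's occupancy is the unweighted mean over its
occurrences (not gene-weighted — the simplest interpretable estimator),
rescaled so the mean over observed codons is 1. The meta-codon profile uses
the same normalization with the half-window $W$ as the edge exclusion, so
its centre value equals the pre-rescale occupancy when the windows match —
a consistency the tests assert within 2%.

**Translation efficiency.** TE is footprint density over RNA density per
gene; the shift is $\log_2 TE_{KO} - \log_2 TE_{WT}$ with set thresholds
$\pm\log_2 1.5$ and a 32-count floor in every library (data-set criteria
for the published TE sets are unstated; these are package conventions).

# Codon-bias statistics

"Average codon usage" is the unweighted mean of per-gene frequency vectors
(terminal stop excluded), preventing long genes from dominating; a pooled
mode is available because frequency-vs-frequency comparisons may be built
either way. Family-relative representation is $r(c) = f(c) / \sum_{c' \in
\mathrm{family}(c)} f(c')$ and the skew is the difference $r_\mathrm{set} -
r_\mathrm{background}$ — symmetric, bounded, and zero-sum within each
family. The Leu A/U- versus G/C-rich split (UUA/UUG/CUA/CUU versus
CUC/CUG) follows the stalling observations; the Ser split
(UCA/UCU/AGU versus UCC/UCG/AGC) is the package's analogous convention.
Dipeptide frequencies are pooled adjacent amino-acid pairs with a
$10^{-6}$ pseudocount on the log2 enrichment.

# Closed-form assays

* **Sanger**: per trace, $100\,T/(C+T)$ at the queried position; the water
  control is subtracted and negative nets are clamped to 0.
* **Charging**: $\Delta\Delta C_t = (\bar{C_t}^{tgt} -
  \bar{C_t}^{spike})_{ox} - (\bar{C_t}^{tgt} - \bar{C_t}^{spike})_{con}$,
  charged fraction $2^{-\Delta\Delta C_t}$, replicate means per (target,
  treatment). Values above 1 are reported with a warning, not capped.
* **Expression**: classic $2^{-\Delta\Delta C_t}$ with a reference gene, or
  $2^{-\Delta C_t}$ against the calibrator without one.
* **Breeding ratios**: Pearson chi-square goodness of fit against Mendelian
  proportions, and a two-sided Fisher exact test on the 2x2 collapse
  (Thumpd1-null versus not, by Gcn2 stratum); the full 3x3 table is
  reported alongside.
* **Densitometry**: the published normalization formula is printed
  incompletely (its numerator is missing); the natural reading
  $100 \cdot \mathrm{signal}/\mathrm{loading}$ is implemented and flagged
  as an interpretation.

The cohort model reweights the dihybrid $1{:}2{:}1 \times 1{:}2{:}1$ prior
by genotype viabilities. Defaults are solved in closed form so the expected
Thumpd1-null proportion is exactly 13% among Gcn2-functional offspring and
22% among Gcn2-null offspring: $v = 3p/(1-p)$ for the null genotype in each
stratum, 1 elsewhere; all-unit viabilities recover the Mendelian 25%
exactly. The qPCR simulator uses the ideal-doubling model $C_t =
C_t^{base} - \log_2(\mathrm{template}) + \mathcal{N}(0, \sigma^2)$, which
the charging formula inverts exactly at $\sigma = 0$.

# Numerical and validation choices

Every generator draws from one seeded stream per call (`withr::with_seed`),
leaving global RNG state untouched; fixed seeds give byte-identical output.
Coordinates are 0-based half-open internally and 1-based inclusive in TSV
reports. Validation problem sizes were chosen so each recovery is decisively
powered at desk scale: 1000 reads per gene for site calling (signal ~23
standard errors above the 2% filter), 2x2 replicates of 200,000 reads for
the ±15% depletion recovery, 120,000–500,000 footprints per library for
occupancy ranking and 5% dwell recovery, 500 cohorts of 262 offspring for
the breeding percentages, and 200 simulated null datasets for test
calibration.

# What the generator does and does not emulate

It emulates the statistical structure the analyses rely on: branch
chemistry at modified sites, uniform background errors, multinomial
sampling of near-identical isodecoders, codon-conditional dwell sampling
with length-dependent offsets, ideal qPCR doubling, and viability-reweighted
Mendelian draws. It does **not** emulate base-quality error profiles,
ligation or PCR bias, paired-end chemistry, RT stops in tRNA-seq libraries,
rRNA/ncRNA contamination, uORF translation, or rRNA (18S) acetylation.
Passing recovery tests therefore demonstrate the estimators' correctness
under these idealized conditions — not robustness to every artifact of real
libraries, where adapter chemistry, mapping bias, and modification-driven
RT artifacts are harsher.

# Known limitations

* The aligner is exhaustive and ungapped: appropriate for tRNA-scale
  references and synthetic reads, not a genome aligner.
* Isodecoder names follow the package's own synthetic scheme
  (`Leu-UAA-2`); no mapping to genomic tRNA gene nomenclature is claimed.
* The differential test is a transparent t on log proportions, not a
  count-model test; with two replicates its power is limited and the fold
  estimate, not the p value, carries most information.
* Occupancy conventions (offsets, edge exclusion, density floor) are
  self-consistent package defaults; applying the analysis half to real
  footprint data requires calibrating offsets for that protocol.

```{r example, eval = FALSE}
# the whole pipeline at a glance
ref <- make_trna_reference(seed = 1)
prof <- acetylation_profile(ref)
arm <- function(treatment, seed) {
  reads <- simulate_ac4cseq_reads(ref, prof, treatment, depth = 1000,
                                  seed = seed)
  pp <- preprocess_reads(reads)
  build_pileup(align_ungapped(pp, ref), pp, ref)
}
sites <- call_sites(arm("reduced", 3), arm("mock", 4), ref)
subset(sites, passes)
```
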
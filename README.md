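# stallkit

Simulation and analysis toolkit for the molecular consequences of losing
tRNA C12 acetylation. N4-acetylcytidine (ac4C) is written at position C12
of leucine and serine tRNAs by the acetyltransferase NAT10 with its adapter
THUMPD1. When the mark is lost, specific Leu/Ser isodecoders drop in
abundance, ribosomes stall and collide at the codons those tRNAs decode,
and the integrated stress response (via GCN2) shapes organismal outcomes.
stallkit implements the computational readouts of this biology as one
tested pipeline, aimed at methods developers and analysts who need a
desk-scale, fully seeded testbed for these assay types:

* **ac4C site calling** from reduction-readout sequencing: chemical
  reduction converts ac4C into C→T misincorporations or RT stops; sites are
  called from reduced-vs-mock pileups as `rate = T/(C+T)`, net of the mock
  background, with depth (>100 reads) and stoichiometry (≥2%) filters and
  5'-CCG-3' consensus annotation. At a site with stoichiometry *s* and
  stop/misincorporation propensities *p*<sub>stop</sub>, *p*<sub>mis</sub>,
  the expected rate is *s·p*<sub>mis</sub>/(1 − *s·p*<sub>stop</sub>).
* **Isodecoder quantification** tolerant of modification-induced
  mismatches, with fractional multimapper weights, pooled-t differential
  abundance on log proportions, and anticodon-level aggregation.
* **Ribosome and disome profiling**: A-site codon occupancy for 25–40 nt
  monosome and 40–80 nt disome (collision) footprints, KO/WT occupancy
  ratios, meta-codon profiles, per-gene tracks, and translation-efficiency
  gene sets.
* **Codon-bias statistics**: per-gene-averaged codon usage against a
  background, within-amino-acid-family skew (zero-sum by construction),
  A/U- vs G/C-rich Leu/Ser classes, and dipeptide enrichments.
* **Closed-form assays**: Sanger percent misincorporation, ΔΔCt charged
  fraction (2<sup>−ΔΔCt</sup>) and relative expression, densitometry
  normalization, Mendelian chi-square and stratified Fisher tests.
* **A synthetic-data generator** for every input above, whose defaults
  encode the study conditions (26 Leu/Ser substrate genes over 9
  anticodons; a 4-fold Leu-UAA-2 depletion; stall codons UUG/CUA/CUU/UUA
  for monosomes and UCA/CUC/UUG/UUA for disomes; 13%/22% knockout-offspring
  proportions by Gcn2 stratum), so every stage is validated by parameter
  recovery.

## Worked example

Simulate the default reduced/mock library pair at 1000 reads per gene, run
the full caller (trim/dedup → align → pileup → call), then quantify the
knockout's isodecoder depletion from synthetic tRNA-seq libraries:

```r
library(stallkit)

ref  <- make_trna_reference(seed = 1)
ref
#> trna_reference: 36 genes (26 substrate over 9 anticodons, 10 decoy)

prof <- acetylation_profile(ref)
arm <- function(treatment, seed) {
  reads <- simulate_ac4cseq_reads(ref, prof, treatment, depth = 1000,
                                  seed = seed)
  pp <- preprocess_reads(reads)
  build_pileup(align_ungapped(pp, ref), pp, ref)
}
sites <- call_sites(arm("reduced", 3), arm("mock", 4), ref)
head(subset(sites, passes)[, c("ref_id", "pos", "net_rate",
                               "depth_reduced", "stop_fraction",
                               "is_ccg")], 5)
#>       ref_id pos net_rate depth_reduced stop_fraction is_ccg
#> 5  Leu-UAA-1  11    0.467           687         0.313   TRUE
#> 33 Leu-UAA-2  11    0.460           676         0.324   TRUE
#> 54 Leu-UAA-3  11    0.429           706         0.294   TRUE
#> 73 Leu-AAG-1  11    0.454           689         0.311   TRUE
#> 93 Leu-AAG-2  11    0.437           671         0.329   TRUE
```

All 26 called sites (no more, no fewer) are the annotated C12 positions:
the net misincorporation rate ~0.46 is the chemistry's expected
0.9·0.35/(1 − 0.9·0.35) ≈ 0.46 for Leu substrates, RT stops remove ~31% of
coverage at the site, and every site carries the CCG consensus.

```r
quant <- function(cond, rep, seed) {
  reads <- simulate_trnaseq_reads(ref, default_abundance(ref, cond),
                                  default_misinc_signature(ref, cond),
                                  depth = 200000, seed = seed)
  quantify(align_ungapped(reads, ref), ref, condition = cond,
           replicate = rep)
}
wt <- rbind(quant("WT", 1, 11), quant("WT", 2, 12))
ko <- rbind(quant("KO", 1, 13), quant("KO", 2, 14))
d  <- differential(wt, ko)
head(d[order(d$log2fc), ], 5)
#>      gene_id mean_wt mean_ko log2fc  p_value p_adjusted
#> 17 Leu-UAA-2  0.0273 0.00734 -1.893 7.07e-05    0.00254
#> 36 Ser-UGA-4  0.0280 0.01955 -0.520 3.95e-04    0.00356
#> 10 Leu-AAG-3  0.0280 0.01987 -0.496 2.33e-04    0.00356
#> 18 Leu-UAA-3  0.0274 0.01946 -0.495 1.16e-03    0.00838
#> 26 Ser-AGA-3  0.0277 0.01976 -0.488 1.83e-03    0.00992
```

The five depleted isodecoders surface at the top, with Leu-UAA-2 recovered
at 2^1.89 ≈ 3.7-fold — slightly under the injected 4-fold because
proportions renormalize after depletion.

A thin command-line wrapper for the simulate and site-calling steps ships
at `inst/scripts/stallkit.R`; the remaining analyses are R functions (see
the vignette in `vignettes/stallkit-methods.Rmd`).

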
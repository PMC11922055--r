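test_that("default reference satisfies the substrate-complement invariants", {
  ref <- make_trna_reference(seed = 1)
  g <- ref$genes
  expect_equal(sum(g$is_substrate), 26)
  expect_equal(length(unique(g$anticodon[g$is_substrate])), 9)
  expect_equal(anyDuplicated(g$gene_id), 0L)
  expect_equal(anyDuplicated(g$sequence), 0L)
  sub <- g[g$is_substrate, ]
  # 0-based c12_index: context is 1-based (c12_index .. c12_index + 2)
  expect_true(all(substr(sub$sequence, sub$c12_index,
                         sub$c12_index + 2) == "CCG"))
  expect_true(all(is.na(g$c12_index[!g$is_substrate])))
  expect_true(all(nchar(g$sequence) >= 70 & nchar(g$sequence) <= 90))
  r1 <- make_trna_reference(substrate_copies = integer(), n_decoys = 1,
                            seed = 2)
  expect_equal(nrow(r1$genes), 1)
  expect_true(is.na(r1$genes$c12_index))
  expect_error(make_trna_reference(substrate_copies = integer(),
                                   n_decoys = 0), "zero genes")
})

test_that("reference FASTA round-trips with metadata intact", {
  ref <- make_trna_reference(seed = 3)
  path <- withr::local_tempfile(fileext = ".fa")
  write_trna_fasta(ref, path)
  back <- read_trna_fasta(path)
  expect_equal(back$genes, ref$genes)
})

test_that("generators are byte-reproducible for a fixed seed", {
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_trna_fasta(make_trna_reference(seed = 5), f1)
  write_trna_fasta(make_trna_reference(seed = 5), f2)
  expect_identical(readLines(f1), readLines(f2))
  ref <- make_trna_reference(seed = 1)
  prof <- acetylation_profile(ref)
  expect_identical(
    simulate_ac4cseq_reads(ref, prof, "reduced", depth = 50, seed = 3),
    simulate_ac4cseq_reads(ref, prof, "reduced", depth = 50, seed = 3))
  expect_identical(
    simulate_trnaseq_reads(ref, default_abundance(ref), depth = 200,
                           seed = 4),
    simulate_trnaseq_reads(ref, default_abundance(ref), depth = 200,
                           seed = 4))
  expect_identical(make_transcriptome(n_genes = 10, seed = 9),
                   make_transcriptome(n_genes = 10, seed = 9))
  dw <- dwell_model("WT")
  tx <- make_transcriptome(n_genes = 10, seed = 9)
  expect_identical(
    simulate_footprints(tx, dwell = dw, depth = 500, seed = 2),
    simulate_footprints(tx, dwell = dw, depth = 500, seed = 2))
  expect_identical(simulate_cohort(100, seed = 8),
                   simulate_cohort(100, seed = 8))
})

test_that("reduction readout follows the stop/misincorporation branches", {
  ref1 <- make_trna_reference(substrate_copies = c("Leu-TAA" = 1),
                              n_decoys = 0, seed = 2)
  c12 <- ref1$genes$c12_index[1]
  forced <- data.frame(gene_id = ref1$genes$gene_id, s = 1, p_mis = 1,
                       p_stop = 0, epsilon = 0)
  rs <- simulate_ac4cseq_reads(ref1, forced, "reduced", depth = 100,
                               seed = 6, umi_5p_len = 0, umi_3p_len = 0,
                               adapter = "")
  expect_equal(nrow(rs), 100)                       # count conservation
  expect_true(all(substr(rs$sequence, c12 + 1, c12 + 1) == "T"))

  # mock background: T fraction at C12 is epsilon (per-substitution rate)
  mockp <- data.frame(gene_id = ref1$genes$gene_id, s = 0.9, p_mis = 1,
                      p_stop = 0, epsilon = 0.005)
  rs <- simulate_ac4cseq_reads(ref1, mockp, "mock", depth = 10000,
                               seed = 7, umi_5p_len = 0, umi_3p_len = 0,
                               adapter = "")
  n_t <- sum(substr(rs$sequence, c12 + 1, c12 + 1) == "T")
  expect_true(n_t >= binom_ci99(10000, 0.005)[1] &&
              n_t <= binom_ci99(10000, 0.005)[2])

  # branch enumeration: among non-truncated reads the T fraction at C12 is
  # s * p_mis / (1 - s * p_stop)
  mixed <- data.frame(gene_id = ref1$genes$gene_id, s = 0.5, p_mis = 0.8,
                      p_stop = 0.1, epsilon = 0)
  rs <- simulate_ac4cseq_reads(ref1, mixed, "reduced", depth = 50000,
                               seed = 8, umi_5p_len = 0, umi_3p_len = 0,
                               adapter = "")
  full_len <- nchar(ref1$genes$sequence[1])
  full <- rs$sequence[nchar(rs$sequence) == full_len]
  p_exp <- (0.5 * 0.8) / (1 - 0.5 * 0.1)
  p_obs <- mean(substr(full, c12 + 1, c12 + 1) == "T")
  tol <- 3 * sqrt(p_exp * (1 - p_exp) / length(full))
  expect_lt(abs(p_obs - p_exp), tol)
  stop_obs <- mean(nchar(rs$sequence) < full_len)
  expect_lt(abs(stop_obs - 0.05), 3 * sqrt(0.05 * 0.95 / 50000))
  expect_error(
    simulate_ac4cseq_reads(ref1, mixed, treatment = "soup"), "arg")
})

test_that("tRNA-seq sampling is calibrated and respects abundances", {
  ref <- tiny_ref()
  ab <- c("Leu-UAA-1" = 1, "Ala-AGC-1" = 1)
  rs <- simulate_trnaseq_reads(ref, ab, depth = 10000, seed = 11)
  expect_equal(nrow(rs), 10000)
  from_a <- sum(startsWith(rs$read_id, "Leu-UAA-1"))
  ci <- binom_ci99(10000, 0.5)
  expect_true(from_a >= ci[1] && from_a <= ci[2])
  rs <- simulate_trnaseq_reads(ref, c("Leu-UAA-1" = 1, "Ala-AGC-1" = 0),
                               depth = 500, seed = 12)
  expect_true(all(startsWith(rs$read_id, "Leu-UAA-1")))
  expect_error(simulate_trnaseq_reads(
    ref, c("Leu-UAA-1" = 0, "Ala-AGC-1" = 0), depth = 10), "all-zero")
  full <- make_trna_reference(seed = 1)
  expect_equal(
    unname(default_abundance(full, "KO")["Leu-UAA-2"] /
           default_abundance(full, "WT")["Leu-UAA-2"]), 0.25)
})

test_that("transcriptome generator honours CDS invariants and embeds runs", {
  tx <- make_transcriptome(
    n_genes = 5, seed = 4,
    embedded_runs = list(list(gene = 2, after = 1,
                              codons = c("UUA", "UUA", "UUA"))))
  cods <- codon_array(tx)
  for (v in cods) {
    expect_equal(v[1], "ATG")
    expect_true(v[length(v)] %in% stop_codons())
    expect_false(any(v[-length(v)] %in% stop_codons()))
  }
  expect_equal(cods[[2]][2:4], rep("TTA", 3))
  expect_error(make_transcriptome(n_genes = 2, codon_weights = c(TAA = 1)),
               "stop codons")

  # uniform weights: pooled internal-codon frequencies are multinomial(1/61)
  tx <- make_transcriptome(n_genes = 60, length_range = c(150, 250),
                           seed = 13)
  internal <- unlist(lapply(codon_array(tx),
                            function(v) v[2:(length(v) - 1)]))
  n <- length(internal)
  tab <- table(factor(internal, levels = sense_codons()))
  ci <- qbinom(c(0.005 / 61, 1 - 0.005 / 61), n, 1 / 61)
  expect_true(all(tab >= ci[1] & tab <= ci[2]))
})

test_that("expression tables encode recoverable TE shifts", {
  tx <- make_transcriptome(n_genes = 40, seed = 21)
  len <- setNames(3 * tx$genes$n_codons, tx$genes$gene_id)
  null_tabs <- simulate_expression_tables(tx, mean_rna = 500, seed = 22)
  te0 <- compute_te(null_tabs$rpf, null_tabs$rna, len)
  expect_lt(max(abs(te0$dte$delta_te_log2)), 0.585)
  expect_length(te0$te_down, 0)
  expect_length(te0$te_up, 0)
  eff <- setNames(0.5, tx$genes$gene_id[7])
  tabs <- simulate_expression_tables(tx, te_effects = eff, mean_rna = 500,
                                     seed = 23)
  te <- compute_te(tabs$rpf, tabs$rna, len)
  hit <- te$dte$delta_te_log2[te$dte$gene_id == tx$genes$gene_id[7]]
  expect_lt(abs(hit - (-1)), 0.35)
  expect_true(tx$genes$gene_id[7] %in% te$te_down)
  expect_error(simulate_expression_tables(tx, mean_rna = -5), "negative")
})

test_that("qPCR simulator inverts exactly without noise and calibrates with",
{
  ct <- simulate_qpcr_ct("Leu", 1, ct_noise_sd = 0, seed = 1)
  expect_equal(charged_fraction(ct, "Leu"), 1)
  ct <- simulate_qpcr_ct("Leu", 0.25, ct_noise_sd = 0, seed = 1)
  expect_equal(charged_fraction(ct, "Leu"), 0.25)
  expect_error(simulate_qpcr_ct("Leu", 0), "\\(0, 1\\]")
  ok <- vapply(1:200, function(i) {
    ct <- simulate_qpcr_ct("Leu", 0.4, ct_noise_sd = 0.1,
                           n_replicates = 3, seed = 3000 + i)
    abs(charged_fraction(ct, "Leu") - 0.4) <= 0.1
  }, TRUE)
  expect_gte(mean(ok), 0.95)
})

test_that("cohort model reproduces Mendelian and calibrated expectations", {
  # closed form: conditional Thumpd1-/- expectation per Gcn2 stratum
  m <- cohort_model()
  p <- outer(c(0.25, 0.5, 0.25), c(0.25, 0.5, 0.25)) * m$viability
  cond <- p[3, ] / colSums(p)
  expect_equal(unname(cond[1:2]), c(0.13, 0.13))
  expect_equal(unname(cond[3]), 0.22)

  # unit viabilities: Mendelian 1:2:1 marginals
  unit <- cohort_model(viability = matrix(1, 3, 3))
  tb <- simulate_cohort(1e6, unit, seed = 31)
  expect_equal(sum(tb$count), 1e6)
  ko <- sum(tb$count[tb$thumpd1 == "-/-"])
  ci <- binom_ci99(1e6, 0.25)
  expect_true(ko >= ci[1] && ko <= ci[2])
  het <- sum(tb$count[tb$gcn2 == "+/-"])
  ci <- binom_ci99(1e6, 0.5)
  expect_true(het >= ci[1] && het <= ci[2])

  lethal <- matrix(1, 3, 3)
  lethal[3, ] <- 0
  tb <- simulate_cohort(5000, cohort_model(viability = lethal), seed = 32)
  expect_equal(sum(tb$count[tb$thumpd1 == "-/-"]), 0)
  expect_error(cohort_model(viability = matrix(0, 3, 3)), "positive")
})

test_that("Sanger trace simulator matches its closed form", {
  tr <- simulate_sanger_trace(0.5, 0, noise_sd = 0, seed = 1)
  h <- tr$treated$height
  expect_equal(h[tr$treated$base == "T"], h[tr$treated$base == "C"])
  tr <- simulate_sanger_trace(0, 0.02, noise_sd = 0, seed = 2)
  expect_equal(sanger_percent_misinc(tr$treated, tr$control, 12), 0)
})
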
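# Shared pipeline fixture: default reference, WT chemistry, moderate depth.
ref_pipe <- make_trna_reference(seed = 1)
prof_pipe <- acetylation_profile(ref_pipe)
pile_red <- ac4c_pileup(ref_pipe, prof_pipe, "reduced", depth = 600,
                        seed = 41)
pile_mock <- ac4c_pileup(ref_pipe, prof_pipe, "mock", depth = 600, seed = 42)
sites_pipe <- call_sites(pile_red, pile_mock, ref_pipe)

test_that("adapter trimming removes full and partial adapter suffixes", {
  ad <- default_adapter()
  inserts <- c("ACGTACGTACGTACGTACGTACGTACGTACGT",
               "TTTTGGGGCCCCAAAATTTTGGGGCCCCAAAA",
               "GATCGATCGATCGATCGATCGATCGATCGATC",
               "CCGGAACCGGTTCCGGAACCGGTTCCGGAACC")
  reads <- c(paste0(inserts[1], ad),                   # full adapter
             paste0(inserts[2], substr(ad, 1, 12)),    # partial adapter
             paste0(inserts[3], sub("^A", "T", ad)),   # one mismatch
             inserts[4])                               # no adapter
  out <- preprocess_reads(as_read_set(reads),
                          umi_5p_len = 0, umi_3p_len = 0)
  expect_equal(out$sequence, inserts)
  expect_error(preprocess_reads(as_read_set(full), adapter = "ACGTACGT"),
               "invalid config")
})

test_that("deduplication keys on the sequence including UMI bases", {
  insert <- "ACGTACGTACGTACGTACGTACGTACGTACGT"
  r <- as_read_set(c(paste0("AAAAAA", insert, "CCCCCC"),
                     paste0("AAAAAA", insert, "CCCCCC"),
                     paste0("GGGGGG", insert, "TTTTTT")),
                   ids = c("a", "b", "c"))
  out <- preprocess_reads(r, adapter = default_adapter(),
                          umi_5p_len = 6, umi_3p_len = 6)
  # identical including UMI collapses; identical insert, different UMI stays
  expect_equal(nrow(out), 2)
  expect_equal(attr(out, "n_duplicates"), 1)
  expect_equal(out$sequence, rep(insert, 2))
  expect_equal(out$read_id, c("a", "c"))

  # idempotence on already-processed reads
  once <- preprocess_reads(as_read_set(out$sequence, out$read_id),
                           umi_5p_len = 0, umi_3p_len = 0)
  twice <- preprocess_reads(as_read_set(once$sequence, once$read_id),
                            umi_5p_len = 0, umi_3p_len = 0)
  expect_equal(once$sequence, twice$sequence)
})

test_that("ungapped aligner places exact and multimapping reads correctly", {
  ref <- tiny_ref()
  read <- substr(ref$genes$sequence[1], 21, 60)
  al <- align_ungapped(as_read_set(read), ref)
  expect_equal(nrow(al), 1)
  expect_equal(al$ref_id, "Leu-UAA-1")
  expect_equal(al$ref_start, 20)
  expect_equal(al$ref_end, 60)
  expect_equal(al$weight, 1)

  twin <- structure(list(genes = data.frame(
    gene_id = c("dup-1", "dup-2"),
    amino_acid = "Ala", anticodon = "AGC", copy_index = 1:2,
    sequence = rep(ref$genes$sequence[2], 2),
    c12_index = NA_integer_, is_substrate = FALSE,
    stringsAsFactors = FALSE)), class = "trna_reference")
  al <- align_ungapped(as_read_set(substr(ref$genes$sequence[2], 5, 50)),
                       twin)
  expect_equal(nrow(al), 2)
  expect_equal(al$multimap_count, c(2L, 2L))
  expect_equal(al$weight, c(0.5, 0.5))
})

test_that("aligner agrees with a brute-force Hamming scanner", {
  ref <- tiny_ref()
  set.seed(51)
  reads <- replicate(100, {
    g <- sample(2, 1)
    sq <- ref$genes$sequence[g]
    len <- sample(30:60, 1)
    start <- sample(nchar(sq) - len + 1, 1)
    r <- substr(sq, start, start + len - 1)
    n_mut <- sample(0:3, 1)
    if (n_mut > 0) {
      for (p in sample(len, n_mut)) {
        substr(r, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                          substr(r, p, p)), 1)
      }
    }
    r
  })
  # a few unplaceable reads
  reads <- c(reads, replicate(5, paste(
    sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = "")))
  al <- align_ungapped(as_read_set(reads), ref)
  for (i in seq_along(reads)) {
    want <- oracle_align(reads[i], ref$genes)
    got <- al[al$read_id == sprintf("r%d", i), ]
    expect_equal(nrow(got), nrow(want), info = paste("read", i))
    if (nrow(want)) {
      expect_setequal(paste(got$ref_id, got$ref_start),
                      paste(ref$genes$gene_id[want$ref], want$start))
      expect_equal(sort(got$n_mismatch), sort(want$mm))
    }
  }
})

test_that("pileup accumulates weighted bases and RT stops", {
  ref <- tiny_ref()
  sq <- ref$genes$sequence[1]
  reads <- as_read_set(rep(sq, 10))
  al <- align_ungapped(reads, ref)
  pl <- build_pileup(al, reads, ref)
  p1 <- pl[pl$ref_id == "Leu-UAA-1", ]
  expect_equal(p1$depth, rep(10, nchar(sq)))
  base_count <- mapply(function(b, i) p1[[tolower(b)]][i],
                       p1$ref_base, seq_len(nrow(p1)))
  expect_equal(unname(base_count), rep(10, nchar(sq)))
  expect_equal(sum(p1$stop_count), 0)

  # all-stop chemistry: truncated reads start at c12 + 1
  ref1 <- make_trna_reference(substrate_copies = c("Leu-TAA" = 1),
                              n_decoys = 0, seed = 2)
  c12 <- ref1$genes$c12_index[1]
  stopprof <- data.frame(gene_id = ref1$genes$gene_id, s = 1, p_mis = 0,
                         p_stop = 1, epsilon = 0)
  rs <- simulate_ac4cseq_reads(ref1, stopprof, "reduced", depth = 100,
                               seed = 43, umi_5p_len = 0, umi_3p_len = 0,
                               adapter = "")
  al <- align_ungapped(rs, ref1)
  pl <- build_pileup(al, rs, ref1)
  expect_equal(pl$stop_count[pl$pos == c12], 100)
  expect_equal(pl$depth[pl$pos == c12], 0)
  expect_equal(pl$depth[pl$pos == c12 + 1], 100)
})

test_that("pileup depth equals an interval-stabbing coverage oracle", {
  ref <- tiny_ref()
  set.seed(52)
  reads <- vapply(1:60, function(i) {
    g <- sample(2, 1)
    sq <- ref$genes$sequence[g]
    len <- sample(30:55, 1)
    start <- sample(nchar(sq) - len + 1, 1)
    substr(sq, start, start + len - 1)
  }, "")
  rset <- as_read_set(reads)
  al <- align_ungapped(rset, ref)
  pl <- build_pileup(al, rset, ref)
  for (gid in ref$genes$gene_id) {
    a <- al[al$ref_id == gid, ]
    p <- pl[pl$ref_id == gid, ]
    want <- vapply(p$pos, function(pos) {
      sum(a$weight[a$ref_start <= pos & a$ref_end > pos])
    }, 0)
    expect_equal(p$depth, want)
  }
})

test_that("site calling applies the printed rate arithmetic and filters", {
  mk_pile <- function(t_red, c_red, t_mock, c_mock) {
    ref <- tiny_ref()
    row <- function(tt, cc) {
      structure(data.frame(
        ref_id = "Leu-UAA-1", pos = 11L, ref_base = "C", a = 0, c = cc,
        g = 0, t = tt, depth = tt + cc, stop_count = 0,
        stringsAsFactors = FALSE),
        class = c("pileup_table", "data.frame"))
    }
    call_sites(row(t_red, c_red), row(t_mock, c_mock), ref)
  }
  s <- mk_pile(30, 70, 1, 99)
  expect_equal(s$net_rate, 0.30 - 0.01)
  expect_false(s$passes)                        # depth 100 is not > 100
  expect_true(s$is_ccg)
  s <- mk_pile(45, 105, 0, 150)                 # depth 150, net 0.30
  expect_true(s$passes)
  s <- mk_pile(3, 197, 1, 199)                  # net 0.015 < 0.02
  expect_false(s$passes)
})

test_that("stop fractions follow their definition and the Leu/Ser contrast",
{
  pl <- structure(data.frame(
    ref_id = "x", pos = 11L, ref_base = "C", a = 0, c = 60, g = 0, t = 0,
    depth = 60, stop_count = 40, stringsAsFactors = FALSE),
    class = c("pileup_table", "data.frame"))
  expect_equal(stop_profile(pl)$stop_fraction, 0.4)

  # default chemistry favours stops for Leu over Ser at C12
  c12 <- sites_pipe[sites_pipe$is_c12, ]
  aa <- sub("-.*", "", c12$ref_id)
  expect_gt(mean(c12$stop_fraction[aa == "Leu"]),
            mean(c12$stop_fraction[aa == "Ser"]))
})

test_that("Thumpd1 sensitivity classification compares WT and KO calls", {
  wt <- sites_pipe
  ko_prof <- acetylation_profile(ref_pipe, stoichiometry = 0)
  ko_red <- ac4c_pileup(ref_pipe, ko_prof, "reduced", depth = 600,
                        seed = 44)
  ko_mock <- ac4c_pileup(ref_pipe, ko_prof, "mock", depth = 600, seed = 45)
  ko <- call_sites(ko_red, ko_mock, ref_pipe)
  out <- thumpd1_sensitivity(wt, ko)
  passing <- out[out$passes, ]
  expect_true(all(passing$is_c12))
  expect_true(all(passing$thumpd1_sensitive))
  # a site equally modified in both genotypes is not sensitive
  same <- thumpd1_sensitivity(wt, wt)
  expect_false(any(same$thumpd1_sensitive[same$passes]))
  # positions absent from the KO table are uncallable
  out2 <- thumpd1_sensitivity(wt, ko[0, ])
  expect_true(all(is.na(out2$thumpd1_sensitive)))
})

test_that("net rate converges to s*p_mis / (1 - s*p_stop) at high depth", {
  ref1 <- make_trna_reference(substrate_copies = c("Leu-TAA" = 1),
                              n_decoys = 0, seed = 2)
  prof <- data.frame(gene_id = ref1$genes$gene_id, s = 0.6, p_mis = 0.5,
                     p_stop = 0.3, epsilon = 0)
  depth <- 50000
  mk <- function(treatment, seed) {
    rs <- simulate_ac4cseq_reads(ref1, prof, treatment, depth = depth,
                                 seed = seed, umi_5p_len = 0,
                                 umi_3p_len = 0, adapter = "")
    al <- align_ungapped(rs, ref1)
    build_pileup(al, rs, ref1)
  }
  sites <- call_sites(mk("reduced", 61), mk("mock", 62), ref1)
  c12 <- sites[sites$is_c12, ]
  p_exp <- 0.6 * 0.5 / (1 - 0.6 * 0.3)
  n_eff <- depth * (1 - 0.6 * 0.3)
  expect_lt(abs(c12$net_rate - p_exp),
            3 * sqrt(p_exp * (1 - p_exp) / n_eff))
})

test_that("net rate is nondecreasing in stoichiometry", {
  ref1 <- make_trna_reference(substrate_copies = c("Ser-AGA" = 1),
                              n_decoys = 0, seed = 2)
  rates <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(s) {
    prof <- data.frame(gene_id = ref1$genes$gene_id, s = s, p_mis = 0.6,
                       p_stop = 0.1, epsilon = 0)
    mk <- function(treatment, seed) {
      rs <- simulate_ac4cseq_reads(ref1, prof, treatment, depth = 20000,
                                   seed = seed, umi_5p_len = 0,
                                   umi_3p_len = 0, adapter = "")
      al <- align_ungapped(rs, ref1)
      build_pileup(al, rs, ref1)
    }
    sites <- call_sites(mk("reduced", 63), mk("mock", 64), ref1)
    sites$net_rate[sites$is_c12]
  }, 0)
  expect_true(all(diff(rates) >= 0))
})

test_that("no substrate means no called sites (specificity)", {
  ref0 <- make_trna_reference(substrate_copies = integer(), n_decoys = 20,
                              seed = 9)
  prof <- acetylation_profile(ref0)
  red <- ac4c_pileup(ref0, prof, "reduced", depth = 2000, seed = 71)
  mock <- ac4c_pileup(ref0, prof, "mock", depth = 2000, seed = 72)
  sites <- call_sites(red, mock, ref0)
  expect_equal(sum(sites$passes), 0)
})
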
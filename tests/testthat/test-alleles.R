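test_that("read pairs classify by orientation and insert size", {
  mk <- function(p1, s1, p2, s2, c1 = "c", c2 = "c") {
    data.frame(chrom1 = c1, pos1 = p1, strand1 = s1,
               chrom2 = c2, pos2 = p2, strand2 = s2, stringsAsFactors = FALSE)
  }
  cl <- function(p) classify_read_pairs(p, insert_mean = 400, insert_sd = 50)
  expect_equal(cl(mk(1000, "-", 1100, "+")), "face_away")
  expect_equal(cl(mk(1000, "+", 1100, "+")), "same_orientation")
  expect_equal(cl(mk(1000, "-", 1100, "-")), "same_orientation")
  expect_equal(cl(mk(1000, "+", 1200, "-")), "proper")
  expect_equal(cl(mk(1000, "+", 2000, "-")), "long_insert")  # > 400 + 5*50
  expect_equal(cl(mk(1000, "+", 1100, "-", c2 = "d")), "crossmapped")
  # mate order does not matter for orientation logic
  expect_equal(cl(mk(1100, "+", 1000, "-")), "face_away")
  expect_error(cl(mk(1000, "x", 1100, "+")), "strand")
})

test_that("simulated junction reads round-trip through the classifier", {
  ref <- simulate_reference(seed = 71)
  s <- tiny_samples(c("S001", "S002", "S003"))
  planted <- data.frame(sample_id = c("S001", "S002", "S003"), chrom = "2L",
                        start_window = c(100, 400, 700),
                        end_window = c(120, 420, 720),
                        copies_added = 1L, zygosity = 1L,
                        mechanism = c("tandem_duplication", "tandem_inversion",
                                      "deletion_within_amplification"),
                        allele_id = c("dup", "inv", "del"))
  rd <- simulate_breakpoint_reads(ref, s, planted, seed = 72,
                                  background_pairs = 0)
  cls <- classify_read_pairs(rd$pairs, 400, 50)
  expect_true(all(cls[rd$pairs$sample_id == "S001"] == "face_away"))
  expect_true(all(cls[rd$pairs$sample_id == "S002"] == "same_orientation"))
  expect_true(all(cls[rd$pairs$sample_id == "S003"] == "long_insert"))
  # every carrier has at least two diagnostic reads
  expect_true(all(table(rd$pairs$sample_id) >= 2))
  # no planted CNVs, no background: no diagnostic reads at all
  rd0 <- simulate_breakpoint_reads(ref, s, NULL, seed = 73,
                                   background_pairs = 0)
  expect_equal(nrow(rd0$pairs), 0)
  expect_equal(nrow(rd0$clips), 0)
  expect_error(simulate_breakpoint_reads(ref, s, planted, insert_mean = 150),
               "twice the read length")
})

test_that("allele presence needs at least two supporting diagnostic reads", {
  sig <- data.frame(allele_id = "a", chrom = "c", type = "face_away",
                    anchor1 = 1000, anchor2 = 4000, tol = 300,
                    stringsAsFactors = FALSE)
  mkp <- function(n, sample = "S1") {
    data.frame(sample_id = sample, chrom1 = "c", pos1 = rep(1000, n),
               strand1 = "-", chrom2 = "c", pos2 = rep(4000, n),
               strand2 = "+", stringsAsFactors = FALSE)
  }
  a1 <- call_alleles(mkp(1), NULL, sig, samples = "S1")
  expect_false(a1$present)
  a2 <- call_alleles(mkp(2), NULL, sig, samples = "S1")
  expect_true(a2$present)
  # a read outside the anchor tolerance does not support
  p <- mkp(2); p$pos1 <- c(1000, 2000)
  a3 <- call_alleles(p, NULL, sig, samples = "S1")
  expect_equal(a3$n_support, 1L)
  # monotone in depth: adding supporting reads never flips present -> absent
  for (n in 2:6) expect_true(call_alleles(mkp(n), NULL, sig, "S1")$present)
  # clips support breakpoint_clip signatures within +-tol
  sigc <- data.frame(allele_id = "a", chrom = "c", type = "breakpoint_clip",
                     anchor1 = 1000, anchor2 = 4000, tol = 10)
  clips <- data.frame(sample_id = "S1", chrom = "c", pos = c(1005, 3995, 1500),
                      side = "end", seq = "ACGT", stringsAsFactors = FALSE)
  ac <- call_alleles(NULL, clips, sigc, "S1")
  expect_equal(ac$n_support, 2L)
})

test_that("copy-number solver recovers noiseless overlapping-allele profiles", {
  win <- tiny_windows(60)
  samples <- tiny_samples("S1")
  spans <- data.frame(allele_id = c("A", "B"), chrom = "chr1",
                      start = c(3000, 6000), end = c(12000, 12000))
  # nested alleles: +1 over A-only stretch, +3 where both overlap
  norm <- matrix(2, 1, 60, dimnames = list("S1", NULL))
  norm[1, 11:20] <- 3   # windows 3000-6000: A only
  norm[1, 21:40] <- 5   # windows 6000-12000: A + B
  cov <- make_cov(norm, win, samples)
  pres <- data.frame(sample_id = "S1", allele_id = c("A", "B"), present = TRUE)
  cn <- estimate_allele_copy_numbers(cov, pres, spans)
  expect_equal(unname(cn$copies["S1", ]), c(1, 2))
  expect_equal(unname(cn$raw["S1", ]), c(1, 2), tolerance = 1e-8)
  # single allele, exact step 2 -> 4
  spans1 <- spans[1, ]
  norm1 <- matrix(2, 1, 60, dimnames = list("S1", NULL))
  norm1[1, 11:40] <- 4
  cn1 <- estimate_allele_copy_numbers(make_cov(norm1, win, samples),
                                      pres[1, ], spans1)
  expect_equal(unname(cn1$copies["S1", 1]), 2)
  # identical spans for two present alleles are non-identifiable
  spans_id <- data.frame(allele_id = c("A", "B"), chrom = "chr1",
                         start = 3000, end = 12000)
  cnid <- estimate_allele_copy_numbers(cov, pres, spans_id)
  expect_true(all(is.na(cnid$copies["S1", ])))
  expect_true(all(cnid$flags$flag == "NON_IDENTIFIABLE"))
})

test_that("a single sample reaching 2.5 is rounded down to 2 and flagged", {
  win <- tiny_windows(40)
  samples <- tiny_samples(c("S1", "S2", "S3"))
  spans <- data.frame(allele_id = "A", chrom = "chr1", start = 3000, end = 9000)
  norm <- matrix(2, 3, 40, dimnames = list(samples$sample_id, NULL))
  norm[1, 11:30] <- 4.6   # raw estimate 2.6 for S1 only
  norm[2, 11:30] <- 4     # raw 2
  cov <- make_cov(norm, win, samples)
  pres <- data.frame(sample_id = c("S1", "S2"), allele_id = "A",
                     present = TRUE)
  cn <- estimate_allele_copy_numbers(cov, pres, spans)
  expect_equal(unname(cn$copies[, "A"]), c(2, 2, 0))
  expect_equal(cn$flags$flag, "ROUNDED_25_TO_2")
  # two samples above 2.5: the exception does not apply
  norm[2, 11:30] <- 4.8
  cn2 <- estimate_allele_copy_numbers(make_cov(norm, win, samples), pres, spans)
  expect_equal(unname(cn2$copies[, "A"]), c(3, 3, 0))
})

test_that("exact HWE test agrees with its sampling oracle and known regimes", {
  expect_gt(hwe_exact_test(81, 18, 1), 0.05)   # near HWE at freq 0.1
  expect_lt(hwe_exact_test(90, 0, 10), 1e-6)   # total heterozygote deficit
  expect_equal(hwe_exact_test(0, 0, 0), 1)
  set.seed(73)
  for (tab in list(c(40, 15, 5), c(20, 20, 20), c(50, 9, 1))) {
    p_mc <- oracle_hwe_mc(tab[1], tab[2], tab[3], reps = 30000)
    p <- hwe_exact_test(tab[1], tab[2], tab[3])
    expect_lt(abs(p - p_mc), 4 * sqrt(p_mc * (1 - p_mc) / 30000) + 0.01)
  }
})

test_that("genotyping applies the copy ceiling, triplication and HWE filters", {
  mk_copies <- function(v) {
    matrix(v, length(v), 1, dimnames = list(sprintf("S%02d", seq_along(v)), "A"))
  }
  manifest <- function(n) data.frame(sample_id = sprintf("S%02d", 1:n),
                                     population = "p", stringsAsFactors = FALSE)
  # copies above 2: allele excluded
  g1 <- genotype_alleles(mk_copies(c(3, rep(0, 19))), manifest(20))
  expect_equal(g1$excluded$reason, "CN_GT2")
  # near-HWE duplication: genotyped 0/1/2
  cp <- c(rep(0, 81), rep(1, 18), rep(2, 1))
  g2 <- genotype_alleles(mk_copies(cp), manifest(100))
  expect_equal(nrow(g2$excluded), 0)
  expect_equal(unname(g2$genotypes[, 1]), cp)
  # heterozygote deficit fails HWE (one true het keeps the allele a
  # duplication rather than a pure triplication)
  cp3 <- c(rep(0, 90), 1, rep(2, 9))
  g3 <- genotype_alleles(mk_copies(cp3), manifest(100))
  expect_equal(g3$excluded$reason, "HWE_FAIL")
  # pure triplication: all carriers have 2 copies and genotype heterozygous
  cp4 <- c(rep(0, 80), rep(2, 20))
  # in HWE as het genotypes (freq 0.1): 2*0.1*0.9*100 = 18 het expected
  g4 <- genotype_alleles(mk_copies(cp4), manifest(100))
  expect_equal(nrow(g4$excluded), 0)
  expect_equal(unname(g4$genotypes[cp4 == 2, 1]), rep(1L, 20))
  # excluded set invariant to sample order
  ord <- sample(100)
  g5 <- genotype_alleles(mk_copies(cp3[ord]), manifest(100))
  expect_equal(g5$excluded$reason, "HWE_FAIL")
})

test_that("duplications segregating under HWE survive the filter", {
  set.seed(74)
  pass <- vapply(1:100, function(r) {
    gt <- rbinom(100, 1, 0.2) + rbinom(100, 1, 0.2)  # copies under HWE, p=0.2
    m <- data.frame(sample_id = sprintf("S%03d", 1:100), population = "p")
    cp <- matrix(gt, 100, 1, dimnames = list(m$sample_id, "A"))
    nrow(genotype_alleles(cp, m)$excluded) == 0
  }, logical(1))
  expect_gte(mean(pass), 0.95)
})

test_that("breakpoint clip consensus takes the majority base per position", {
  clips <- data.frame(allele_id = "a", side = "end",
                      seq = c("ACGT", "ACGT", "ACGT"))
  expect_equal(unname(breakpoint_clip_consensus(clips)), "ACGT")
  clips$seq <- c("ACGT", "ACTT", "ACGT")
  expect_equal(unname(breakpoint_clip_consensus(clips)), "ACGT")
  # right-alignment for clips preceding the breakpoint
  clips2 <- data.frame(allele_id = "a", side = "start",
                       seq = c("GGACGT", "ACGT", "ACGT"))
  expect_equal(unname(breakpoint_clip_consensus(clips2)), "GGACGT")
  expect_error(breakpoint_clip_consensus(
    data.frame(allele_id = "a", side = "end", seq = "")), "non-empty")
  # simulator round-trip: consensus equals the planted junction sequence
  ref <- simulate_reference(seed = 75)
  s <- tiny_samples(c("S001", "S002"))
  planted <- data.frame(sample_id = c("S001", "S002"), chrom = "2L",
                        start_window = 100, end_window = 120,
                        copies_added = 1L, zygosity = 1L,
                        mechanism = "tandem_duplication", allele_id = "dup")
  rd <- simulate_breakpoint_reads(ref, s, planted, seed = 76)
  cons <- breakpoint_clip_consensus(rd$clips)
  expect_equal(unname(cons["dup/end"]), rd$clips$seq[1])
  # FASTA export writes one record per allele/side
  fa <- tempfile(fileext = ".fa")
  export_breakpoint_clips(rd$clips, fa)
  expect_true(file.exists(fa))
  expect_equal(sum(grepl("^>", readLines(fa))), 2)
})
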
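test_that("chromatin classification uses the any-overlap rule", {
  het <- data.frame(chrom = "c", start = 199, end = 300)
  expect_equal(classify_chromatin(data.frame(chrom = "c", start = 100, end = 200),
                                  het), "heterochromatic")  # 1-bp overlap
  expect_equal(classify_chromatin(data.frame(chrom = "c", start = 100, end = 199),
                                  het), "euchromatic")       # touching only
  # random intervals against a per-bp oracle
  set.seed(51)
  for (i in 1:50) {
    v <- sort(sample(0:200, 2)); h <- sort(sample(0:200, 2))
    if (v[1] == v[2] || h[1] == h[2]) next
    got <- classify_chromatin(data.frame(chrom = "c", start = v[1], end = v[2]),
                              data.frame(chrom = "c", start = h[1], end = h[2]))
    bp <- length(intersect(seq(v[1], v[2] - 1), seq(h[1], h[2] - 1))) > 0
    expect_equal(got == "heterochromatic", bp)
  }
})

test_that("position null matches exact enumeration on a toy genome", {
  win <- tiny_windows(20, chrom = "c", w = 10)
  het <- data.frame(chrom = "c", start = 150, end = 200)  # last 5 windows
  v <- data.frame(variant_id = "V1", chrom = "c", start = 20, end = 50)
  r <- simulate_position_null(v, win, rep(TRUE, 20), het, n_sims = 1e5,
                              seed = 52)
  # exact: 18 admissible starts for a 3-window span; 5 of them reach the het
  p_exact <- 5 / 18
  se <- sqrt(p_exact * (1 - p_exact) / 1e5)
  expect_lt(abs(mean(r$het$null) - p_exact), 3 * se)
  # degenerate: no heterochromatin at all -> p capped at 1
  r0 <- simulate_position_null(v, win, rep(TRUE, 20),
                               data.frame(chrom = character(),
                                          start = numeric(), end = numeric()),
                               n_sims = 1000, seed = 53)
  expect_equal(r0$het$observed, 0)
  expect_equal(r0$het$p_value, 1)
  # an observed count beyond every null draw reports the 2/n bound
  vh <- data.frame(variant_id = paste0("V", 1:3), chrom = "c",
                   start = c(0, 30, 60), end = c(30, 60, 90))
  win2 <- tiny_windows(2000, chrom = "c", w = 10)
  het2 <- data.frame(chrom = "c", start = 0, end = 90)
  rh <- simulate_position_null(vh, win2, rep(TRUE, 2000), het2,
                               n_sims = 10000, seed = 54)
  expect_equal(rh$het$observed, 3)
  expect_true(rh$het$p_is_upper_bound)
  expect_equal(rh$het$p_value, 2 / 10000)
  # a variant larger than the chromosome is an error naming the variant
  vbig <- data.frame(variant_id = "Vbig", chrom = "c", start = 0, end = 200)
  expect_error(simulate_position_null(vbig, win, rep(FALSE, 20), het),
               "Vbig")
})

test_that("placement frequency is uniform over admissible starts", {
  # het covering exactly the last window: only the final placement hits it
  win <- tiny_windows(20, chrom = "c", w = 10)
  het <- data.frame(chrom = "c", start = 190, end = 200)
  v <- data.frame(variant_id = "V1", chrom = "c", start = 0, end = 30)
  r <- simulate_position_null(v, win, rep(TRUE, 20), het, n_sims = 1e5,
                              seed = 55)
  p_exact <- 1 / 18
  se <- sqrt(p_exact * (1 - p_exact) / 1e5)
  expect_lt(abs(mean(r$het$null) - p_exact), 3 * se)
})

test_that("gene copy rules follow the 50%-kept and all-kept-inside criteria", {
  win <- tiny_windows(100)
  keep <- rep(TRUE, 100)
  genes <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "chr1",
                      start = c(3000, 30000, 24000),
                      end = c(4500, 33000, 26400),
                      stringsAsFactors = FALSE)
  v <- data.frame(variant_id = "V1", chrom = "chr1", start = 2700, end = 5100)
  gt <- gene_copy_table(v, genes, win, keep)
  expect_equal(gt$copies$gene_id, "g1")  # fully inside, all windows kept
  # gene with <50% kept windows is never retained
  keep2 <- keep; keep2[11:15] <- FALSE   # windows 3000-4500 dropped (5 of 5)
  gt2 <- gene_copy_table(v, genes, win, keep2)
  expect_false(gt2$genes$retained[1])
  expect_equal(nrow(gt2$copies), 0)
  # gene whose dropped windows extend beyond the variant is still copied
  keep3 <- keep; keep3[14:15] <- FALSE   # gene g1 windows 3900-4500 dropped
  v3 <- data.frame(variant_id = "V1", chrom = "chr1", start = 2700, end = 3900)
  gt3 <- gene_copy_table(v3, genes, win, keep3)
  expect_true("g1" %in% gt3$copies$gene_id)
})

test_that("gene identity null matches the binomial expectation", {
  genes <- data.frame(gene_id = paste0("g", 1:10), chrom = "c",
                      detox = c(rep(FALSE, 4), TRUE, rep(FALSE, 5)),
                      stringsAsFactors = FALSE)
  gc1 <- data.frame(variant_id = "V1", gene_id = "g5")
  r <- simulate_gene_identity_null(gc1, genes, n_sims = 2e4, seed = 56)
  se <- sqrt(0.1 * 0.9 / 2e4)
  expect_lt(abs(r$null_mean - 0.1), 3 * se)
  expect_equal(r$observed, 1)
  # no detox genes anywhere: null identically zero
  genes$detox <- FALSE
  r0 <- simulate_gene_identity_null(gc1, genes, n_sims = 1000, seed = 57)
  expect_true(all(r0$null == 0))
  # a CNV covering several detox genes still counts once
  genes2 <- genes; genes2$detox <- c(TRUE, TRUE, rep(FALSE, 8))
  gc2 <- data.frame(variant_id = c("V1", "V1"), gene_id = c("g1", "g2"))
  r2 <- simulate_gene_identity_null(gc2, genes2, n_sims = 500, seed = 58)
  expect_equal(r2$observed, 1)
  expect_true(all(r2$null <= 1))
})

test_that("size comparison reproduces an exact rank-sum computation", {
  # all het values below all eu values: W = 0
  r <- compare_cnv_sizes(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$W, 0)
  expect_equal(r$median_het, 2)
  # random vectors: W equals the pair-count definition
  set.seed(59)
  x <- runif(30); y <- runif(40)
  r2 <- compare_cnv_sizes(x, y)
  expect_equal(r2$W, sum(outer(x, y, ">")))
  expect_error(compare_cnv_sizes(numeric(0), y), "non-empty")
  # identical groups: p close to 1
  expect_gt(compare_cnv_sizes(1:20, 1:20)$p_value, 0.9)
})

test_that("rank-sum test holds its nominal type-I error", {
  set.seed(60)
  rej <- vapply(1:1000, function(i) {
    compare_cnv_sizes(rnorm(20), rnorm(20))$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.025)
  expect_lt(mean(rej), 0.08)
})

test_that("two-tailed p is reproducible and invariant to variant relabeling", {
  win <- tiny_windows(50, chrom = "c", w = 10)
  het <- data.frame(chrom = "c", start = 400, end = 500)
  v <- data.frame(variant_id = c("V1", "V2"), chrom = "c",
                  start = c(0, 100), end = c(30, 150))
  r1 <- simulate_position_null(v, win, rep(TRUE, 50), het, n_sims = 2000,
                               seed = 61)
  r2 <- simulate_position_null(v, win, rep(TRUE, 50), het, n_sims = 2000,
                               seed = 61)
  expect_identical(r1$het$null, r2$het$null)
  v3 <- v; v3$variant_id <- c("B", "A")
  r3 <- simulate_position_null(v3, win, rep(TRUE, 50), het, n_sims = 2000,
                               seed = 61)
  expect_equal(r1$het$p_value, r3$het$p_value)
})

test_that("contingency test falls back to Monte Carlo on large tables", {
  tab <- matrix(c(10, 0, 0, 10), 2)
  expect_lt(contingency_test(tab)$p.value, 0.001)
  big <- matrix(rpois(64, 500), 8)
  r <- contingency_test(big, B = 1e4, seed = 62)
  expect_true(r$p.value >= 0 && r$p.value <= 1)
})
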
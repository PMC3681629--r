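test_that("flat coverage gives the closed-form adjusted track", {
  tr <- adjust_coverage(rep(5L, 3000), L = 200, p = 4)
  expect_equal(tr$mu, 5)
  expect_equal(tr$W, rep(5, 3000))
  expect_equal(tr$Y, rep(log2(1 / 4), 3000))
  tr2 <- adjust_coverage(rep(7L, 3000), L = 200, p = 2)
  expect_equal(tr2$Y, rep(-1, 3000))
})

test_that("transformed scores are invariant to coverage rescaling", {
  set.seed(5)
  x <- rnbinom(20000, size = 10, mu = 4)
  a <- adjust_coverage(x, L = 500, p = 4)
  b <- adjust_coverage(2L * x, L = 500, p = 4)
  keep <- a$W > 0 & b$W > 0
  expect_gt(mean(keep), 0.95)
  expect_equal(a$Y[keep], b$Y[keep], tolerance = 1e-12)
  expect_equal(b$mu, 2 * a$mu)
})

test_that("a narrow spike at 2 p mu scores about 1", {
  x <- rep(10L, 50001)
  x[25000] <- 10L * 4L * 2L
  tr <- adjust_coverage(x, L = 5000, p = 4)
  expect_equal(tr$Y[25000], 1, tolerance = 0.02)
  expect_lt(abs(mean(tr$W) - tr$mu), 0.01)
})

test_that("degenerate coverage inputs are rejected", {
  expect_error(adjust_coverage(rep(0L, 1000), L = 10, p = 4),
               "no coverage")
  expect_error(adjust_coverage(rep(2L, 1000), L = 10, p = 0),
               "positive")
  expect_error(adjust_coverage(rep(2L, 1000), L = 600, p = 4),
               "window")
})

test_that("segment finder reproduces worked examples", {
  seg <- find_high_scoring_segments(c(-1, 2, 3, -1, -5, 1))
  expect_equal(seg$start, c(1L, 5L))
  expect_equal(seg$end, c(3L, 6L))
  expect_equal(seg$score, c(5, 1))
  expect_equal(nrow(find_high_scoring_segments(c(-2, -0.5, -3))), 0L)
  # a single positive base flanked by zeros: ties broken to shortest
  seg1 <- find_high_scoring_segments(c(0, 0, 1, 0, 0))
  expect_equal(as.numeric(seg1), c(2, 3, 1))
  expect_error(find_high_scoring_segments(c(1, NA, 2)), "finite")
})

test_that("segment finder agrees with the brute-force oracle", {
  set.seed(71)
  for (i in 1:250) {
    n <- sample(1:40, 1)
    y <- as.numeric(sample(-3:3, n, replace = TRUE))
    expect_equal(unname(as.matrix(find_high_scoring_segments(y))),
                 unname(as.matrix(hss_brute(y))))
  }
})

test_that("quadratic oracle matches the brute-force oracle", {
  set.seed(72)
  for (i in 1:150) {
    n <- sample(2:35, 1)
    y <- as.numeric(sample(-2:2, n, replace = TRUE))
    expect_equal(unname(as.matrix(hss_quadratic(y))),
                 unname(as.matrix(hss_brute(y))))
  }
})

test_that("segments are sorted, disjoint and positive-scoring", {
  set.seed(73)
  for (i in 1:50) {
    y <- rnorm(500)
    seg <- find_high_scoring_segments(y)
    if (nrow(seg) < 2) next
    expect_true(all(diff(seg$start) > 0))
    expect_true(all(seg$start[-1] >= seg$end[-nrow(seg)]))
    expect_true(all(seg$score > 0))
  }
})

test_that("mappability filtering removes any 1 bp overlap", {
  pk <- GenomicRanges::GRanges("c1", IRanges::IRanges(
    start = c(101, 500), end = c(200, 600)))
  S4Vectors::mcols(pk)$sample_id <- "s1"
  mask <- GenomicRanges::GRanges("c1", IRanges::IRanges(200, 300))
  kept <- filter_mappability(pk, mask)
  expect_equal(GenomicRanges::start(kept), 500)
  expect_identical(filter_mappability(pk, GenomicRanges::GRanges()), pk)
  all_mask <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 1000))
  expect_length(filter_mappability(pk, all_mask), 0L)
})

test_that("consolidation merges overlapping peaks across samples", {
  g1 <- GenomicRanges::GRanges("c1", IRanges::IRanges(101, 200))
  S4Vectors::mcols(g1)$sample_id <- "s1"
  g2 <- GenomicRanges::GRanges("c1", IRanges::IRanges(151, 250))
  S4Vectors::mcols(g2)$sample_id <- "s2"
  one <- consolidate_peaks(list(g1))
  expect_equal(GenomicRanges::start(one), 101)
  both <- consolidate_peaks(list(g1, g2))
  expect_equal(GenomicRanges::start(both), 101)
  expect_equal(GenomicRanges::end(both), 250)
  expect_equal(S4Vectors::mcols(both)$n_samples, 2L)
  twin <- consolidate_peaks(list(g1, g1))
  expect_equal(GenomicRanges::end(twin), 200)
  expect_length(twin, 1L)
})

test_that("few peaks are called on homogeneous NB noise at p = 4", {
  set.seed(9)
  fp <- 0L
  for (r in 1:5) {
    x <- rnbinom(2e5, size = 20, mu = 2)
    pk <- call_peaks(x, p = 4, window = 20001, min_score = 5)
    fp <- fp + length(pk)
  }
  expect_lte(fp / 5, 2)   # about one spurious segment per 200 Kb
})
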
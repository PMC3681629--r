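test_that("peak counting sums coverage and is additive", {
  cov <- list(s1 = list(c1 = rep(3L, 100)), s2 = list(c1 = rep(0L, 100)))
  pk <- GenomicRanges::GRanges("c1", IRanges::IRanges(
    start = c(11, 21, 11), end = c(20, 40, 40)))
  S4Vectors::mcols(pk)$peak_id <- c("a", "b", "ab")
  m <- count_in_peaks(pk, cov)
  expect_equal(m["a", "s1"], 30L)
  expect_equal(m["ab", "s1"], m["a", "s1"] + m["b", "s1"])
  expect_true(all(m[, "s2"] == 0L))
  out <- GenomicRanges::GRanges("c1", IRanges::IRanges(90, 150))
  S4Vectors::mcols(out)$peak_id <- "x"
  expect_error(count_in_peaks(out, cov), "outside")
})

test_that("size factors follow the median-of-ratios definition", {
  m <- matrix(rep(c(10L, 20L, 40L), each = 4), nrow = 4)
  expect_equal(size_factors(m) / size_factors(m)[1], c(1, 2, 4))
  ident <- matrix(5L, 6, 3)
  expect_equal(size_factors(ident), rep(1, 3))
  one_row <- matrix(c(2L, 8L), 1)
  expect_equal(size_factors(one_row), c(0.5, 2))
  set.seed(4)
  base <- matrix(rnbinom(300, size = 10, mu = 100), 100, 3)
  doubled <- cbind(base, 2L * base[, 3])
  sf <- size_factors(doubled)
  expect_equal(sf[4] / sf[3], 2, tolerance = 1e-9)
  sparse <- matrix(c(0L, 5L, 3L, 0L), 2)
  expect_warning(sf2 <- size_factors(sparse), "total-count")
  expect_true(all(sf2 > 0))
})

test_that("size factors agree with DESeq2's estimator", {
  skip_if_not_installed("DESeq2")
  set.seed(14)
  m <- matrix(rnbinom(19 * 200, size = 8, mu = 150), 200, 19)
  m <- round(sweep(m, 2, exp(runif(19, -0.5, 0.5)), "*"))
  # conventions differ only in how an even-count median interpolates
  # (median of ratios vs exp of median log ratio)
  expect_equal(size_factors(m),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-4)
})

test_that("BH adjustment reproduces hand-computed values", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.1, NA)), "NA")
  set.seed(2)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
})

test_that("identical counts in every sample give p near 1", {
  strain <- study_design()
  cnt <- matrix(200L, 3, 19,
                dimnames = list(paste0("p", 1:3), NULL))
  r <- test_strain_variability(cnt, strain)
  expect_true(all(r$pvalue > 0.99))
  expect_false(any(r$variable_fdr10))
})

test_that("all-zero peaks are flagged untestable with p = 1", {
  strain <- study_design()
  set.seed(31)
  cnt <- rbind(null_counts(5), zero = rep(0L, 19))
  r <- test_strain_variability(cnt, strain)
  expect_true(r$untestable[6])
  expect_equal(r$pvalue[6], 1)
  expect_false(r$variable_fdr10[6])
})

test_that("planted discrete losses are detected with high power", {
  strain <- study_design()
  set.seed(32)
  n <- 300
  cnt <- null_counts(n, mu_range = c(100, 2000))
  lost <- seq_len(60)
  for (i in lost) {
    absent <- sample(dhs_strains(), sample(1:3, 1))
    cols <- strain %in% absent
    cnt[i, cols] <- rnbinom(sum(cols), size = 20,
                            mu = rowMeans(cnt)[i] / 8)
  }
  r <- test_strain_variability(cnt, strain)
  expect_gt(mean(r$variable_fdr01[lost]), 0.9)
  expect_lt(mean(r$variable_fdr10[-lost]), 0.05)
})

test_that("the design precondition is enforced", {
  cnt <- matrix(10L, 4, 2)
  expect_error(test_strain_variability(cnt, c("a", "b")), "replicates")
})

test_that("heritability matches its variance-components definition", {
  two <- heritability(c(0, 0, 2, 2), c("s1", "s1", "s2", "s2"))
  expect_equal(unname(two["h2"]), 1)
  flat <- heritability(rep(7, 8), rep(c("a", "b", "c", "d"), each = 2))
  expect_equal(unname(flat["h2"]), 0)
  # balanced two-group data built so V_b equals V_w
  d <- sqrt(6)
  y <- c(-1, 1, -1 + d, 1 + d)
  vb_vw <- heritability(y, c("a", "a", "b", "b"), log = FALSE)
  expect_equal(unname(vb_vw["v_between"]), unname(vb_vw["v_within"]))
  expect_equal(unname(vb_vw["h2"]), 1 / 3)
  expect_error(heritability(c(1, 2), c("a", "b")), "replication")
})

test_that("heritability increases with between-strain effect size", {
  strain <- study_design()
  set.seed(33)
  h <- vapply(c(0, 0.3, 0.8, 1.6), function(s) {
    mean(vapply(1:200, function(i) {
      b <- rnorm(8, 0, s)[match(strain, dhs_strains())]
      y <- b + rnorm(19, 0, 0.5)
      unname(heritability(y, strain, log = FALSE)["h2"])
    }, 0))
  }, 0)
  expect_true(all(diff(h) > 0))
})

test_that("heritability recovers generating values on the study design", {
  strain <- study_design()
  set.seed(34)
  for (ratio in c(1, 4)) {
    vw <- 0.3
    vb <- ratio * vw
    gen <- (vb / 2) / (vw + vb / 2)
    est <- vapply(1:400, function(i) {
      b <- rnorm(8, 0, sqrt(vb))[match(strain, dhs_strains())]
      unname(heritability(b + rnorm(19, 0, sqrt(vw)), strain,
                          log = FALSE)["h2"])
    }, 0)
    expect_lt(abs(mean(est) - gen), 0.05)
  }
})
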
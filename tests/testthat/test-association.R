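test_that("SDP extraction follows the A/B letter convention", {
  # variant private to A/J and LP/J
  al <- c("A", "G", "G", "G", "G", "G", "G", "A")
  sdp <- extract_sdp(al)
  expect_equal(sdp$letters, "ABBBBBBA")
  expect_equal(sdp$bits[1], 0L)
  # complement folding: swapping allele labels changes nothing
  expect_equal(extract_sdp(rev(c("G", "A", "A", "A", "A", "A", "A",
                                 "G")))$letters, "ABBBBBBA")
  expect_error(extract_sdp(rep("T", 8)), "monomorphic")
})

test_that("multi-allelic variants decompose into di-allelic SDPs", {
  al <- c("A", "C", "G", "A", "A", "C", "A", "A")
  parts <- sdp_decompose(al)
  expect_length(parts, 3L)
  expect_true("ABBAABAA" %in% vapply(parts, `[[`, "", "letters"))
  expect_length(sdp_decompose(c("A", "C", "A", "A", "A", "A", "A",
                                "A")), 1L)
})

test_that("SDP counting matches exhaustive enumeration", {
  expect_equal(count_sdps(8), 127L)
  expect_equal(count_sdps(2), 1L)
  expect_error(count_sdps(1), ">= 2")
  for (n in 2:10) {
    # fold all 2^n binary vectors and count distinct non-constant ones
    all_vec <- expand.grid(rep(list(0:1), n))
    folded <- apply(all_vec, 1, function(b) {
      if (b[1] == 1) b <- 1 - b
      paste(b, collapse = "")
    })
    n_brute <- length(setdiff(unique(folded),
                              paste(rep(0, n), collapse = "")))
    expect_equal(count_sdps(n), n_brute)
    expect_length(all_sdps(n), n_brute)
  }
})

mk_assoc_fixture <- function(n_null_variants = 30, seed = 51) {
  set.seed(seed)
  strain <- study_design()
  strains <- dhs_strains()
  pk <- GenomicRanges::GRanges("c1", IRanges::IRanges(5001, 5400))
  S4Vectors::mcols(pk)$peak_id <- "pk1"
  bits <- c(0L, 1L, 1L, 0L, 0L, 1L, 0L, 1L)
  mu <- ifelse(bits == 1, 3000, 800)[match(strain, strains)]
  cnt <- matrix(rnbinom(19, size = 20, mu = mu), 1,
                dimnames = list("pk1", NULL))
  mk_row <- function(id, pos, b) {
    al <- ifelse(b == 0, "A", "G")
    c(list(variant_id = id, contig = "c1", pos = pos, type = "SNP"),
      as.list(setNames(al, strains)))
  }
  rows <- list(mk_row("causal", 5200L, bits))
  for (k in seq_len(n_null_variants)) {
    b <- rbinom(8, 1, 0.5)
    while (length(unique(b)) < 2) b <- rbinom(8, 1, 0.5)
    rows[[k + 1]] <- mk_row(sprintf("null%02d", k),
                            5000L + 10L * k, b)
  }
  vars <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, check.names = FALSE)))
  list(pk = pk, cnt = cnt, strain = strain, vars = vars)
}

test_that("a planted causal variant is recovered at FDR 5%", {
  fx <- mk_assoc_fixture()
  res <- associate_peak_variants(fx$pk, fx$cnt, fx$strain, fx$vars,
                                 sf = rep(1, 19), window_bp = 100)
  expect_true(res$significant[res$variant_id == "causal"])
  expect_equal(res$distance[res$variant_id == "causal"], 0L)
})

test_that("variants with identical SDPs get identical p-values", {
  fx <- mk_assoc_fixture(n_null_variants = 2)
  twin <- fx$vars[fx$vars$variant_id == "causal", ]
  twin$variant_id <- "twin"
  twin$pos <- 5100L
  res <- associate_peak_variants(fx$pk, fx$cnt, fx$strain,
                                 rbind(fx$vars, twin),
                                 sf = rep(1, 19))
  expect_equal(res$pvalue[res$variant_id == "causal"],
               res$pvalue[res$variant_id == "twin"])
})

test_that("null heights give about 5% significant tests", {
  set.seed(55)
  strain <- study_design()
  strains <- dhs_strains()
  n_pk <- 60
  pk <- GenomicRanges::GRanges("c1", IRanges::IRanges(
    start = seq(1000, by = 2000, length.out = n_pk), width = 300))
  S4Vectors::mcols(pk)$peak_id <- sprintf("pk%03d", seq_len(n_pk))
  cnt <- matrix(rnbinom(19 * n_pk, size = 20, mu = 1000), n_pk,
                dimnames = list(S4Vectors::mcols(pk)$peak_id, NULL))
  rows <- lapply(seq_len(n_pk), function(i) {
    b <- rbinom(8, 1, 0.5)
    while (length(unique(b)) < 2) b <- rbinom(8, 1, 0.5)
    c(list(variant_id = sprintf("v%03d", i), contig = "c1",
           pos = GenomicRanges::start(pk)[i] + 50L, type = "SNP"),
      as.list(setNames(ifelse(b == 0, "A", "G"), strains)))
  })
  vars <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, check.names = FALSE)))
  res <- associate_peak_variants(pk, cnt, strain, vars, sf = rep(1, 19))
  # uncorrected positives near alpha; BH keeps the FDR-significant
  # fraction at or below that
  expect_lt(mean(res$pvalue < 0.05), 0.15)
  expect_lte(mean(res$significant), mean(res$pvalue < 0.05))
})

test_that("the distance scan is monotone and starts at zero", {
  fx <- mk_assoc_fixture()
  no_inside <- fx$vars[fx$vars$pos > 5400 + 50, , drop = FALSE]
  d0 <- distance_scan(fx$pk, fx$cnt, fx$strain, no_inside,
                      sf = rep(1, 19), grid = c(0))
  expect_equal(d0$frac_associated, 0)
  ds <- distance_scan(fx$pk, fx$cnt, fx$strain, fx$vars,
                      sf = rep(1, 19),
                      grid = c(0, 50, 200, 1000, 100000))
  expect_true(all(diff(ds$frac_associated) >= 0))
  expect_error(distance_scan(fx$pk, fx$cnt, fx$strain, fx$vars,
                             grid = numeric(0)), "empty")
})

test_that("structural variants overlapping peaks are reported", {
  fx <- mk_assoc_fixture(n_null_variants = 1)
  fx$vars$type[fx$vars$variant_id == "causal"] <- "SV"
  ov <- sv_overlaps(fx$pk, fx$vars)
  expect_equal(ov$variant_id, "causal")
})
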
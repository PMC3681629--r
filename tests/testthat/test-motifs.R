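# brute-force tail probability: enumerate all 4^w words with the same
# discretized scores the scanner uses
motif_tail_brute <- function(pw, s) {
  w <- ncol(pw$iscore)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  sc <- vapply(seq_len(nrow(words)), function(i)
    sum(pw$iscore[cbind(words[i, ], seq_len(w))]), 0L)
  pr <- apply(words, 1, function(b) prod(pw$background[b]))
  sum(pr[sc >= s])
}

test_that("a width-1 A motif has tail probability exactly 1/4", {
  pw <- pwm(matrix(c(96, 1, 1, 1), 4), pseudocount = 0.1)
  mx <- max(pw$iscore)
  expect_equal(dhsvar:::pwm_tail_p(pw, mx), 0.25)
  # every base scoring below the max contributes the remaining 3/4
  expect_equal(dhsvar:::pwm_tail_p(pw, min(pw$iscore)), 1)
})

test_that("DP tail probabilities equal brute-force enumeration", {
  set.seed(61)
  for (w in c(2, 4, 6)) {
    counts <- matrix(rpois(4 * w, 5) + 1, 4, w)
    bg <- c(0.3, 0.2, 0.2, 0.3)
    pw <- pwm(counts, background = bg, motif_id = paste0("m", w))
    probes <- quantile(as.numeric(pw$iscore) * w, c(0.1, 0.5, 0.9))
    for (s in unique(round(probes))) {
      expect_equal(dhsvar:::pwm_tail_p(pw, as.integer(s)),
                   motif_tail_brute(pw, as.integer(s)),
                   tolerance = 1e-12)
    }
  }
})

strong_pwm <- function(seq_consensus, motif_id = "cons") {
  idx <- match(strsplit(seq_consensus, "")[[1]], c("A", "C", "G", "T"))
  counts <- matrix(1, 4, length(idx))
  counts[cbind(idx, seq_along(idx))] <- 400
  pwm(counts, motif_id = motif_id)
}

test_that("motif scanning finds planted sites on both strands", {
  pw <- strong_pwm("ACGTACGTAC")
  seq <- paste0("TTTTTTTT", "ACGTACGTAC", "TTTTTTTTTT")
  hits <- scan_motifs(seq, pw)
  expect_true(any(hits$start == 8 & hits$strand == "+"))
  # reverse-complementing the sequence flips strands, keeps positions
  rc <- dhsvar:::revcomp(seq)
  hits_rc <- scan_motifs(rc, pw)
  expect_equal(nrow(hits_rc), nrow(hits))
  expect_true(any(hits_rc$strand == "-"))
  expect_equal(sort(nchar(seq) - (hits$start + hits$width)),
               sort(hits_rc$start))
})

test_that("ambiguous bases score as background expectation", {
  pw <- strong_pwm("ACGTACGTAC")
  seqN <- paste0("TTTTTTTT", "ACGTNCGTAC", "TTTTTTTTTT")
  hits <- scan_motifs(seqN, pw, pthresh = 1e-5)
  # one mismatching N weakens but need not abolish a strong site
  expect_true(all(is.finite(hits$pvalue)))
})

test_that("variant effects on motifs are classified", {
  pw <- strong_pwm("ACGTACGTAC")
  ref <- paste0("TTTTTTTT", "ACGTACGTAC", "TTTTTTTTTT")
  alt <- paste0("TTTTTTTT", "ACGTTCGTAC", "TTTTTTTTTT")  # A12T
  expect_equal(classify_motif_effect(ref, alt, var_pos = 12, pwms = list(pw)),
               "disrupted")
  expect_equal(classify_motif_effect(alt, ref, var_pos = 12, pwms = list(pw)),
               "created")
  far_ref <- paste0(ref, "AAAA")
  far_alt <- paste0(ref, "AAAC")
  expect_equal(classify_motif_effect(far_ref, far_alt, var_pos = 31,
                                     pwms = list(pw)), "none")
  # an insertion completing a motif absent from the reference allele
  ins_ref <- paste0("TTTTTTTT", "ACGTCGTAC", "TTTTTTTTTT")
  ins_alt <- paste0("TTTTTTTT", "ACGTACGTAC", "TTTTTTTTTT")
  expect_equal(classify_motif_effect(ins_ref, ins_alt, var_pos = 11,
                                     ref_len = 1, alt_len = 2,
                                     pwms = list(pw)), "created")
  expect_error(classify_motif_effect(ref, ref, 12, pwms = list(pw)),
               "identical")
})

test_that("PWM text files round-trip", {
  path <- file.path(tempdir(), "motifs.txt")
  writeLines(c("BACKGROUND 0.3 0.2 0.2 0.3",
               "MOTIF tf1",
               "10 1 1 1", "1 10 1 1", "1 1 10 1",
               "MOTIF tf2",
               "5 5 1 1", "1 1 5 5"), path)
  pws <- read_pwm_file(path)
  expect_length(pws, 2L)
  expect_equal(pws[[1]]$motif_id, "tf1")
  expect_equal(ncol(pws[[1]]$logodds), 3L)
  expect_equal(pws[[1]]$background, c(0.3, 0.2, 0.2, 0.3))
  writeLines(c("MOTIF bad", "1 2 3"), path)
  expect_error(read_pwm_file(path), "malformed")
  expect_error(pwm(matrix(1, 3, 2)), "4 x width")
})
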
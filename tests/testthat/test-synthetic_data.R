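test_that("invalid configurations are rejected", {
  expect_error(simulation_config(frac_variable = 1.2), "fractions")
  expect_error(simulation_config(replicates_per_strain = c(2L, 2L)),
               "n_strains")
  expect_error(simulation_config(genome_length = 1000, n_peaks = 50),
               "too small")
  expect_error(simulation_config(peak_enrichment = 0.5), "invalid")
})

test_that("simulation is deterministic given the seed", {
  cfg <- tiny_config(rng_seed = 77L)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(serialize(d1, NULL), serialize(d2, NULL))
  d3 <- simulate_dataset(tiny_config(rng_seed = 78L))
  expect_false(identical(d1$coverage[[1]][[1]], d3$coverage[[1]][[1]]))
})

test_that("null configuration plants no variable peaks", {
  ds <- simulate_dataset(tiny_config(frac_variable = 0, rng_seed = 3L))
  expect_true(all(S4Vectors::mcols(ds$truth$peaks)$class == "constant"))
  expect_true(all(ds$truth$multipliers == 1))
})

test_that("every simulated SDP is one of the 127 canonical patterns", {
  ds <- simulate_dataset(tiny_config(rng_seed = 5L))
  canon <- vapply(all_sdps(8), dhsvar:::sdp_letters, "")
  expect_length(canon, 127L)
  strains <- dhs_strains()
  letters <- vapply(seq_len(nrow(ds$variants)), function(i)
    extract_sdp(as.character(unlist(ds$variants[i, strains])))$letters,
    "")
  expect_true(all(letters %in% canon))
})

test_that("background counts match the NB model's moments", {
  cfg <- tiny_config(rng_seed = 8L)
  ds <- simulate_dataset(cfg)
  # a peak- and mask-free background window
  occupied <- c(ds$truth$peaks, ds$mask)
  x <- ds$coverage[[1]][[1]]
  free <- rep(TRUE, length(x))
  for (i in seq_along(occupied)) {
    free[GenomicRanges::start(occupied)[i]:
           GenomicRanges::end(occupied)[i]] <- FALSE
  }
  xb <- x[free]
  expect_gt(length(xb), 1e5)
  mu <- cfg$background_rate
  v <- mu + cfg$nb_dispersion * mu^2
  expect_equal(mean(xb), mu, tolerance = 0.02)
  expect_equal(var(xb), v, tolerance = 0.05)
})

test_that("discrete-loss strains revert to pure background", {
  cfg <- tiny_config(frac_discrete = 1, frac_compound = 0, rng_seed = 9L)
  ds <- simulate_dataset(cfg)
  tr <- ds$truth$peaks
  var_ix <- which(S4Vectors::mcols(tr)$class != "constant")
  expect_true(all(apply(
    ds$truth$multipliers[var_ix, , drop = FALSE], 1,
    function(m) any(m == 0))))
  # expected coverage inside a lost peak equals background
  i <- var_ix[1]
  absent <- names(which(ds$truth$multipliers[i, ] == 0))[1]
  samp <- ds$design$sample_id[ds$design$strain == absent]
  idx <- GenomicRanges::start(tr)[i]:GenomicRanges::end(tr)[i]
  obs <- mean(vapply(samp, function(s)
    mean(ds$coverage[[s]][[as.character(
      GenomicRanges::seqnames(tr))[i]]][idx]), 0))
  expect_lt(obs, 3 * cfg$background_rate)
})

test_that("planted causal variants carry their peak's SDP", {
  ds <- simulate_dataset(tiny_config(rng_seed = 12L))
  tr <- ds$truth$peaks
  strains <- dhs_strains()
  causal_pk <- which(S4Vectors::mcols(tr)$causal &
                       !is.na(S4Vectors::mcols(tr)$sdp))
  expect_gt(length(causal_pk), 5L)
  cv <- ds$variants[ds$variants$causal, ]
  gr_cv <- GenomicRanges::GRanges(cv$contig,
                                  IRanges::IRanges(cv$pos + 1L, width = 1L))
  for (i in causal_pk) {
    hits <- GenomicRanges::findOverlaps(gr_cv, tr[i] + 100L)
    expect_gte(length(hits), 1L)
    k <- S4Vectors::queryHits(hits)[1]
    v_sdp <- extract_sdp(as.character(unlist(cv[k, strains])))$letters
    expect_equal(v_sdp, S4Vectors::mcols(tr)$sdp[i])
    # SDP equals the two-level pattern of the strain multipliers
    m <- ds$truth$multipliers[i, ]
    bits <- dhsvar:::canonical_bits(as.integer(m != m[1]))
    expect_equal(dhsvar:::sdp_letters(bits),
                 S4Vectors::mcols(tr)$sdp[i])
  }
})

test_that("fixtures round-trip through disk exactly", {
  ds <- simulate_dataset(tiny_config(rng_seed = 21L))
  dir <- file.path(tempdir(), "fx1")
  man <- write_fixture(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_fixture(dir, with_truth = TRUE)
  expect_identical(back$coverage, ds$coverage)
  expect_equal(back$design, ds$design)
  expect_identical(back$contigs, ds$contigs)
  expect_equal(back$tx_counts, ds$tx_counts)
  expect_equal(back$variants[, c("contig", "pos", "type")],
               ds$variants[, c("contig", "pos", "type")])
  expect_equal(S4Vectors::mcols(back$transcripts)$tss,
               S4Vectors::mcols(ds$transcripts)$tss)
  expect_equal(GenomicRanges::start(back$mask),
               GenomicRanges::start(ds$mask))
  expect_equal(S4Vectors::mcols(back$truth$peaks)$class,
               S4Vectors::mcols(ds$truth$peaks)$class)

  # manifest checksums change iff content changes
  f <- file.path(dir, "design.tsv")
  old <- man$files[["design.tsv"]]
  man2 <- write_fixture(ds, dir)
  expect_equal(man2$files[["design.tsv"]], old)
  writeLines(c(readLines(f), "# touched"), f)
  sums <- tools::md5sum(f)
  expect_false(unname(sums) == old)
})

test_that("an empty dataset writes valid empty files", {
  cfg <- tiny_config(n_peaks = 0L, n_decoy_variants = 5L,
                     n_transcripts = 3L, frac_linked = 0,
                     rng_seed = 2L)
  ds <- simulate_dataset(cfg)
  expect_length(ds$truth$peaks, 0L)
  dir <- file.path(tempdir(), "fx0")
  expect_silent(write_fixture(ds, dir))
  back <- read_fixture(dir, with_truth = TRUE)
  expect_length(back$truth$peaks, 0L)
})
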
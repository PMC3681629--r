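# Haplotype association of variable peaks with sequence variants via
# strain distribution patterns.

# distance from a 0-based variant position to a peak (0 inside)
variant_peak_distance <- function(pos0, peak_start1, peak_end1) {
  pmax(0L, peak_start1 - 1L - pos0, pos0 - (peak_end1 - 1L))
}

# two-group slope test of y on a binary design; pooled-variance t
sdp_group_test <- function(y, g) {
  n1 <- sum(g == 1L); n0 <- sum(g == 0L)
  if (n1 == 0L || n0 == 0L) return(c(est = NA_real_, t = NA_real_,
                                     p = NA_real_))
  m1 <- mean(y[g == 1L]); m0 <- mean(y[g == 0L])
  ss <- sum((y[g == 1L] - m1)^2) + sum((y[g == 0L] - m0)^2)
  df <- n1 + n0 - 2L
  se <- sqrt(ss / df * (1 / n1 + 1 / n0))
  tt <- if (se > 0) (m1 - m0) / se else sign(m1 - m0) * Inf
  c(est = m1 - m0, t = tt, p = 2 * pt(abs(tt), df, lower.tail = FALSE))
}

#' Associate variable peaks with nearby variants through their SDPs
#'
#' For every variable peak and every variant within `window_bp` of the
#' peak edges, regresses sample-level `log2(normalized count + 0.5)`
#' peak heights on the variant's strain-distribution-pattern indicator
#' (a two-group linear model over the 19 samples; strain-mean response
#' available via `response = "strain_mean"`), with a two-sided t-test
#' on the group difference.  P-values are pooled across all
#' peak-by-variant tests in the run and adjusted by Benjamini-
#' Hochberg; `significant` flags tests at `fdr`.
#'
#' @param peaks `GRanges` of variable peaks with `peak_id`.
#' @param counts Peak-by-sample count matrix covering at least these
#'   peaks (rownames = peak ids).
#' @param strain Strain of each sample column.
#' @param variants Variant data.frame (columns `variant_id`, `contig`,
#'   `pos` 0-based, `type`, one allele column per strain).
#' @param sf Size factors (computed when `NULL`).
#' @param window_bp Search window beyond the peak edges (default 100).
#' @param fdr FDR level for the `significant` flag (default 0.05).
#' @param response `"sample"` (default) or `"strain_mean"`.
#' @return data.frame of per-test results: `peak_id`, `variant_id`,
#'   `sdp`, `distance`, `estimate`, `t`, `pvalue`, `padj`,
#'   `significant`.  Variants whose SDP leaves a sample group empty are
#'   skipped with a warning.
#' @export
associate_peak_variants <- function(peaks, counts, strain, variants,
                                    sf = NULL, window_bp = 100,
                                    fdr = 0.05,
                                    response = c("sample", "strain_mean")) {
  response <- match.arg(response)
  counts <- as.matrix(counts)
  strain <- as.character(strain)
  if (is.null(sf)) sf <- size_factors(counts)
  y_all <- log2(sweep(counts, 2, sf, "/") + 0.5)
  strains <- unique(strain)
  allele_cols <- intersect(strains, colnames(variants))
  if (length(allele_cols) != length(strains)) {
    stop("variants lack one allele column per strain")
  }

  res <- list()
  skipped <- 0L
  ctg <- as.character(seqnames(peaks))
  for (i in seq_along(peaks)) {
    pid <- mcols(peaks)$peak_id[i]
    if (!pid %in% rownames(y_all)) next
    vv <- variants[variants$contig == ctg[i], , drop = FALSE]
    if (!nrow(vv)) next
    d <- variant_peak_distance(vv$pos, start(peaks)[i], end(peaks)[i])
    vv <- vv[d <= window_bp, , drop = FALSE]
    d <- d[d <= window_bp]
    if (!nrow(vv)) next
    y <- y_all[pid, ]
    if (response == "strain_mean") {
      y <- vapply(strains, function(s) mean(y[strain == s]), 0)
    }
    for (k in seq_len(nrow(vv))) {
      alleles <- as.character(unlist(vv[k, allele_cols]))
      sdps <- tryCatch(sdp_decompose(alleles), error = function(e) NULL)
      if (is.null(sdps)) next
      for (sd in sdps) {
        g_strain <- sd$bits
        g <- if (response == "strain_mean") g_strain else
          g_strain[match(strain, strains)]
        tst <- sdp_group_test(y, g)
        if (is.na(tst["p"])) { skipped <- skipped + 1L; next }
        res[[length(res) + 1L]] <- data.frame(
          peak_id = pid, variant_id = vv$variant_id[k],
          sdp = sd$letters, distance = d[k],
          estimate = tst[["est"]], t = tst[["t"]], pvalue = tst[["p"]],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (skipped > 0L) {
    warning(skipped, " SDP(s) with an empty sample group skipped")
  }
  if (!length(res)) {
    return(data.frame(peak_id = character(), variant_id = character(),
                      sdp = character(), distance = integer(),
                      estimate = numeric(), t = numeric(),
                      pvalue = numeric(), padj = numeric(),
                      significant = logical()))
  }
  out <- do.call(rbind, res)
  out$padj <- bh_fdr(out$pvalue)
  out$significant <- out$padj <= fdr
  rownames(out) <- NULL
  out
}

#' Fraction of peaks with an associated variant, by search distance
#'
#' Runs the SDP association once with the largest window of `grid`
#' (one genome-wide FDR set), then reports, for each window size, the
#' fraction of variable peaks having at least one FDR-significant
#' variant within that distance of the peak edge.  Because the
#' significant set is fixed, the curve is non-decreasing in window
#' size: with dense variants it keeps rising even when the causal
#' fraction is fixed, the chance-association behaviour expected of
#' haplotype mapping at long range.
#'
#' @inheritParams associate_peak_variants
#' @param grid Increasing vector of window sizes in bp (default up to
#'   100 Kb).
#' @return data.frame with `window_bp` and `frac_associated`.
#' @export
distance_scan <- function(peaks, counts, strain, variants, sf = NULL,
                          grid = c(0, 100, 1000, 5000, 10000, 25000,
                                   50000, 100000),
                          fdr = 0.05) {
  if (!length(grid)) stop("empty window grid")
  grid <- sort(grid)
  assoc <- associate_peak_variants(peaks, counts, strain, variants,
                                   sf = sf, window_bp = max(grid),
                                   fdr = fdr)
  sig <- assoc[assoc$significant, , drop = FALSE]
  n <- length(peaks)
  frac <- vapply(grid, function(w) {
    if (!nrow(sig)) return(0)
    length(unique(sig$peak_id[sig$distance <= w])) / n
  }, 0)
  data.frame(window_bp = grid, frac_associated = frac)
}

#' Structural variants overlapping peaks
#'
#' Direct interval intersection of SV-type variants with a peak set,
#' reported separately from SDP testing.
#'
#' @param peaks `GRanges` with `peak_id`.
#' @param variants Variant data.frame (`type == "SV"` rows are used).
#' @return data.frame of `peak_id`, `variant_id` pairs.
#' @export
sv_overlaps <- function(peaks, variants) {
  sv <- variants[variants$type == "SV", , drop = FALSE]
  if (!nrow(sv)) {
    return(data.frame(peak_id = character(), variant_id = character()))
  }
  gr <- GRanges(sv$contig, IRanges(sv$pos + 1L, width = 1L))
  hits <- findOverlaps(gr, peaks)
  data.frame(peak_id = mcols(peaks)$peak_id[subjectHits(hits)],
             variant_id = sv$variant_id[queryHits(hits)],
             stringsAsFactors = FALSE)
}
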
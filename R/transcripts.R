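# Linking variable peaks to strain-variable transcripts: distance,
# proximity contingency and height/abundance correlation.

#' Flag transcripts that vary between strains
#'
#' Applies the same negative-binomial strain-variability test used for
#' peaks to transcript counts, with a Benjamini-Hochberg flag at `fdr`.
#'
#' @param tx_counts Transcript-by-sample count matrix.
#' @param strain Strain of each sample column.
#' @param sf Size factors (computed from the transcript counts when
#'   `NULL`).
#' @param fdr FDR level for the `variable` flag (default 0.05).
#' @return data.frame from [test_strain_variability()] plus a
#'   `variable` column.
#' @export
variable_transcripts <- function(tx_counts, strain, sf = NULL,
                                 fdr = 0.05) {
  res <- test_strain_variability(tx_counts, strain, sf = sf,
                                 fdr_levels = fdr)
  res$variable <- res[[sprintf("variable_fdr%02d", round(100 * fdr))]]
  names(res)[1] <- "tx_id"
  res
}

#' Signed distance from each peak to the nearest transcript start
#'
#' Distance is 0 when a start lies inside the peak, otherwise the
#' signed offset from the peak midpoint to the nearest start (positive
#' when the start has the larger coordinate).  Contigs without
#' transcripts yield `Inf`.
#'
#' @param peaks `GRanges` of peaks.
#' @param tss Integer vector of 0-based transcript start positions.
#' @param tss_contig Contig of each transcript start.
#' @return Numeric vector of signed distances (bp), one per peak.
#' @export
nearest_distance <- function(peaks, tss, tss_contig) {
  ctg <- as.character(seqnames(peaks))
  mid <- floor((start(peaks) - 1L + end(peaks)) / 2)   # 0-based midpoint
  out <- rep(Inf, length(peaks))
  for (nm in unique(ctg)) {
    t0 <- tss[tss_contig == nm]
    if (!length(t0)) next
    ix <- which(ctg == nm)
    for (i in ix) {
      inside <- t0 >= start(peaks)[i] - 1L & t0 <= end(peaks)[i] - 1L
      if (any(inside)) { out[i] <- 0; next }
      d <- t0 - mid[i]
      out[i] <- d[which.min(abs(d))]
    }
  }
  out
}

#' Proximity of variable vs non-variable peaks to variable transcripts
#'
#' Builds the 2x2 table of peaks within / beyond `window_bp` of any
#' variable transcript start, for the variable and the comparison peak
#' set, and tests it with [fisher_exact()].  A peak counts as "within"
#' when a start lies inside it or within `window_bp` of its midpoint.
#'
#' @param var_peaks,nonvar_peaks `GRanges` of the two peak sets.
#' @param tss,tss_contig Variable transcript starts (0-based) and their
#'   contigs.
#' @param window_bp Proximity window (default 10 Kb).
#' @return List with `table` (2x2), `odds_ratio`, `pvalue`.
#' @export
proximity_table <- function(var_peaks, nonvar_peaks, tss, tss_contig,
                            window_bp = 10000) {
  if (length(var_peaks) == 0L || length(nonvar_peaks) == 0L ||
      length(tss) == 0L) {
    stop("empty peak or transcript set")
  }
  near <- function(pk) {
    d <- nearest_distance(pk, tss, tss_contig)
    sum(abs(d) <= window_bp)
  }
  a <- near(var_peaks); b <- length(var_peaks) - a
  c_ <- near(nonvar_peaks); d_ <- length(nonvar_peaks) - c_
  tab <- matrix(c(a, b, c_, d_), 2, byrow = TRUE,
                dimnames = list(c("variable", "non_variable"),
                                c("within", "beyond")))
  ft <- fisher_exact(tab)
  list(table = tab, odds_ratio = ft$odds_ratio, pvalue = ft$pvalue)
}

#' Correlation between peak height and transcript abundance
#'
#' Correlates strain-mean `log2(normalized value + 0.5)` peak heights
#' with strain-mean transcript abundances (eight points by default;
#' sample-level mode via `level = "sample"`), two-sided test.
#'
#' @param peak_counts Counts for one peak (one per sample).
#' @param tx_counts Counts for one transcript (one per sample).
#' @param strain Strain of each sample.
#' @param sf_peak,sf_tx Size factors for the two assays.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param level `"strain"` (default, strain means) or `"sample"`.
#' @return List with `r`, `pvalue`, `n`, and `defined` (`FALSE` when a
#'   vector has zero variance).
#' @export
peak_transcript_correlation <- function(peak_counts, tx_counts, strain,
                                        sf_peak = NULL, sf_tx = NULL,
                                        method = c("pearson", "spearman"),
                                        level = c("strain", "sample")) {
  method <- match.arg(method)
  level <- match.arg(level)
  strain <- as.character(strain)
  if (is.null(sf_peak)) sf_peak <- rep(1, length(peak_counts))
  if (is.null(sf_tx)) sf_tx <- rep(1, length(tx_counts))
  x <- log2(peak_counts / sf_peak + 0.5)
  y <- log2(tx_counts / sf_tx + 0.5)
  if (level == "strain") {
    strains <- unique(strain)
    x <- vapply(strains, function(s) mean(x[strain == s]), 0)
    y <- vapply(strains, function(s) mean(y[strain == s]), 0)
  }
  if (var(x) == 0 || var(y) == 0) {
    return(list(r = NA_real_, pvalue = NA_real_, n = length(x),
                defined = FALSE))
  }
  ct <- suppressWarnings(cor.test(x, y, method = method))
  list(r = unname(ct$estimate), pvalue = ct$p.value, n = length(x),
       defined = TRUE)
}

#' Link variable peaks to nearby variable transcripts
#'
#' For every (variable peak, variable transcript) pair whose start lies
#' within `window_bp` of the peak (inside counts as distance 0), tests
#' the peak-height/transcript-abundance correlation and flags pairs
#' with `pvalue < alpha` (uncorrected, as in exploratory eQTL-style
#' screens; the expected false-discovery count is `alpha` times the
#' number of unlinked pairs tested).
#'
#' @param peaks `GRanges` of variable peaks with `peak_id`.
#' @param peak_counts Peak-by-sample counts (rownames = peak ids).
#' @param transcripts `GRanges` with `tx_id` and `tss` metadata.
#' @param tx_counts Transcript-by-sample counts (rownames = tx ids).
#' @param strain Strain of each sample column.
#' @param sf_peak,sf_tx Size factors (computed when `NULL`).
#' @param window_bp Pairing window (default 10 Kb).
#' @param alpha Per-pair significance level (default 0.05).
#' @inheritParams peak_transcript_correlation
#' @return data.frame of pairs: `peak_id`, `tx_id`, `distance`, `r`,
#'   `pvalue`, `linked`.
#' @export
link_transcripts <- function(peaks, peak_counts, transcripts, tx_counts,
                             strain, sf_peak = NULL, sf_tx = NULL,
                             window_bp = 10000, alpha = 0.05,
                             method = "pearson", level = "strain") {
  if (is.null(sf_peak)) sf_peak <- size_factors(peak_counts)
  if (is.null(sf_tx)) sf_tx <- size_factors(tx_counts)
  tss <- mcols(transcripts)$tss
  txc <- as.character(seqnames(transcripts))
  ctg <- as.character(seqnames(peaks))
  mid <- floor((start(peaks) - 1L + end(peaks)) / 2)
  out <- list()
  for (i in seq_along(peaks)) {
    pid <- mcols(peaks)$peak_id[i]
    if (!pid %in% rownames(peak_counts)) next
    cand <- which(txc == ctg[i])
    if (!length(cand)) next
    inside <- tss[cand] >= start(peaks)[i] - 1L &
      tss[cand] <= end(peaks)[i] - 1L
    d <- ifelse(inside, 0, abs(tss[cand] - mid[i]))
    cand <- cand[d <= window_bp]
    d <- d[d <= window_bp]
    for (k in seq_along(cand)) {
      tid <- mcols(transcripts)$tx_id[cand[k]]
      ct <- peak_transcript_correlation(
        peak_counts[pid, ], tx_counts[tid, ], strain,
        sf_peak = sf_peak, sf_tx = sf_tx, method = method,
        level = level)
      out[[length(out) + 1L]] <- data.frame(
        peak_id = pid, tx_id = tid, distance = d[k], r = ct$r,
        pvalue = ct$pvalue,
        linked = isTRUE(ct$defined && ct$pvalue < alpha),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(peak_id = character(), tx_id = character(),
                      distance = numeric(), r = numeric(),
                      pvalue = numeric(), linked = logical()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
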
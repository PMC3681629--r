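# Classify variable peaks into continuous, discrete-simple and
# discrete-compound modes via an explicit presence/absence rule and
# single-linkage clustering of co-varying discrete peaks.

#' Per-strain presence/absence calls for peaks
#'
#' A strain is called absent at a peak when its mean normalized count
#' is both at most `absence_ratio` times the largest strain mean
#' (relative criterion) and at most the supplied background threshold
#' (absolute criterion); otherwise it is present.  When even the
#' largest strain mean does not exceed the background threshold the
#' peak is degenerate and every strain is called absent.  The rule
#' replaces subjective visual inspection with a deterministic call.
#'
#' @param counts Integer matrix, peaks by samples.
#' @param strain Strain of each sample column.
#' @param sf Size factors (computed when `NULL`).
#' @param background Background thresholds on the normalized-count
#'   scale: either one value per peak or a single value recycled.  See
#'   [background_quantiles()].
#' @param absence_ratio Relative threshold (default 0.1).
#' @return Logical matrix, peaks by strains (`TRUE` = present).
#' @export
strain_presence <- function(counts, strain, sf = NULL, background,
                            absence_ratio = 0.1) {
  counts <- as.matrix(counts)
  strain <- as.character(strain)
  if (is.null(sf)) sf <- size_factors(counts)
  q <- sweep(counts, 2, sf, "/")
  strains <- unique(strain)
  sm <- vapply(strains, function(s)
    rowMeans(q[, strain == s, drop = FALSE]), numeric(nrow(q)))
  sm <- matrix(sm, nrow = nrow(q),
               dimnames = list(rownames(counts), strains))
  bg <- rep_len(background, nrow(sm))
  mx <- apply(sm, 1, max)
  absent <- ((sm <= absence_ratio * mx) | mx <= bg) & (sm <= bg)
  !absent
}

#' Background count thresholds for width-matched random intervals
#'
#' Samples `n_draws` random intervals from regions not overlapping any
#' peak, computes per-strain mean normalized coverage in them (the
#' same statistic the absence rule thresholds, so replicate-number
#' noise is represented), and returns the requested quantile of that
#' background distribution scaled to each peak's width.
#'
#' @param coverage Per-sample list of per-contig coverage vectors.
#' @param peaks `GRanges` of peaks (defines widths and excluded
#'   regions).
#' @param sf Size factors.
#' @param strain Strain of each sample; when supplied, the background
#'   distribution is over per-strain means rather than the grand mean.
#' @param prob Quantile of the background distribution (default 0.95).
#' @param n_draws Random background intervals to sample.
#' @return Numeric vector, one threshold per peak, on the normalized
#'   per-peak count scale.
#' @export
background_quantiles <- function(coverage, peaks, sf, strain = NULL,
                                 prob = 0.95, n_draws = 200L) {
  ref_w <- 100L
  contigs <- names(coverage[[1]])
  lens <- vapply(coverage[[1]], length, 0L)
  per_base <- numeric(0)
  tries <- 0L
  while (length(per_base) < n_draws && tries < 20L * n_draws) {
    tries <- tries + 1L
    ci <- sample(seq_along(contigs), 1L)
    s <- sample.int(lens[ci] - ref_w, 1L)
    cand <- GRanges(contigs[ci], IRanges(s, width = ref_w))
    if (length(peaks) && length(findOverlaps(cand, peaks))) next
    cnt <- vapply(seq_along(coverage), function(j)
      sum(coverage[[j]][[contigs[ci]]][s:(s + ref_w - 1L)]) / sf[j], 0)
    if (is.null(strain)) {
      per_base <- c(per_base, mean(cnt) / ref_w)
    } else {
      sm <- tapply(cnt, strain, mean) / ref_w
      per_base <- c(per_base, as.numeric(sm))
    }
  }
  qb <- quantile(per_base, prob, names = FALSE)
  qb * GenomicRanges::width(peaks)
}

#' Classify variable peaks by mode of variation
#'
#' Peaks with a mixed presence/absence pattern are discrete; discrete
#' peaks whose nearest discrete neighbour with an identical presence
#' pattern lies within `cluster_bp` form compound clusters by
#' single-linkage chaining; all remaining variable peaks are
#' continuous.  Peaks absent in every strain are flagged degenerate and
#' given class `NA`.
#'
#' @param peaks `GRanges` of the variable peaks (with `peak_id`).
#' @param presence Logical matrix from [strain_presence()], rows
#'   matching `peaks`.
#' @param cluster_bp Maximum edge-to-edge distance joining two discrete
#'   peaks into one cluster (default 10 Kb).
#' @return data.frame with `peak_id`, `class`, `presence` (P/A string),
#'   `cluster` (id or `NA`), `degenerate`.
#' @export
classify_peaks <- function(peaks, presence, cluster_bp = 10000) {
  presence <- as.matrix(presence)
  stopifnot(length(peaks) == nrow(presence))
  n <- length(peaks)
  pat <- apply(presence, 1, function(p)
    paste(ifelse(p, "P", "A"), collapse = ""))
  n_abs <- rowSums(!presence)
  degenerate <- n_abs == ncol(presence)
  cls <- rep("continuous", n)
  cls[n_abs > 0 & !degenerate] <- "discrete_simple"
  cls[degenerate] <- NA_character_

  cluster <- rep(NA_integer_, n)
  next_cl <- 0L
  disc <- which(cls == "discrete_simple")
  if (length(disc) > 1L) {
    key <- paste(as.character(seqnames(peaks))[disc], pat[disc])
    for (k in unique(key)) {
      ix <- disc[key == k]
      if (length(ix) < 2L) next
      ix <- ix[order(start(peaks)[ix])]
      gap <- start(peaks)[ix][-1] - end(peaks)[ix][-length(ix)] - 1L
      brk <- cumsum(c(0L, as.integer(gap > cluster_bp)))
      for (b in unique(brk)) {
        mem <- ix[brk == b]
        if (length(mem) >= 2L) {
          next_cl <- next_cl + 1L
          cluster[mem] <- next_cl
          cls[mem] <- "discrete_compound"
        }
      }
    }
  }
  data.frame(peak_id = mcols(peaks)$peak_id, class = cls,
             presence = pat, cluster = cluster, degenerate = degenerate,
             stringsAsFactors = FALSE)
}
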
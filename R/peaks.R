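# Peak calling: local-mean coverage adjustment, coverage-independent log
# transform, and maximal high-scoring segment detection.

#' Adjust per-base coverage for local background and transform to scores
#'
#' Removes slowly-varying local trends from a per-base read-coverage
#' track and converts it to a coverage-independent log score.  With
#' \eqn{X_j} the read count at base \eqn{j} and \eqn{\mu} the mean
#' coverage over mappable bases, the deviation of the local mean (window
#' of width `2L+1`, truncated at contig ends) from \eqn{\mu} is
#' subtracted: \eqn{W_j = \max(0, X_j - d_j)} where
#' \eqn{d_j = \mathrm{localmean}_j - \mu}, which keeps the overall
#' mean at \eqn{\mu} (a constant track is unchanged).  Scores are
#' \eqn{Y_j = \log_2(W_j / p\mu)}, floored at `y_floor`, so that a base
#' scores positively only where adjusted coverage exceeds `p` times the
#' mean; doubling all counts leaves \eqn{Y} unchanged (up to the floor).
#'
#' @param x Integer or numeric vector of per-base read counts.
#' @param L Half-width of the local-mean window in bases (window width
#'   `2L+1`).
#' @param p Stringency: adjusted coverage must exceed `p` times the mean
#'   coverage to score positively.
#' @param mappable Optional logical vector (same length as `x`); the mean
#'   coverage \eqn{\mu} is computed over mappable bases only.
#' @param y_floor Lower bound for the transformed score; bases with
#'   \eqn{W_j = 0} (and any score below the floor) are set to this value
#'   so isolated zero-coverage bases carry bounded negative weight.
#' @return A list with elements `W` (adjusted coverage), `Y` (scores),
#'   `mu` (mean coverage), `L`, `p`.
#' @examples
#' tr <- adjust_coverage(rep(5L, 2000), L = 100, p = 4)
#' stopifnot(all(abs(tr$Y + 2) < 1e-12))  # log2(1/4) everywhere
#' @export
adjust_coverage <- function(x, L, p = 4, mappable = NULL, y_floor = -8) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0) {
    stop("'p' must be a positive scalar")
  }
  n <- length(x)
  if (2 * L + 1 > n) stop("local-mean window exceeds contig length")
  x <- as.numeric(x)
  if (is.null(mappable)) mappable <- rep(TRUE, n)
  if (!any(mappable) || sum(x[mappable]) == 0) {
    stop("no coverage on mappable bases")
  }
  mu <- mean(x[mappable])
  local <- running_mean(x, L)
  d <- local - mu
  W <- pmax(0, x - d)
  Y <- ifelse(W > 0, log2(W / (p * mu)), y_floor)
  Y <- pmax(Y, y_floor)
  list(W = W, Y = Y, mu = mu, L = L, p = p)
}

# mean of x over [j-L, j+L], window truncated at the ends
running_mean <- function(x, L) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - L, 1L)
  hi <- pmin(seq_len(n) + L, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Find all maximal high-scoring segments of a score vector
#'
#' A segment is an interval whose score sum is strictly positive and
#' strictly exceeds the sum of every strictly containing interval;
#' among zero-sum extensions the shortest interval is reported.  The
#' returned segments are sorted and pairwise disjoint.  Runs in linear
#' time via a prefix-sum sweep.
#'
#' @param y Numeric vector of finite per-base scores.
#' @return A data.frame with columns `start`, `end` (0-based half-open)
#'   and `score` (segment sum).
#' @examples
#' find_high_scoring_segments(c(-1, 2, 3, -1, -5, 1))
#' @export
find_high_scoring_segments <- function(y) {
  y <- as.numeric(y)
  if (anyNA(y) || any(!is.finite(y))) stop("scores must be finite")
  if (length(y) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      score = numeric()))
  }
  .hss_cpp(y)
}

#' Call peaks on one coverage track
#'
#' Runs [adjust_coverage()] followed by [find_high_scoring_segments()]
#' and returns peaks as a `GRanges`.  Segments with score below
#' `min_score` are dropped: on sparse tracks single high bases can form
#' tiny positive segments, and a minimum cumulative log2 evidence keeps
#' only well-supported sites.
#'
#' @param x Per-base counts for one contig.
#' @param contig Contig name.
#' @param window Width of the local-mean window in bases (`2L+1`).
#' @param min_score Minimum segment score (sum of `Y`) to report.
#' @param sample_id Stored in the `sample_id` metadata column.
#' @inheritParams adjust_coverage
#' @return `GRanges` with metadata columns `score` and `sample_id`.
#' @export
call_peaks <- function(x, contig = "chr1", p = 4, window = 50000,
                       mappable = NULL, y_floor = -8, min_score = 5,
                       sample_id = NA_character_) {
  L <- floor(window / 2)
  adj <- adjust_coverage(x, L = L, p = p, mappable = mappable,
                         y_floor = y_floor)
  seg <- find_high_scoring_segments(adj$Y)
  seg <- seg[seg$score >= min_score, , drop = FALSE]
  gr <- GRanges(rep(contig, nrow(seg)),
                IRanges(start = seg$start + 1L, end = seg$end))
  mcols(gr)$score <- seg$score
  mcols(gr)$sample_id <- rep(sample_id, length(gr))
  gr
}

#' Remove peaks overlapping a low-mappability mask
#'
#' Peaks overlapping any masked interval by at least one base are
#' excluded, mirroring the exclusion of regions where short reads
#' cannot be uniquely aligned.
#'
#' @param peaks `GRanges` of peaks.
#' @param mask `GRanges` of low-mappability intervals (may be empty).
#' @return The mappable subset of `peaks`.
#' @export
filter_mappability <- function(peaks, mask) {
  if (length(mask) == 0L) return(peaks)
  hits <- findOverlaps(peaks, mask, minoverlap = 1L)
  drop <- unique(queryHits(hits))
  if (length(drop)) peaks[-drop] else peaks
}

#' Consolidate per-sample peak sets into one catalogue
#'
#' Takes the interval union of per-sample peaks (overlapping intervals
#' merged) and records, per consolidated peak, the contributing samples
#' and the number of samples supporting it.
#'
#' @param peak_list List of per-sample `GRanges` (each with a
#'   `sample_id` metadata column).
#' @return Sorted disjoint `GRanges` with metadata columns `peak_id`,
#'   `n_samples` and `samples` (comma-separated contributing sample
#'   ids).
#' @export
consolidate_peaks <- function(peak_list) {
  if (length(peak_list) < 1L) stop("need at least one peak set")
  all_peaks <- suppressWarnings(do.call(c, unname(peak_list)))
  merged <- reduce(sort(all_peaks))
  hits <- findOverlaps(merged, all_peaks)
  samp <- mcols(all_peaks)$sample_id[subjectHits(hits)]
  by_peak <- split(samp, factor(queryHits(hits), levels = seq_along(merged)))
  mcols(merged)$peak_id <- sprintf("peak_%05d", seq_along(merged))
  mcols(merged)$n_samples <- unname(vapply(by_peak,
                                           function(s) length(unique(s)),
                                           0L))
  mcols(merged)$samples <- unname(vapply(by_peak, function(s)
    paste(sort(unique(s)), collapse = ","), ""))
  merged
}

# logical mappability vector for one contig from a mask GRanges
mappable_vector <- function(contig, contig_length, mask) {
  m <- rep(TRUE, contig_length)
  if (length(mask) == 0L) return(m)
  mk <- mask[as.character(seqnames(mask)) == contig]
  for (i in seq_along(mk)) {
    lo <- max(1L, start(mk)[i])
    hi <- min(contig_length, end(mk)[i])
    if (lo <= hi) m[lo:hi] <- FALSE
  }
  m
}
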
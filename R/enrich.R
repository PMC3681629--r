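# Exact contingency tests for feature and QTL-candidate enrichment
# contrasts between variable and comparison peak sets.

#' Two-sided Fisher exact test on a 2x2 table
#'
#' The two-sided p-value sums hypergeometric table probabilities no
#' larger than the observed table's (the probability-ordering
#' convention of mainstream statistical software); the reported odds
#' ratio is the sample estimate `ad/bc` (`Inf` when only `bc` is zero,
#' `NaN` when both products vanish).
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @param alternative `"two.sided"` (default), `"greater"` or
#'   `"less"`.
#' @return List with `odds_ratio`, `pvalue`, `log10p` (-log10 p).
#' @examples
#' fisher_exact(matrix(c(199, 2614, 188, 3220), 2, byrow = TRUE))
#' @export
fisher_exact <- function(tab, alternative = "two.sided") {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2L) || any(tab < 0) || any(tab != round(tab))) {
    stop("need a 2x2 matrix of non-negative integer counts")
  }
  if (sum(tab) == 0) stop("all-zero table")
  p <- fisher.test(tab, alternative = alternative)$p.value
  ad <- tab[1, 1] * tab[2, 2]
  bc <- tab[1, 2] * tab[2, 1]
  or <- if (ad == 0 && bc == 0) NaN else if (bc == 0) Inf else ad / bc
  list(odds_ratio = or, pvalue = p, log10p = -log10(p))
}

#' Feature enrichment of a variable peak set against a comparison set
#'
#' Scores each peak for a feature, either by interval overlap (>= 1 bp
#' with a `GRanges` of feature intervals, e.g. conservation, enhancer
#' or promoter chromatin) or from a supplied logical flag (e.g. variant
#' within 100 bp), builds the (has feature / lacks feature) x
#' (variable / comparison) table and reports per-set percentages and
#' the -log10 Fisher p.
#'
#' @param var_peaks,comp_peaks `GRanges` of the two peak sets, or
#'   logical vectors of per-peak feature flags.
#' @param feature `GRanges` of feature intervals (ignored when logical
#'   flags are supplied); an empty feature set yields p = 1 with a
#'   warning.
#' @param feature_name Label carried into the output.
#' @return List with `feature`, `table`, `pct_variable`,
#'   `pct_comparison`, `odds_ratio`, `pvalue`, `log10p`.
#' @export
feature_enrichment <- function(var_peaks, comp_peaks, feature = NULL,
                               feature_name = "feature") {
  flag <- function(x) {
    if (is.logical(x)) return(x)
    if (is.null(feature) || length(feature) == 0L) {
      return(rep(FALSE, length(x)))
    }
    !is.na(findOverlaps(x, feature, minoverlap = 1L, select = "first"))
  }
  fv <- flag(var_peaks)
  fc <- flag(comp_peaks)
  if (!is.logical(var_peaks) &&
      (is.null(feature) || length(feature) == 0L)) {
    warning("empty feature set; p = 1")
    return(list(feature = feature_name,
                table = matrix(c(0L, length(var_peaks), 0L,
                                 length(comp_peaks)), 2, byrow = TRUE),
                pct_variable = 0, pct_comparison = 0,
                odds_ratio = NaN, pvalue = 1, log10p = 0))
  }
  tab <- matrix(c(sum(fv), sum(!fv), sum(fc), sum(!fc)), 2,
                byrow = TRUE,
                dimnames = list(c("variable", "comparison"),
                                c("has_feature", "lacks_feature")))
  ft <- fisher_exact(tab)
  list(feature = feature_name, table = tab,
       pct_variable = 100 * mean(fv), pct_comparison = 100 * mean(fc),
       odds_ratio = ft$odds_ratio, pvalue = ft$pvalue,
       log10p = ft$log10p)
}

#' QTL-candidate enrichment among variants in variable peaks
#'
#' Counts candidate and non-candidate variants lying within
#' `window_bp` of each peak set (a variant near both sets is counted
#' in both, as each set is tallied independently) and tests the 2x2
#' table with [fisher_exact()].
#'
#' @param var_peaks,nonvar_peaks `GRanges` of the two peak sets.
#' @param variants Variant data.frame with `contig`, `pos` (0-based)
#'   and a logical `qtl_candidate` column.
#' @param window_bp Window beyond peak edges (default 100).
#' @return List with `table`, `odds_ratio`, `pvalue`, `log10p`.
#' @export
qtl_candidate_enrichment <- function(var_peaks, nonvar_peaks, variants,
                                     window_bp = 100) {
  tally <- function(pk) {
    gr <- GRanges(variants$contig,
                  IRanges(variants$pos + 1L, width = 1L))
    hits <- findOverlaps(gr, pk + window_bp)
    ix <- unique(queryHits(hits))
    c(cand = sum(variants$qtl_candidate[ix]),
      non = sum(!variants$qtl_candidate[ix]))
  }
  v <- tally(var_peaks)
  nv <- tally(nonvar_peaks)
  tab <- matrix(c(v["cand"], v["non"], nv["cand"], nv["non"]), 2,
                byrow = TRUE,
                dimnames = list(c("variable", "non_variable"),
                                c("candidate", "non_candidate")))
  ft <- fisher_exact(tab)
  list(table = tab, odds_ratio = ft$odds_ratio, pvalue = ft$pvalue,
       log10p = ft$log10p)
}
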
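# Between-strain variability of peak heights: size factors, a
# negative-binomial likelihood-ratio test with a strain factor, and
# variance-components heritability.

#' Count reads in peaks
#'
#' Sums per-base coverage within each peak for every sample.  Because
#' the tracks hold per-base aligned-read coverage, the raw base-count
#' sum scales with both read number and read length; an optional
#' `redundancy` divisor (e.g. mean read length) converts it to an
#' approximate fragment count.
#'
#' @param peaks `GRanges` of consolidated peaks.
#' @param coverage Per-sample list of per-contig integer coverage
#'   vectors (as in a `dhs_dataset`).
#' @param redundancy Divisor applied before rounding (default 1: raw
#'   base-count sums).
#' @return Integer matrix, peaks by samples.
#' @export
count_in_peaks <- function(peaks, coverage, redundancy = 1) {
  samples <- names(coverage)
  out <- matrix(0L, length(peaks), length(samples),
                dimnames = list(mcols(peaks)$peak_id, samples))
  ctg <- as.character(seqnames(peaks))
  for (j in seq_along(samples)) {
    trk <- coverage[[j]]
    for (nm in unique(ctg)) {
      if (is.null(trk[[nm]])) stop("no coverage for contig ", nm)
      ix <- which(ctg == nm)
      if (any(end(peaks)[ix] > length(trk[[nm]]))) {
        stop("peak outside contig ", nm)
      }
      cs <- c(0, cumsum(as.numeric(trk[[nm]])))
      out[ix, j] <- as.integer(round(
        (cs[end(peaks)[ix] + 1L] - cs[start(peaks)[ix]]) / redundancy))
    }
  }
  out
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over peaks (rows with
#' all-positive counts) of that sample's count divided by the row
#' geometric mean.  When no row is all-positive, falls back to
#' total-count ratios (scaled to geometric mean 1) with a warning.
#'
#' @param counts Non-negative integer matrix, peaks by samples.
#' @return Positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  ok <- rowSums(counts > 0) == ncol(counts)
  if (!any(ok)) {
    warning("no peak with positive counts in all samples; ",
            "using total-count ratios")
    tot <- colSums(counts)
    return(tot / exp(mean(log(tot))))
  }
  lg <- rowMeans(log(counts[ok, , drop = FALSE]))
  apply(counts[ok, , drop = FALSE], 2, function(cnt)
    median(exp(log(cnt) - lg)))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param p Numeric vector of p-values in \[0, 1\]; `NA`/`NaN` are
#'   rejected.
#' @return Step-up adjusted p-values, monotone in rank.
#' @export
bh_fdr <- function(p) {
  if (anyNA(p)) stop("p-values must not contain NA/NaN")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

# log-likelihood of NB counts with fixed dispersion and per-sample
# offsets, group means fitted by Newton on the log scale
nb_group_loglik <- function(k, s, alpha) {
  if (sum(k) == 0) return(0)            # mu -> 0 gives loglik 0
  b <- log(sum(k) / sum(s))
  for (it in 1:50) {
    mu <- s * exp(b)
    u <- sum((k - mu) / (1 + alpha * mu))
    du <- -sum(mu * (1 + alpha * k) / (1 + alpha * mu)^2)
    step <- u / du
    b <- b - step
    if (abs(step) < 1e-12) break
  }
  mu <- s * exp(b)
  if (alpha > 0) {
    sum(dnbinom(k, size = 1 / alpha, mu = mu, log = TRUE))
  } else {
    sum(stats::dpois(k, mu, log = TRUE))
  }
}

# method-of-moments dispersion from within-strain replicate variation
# of size-factor-normalized counts; Var(K/s) = mu/s + alpha * mu^2
mom_dispersion <- function(counts, sf, strain) {
  q <- sweep(counts, 2, sf, "/")
  mu <- rowMeans(q)
  groups <- split(seq_along(strain), strain)
  groups <- groups[vapply(groups, length, 0L) >= 2L]
  ss <- 0 * mu; df <- 0
  for (g in groups) {
    qm <- rowMeans(q[, g, drop = FALSE])
    ss <- ss + rowSums((q[, g, drop = FALSE] - qm)^2)
    df <- df + length(g) - 1L
  }
  v <- ss / df
  xi <- mean(1 / sf)
  (v - mu * xi) / mu^2
}

# dispersion-mean trend: alpha(mu) = a0 + a1 / mu fitted to positive
# method-of-moments estimates
dispersion_trend <- function(alpha_mom, mu) {
  ok <- is.finite(alpha_mom) & alpha_mom > 0 & mu > 0
  if (sum(ok) < 10) {
    a <- c(max(1e-4, median(alpha_mom[ok], na.rm = TRUE)), 0)
    if (!is.finite(a[1])) a[1] <- 0.01
    return(a)
  }
  fit <- lm(alpha_mom[ok] ~ I(1 / mu[ok]))
  a <- coef(fit)
  c(max(a[1], 1e-6), max(a[2], 0))
}

#' Test peaks for between-strain variability
#'
#' For each peak, a negative-binomial likelihood-ratio test compares a
#' model with a strain factor (log link, size-factor offsets) against
#' an intercept-only model; the statistic is referred to a chi-squared
#' distribution with `n_strains - 1` degrees of freedom.  The NB
#' dispersion is held fixed per peak at a mean-dispersion trend fitted
#' across peaks from within-strain method-of-moments estimates, so
#' single peaks with accidentally small replicate variance do not
#' produce spurious calls, and the statistics receive an empirical-null
#' rescaling that corrects the chi-squared approximation at few
#' replicates.  Heritability is estimated for every peak from the same
#' normalized counts (see [heritability()]).
#'
#' @param counts Integer matrix, peaks by samples.
#' @param strain Character/factor vector mapping each column to a
#'   strain.
#' @param sf Size factors; computed with [size_factors()] when `NULL`.
#' @param fdr_levels FDR thresholds at which `variable` flags are set.
#' @param moderate `"trend"` (default) holds dispersion at the fitted
#'   mean-dispersion trend; `"max"` takes the maximum of the per-peak
#'   estimate and the trend (more conservative).
#' @param empirical_null Rescale the likelihood-ratio statistics so
#'   that their lower quartile matches the reference chi-squared
#'   quartile (a genomic-control-style empirical-null correction for
#'   the small-sample inflation of the LRT); applied when at least 100
#'   peaks are testable.
#' @return data.frame with per-peak `base_mean`, `dispersion`, `pvalue`,
#'   `padj`, `h2`, `v_between`, `v_within`, `untestable`, and one
#'   logical `variable_fdrXX` column per entry of `fdr_levels`.
#' @export
test_strain_variability <- function(counts, strain, sf = NULL,
                                    fdr_levels = c(0.10, 0.01),
                                    moderate = c("trend", "max"),
                                    empirical_null = TRUE) {
  moderate <- match.arg(moderate)
  counts <- as.matrix(counts)
  strain <- as.character(strain)
  if (length(strain) != ncol(counts)) stop("one strain per column required")
  tab <- table(strain)
  if (length(tab) < 2L || sum(tab >= 2L) == 0L) {
    stop("need >= 2 strains and replicates somewhere in the design")
  }
  if (is.null(sf)) sf <- size_factors(counts)

  q <- sweep(counts, 2, sf, "/")
  mu <- rowMeans(q)
  alpha_mom <- mom_dispersion(counts, sf, strain)
  tr <- dispersion_trend(alpha_mom, mu)
  alpha_fit <- tr[1] + tr[2] / pmax(mu, 1e-8)
  alpha <- if (moderate == "max") {
    pmax(alpha_mom, alpha_fit, 1e-8)
  } else {
    pmax(alpha_fit, 1e-8)
  }

  groups <- split(seq_along(strain), strain)
  df_test <- length(groups) - 1L
  n <- nrow(counts)
  lrstat <- rep(0, n)
  untestable <- rowSums(counts) == 0
  for (i in seq_len(n)) {
    if (untestable[i]) next
    k <- counts[i, ]
    ll0 <- nb_group_loglik(k, sf, alpha[i])
    ll1 <- sum(vapply(groups, function(g)
      nb_group_loglik(k[g], sf[g], alpha[i]), 0))
    lrstat[i] <- max(0, 2 * (ll1 - ll0))
  }
  # empirical-null rescaling: with most peaks null, the lower quartile
  # of the LRT is signal-free and anchors a genomic-control factor
  if (empirical_null && sum(!untestable) >= 100) {
    q_obs <- quantile(lrstat[!untestable], 0.25, names = FALSE)
    if (q_obs > 0) {
      lrstat <- lrstat * (stats::qchisq(0.25, df_test) / q_obs)
    }
  }
  pval <- rep(1, n)
  pval[!untestable] <- pchisq(lrstat[!untestable], df = df_test,
                              lower.tail = FALSE)
  padj <- rep(NA_real_, n)
  padj[!untestable] <- bh_fdr(pval[!untestable])
  padj[untestable] <- 1

  her <- t(vapply(seq_len(n), function(i)
    heritability(counts[i, ], strain, sf = sf), c(h2 = 0, v_between = 0,
                                                  v_within = 0)))
  out <- data.frame(peak_id = rownames(counts) %||%
                      sprintf("peak_%05d", seq_len(n)),
                    base_mean = mu, dispersion = alpha, pvalue = pval,
                    padj = padj, h2 = her[, "h2"],
                    v_between = her[, "v_between"],
                    v_within = her[, "v_within"],
                    untestable = untestable,
                    stringsAsFactors = FALSE)
  for (f in fdr_levels) {
    out[[sprintf("variable_fdr%02d", round(100 * f))]] <-
      !untestable & padj <= f
  }
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Variance-components heritability of a peak
#'
#' One-way random-effects ANOVA on `log2(normalized count + 0.5)` with
#' the unbalanced-design coefficient
#' \eqn{n_0 = (N - \sum n_i^2 / N) / (k - 1)}: the within-strain
#' component is the mean square within, the between-strain component is
#' \eqn{\max(0, (MSB - MSW) / n_0)}, and heritability is half the
#' between-strain component divided by the within-strain variance plus
#' half the between-strain component.  Returns 0 when both components
#' vanish.
#'
#' @param k Counts for one peak (one value per sample), or already
#'   log-transformed values when `log = FALSE`.
#' @param strain Strain of each sample.
#' @param sf Size factors (default all 1).
#' @param log Transform counts to `log2(k / sf + 0.5)` first.
#' @return Named numeric vector `h2`, `v_between`, `v_within`.
#' @export
heritability <- function(k, strain, sf = NULL, log = TRUE) {
  strain <- as.character(strain)
  if (is.null(sf)) sf <- rep(1, length(k))
  y <- if (log) log2(k / sf + 0.5) else k
  groups <- split(y, strain)
  ni <- vapply(groups, length, 0L)
  kk <- length(groups)
  N <- sum(ni)
  if (kk < 2L || N - kk < 1L) {
    stop("heritability needs >= 2 strains and replication")
  }
  gm <- vapply(groups, mean, 0)
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0))
  ssb <- sum(ni * (gm - mean(y))^2)
  msw <- ssw / (N - kk)
  msb <- ssb / (kk - 1)
  n0 <- (N - sum(ni^2) / N) / (kk - 1)
  vw <- msw
  vb <- max(0, (msb - msw) / n0)
  h2 <- if (vw + vb / 2 <= 0) 0 else (vb / 2) / (vw + vb / 2)
  c(h2 = h2, v_between = vb, v_within = vw)
}
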
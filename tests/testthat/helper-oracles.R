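# Independent oracles and shared fixture builders.

# Brute-force maximal-segment oracle, straight from the definition:
# sum > 0, no strictly containing interval with a larger sum, and no
# strictly contained interval with an equal-or-larger sum (the
# shortest-interval tie-break).  O(n^4); for short arrays only.
hss_brute <- function(y) {
  n <- length(y)
  P <- c(0, cumsum(y))
  res <- list()
  for (m in 0:(n - 1)) {
    for (e in (m + 1):n) {
      S <- P[e + 1] - P[m + 1]
      if (S <= 0) next
      ok <- TRUE
      for (u in 0:m) {
        for (v in e:n) {
          if (u == m && v == e) next
          if (P[v + 1] - P[u + 1] > S) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (ok) {
        for (u in m:(e - 1)) {
          for (v in (u + 1):e) {
            if (u == m && v == e) next
            if (P[v + 1] - P[u + 1] >= S) { ok <- FALSE; break }
          }
          if (!ok) break
        }
      }
      if (ok) res[[length(res) + 1L]] <- c(m, e, S)
    }
  }
  if (!length(res)) {
    return(data.frame(start = integer(), end = integer(),
                      score = numeric()))
  }
  df <- do.call(rbind, res)
  out <- data.frame(start = df[, 1], end = df[, 2], score = df[, 3])
  out[order(out$start), , drop = FALSE]
}

# Same conditions evaluated with vectorized per-start sweeps; O(n^2),
# usable up to a few hundred bases.  Cross-validated against
# hss_brute in the unit tests before the large acceptance sweep.
hss_quadratic <- function(y) {
  n <- length(y)
  P <- c(0, cumsum(y))           # P[i+1] = sum of first i scores
  prefmin <- cummin(P)
  sufmax <- rev(cummax(rev(P)))
  res <- list()
  for (m in 0:(n - 1)) {
    if (P[m + 1] > prefmin[m + 1]) next
    ends <- (m + 1):n
    S <- P[ends + 1] - P[m + 1]
    valid_end <- P[ends + 1] >= sufmax[ends + 1]
    # interior prefix values (positions m+1 .. e-1) must lie strictly
    # between P[m] and P[e]
    v <- P[(m + 2):(n + 1)]
    run_min <- cummin(c(Inf, v[-length(v)]))
    run_max <- cummax(c(-Inf, v[-length(v)]))
    ok <- S > 0 & valid_end & run_min > P[m + 1] & run_max < P[ends + 1]
    for (e in ends[ok]) {
      res[[length(res) + 1L]] <- c(m, e, P[e + 1] - P[m + 1])
    }
  }
  if (!length(res)) {
    return(data.frame(start = integer(), end = integer(),
                      score = numeric()))
  }
  df <- do.call(rbind, res)
  out <- data.frame(start = df[, 1], end = df[, 2], score = df[, 3])
  out[order(out$start), , drop = FALSE]
}

# two-sided Fisher p by hypergeometric enumeration (probability
# ordering), independent of fisher.test
fisher_enum <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- c_ + d; k <- a + c_
  lo <- max(0, k - n); hi <- min(k, m)
  x <- lo:hi
  pr <- dhyper(x, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# the 19-sample, 8-strain design of the study
study_design <- function() {
  rep(dhs_strains(), c(3L, 2L, 2L, 2L, 3L, 3L, 2L, 2L))
}

# miniature simulation config for fast unit tests
tiny_config <- function(...) {
  defaults <- list(genome_length = 250000, n_contigs = 1L,
                   n_peaks = 40L, n_decoy_variants = 250L,
                   n_transcripts = 40L, n_mask = 2L)
  over <- list(...)
  defaults[names(over)] <- over
  do.call(simulation_config, defaults)
}

# NB null count matrix for the study design
null_counts <- function(n_peaks, dispersion = 0.05,
                        mu_range = c(50, 5000)) {
  strain <- study_design()
  mu <- exp(runif(n_peaks, log(mu_range[1]), log(mu_range[2])))
  cnt <- t(vapply(mu, function(m)
    rnbinom(length(strain), size = 1 / dispersion, mu = m),
    numeric(length(strain))))
  rownames(cnt) <- sprintf("p%05d", seq_len(n_peaks))
  cnt
}
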
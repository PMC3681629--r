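# Position-weight-matrix scanning with exact null p-values.
#
# Scores are log2 odds of a count-derived base probability over a
# background composition.  For significance, the per-position scores
# are discretized to a fixed bin width and the exact distribution of
# the total score under the background model is computed by dynamic
# programming (convolution across motif positions); observed scores
# are computed on the same discretized scale, so DP tail probabilities
# are exact for the discretized scores.

DNA <- c("A", "C", "G", "T")

#' Build a position weight matrix from base counts
#'
#' @param counts Numeric matrix, 4 rows (A, C, G, T) by motif
#'   positions, of observed base counts (or probabilities).
#' @param background Background base frequencies, summing to 1.
#' @param pseudocount Added to every count before normalization.
#' @param motif_id Identifier carried through scan results.
#' @param bin Discretization width for the exact score distribution.
#' @return Object of class `dhs_pwm` with the log2-odds matrix, its
#'   integer-discretized form, and the exact tail distribution of the
#'   discretized score under the background model.
#' @export
pwm <- function(counts, background = rep(0.25, 4), pseudocount = 0.1,
                motif_id = "motif", bin = 1e-3) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L || ncol(counts) < 1L) {
    stop("counts must be a 4 x width matrix")
  }
  if (abs(sum(background) - 1) > 1e-8 || any(background <= 0)) {
    stop("background must be positive and sum to 1")
  }
  prob <- sweep(counts + pseudocount, 2,
                colSums(counts + pseudocount), "/")
  logodds <- log2(prob / background)
  if (any(!is.finite(logodds))) stop("non-finite log-odds")
  iscore <- round(logodds / bin)
  storage.mode(iscore) <- "integer"
  dimnames(logodds) <- dimnames(iscore) <- list(DNA, NULL)
  obj <- list(motif_id = motif_id, logodds = logodds, iscore = iscore,
              background = background, bin = bin,
              dist = iscore_distribution(iscore, background))
  class(obj) <- "dhs_pwm"
  obj
}

# exact distribution of the summed integer score under the background:
# returns list(offset, prob, tail) where prob[k] = P(sum == offset+k-1)
iscore_distribution <- function(iscore, background) {
  w <- ncol(iscore)
  cur_lo <- 0L
  # running support [cur_lo, cur_lo + length(vec) - 1]
  vec <- c(1)
  for (j in seq_len(w)) {
    smin <- min(iscore[, j]); smax <- max(iscore[, j])
    new <- numeric(length(vec) + smax - smin)
    for (b in 1:4) {
      sh <- iscore[b, j] - smin
      idx <- seq_along(vec) + sh
      new[idx] <- new[idx] + vec * background[b]
    }
    vec <- new
    cur_lo <- cur_lo + smin
  }
  tail <- rev(cumsum(rev(vec)))
  list(offset = cur_lo, prob = vec, tail = tail)
}

# P(background score >= s) for integer scores s (vectorized)
pwm_tail_p <- function(pw, s) {
  d <- pw$dist
  idx <- s - d$offset + 1L
  idx <- pmax(idx, 1L)
  out <- numeric(length(s))
  inside <- idx <= length(d$tail)
  out[inside] <- d$tail[idx[inside]]
  out[!inside] <- 0
  out
}

#' Read position weight matrices from a count-matrix text file
#'
#' Minimal MEME-like format: blocks starting `MOTIF <id>` followed by
#' one line per motif position holding four whitespace-separated counts
#' in A, C, G, T order.  An optional line `BACKGROUND a c g t` before
#' the first motif sets the background composition.
#'
#' @param path File path.
#' @inheritParams pwm
#' @return List of [pwm()] objects.
#' @export
read_pwm_file <- function(path, pseudocount = 0.1, bin = 1e-3) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  background <- rep(0.25, 4)
  out <- list()
  cur_id <- NULL
  cur_rows <- list()
  flush <- function() {
    if (!is.null(cur_id)) {
      m <- t(do.call(rbind, cur_rows))
      out[[length(out) + 1L]] <<- pwm(m, background = background,
                                      pseudocount = pseudocount,
                                      motif_id = cur_id, bin = bin)
    }
  }
  for (ln in lines) {
    if (startsWith(ln, "BACKGROUND")) {
      background <- as.numeric(strsplit(ln, "\\s+")[[1]][2:5])
    } else if (startsWith(ln, "MOTIF")) {
      flush()
      cur_id <- strsplit(ln, "\\s+")[[1]][2]
      cur_rows <- list()
    } else {
      v <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1]]))
      if (length(v) != 4L || anyNA(v)) {
        stop("malformed PWM line: ", ln)
      }
      cur_rows[[length(cur_rows) + 1L]] <- v
    }
  }
  flush()
  if (!length(out)) stop("no motifs in ", path)
  out
}

encode_dna <- function(sequence) {
  v <- match(strsplit(toupper(sequence), "")[[1]], DNA)
  v   # N and other ambiguity codes become NA
}

revcomp <- function(sequence) {
  chartr("ACGTacgt", "TGCAtgca",
         paste(rev(strsplit(sequence, "")[[1]]), collapse = ""))
}

# reverse-complement a pwm (scan reverse strand by forward scanning)
pwm_revcomp <- function(pw) {
  ridx <- c(4L, 3L, 2L, 1L)
  obj <- pw
  obj$logodds <- pw$logodds[ridx, rev(seq_len(ncol(pw$logodds))),
                            drop = FALSE]
  obj$iscore <- pw$iscore[ridx, rev(seq_len(ncol(pw$iscore))),
                          drop = FALSE]
  rownames(obj$logodds) <- rownames(obj$iscore) <- DNA
  # the null distribution depends on the background, which need not be
  # strand-symmetric, so recompute it for the reversed matrix
  obj$dist <- iscore_distribution(obj$iscore, pw$background)
  obj
}

scan_one_strand <- function(code, pw, pthresh, strand_label) {
  w <- ncol(pw$iscore)
  n <- length(code)
  if (w > n) {
    return(data.frame(start = integer(), width = integer(),
                      strand = character(), motif_id = character(),
                      score = numeric(), pvalue = numeric()))
  }
  npos <- n - w + 1L
  total <- numeric(npos)
  for (j in seq_len(w)) {
    b <- code[j:(j + npos - 1L)]
    sc <- pw$iscore[, j][b]
    # ambiguous base: expected score under the background
    sc[is.na(b)] <- round(sum(pw$background * pw$iscore[, j]))
    total <- total + sc
  }
  pv <- pwm_tail_p(pw, total)
  hit <- which(pv < pthresh)
  data.frame(start = hit - 1L, width = rep(w, length(hit)),
             strand = rep(strand_label, length(hit)),
             motif_id = rep(pw$motif_id, length(hit)),
             score = total[hit] * pw$bin, pvalue = pv[hit],
             stringsAsFactors = FALSE)
}

#' Scan a sequence for motif hits with exact p-values
#'
#' Scores every position on both strands and reports positions whose
#' exact null p-value (computed by dynamic programming over the
#' discretized score distribution under the background model) is below
#' `pthresh`.  Ambiguous bases (N) contribute their expected background
#' score.
#'
#' @param sequence DNA string over A, C, G, T, N.
#' @param pwms A [pwm()] object or list of them.
#' @param pthresh Hit threshold on the exact p-value (default 1e-5).
#' @return data.frame with `start` (0-based), `width`, `strand`,
#'   `motif_id`, `score` (log2 odds on the discretized scale) and
#'   `pvalue`.
#' @export
scan_motifs <- function(sequence, pwms, pthresh = 1e-5) {
  if (inherits(pwms, "dhs_pwm")) pwms <- list(pwms)
  if (!length(pwms)) stop("empty PWM list")
  code <- encode_dna(sequence)
  out <- list()
  for (pw in pwms) {
    out[[length(out) + 1L]] <- scan_one_strand(code, pw, pthresh, "+")
    out[[length(out) + 1L]] <- scan_one_strand(code, pwm_revcomp(pw),
                                               pthresh, "-")
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$motif_id, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Classify a variant's effect on motif matches
#'
#' Scans the two allele sequences and compares hits overlapping the
#' variant footprint: a motif hit present with the reference-like
#' allele but absent with the alternate allele is a disruption; the
#' converse is a creation.  Disruption takes precedence when both
#' occur (for different motifs).
#'
#' @param ref_seq,alt_seq Flanking sequence carrying the reference-like
#'   and alternate allele, respectively.
#' @param var_pos 0-based position of the variant within `ref_seq`.
#' @param ref_len,alt_len Allele lengths in the two sequences.
#' @param pwms List of [pwm()] objects.
#' @param pthresh Hit threshold (default 1e-5).
#' @return One of `"disrupted"`, `"created"`, `"none"`.
#' @export
classify_motif_effect <- function(ref_seq, alt_seq, var_pos,
                                  ref_len = 1L, alt_len = 1L, pwms,
                                  pthresh = 1e-5) {
  if (identical(ref_seq, alt_seq)) stop("alleles are identical")
  hits_r <- scan_motifs(ref_seq, pwms, pthresh)
  hits_a <- scan_motifs(alt_seq, pwms, pthresh)
  over <- function(h, len) {
    h[h$start < var_pos + len & h$start + h$width > var_pos, ,
      drop = FALSE]
  }
  key <- function(h) unique(paste(h$motif_id, h$strand))
  kr <- key(over(hits_r, ref_len))
  ka <- key(over(hits_a, alt_len))
  if (length(setdiff(kr, ka))) return("disrupted")
  if (length(setdiff(ka, kr))) return("created")
  "none"
}
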
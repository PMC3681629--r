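# Strain distribution patterns: the binary partition of the inbred
# strains induced by a di-allelic variant.  A pattern and its
# complement are equivalent; the canonical form fixes the first strain
# to 0, and the letter form writes A for strains sharing the first
# strain's allele and B otherwise (so a variant private to A/J and
# LP/J reads ABBBBBBA).

# fold a 0/1 vector so its first element is 0
canonical_bits <- function(bits) {
  bits <- as.integer(bits)
  if (bits[1] == 1L) bits <- 1L - bits
  bits
}

sdp_letters <- function(bits) {
  paste(c("A", "B")[canonical_bits(bits) + 1L], collapse = "")
}

#' Strain distribution pattern of a variant
#'
#' @param alleles Character vector of per-strain allele labels in the
#'   canonical strain order.
#' @return List with `bits` (canonical 0/1 vector, first strain 0) and
#'   `letters` (A/B string).  Errors on monomorphic input; for
#'   multi-allelic variants use [sdp_decompose()].
#' @examples
#' extract_sdp(c("A", "G", "G", "G", "G", "G", "G", "A"))$letters
#' @export
extract_sdp <- function(alleles) {
  u <- unique(alleles)
  if (length(u) < 2L) stop("monomorphic variant has no SDP")
  if (length(u) > 2L) {
    stop("multi-allelic variant; use sdp_decompose()")
  }
  bits <- canonical_bits(as.integer(alleles != alleles[1]))
  list(bits = bits, letters = sdp_letters(bits))
}

#' Decompose a variant into di-allelic strain distribution patterns
#'
#' A multi-allelic variant is split into one pattern per allele
#' (carriers of that allele vs all others), keeping the di-allelic SDP
#' algebra intact; a di-allelic variant yields its single SDP.
#'
#' @inheritParams extract_sdp
#' @return List of SDPs as returned by [extract_sdp()], deduplicated.
#' @export
sdp_decompose <- function(alleles) {
  u <- unique(alleles)
  if (length(u) < 2L) stop("monomorphic variant has no SDP")
  if (length(u) == 2L) return(list(extract_sdp(alleles)))
  out <- lapply(u, function(a) {
    bits <- canonical_bits(as.integer(alleles == a))
    list(bits = bits, letters = sdp_letters(bits))
  })
  out[!duplicated(vapply(out, `[[`, "", "letters"))]
}

#' Number of distinct strain distribution patterns
#'
#' Di-allelic variants over `n` strains admit `2^(n-1) - 1` canonical
#' non-constant patterns (complement pairs folded); for eight strains
#' this is 127.
#'
#' @param n_strains Number of strains (>= 2).
#' @return Integer count.
#' @export
count_sdps <- function(n_strains) {
  if (n_strains < 2L) stop("need >= 2 strains")
  as.integer(2^(n_strains - 1) - 1)
}

#' Enumerate all canonical strain distribution patterns
#'
#' @param n_strains Number of strains (>= 2).
#' @return List of canonical 0/1 vectors (first element 0), one per
#'   pattern; length equals [count_sdps()].
#' @export
all_sdps <- function(n_strains) {
  if (n_strains < 2L) stop("need >= 2 strains")
  lapply(seq_len(2^(n_strains - 1) - 1), function(i) {
    c(0L, as.integer(intToBits(i)[seq_len(n_strains - 1)]))
  })
}
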
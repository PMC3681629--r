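# Synthetic multi-strain DNase-seq data with planted ground truth.
#
# The generator emulates the statistical structure the downstream
# analysis assumes: per-base counts are negative-binomially distributed
# around a flat background, peaks add strain-dependent signal, and the
# per-sample signal inside a peak shares one gamma factor so that
# peak-level read counts are themselves NB(mean, dispersion) -- the
# model the variability test fits.  Causal variants carry the strain
# distribution pattern (SDP) of their peak's strain effect; decoy
# variants inherit the SDP of a simulated haplotype block or draw one
# uniformly from the canonical patterns.

#' Configuration for the synthetic dataset generator
#'
#' Builds and validates a simulation configuration.  Defaults emulate
#' the 19-sample, eight-strain design (three replicates of A/J,
#' C57BL/6J and CBA/J, two of each remaining strain) at a miniature
#' genome scale on which the full pipeline runs in minutes.
#'
#' @param n_strains Number of inbred strains.
#' @param replicates_per_strain Integer vector of replicates per strain,
#'   in the canonical strain order.
#' @param genome_length Bases per contig.
#' @param n_contigs Number of contigs.
#' @param n_peaks Number of planted peaks.
#' @param frac_variable Fraction of peaks given a between-strain effect.
#' @param frac_discrete Fraction of variable peaks simulated as total
#'   loss of signal in at least one strain.
#' @param frac_compound Fraction of discrete peaks planted as clusters
#'   of co-varying peaks within 10 Kb sharing one presence pattern.
#' @param peak_width_range Range of peak widths in bases.
#' @param background_rate Mean background coverage, reads per base.
#' @param peak_enrichment Fold enrichment of a fully present peak over
#'   background.
#' @param nb_dispersion NB dispersion alpha (Var = mu + alpha mu^2) of
#'   counts, at base level and, through the shared gamma factor, at
#'   peak level.
#' @param frac_causal Fraction of variable peaks whose effect is driven
#'   by a planted variant with matching SDP.
#' @param n_decoy_variants Number of non-causal variants.
#' @param n_transcripts Number of transcripts.
#' @param frac_linked Fraction of variable peaks with a transcript whose
#'   abundance tracks the peak's strain effect, start within 10 Kb.
#' @param rng_seed Integer seed; all outputs are deterministic given it.
#' @param strain_effect_sdlog Log-normal sd of continuous strain
#'   effects.
#' @param causal_fold_range Fold-change range (as powers of two) for
#'   two-level causal effects.
#' @param max_absent_strains Maximum strains losing a discrete peak.
#' @param tx_depth Mean transcript read count per sample.
#' @param block_bp Mean haplotype-block length for decoy SDPs.
#' @param ld_fidelity Probability a decoy variant inherits its block's
#'   SDP rather than an independent uniform one.
#' @param repeat_boost Coverage multiplier inside masked (multi-copy)
#'   regions.
#' @param n_mask Number of masked intervals per contig.
#' @param mask_width_range Width range of masked intervals.
#' @return A validated list of class `dhs_sim_config`.
#' @export
simulation_config <- function(n_strains = 8L,
                              replicates_per_strain = c(3L, 2L, 2L, 2L,
                                                        3L, 3L, 2L, 2L),
                              genome_length = 2e6,
                              n_contigs = 2L,
                              n_peaks = 300L,
                              frac_variable = 0.3,
                              frac_discrete = 0.3,
                              frac_compound = 0.3,
                              peak_width_range = c(150L, 600L),
                              background_rate = 1,
                              peak_enrichment = 12,
                              nb_dispersion = 0.05,
                              frac_causal = 0.8,
                              n_decoy_variants = 3000L,
                              n_transcripts = 200L,
                              frac_linked = 0.5,
                              rng_seed = 1L,
                              strain_effect_sdlog = 0.5,
                              causal_fold_range = c(1, 2),
                              max_absent_strains = 3L,
                              tx_depth = 100,
                              block_bp = 30000,
                              ld_fidelity = 0.8,
                              repeat_boost = 3,
                              n_mask = 4L,
                              mask_width_range = c(5000L, 20000L)) {
  cfg <- as.list(environment())
  fracs <- c(frac_variable, frac_discrete, frac_compound, frac_causal,
             frac_linked, ld_fidelity)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (length(replicates_per_strain) != n_strains) {
    stop("replicates_per_strain must have n_strains entries")
  }
  if (any(replicates_per_strain < 1L)) stop("need >= 1 replicate per strain")
  if (genome_length * n_contigs <= n_peaks * max(peak_width_range)) {
    stop("genome too small for the requested peaks")
  }
  if (background_rate <= 0 || peak_enrichment <= 1 || nb_dispersion < 0) {
    stop("invalid rate, enrichment or dispersion")
  }
  class(cfg) <- "dhs_sim_config"
  cfg
}

sim_strain_names <- function(n) {
  if (n == 8L) dhs_strains() else paste0("strain_", seq_len(n))
}

sim_design <- function(cfg) {
  strains <- sim_strain_names(cfg$n_strains)
  strain <- rep(strains, cfg$replicates_per_strain)
  rep_no <- unlist(lapply(cfg$replicates_per_strain, seq_len))
  data.frame(sample_id = paste0(gsub("[^A-Za-z0-9]", "", strains)[
    match(strain, strains)], "_r", rep_no),
    strain = strain, stringsAsFactors = FALSE)
}

#' Simulate a miniature multi-strain DNase-seq dataset
#'
#' Generates per-base coverage tracks for every sample, a mappability
#' mask, a variant table with per-strain alleles and QTL-candidate
#' flags, transcripts with per-sample counts, annotation interval sets
#' (conservation, enhancer, promoter) and a ground-truth object kept
#' separate from the inputs so that no analysis stage can read it.
#'
#' Peaks are rectangles of mean coverage
#' `background_rate * (1 + (peak_enrichment - 1) * m_s)` where the
#' strain multiplier `m_s` is 1 for constant peaks, log-normal for
#' continuous variable peaks, two-level (allele-driven) for causal
#' peaks and 0 (pure background) for strains losing a discrete peak.
#' Within one sample all bases of a peak share one gamma factor, so
#' peak-level counts are NB with the configured dispersion.
#'
#' @param cfg A [simulation_config()].
#' @return A list of class `dhs_dataset` with elements `design`,
#'   `contigs`, `coverage` (per sample, per contig integer vectors),
#'   `mask`, `variants`, `transcripts`, `tx_counts`, `annotations` and
#'   `truth`.
#' @export
simulate_dataset <- function(cfg) {
  if (!inherits(cfg, "dhs_sim_config")) stop("cfg must be a simulation_config")
  with_seed(cfg$rng_seed, simulate_dataset_impl(cfg))
}

simulate_dataset_impl <- function(cfg) {
  design <- sim_design(cfg)
  strains <- sim_strain_names(cfg$n_strains)
  contigs <- setNames(rep(as.integer(cfg$genome_length), cfg$n_contigs),
                      paste0("contig_", seq_len(cfg$n_contigs)))

  truth_peaks <- plant_peaks(cfg, contigs, strains)
  mask <- plant_mask(cfg, contigs, truth_peaks$gr)
  variants <- plant_variants(cfg, contigs, truth_peaks, strains)
  tx <- plant_transcripts(cfg, contigs, truth_peaks, design, strains)
  annotations <- plant_annotations(cfg, contigs, truth_peaks$gr)
  coverage <- simulate_coverage(cfg, contigs, truth_peaks, mask, design,
                                strains)

  truth <- list(peaks = truth_peaks$gr,
                multipliers = truth_peaks$mult,
                linked = tx$linked,
                config = cfg)
  structure(list(design = design, contigs = contigs, coverage = coverage,
                 mask = mask, variants = variants,
                 transcripts = tx$transcripts, tx_counts = tx$counts,
                 annotations = annotations, truth = truth),
            class = "dhs_dataset")
}

# decide class labels, strain multipliers and positions of planted peaks
plant_peaks <- function(cfg, contigs, strains) {
  ns <- cfg$n_strains
  n_var <- round(cfg$frac_variable * cfg$n_peaks)
  n_disc <- round(cfg$frac_discrete * n_var)
  n_comp <- round(cfg$frac_compound * n_disc)
  if (n_comp == 1L) n_comp <- 0L              # a cluster needs >= 2 members

  # compound clusters of 2-3 members
  cluster_sizes <- integer(0)
  left <- n_comp
  while (left >= 2L) {
    sz <- if (left >= 3L && runif(1) < 0.4) 3L else 2L
    sz <- min(sz, left)
    cluster_sizes <- c(cluster_sizes, sz)
    left <- left - sz
  }
  n_comp <- sum(cluster_sizes)
  n_simple <- n_disc - n_comp
  n_cont <- n_var - n_disc
  n_const <- cfg$n_peaks - n_var

  classes <- c(rep("discrete_compound", n_comp),
               rep("discrete_simple", n_simple),
               rep("continuous", n_cont),
               rep("constant", n_const))
  cluster_of <- c(rep(seq_along(cluster_sizes), cluster_sizes),
                  rep(NA_integer_, cfg$n_peaks - n_comp))

  widths <- as.integer(round(runif(cfg$n_peaks, cfg$peak_width_range[1],
                                   cfg$peak_width_range[2])))

  # units: compound clusters stay together, everything else is a unit
  unit_of <- ifelse(!is.na(cluster_of), cluster_of,
                    max(c(0L, cluster_of), na.rm = TRUE) +
                      cumsum(is.na(cluster_of)))
  units <- split(seq_len(cfg$n_peaks), unit_of)
  units <- units[sample(length(units))]

  contig_of_unit <- sort(sample(seq_along(contigs), length(units),
                                replace = TRUE))
  pos <- integer(cfg$n_peaks)
  contig_ix <- integer(cfg$n_peaks)
  for (ci in seq_along(contigs)) {
    uix <- which(contig_of_unit == ci)
    if (!length(uix)) next
    # intra-unit gaps keep cluster members within 10 Kb of a neighbour
    unit_lens <- vapply(units[uix], function(ix) {
      sum(widths[ix]) + (length(ix) - 1L) * 4000L
    }, 0L)
    # a minimum 3 Kb gap between units keeps separately planted peaks
    # from fusing into one called segment
    min_gap <- 3000L
    free <- contigs[ci] - sum(unit_lens) - 60000L -
      min_gap * (length(uix) + 1L)
    if (free <= 0) stop("contig too small for planted peaks")
    g <- rexp(length(uix) + 1L)
    gaps <- min_gap + floor(g / sum(g) * free)
    at <- 30000L
    for (k in seq_along(uix)) {
      at <- at + gaps[k]
      for (pk in units[[uix[k]]]) {
        pos[pk] <- at
        contig_ix[pk] <- ci
        at <- at + widths[pk] + 4000L
      }
      at <- at - 4000L
    }
  }

  mult <- matrix(1, nrow = cfg$n_peaks, ncol = ns,
                 dimnames = list(NULL, strains))
  sdp_bits <- vector("list", cfg$n_peaks)
  presence <- matrix(TRUE, cfg$n_peaks, ns)

  # shared presence pattern per compound cluster
  cluster_pattern <- lapply(seq_along(cluster_sizes), function(i)
    random_absent_pattern(ns, cfg$max_absent_strains))
  for (i in seq_len(cfg$n_peaks)) {
    cl <- classes[i]
    if (cl == "constant") next
    if (cl == "continuous") {
      causal <- runif(1) < cfg$frac_causal
      if (causal) {
        bits <- random_sdp_bits(ns)
        fold <- 2^runif(1, cfg$causal_fold_range[1], cfg$causal_fold_range[2])
        hi <- sample(c(0L, 1L), 1L)
        mult[i, ] <- ifelse(bits == hi, fold, 1)
        sdp_bits[[i]] <- bits
      } else {
        mult[i, ] <- rlnorm(ns, 0, cfg$strain_effect_sdlog)
      }
    } else {
      pres <- if (cl == "discrete_compound") {
        cluster_pattern[[cluster_of[i]]]
      } else {
        random_absent_pattern(ns, cfg$max_absent_strains)
      }
      presence[i, ] <- pres
      mult[i, ] <- as.numeric(pres)
      sdp_bits[[i]] <- canonical_bits(as.integer(!pres))
    }
  }

  # avoid accidental compound clusters: distinct discrete units closer
  # than 10 Kb with identical presence get one pattern resampled
  repeat {
    clash <- find_pattern_clash(contig_ix, pos, widths, classes, presence,
                                unit_of)
    if (is.null(clash)) break
    pres <- random_absent_pattern(ns, cfg$max_absent_strains)
    presence[clash, ] <- pres
    mult[clash, ] <- as.numeric(pres)
    sdp_bits[[clash]] <- canonical_bits(as.integer(!pres))
  }

  # causal flags for discrete peaks (cluster-level for compound)
  causal_flag <- !vapply(sdp_bits, is.null, TRUE)
  disc <- classes %in% c("discrete_simple", "discrete_compound")
  cluster_causal <- lapply(seq_along(cluster_sizes), function(i)
    runif(1) < cfg$frac_causal)
  for (i in which(disc)) {
    keep <- if (classes[i] == "discrete_compound") {
      cluster_causal[[cluster_of[i]]]
    } else {
      runif(1) < cfg$frac_causal
    }
    causal_flag[i] <- keep
  }

  gr <- GRanges(names(contigs)[contig_ix],
                IRanges(start = pos + 1L, width = widths))
  mcols(gr)$peak_id <- sprintf("true_%04d", seq_len(cfg$n_peaks))
  mcols(gr)$class <- classes
  mcols(gr)$cluster <- cluster_of
  mcols(gr)$causal <- causal_flag
  mcols(gr)$presence <- apply(presence, 1, function(p)
    paste(ifelse(p, "P", "A"), collapse = ""))
  mcols(gr)$sdp <- vapply(seq_len(cfg$n_peaks), function(i) {
    if (causal_flag[i] && !is.null(sdp_bits[[i]])) {
      sdp_letters(sdp_bits[[i]])
    } else NA_character_
  }, "")
  list(gr = gr, mult = mult, presence = presence, sdp_bits = sdp_bits,
       classes = classes)
}

# first discrete peak within 10 Kb of a discrete peak from another unit
# sharing its presence pattern, or NULL
find_pattern_clash <- function(contig_ix, pos, widths, classes, presence,
                               unit_of) {
  disc <- which(classes %in% c("discrete_simple", "discrete_compound"))
  if (length(disc) < 2L) return(NULL)
  for (a in disc) {
    for (b in disc) {
      if (b <= a || unit_of[a] == unit_of[b]) next
      if (contig_ix[a] != contig_ix[b]) next
      gap <- max(pos[a], pos[b]) -
        min(pos[a] + widths[a], pos[b] + widths[b])
      if (gap <= 10000L && all(presence[a, ] == presence[b, ])) {
        return(if (classes[b] == "discrete_simple") b else a)
      }
    }
  }
  NULL
}

random_sdp_bits <- function(ns) {
  repeat {
    bits <- rbinom(ns, 1L, 0.5)
    if (length(unique(bits)) == 2L) return(canonical_bits(bits))
  }
}

random_absent_pattern <- function(ns, max_absent) {
  n_abs <- sample(seq_len(max_absent), 1L)
  pres <- rep(TRUE, ns)
  pres[sample(ns, n_abs)] <- FALSE
  pres
}

plant_mask <- function(cfg, contigs, peaks) {
  out <- GRanges()
  for (ci in seq_along(contigs)) {
    nm <- names(contigs)[ci]
    pk <- peaks[as.character(seqnames(peaks)) == nm]
    made <- 0L
    tries <- 0L
    while (made < cfg$n_mask && tries < 200L) {
      tries <- tries + 1L
      w <- round(runif(1, cfg$mask_width_range[1], cfg$mask_width_range[2]))
      s <- round(runif(1, 1, contigs[ci] - w))
      cand <- GRanges(nm, IRanges(s, width = w))
      if (length(pk) == 0L ||
          length(findOverlaps(cand, pk + 1000L)) == 0L) {
        out <- suppressWarnings(c(out, cand))
        made <- made + 1L
      }
    }
  }
  sort(out)
}

plant_variants <- function(cfg, contigs, tp, strains) {
  ns <- cfg$n_strains
  gr <- tp$gr
  # haplotype blocks with their own SDPs
  blocks <- list()
  for (ci in seq_along(contigs)) {
    bnd <- c(0, cumsum(rexp(ceiling(contigs[ci] / cfg$block_bp) * 3,
                            1 / cfg$block_bp)))
    bnd <- bnd[bnd < contigs[ci]]
    blocks[[names(contigs)[ci]]] <- list(
      start = floor(bnd),
      sdp = lapply(seq_along(bnd), function(i) random_sdp_bits(ns)))
  }
  block_sdp <- function(contig, p) {
    b <- blocks[[contig]]
    i <- findInterval(p, b$start)
    b$sdp[[max(1L, i)]]
  }

  rows <- list()
  vid <- 0L
  add_variant <- function(contig, pos0, bits, type, causal) {
    vid <<- vid + 1L
    ref <- sample(c("A", "C", "G", "T"), 1L)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    if (type == "INDEL") alt <- paste0(ref, alt)
    if (type == "SV") { ref <- "REF"; alt <- "DEL" }
    alleles <- ifelse(bits == 0L, ref, alt)
    cand <- runif(1) < if (causal) 0.25 else 0.05
    row <- c(list(variant_id = sprintf("var_%05d", vid), contig = contig,
                  pos = as.integer(pos0), type = type),
             as.list(setNames(alleles, strains)),
             list(qtl_candidate = cand, causal = causal))
    rows[[length(rows) + 1L]] <<- row
  }

  # causal variants: inside the peak +/- 100 bp; the containing
  # haplotype block adopts the causal SDP
  for (i in seq_along(gr)) {
    if (!mcols(gr)$causal[i] || is.null(tp$sdp_bits[[i]])) next
    contig <- as.character(seqnames(gr))[i]
    lo <- max(0L, start(gr)[i] - 1L - 100L)
    hi <- min(contigs[contig] - 1L, end(gr)[i] + 100L - 1L)
    pos0 <- round(runif(1, lo, hi))
    type <- sample(c("SNP", "INDEL", "SV"), 1L, prob = c(0.9, 0.08, 0.02))
    add_variant(contig, pos0, tp$sdp_bits[[i]], type, TRUE)
    b <- blocks[[contig]]
    bi <- max(1L, findInterval(pos0, b$start))
    blocks[[contig]]$sdp[[bi]] <- tp$sdp_bits[[i]]
  }

  # decoys: block SDP with probability ld_fidelity, else uniform
  canon <- all_sdps(ns)
  for (k in seq_len(cfg$n_decoy_variants)) {
    ci <- sample(seq_along(contigs), 1L)
    contig <- names(contigs)[ci]
    pos0 <- round(runif(1, 0, contigs[ci] - 1))
    bits <- if (runif(1) < cfg$ld_fidelity) {
      block_sdp(contig, pos0)
    } else {
      canon[[sample(length(canon), 1L)]]
    }
    type <- sample(c("SNP", "INDEL", "SV"), 1L, prob = c(0.9, 0.08, 0.02))
    add_variant(contig, pos0, bits, type, FALSE)
  }

  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, check.names = FALSE, stringsAsFactors = FALSE)))
  df <- df[order(df$contig, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  df
}

plant_transcripts <- function(cfg, contigs, tp, design, strains) {
  gr <- tp$gr
  var_ix <- which(mcols(gr)$class != "constant")
  n_link <- round(cfg$frac_linked * length(var_ix))
  link_ix <- if (n_link > 0) sample(var_ix, n_link) else integer(0)

  n_free <- max(0L, cfg$n_transcripts - n_link)
  tx_contig <- character(0); tss <- integer(0); tx_w <- integer(0)
  mult_rows <- list(); linked_peak <- character(0)

  for (i in link_ix) {
    contig <- as.character(seqnames(gr))[i]
    mid <- floor((start(gr)[i] + end(gr)[i]) / 2)
    t0 <- mid + round(runif(1, -8000, 8000))
    t0 <- min(max(t0, 12000L), contigs[contig] - 20000L)
    tx_contig <- c(tx_contig, contig)
    tss <- c(tss, as.integer(t0))
    tx_w <- c(tx_w, as.integer(round(runif(1, 1000, 10000))))
    mult_rows[[length(mult_rows) + 1L]] <- tp$mult[i, ]
    linked_peak <- c(linked_peak, mcols(gr)$peak_id[i])
  }
  for (k in seq_len(n_free)) {
    ci <- sample(seq_along(contigs), 1L)
    tx_contig <- c(tx_contig, names(contigs)[ci])
    tss <- c(tss, as.integer(round(runif(1, 12000, contigs[ci] - 20000))))
    tx_w <- c(tx_w, as.integer(round(runif(1, 1000, 10000))))
    mult_rows[[length(mult_rows) + 1L]] <- rep(1, cfg$n_strains)
    linked_peak <- c(linked_peak, NA_character_)
  }

  n_tx <- length(tss)
  strand <- sample(c("+", "-"), n_tx, replace = TRUE)
  # interval runs downstream of the TSS on the annotated strand
  starts <- ifelse(strand == "+", tss, pmax(1L, tss - tx_w + 1L))
  transcripts <- GRanges(tx_contig, IRanges(start = starts + 1L,
                                            width = tx_w),
                         strand = strand)
  mcols(transcripts)$tx_id <- sprintf("tx_%04d", seq_len(n_tx))
  mcols(transcripts)$tss <- as.integer(tss)   # 0-based TSS position
  mcols(transcripts)$polyA <- "plus"

  counts <- matrix(0L, n_tx, nrow(design),
                   dimnames = list(mcols(transcripts)$tx_id,
                                   design$sample_id))
  size <- if (cfg$nb_dispersion > 0) 1 / cfg$nb_dispersion else Inf
  for (j in seq_len(nrow(design))) {
    s_ix <- match(design$strain[j], strains)
    mu <- cfg$tx_depth * vapply(mult_rows, function(m) m[s_ix], 0)
    mu <- pmax(mu, 0.5)   # absent-strain linked transcripts keep a floor
    counts[, j] <- if (is.finite(size)) {
      rnbinom(n_tx, size = size, mu = mu)
    } else rpois(n_tx, mu)
  }
  linked <- data.frame(peak_id = linked_peak,
                       tx_id = mcols(transcripts)$tx_id,
                       stringsAsFactors = FALSE)
  linked <- linked[!is.na(linked$peak_id), , drop = FALSE]
  list(transcripts = transcripts, counts = counts, linked = linked)
}

plant_annotations <- function(cfg, contigs, peaks) {
  is_var <- mcols(peaks)$class != "constant"
  pick <- function(ix, p) ix[runif(length(ix)) < p]
  enh <- sort(c(pick(which(is_var), 0.6), pick(which(!is_var), 0.15)))
  pro <- sort(c(pick(which(is_var), 0.1), pick(which(!is_var), 0.4)))
  con <- pick(seq_along(peaks), 0.3)
  jitter_gr <- function(ix) {
    if (!length(ix)) return(GRanges())
    g <- peaks[ix] + 300L
    GenomicRanges::trim(g)
  }
  rand_gr <- function(n, w) {
    ci <- sample(seq_along(contigs), n, replace = TRUE)
    s <- vapply(ci, function(i) round(runif(1, 1, contigs[i] - w)), 0)
    GRanges(names(contigs)[ci], IRanges(s, width = w))
  }
  list(conservation = sort(c(jitter_gr(con), rand_gr(50L, 2000L))),
       enhancer = sort(reduce(jitter_gr(enh))),
       promoter = sort(reduce(jitter_gr(pro))))
}

simulate_coverage <- function(cfg, contigs, tp, mask, design, strains) {
  gr <- tp$gr
  size <- if (cfg$nb_dispersion > 0) 1 / cfg$nb_dispersion else Inf
  coverage <- vector("list", nrow(design))
  names(coverage) <- design$sample_id
  for (j in seq_len(nrow(design))) {
    s_ix <- match(design$strain[j], strains)
    per_contig <- list()
    for (ci in seq_along(contigs)) {
      nm <- names(contigs)[ci]
      len <- contigs[ci]
      mu_bg <- rep(cfg$background_rate, len)
      mk <- mask[as.character(seqnames(mask)) == nm]
      for (k in seq_along(mk)) {
        mu_bg[start(mk)[k]:end(mk)[k]] <- cfg$background_rate *
          cfg$repeat_boost
      }
      x <- if (is.finite(size)) {
        rnbinom(len, size = size, mu = mu_bg)
      } else rpois(len, mu_bg)
      pk <- which(as.character(seqnames(gr)) == nm)
      for (i in pk) {
        m <- tp$mult[i, s_ix]
        if (m == 0) next   # lost peak: the strain keeps plain background
        mu_in <- cfg$background_rate * (1 + (cfg$peak_enrichment - 1) * m)
        idx <- start(gr)[i]:end(gr)[i]
        # one gamma factor per sample x peak: summed counts are NB
        g <- if (is.finite(size)) rgamma(1, shape = size, rate = size) else 1
        x[idx] <- rpois(length(idx), mu_in * g)
      }
      storage.mode(x) <- "integer"
      per_contig[[nm]] <- x
    }
    coverage[[j]] <- per_contig
  }
  coverage
}
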
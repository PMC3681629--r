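# File formats: bedGraph coverage, BED intervals, variant TSV,
# transcript GTF, count TSVs.  Coordinates are 0-based half-open
# internally; conversion happens only at these boundaries (BED and
# bedGraph are already 0-based half-open, POS in the variant table and
# GTF coordinates are 1-based).

coverage_to_granges <- function(x, contig) {
  r <- rle(as.numeric(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  gr <- GRanges(contig, IRanges(starts, ends))
  mcols(gr)$score <- r$values
  gr
}

write_bedgraph <- function(coverage_sample, path) {
  grl <- lapply(names(coverage_sample), function(nm)
    coverage_to_granges(coverage_sample[[nm]], nm))
  gr <- suppressWarnings(do.call(c, grl))
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

read_bedgraph <- function(path, contigs) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) > 1L) {
    ov <- findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
    if (length(ov)) stop("overlapping intervals in ", path)
  }
  out <- lapply(names(contigs), function(nm) {
    g <- gr[as.character(seqnames(gr)) == nm]
    g <- g[order(start(g))]
    len <- contigs[[nm]]
    if (length(g) == 0L) return(integer(len))
    # expand run-length intervals; uncovered gaps are zero coverage
    st <- start(g); en <- end(g); sc <- as.integer(mcols(g)$score)
    gap_st <- c(1L, en + 1L)
    gap_en <- c(st - 1L, len)
    keep <- gap_en >= gap_st
    all_st <- c(st, gap_st[keep])
    all_sc <- c(sc, integer(sum(keep)))
    all_w <- c(en - st + 1L, gap_en[keep] - gap_st[keep] + 1L)
    o <- order(all_st)
    x <- rep(all_sc[o], all_w[o])
    if (length(x) != len) stop("intervals do not tile ", nm, " in ", path)
    x
  })
  names(out) <- names(contigs)
  out
}

write_bed <- function(gr, path, names = NULL, scores = NULL) {
  g <- granges_strip(gr)
  mcols(g)$name <- rep_len(if (is.null(names)) "." else names,
                           length(g))
  mcols(g)$score <- rep_len(if (is.null(scores)) 0 else scores,
                            length(g))
  rtracklayer::export(g, path, format = "BED")
  invisible(path)
}

granges_strip <- function(gr) {
  GRanges(seqnames(gr), IRanges(start(gr), end(gr)), strand = strand(gr))
}

#' Write called peaks as BED6 plus an exact-score TSV
#'
#' The BED score column is `round(10 * segment score)` capped at 1000;
#' the companion TSV keeps exact floating-point scores.
#'
#' @param peaks `GRanges` with `score` and either `sample_id` or
#'   `peak_id` metadata.
#' @param path Output BED path; the TSV is written next to it with
#'   extension `.tsv`.
#' @return Invisibly, the BED path.
#' @export
write_peaks_bed <- function(peaks, path) {
  nm <- mcols(peaks)$peak_id %||% mcols(peaks)$sample_id %||% "."
  sc <- mcols(peaks)$score %||% rep(0, length(peaks))
  write_bed(peaks, path, names = nm, scores = pmin(1000, round(10 * sc)))
  df <- data.frame(contig = as.character(seqnames(peaks)),
                   start = start(peaks) - 1L, end = end(peaks),
                   name = nm, score = sc)
  write_tsv(df, sub("\\.bed$", ".tsv", path))
  invisible(path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE, comment.char = "", ...)
}

write_variants_tsv <- function(variants, path, strains) {
  df <- variants
  df$POS <- df$pos + 1L
  keep <- c("variant_id", "contig", "POS", "type", strains,
            intersect("qtl_candidate", names(df)))
  names(df)[names(df) == "contig"] <- "CHROM"
  keep[keep == "contig"] <- "CHROM"
  write_tsv(df[, keep, drop = FALSE], path)
}

read_variants_tsv <- function(path) {
  df <- read_tsv(path)
  need <- c("CHROM", "POS", "type")
  if (!all(need %in% names(df))) {
    stop("variant table must have CHROM, POS, type columns")
  }
  df$contig <- df$CHROM
  df$pos <- as.integer(df$POS) - 1L
  df$CHROM <- df$POS <- NULL
  df
}

write_transcripts_gtf <- function(transcripts, path) {
  g <- granges_strip(transcripts)
  mcols(g)$type <- "transcript"
  mcols(g)$source <- "dhsvar"
  mcols(g)$gene_id <- mcols(transcripts)$tx_id
  mcols(g)$transcript_id <- mcols(transcripts)$tx_id
  rtracklayer::export(g, path, format = "gtf")
  invisible(path)
}

read_transcripts_gtf <- function(path) {
  g <- rtracklayer::import(path, format = "gtf")
  g <- g[mcols(g)$type == "transcript"]
  mcols(g)$tx_id <- mcols(g)$transcript_id
  # TSS: leftmost base on '+', rightmost on '-' (0-based)
  mcols(g)$tss <- ifelse(as.character(strand(g)) == "-",
                         end(g) - 1L, start(g) - 1L)
  mcols(g)$polyA <- "plus"
  g[, c("tx_id", "tss", "polyA")]
}

read_bed_granges <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Write a simulated dataset to a fixture directory
#'
#' Emits one bedGraph per sample, the mappability mask and annotation
#' sets as BED, the variant table as TSV, transcripts as GTF with a
#' count TSV, the design and contig tables, ground-truth tables under
#' `truth/` (kept apart so analysis stages read only the inputs), and
#' a JSON manifest with an md5 checksum per file.
#'
#' @param dataset A `dhs_dataset` from [simulate_dataset()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
write_fixture <- function(dataset, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create ", outdir)
  dir.create(file.path(outdir, "coverage"), showWarnings = FALSE)
  dir.create(file.path(outdir, "truth"), showWarnings = FALSE)
  strains <- unique(dataset$design$strain)

  for (s in names(dataset$coverage)) {
    write_bedgraph(dataset$coverage[[s]],
                   file.path(outdir, "coverage", paste0(s, ".bedGraph")))
  }
  write_bed(dataset$mask, file.path(outdir, "mask.bed"))
  for (nm in names(dataset$annotations)) {
    write_bed(dataset$annotations[[nm]],
              file.path(outdir, paste0(nm, ".bed")))
  }
  write_variants_tsv(dataset$variants, file.path(outdir, "variants.tsv"),
                     strains)
  write_transcripts_gtf(dataset$transcripts,
                        file.path(outdir, "transcripts.gtf"))
  write_tsv(data.frame(tx_id = rownames(dataset$tx_counts),
                       dataset$tx_counts, check.names = FALSE),
            file.path(outdir, "tx_counts.tsv"))
  write_tsv(dataset$design, file.path(outdir, "design.tsv"))
  write_tsv(data.frame(contig = names(dataset$contigs),
                       length = as.integer(dataset$contigs)),
            file.path(outdir, "contigs.tsv"))

  tr <- dataset$truth
  truth_df <- data.frame(peak_id = mcols(tr$peaks)$peak_id,
                         contig = as.character(seqnames(tr$peaks)),
                         start = start(tr$peaks) - 1L,
                         end = end(tr$peaks),
                         class = mcols(tr$peaks)$class,
                         cluster = mcols(tr$peaks)$cluster,
                         causal = mcols(tr$peaks)$causal,
                         presence = mcols(tr$peaks)$presence,
                         sdp = mcols(tr$peaks)$sdp)
  write_tsv(cbind(truth_df, as.data.frame(tr$multipliers,
                                          check.names = FALSE)),
            file.path(outdir, "truth", "peaks.tsv"))
  write_tsv(tr$linked, file.path(outdir, "truth", "linked_pairs.tsv"))

  files <- list.files(outdir, recursive = TRUE)
  files <- setdiff(files, "manifest.json")
  sums <- tools::md5sum(file.path(outdir, files))
  manifest <- list(format_version = 1L,
                   files = as.list(setNames(unname(sums), files)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a fixture directory back into a dataset
#'
#' Inverse of [write_fixture()]; the ground truth under `truth/` is
#' loaded only when `with_truth = TRUE`.
#'
#' @param dir Fixture directory.
#' @param with_truth Also load the ground-truth tables.
#' @return A `dhs_dataset` list.
#' @export
read_fixture <- function(dir, with_truth = FALSE) {
  ct <- read_tsv(file.path(dir, "contigs.tsv"))
  contigs <- setNames(as.integer(ct$length), ct$contig)
  design <- read_tsv(file.path(dir, "design.tsv"))
  coverage <- lapply(design$sample_id, function(s)
    read_bedgraph(file.path(dir, "coverage", paste0(s, ".bedGraph")),
                  contigs))
  names(coverage) <- design$sample_id
  txc <- read_tsv(file.path(dir, "tx_counts.tsv"))
  tx_counts <- as.matrix(txc[, -1, drop = FALSE])
  rownames(tx_counts) <- txc$tx_id
  ann_files <- c("conservation", "enhancer", "promoter")
  annotations <- lapply(ann_files, function(nm) {
    f <- file.path(dir, paste0(nm, ".bed"))
    if (file.exists(f)) read_bed_granges(f) else GRanges()
  })
  names(annotations) <- ann_files
  out <- list(design = design, contigs = contigs, coverage = coverage,
              mask = read_bed_granges(file.path(dir, "mask.bed")),
              variants = read_variants_tsv(file.path(dir, "variants.tsv")),
              transcripts = read_transcripts_gtf(
                file.path(dir, "transcripts.gtf")),
              tx_counts = tx_counts, annotations = annotations)
  if (with_truth) {
    tp <- read_tsv(file.path(dir, "truth", "peaks.tsv"))
    gr <- GRanges(tp$contig, IRanges(tp$start + 1L, tp$end))
    strains <- unique(design$strain)
    for (col in c("peak_id", "class", "cluster", "causal", "presence",
                  "sdp")) {
      mcols(gr)[[col]] <- tp[[col]]
    }
    out$truth <- list(peaks = gr,
                      multipliers = as.matrix(tp[, strains, drop = FALSE]),
                      linked = read_tsv(file.path(dir, "truth",
                                                  "linked_pairs.tsv")))
  }
  structure(out, class = "dhs_dataset")
}
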
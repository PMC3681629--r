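# End-to-end orchestration: peak calling -> variability -> class ->
# association -> transcripts -> enrichment, with deterministic outputs
# and a JSON summary.

#' Pipeline run configuration
#'
#' Collects the tunable thresholds of every stage with the defaults
#' used throughout the analysis: stringency `p = 4` and a 50 Kb
#' local-mean window for peak calling, variable-peak FDR levels of 10%
#' and 1%, a 0.1 absence ratio with a 0.95 background quantile for
#' presence calls, 10 Kb compound clustering, a 100 bp variant window
#' with 5% FDR for SDP association, 10 Kb / 0.05 for transcript
#' linkage, and a 1e-5 motif p-value threshold.  The `mapq_dnase` and
#' `mapq_rna` read filters (2 and 15) apply upstream of this package
#' when aligning real data; they are recorded here so a run's
#' provenance documents them.
#'
#' @param ... Overrides for any default field.
#' @return List of class `dhs_run_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(p = 4, window = 50000, y_floor = -8, min_score = 5,
              fdr_variable = 0.10, fdr_strict = 0.01,
              nonvar_pvalue = 0.5,
              absence_ratio = 0.1, background_quantile = 0.95,
              cluster_bp = 10000,
              assoc_window = 100, assoc_fdr = 0.05,
              scan_grid = c(0, 100, 1000, 5000, 10000, 25000, 50000,
                            100000),
              tx_fdr = 0.05, tx_window = 10000, cor_alpha = 0.05,
              motif_pthresh = 1e-5,
              mapq_dnase = 2, mapq_rna = 15,
              seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$p > 0, cfg$window > 1,
            cfg$fdr_variable > 0, cfg$fdr_variable < 1,
            cfg$fdr_strict > 0, cfg$fdr_strict <= cfg$fdr_variable,
            cfg$assoc_fdr > 0, cfg$assoc_fdr < 1)
  class(cfg) <- "dhs_run_config"
  cfg
}

stage_msg <- function(stage, ...) {
  message(sprintf("[dhsvar:%s] %s", stage, paste0(...)))
}

#' Run the full analysis pipeline on a dataset
#'
#' Executes peak calling on every sample, mappability filtering,
#' cross-sample consolidation, counting, the between-strain
#' variability test with heritability, presence/absence
#' classification of the strictly variable set, SDP association with
#' a distance scan, transcript variability and linkage, and feature /
#' QTL-candidate enrichment.  All stage tables are written to
#' `outdir` as TSV together with a JSON summary and a provenance
#' record; no stage reads the dataset's ground truth.
#'
#' @param dataset A `dhs_dataset` (from [simulate_dataset()] or
#'   [read_fixture()]).
#' @param outdir Results directory (created if needed); `NULL` skips
#'   writing.
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all stage results and the summary.
#' @export
run_pipeline <- function(dataset, outdir = NULL,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "dhs_run_config"))
  strain <- dataset$design$strain
  run <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  stage_msg("callpeaks", "calling peaks on ", length(dataset$coverage),
            " samples")
  per_sample <- run("callpeaks", {
    lapply(names(dataset$coverage), function(s) {
      pk <- GRanges()
      for (nm in names(dataset$contigs)) {
        mp <- mappable_vector(nm, dataset$contigs[[nm]], dataset$mask)
        pk <- suppressWarnings(
          c(pk, call_peaks(dataset$coverage[[s]][[nm]], contig = nm,
                           p = config$p, window = config$window,
                           mappable = mp, y_floor = config$y_floor,
                           min_score = config$min_score,
                           sample_id = s)))
      }
      filter_mappability(pk, dataset$mask)
    })
  })
  names(per_sample) <- names(dataset$coverage)

  stage_msg("consolidate", "merging across samples")
  peaks <- run("consolidate", consolidate_peaks(per_sample))

  stage_msg("diffpeaks", length(peaks), " consolidated peaks")
  counts <- run("counts", count_in_peaks(peaks, dataset$coverage))
  sf <- run("counts", size_factors(counts))
  vres <- run("diffpeaks",
              test_strain_variability(counts, strain, sf = sf,
                                      fdr_levels = c(config$fdr_variable,
                                                     config$fdr_strict)))
  var_col <- sprintf("variable_fdr%02d", round(100 * config$fdr_strict))
  var_ix <- which(vres[[var_col]])
  var_peaks <- peaks[var_ix]
  nonvar_peaks <- peaks[vres$pvalue > config$nonvar_pvalue &
                          !vres$untestable]

  stage_msg("classify", length(var_peaks), " variable peaks at FDR ",
            config$fdr_strict)
  cls <- run("classify", {
    if (length(var_peaks)) {
      bg <- with_seed(config$seed,
                      background_quantiles(dataset$coverage, peaks, sf,
                                           strain = strain,
                                           prob = config$background_quantile))
      pres <- strain_presence(counts[var_ix, , drop = FALSE], strain,
                              sf = sf, background = bg[var_ix],
                              absence_ratio = config$absence_ratio)
      classify_peaks(var_peaks, pres, cluster_bp = config$cluster_bp)
    } else {
      data.frame(peak_id = character(), class = character(),
                 presence = character(), cluster = integer(),
                 degenerate = logical())
    }
  })

  stage_msg("associate", "SDP association, window ", config$assoc_window,
            " bp")
  assoc <- run("associate",
               associate_peak_variants(var_peaks, counts, strain,
                                       dataset$variants, sf = sf,
                                       window_bp = config$assoc_window,
                                       fdr = config$assoc_fdr))
  dscan <- run("associate",
               distance_scan(var_peaks, counts, strain, dataset$variants,
                             sf = sf, grid = config$scan_grid,
                             fdr = config$assoc_fdr))
  svs <- run("associate", sv_overlaps(var_peaks, dataset$variants))

  stage_msg("link-rna", nrow(dataset$tx_counts), " transcripts")
  txres <- run("link-rna",
               variable_transcripts(dataset$tx_counts, strain,
                                    fdr = config$tx_fdr))
  var_tx <- dataset$transcripts[
    match(txres$tx_id[txres$variable], mcols(dataset$transcripts)$tx_id)]
  links <- run("link-rna", {
    if (length(var_peaks) && length(var_tx)) {
      link_transcripts(var_peaks, counts, var_tx, dataset$tx_counts,
                       strain, sf_peak = sf,
                       window_bp = config$tx_window,
                       alpha = config$cor_alpha)
    } else {
      data.frame(peak_id = character(), tx_id = character(),
                 distance = numeric(), r = numeric(), pvalue = numeric(),
                 linked = logical())
    }
  })
  prox <- run("link-rna", {
    if (length(var_peaks) && length(nonvar_peaks) && length(var_tx)) {
      proximity_table(var_peaks, nonvar_peaks, mcols(var_tx)$tss,
                      as.character(seqnames(var_tx)),
                      window_bp = config$tx_window)
    } else NULL
  })

  stage_msg("enrich", "feature and QTL-candidate contrasts")
  enr <- run("enrich", {
    if (length(var_peaks) && length(nonvar_peaks)) {
      feats <- lapply(names(dataset$annotations), function(nm)
        feature_enrichment(var_peaks, nonvar_peaks,
                           dataset$annotations[[nm]], feature_name = nm))
      names(feats) <- names(dataset$annotations)
      has_var <- function(pk) {
        gr <- GRanges(dataset$variants$contig,
                      IRanges(dataset$variants$pos + 1L, width = 1L))
        !is.na(findOverlaps(pk + config$assoc_window, gr,
                            select = "first"))
      }
      feats$variants <- feature_enrichment(has_var(var_peaks),
                                           has_var(nonvar_peaks),
                                           feature_name = "variants")
      list(features = feats,
           qtl = qtl_candidate_enrichment(var_peaks, nonvar_peaks,
                                          dataset$variants,
                                          window_bp = config$assoc_window))
    } else NULL
  })

  summary <- list(
    n_samples = nrow(dataset$design),
    n_peaks_per_sample = vapply(per_sample, length, 0L),
    n_consolidated = length(peaks),
    n_variable = setNames(
      c(sum(vres[[sprintf("variable_fdr%02d",
                          round(100 * config$fdr_variable))]]),
        length(var_peaks)),
      paste0("fdr", round(100 * c(config$fdr_variable,
                                  config$fdr_strict)))),
    frac_variable = length(var_peaks) / max(1L, length(peaks)),
    mean_h2_variable = if (length(var_ix)) mean(vres$h2[var_ix]) else NA,
    class_counts = as.list(table(cls$class)),
    n_assoc_significant = length(unique(assoc$peak_id[assoc$significant])),
    distance_scan = dscan,
    n_variable_tx = sum(txres$variable),
    n_linked_pairs = sum(links$linked),
    proximity = if (!is.null(prox)) {
      list(table = as.vector(prox$table), pvalue = prox$pvalue)
    } else NULL,
    enrichment = if (!is.null(enr)) {
      lapply(enr$features, function(f)
        list(pct_variable = f$pct_variable,
             pct_comparison = f$pct_comparison, log10p = f$log10p))
    } else NULL,
    qtl_pvalue = if (!is.null(enr)) enr$qtl$pvalue else NULL)

  res <- list(per_sample_peaks = per_sample, peaks = peaks,
              counts = counts, size_factors = sf, variability = vres,
              classes = cls, association = assoc, distance_scan = dscan,
              sv_overlaps = svs, transcripts = txres, links = links,
              proximity = prox, enrichment = enr, summary = summary,
              config = config)

  if (!is.null(outdir)) write_results(res, peaks, outdir, config)
  invisible(res)
}

write_results <- function(res, peaks, outdir, config) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_peaks_bed(peaks, file.path(outdir, "peaks.bed"))
  peak_tab <- cbind(data.frame(contig = as.character(seqnames(peaks)),
                               start = start(peaks) - 1L,
                               end = end(peaks)),
                    res$variability)
  write_tsv(peak_tab, file.path(outdir, "variability.tsv"))
  write_tsv(res$classes, file.path(outdir, "classes.tsv"))
  write_tsv(res$association, file.path(outdir, "association.tsv"))
  write_tsv(res$distance_scan, file.path(outdir, "distance_scan.tsv"))
  write_tsv(res$transcripts, file.path(outdir, "transcripts.tsv"))
  write_tsv(res$links, file.path(outdir, "links.tsv"))
  jsonlite::write_json(res$summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "columns")
  prov <- list(package_version = as.character(utils::packageVersion("dhsvar")),
               r_version = R.version.string,
               config = unclass(config),
               config_hash = unname(tools::md5sum(
                 write_tsv(data.frame(
                   key = names(unclass(config)),
                   value = vapply(unclass(config), function(v)
                     paste(format(v), collapse = ","), "")),
                   file.path(outdir, "config.tsv")))),
               timestamp = "omitted-for-determinism")
  jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}
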
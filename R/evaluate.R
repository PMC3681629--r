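# Parameter-recovery evaluation of a pipeline run against the
# generator's ground truth.  Used by the package's own validation
# suite; analysis stages never see these tables.

#' Score a pipeline run against simulated ground truth
#'
#' Compares a [run_pipeline()] result with the `truth` slot of the
#' dataset it was run on and reports operating characteristics:
#' planted-peak recall, detection of planted variable peaks, class
#' label accuracy among detected variable peaks, recovery of planted
#' causal variants at the association FDR, empirical false-discovery
#' among reported associations (a reported variant counts as a true
#' association when its SDP equals the SDP of the peak's planted
#' effect -- variants sharing the causal SDP are statistically
#' indistinguishable from it), and power to recover planted
#' peak-transcript links.
#'
#' @param dataset A `dhs_dataset` carrying `truth`.
#' @param result The list returned by [run_pipeline()] on `dataset`.
#' @return List of metrics; fractions are in `[0, 1]`, `NA` when the
#'   denominator is empty.
#' @export
evaluate_run <- function(dataset, result) {
  tr <- dataset$truth$peaks
  peaks <- result$peaks
  v <- result$variability
  frac <- function(num, den) if (den > 0) num / den else NA_real_

  recall <- frac(sum(IRanges::overlapsAny(tr, peaks)), length(tr))

  hit <- findOverlaps(peaks, tr)
  map <- data.frame(
    peak_id = mcols(peaks)$peak_id[queryHits(hit)],
    true_id = mcols(tr)$peak_id[subjectHits(hit)],
    class = mcols(tr)$class[subjectHits(hit)],
    sdp = mcols(tr)$sdp[subjectHits(hit)],
    stringsAsFactors = FALSE)
  map$det <- v$variable_fdr01[match(map$peak_id, v$peak_id)]

  is_var <- map$class != "constant"
  det_variable <- frac(sum(map$det[is_var], na.rm = TRUE), sum(is_var))
  false_variable <- frac(sum(map$det[!is_var], na.rm = TRUE),
                         sum(!is_var))

  cls <- result$classes
  map$called <- cls$class[match(map$peak_id, cls$peak_id)]
  scored <- map[is_var & map$det %in% TRUE, , drop = FALSE]
  class_accuracy <- frac(sum(scored$called == scored$class,
                             na.rm = TRUE), nrow(scored))

  causal <- dataset$variants[dataset$variants$causal %in% TRUE, ,
                             drop = FALSE]
  sig <- result$association[result$association$significant, ,
                            drop = FALSE]
  causal_recovery <- frac(sum(causal$variant_id %in% sig$variant_id),
                          nrow(causal))
  true_sdp <- tapply(map$sdp, map$peak_id, function(s)
    paste(stats::na.omit(s), collapse = "|"))
  assoc_true <- vapply(seq_len(nrow(sig)), function(i) {
    ts <- true_sdp[sig$peak_id[i]]
    !is.na(ts) && nzchar(ts) && grepl(sig$sdp[i], ts, fixed = TRUE)
  }, TRUE)
  assoc_fdr <- frac(sum(!assoc_true), nrow(sig))

  lk <- dataset$truth$linked
  linked_power <- NA_real_
  if (nrow(lk)) {
    pk_of_true <- tapply(map$peak_id, map$true_id, `[`, 1)
    got <- paste(pk_of_true[lk$peak_id], lk$tx_id) %in%
      paste(result$links$peak_id[result$links$linked],
            result$links$tx_id[result$links$linked])
    linked_power <- mean(got)
  }

  list(peak_recall = recall,
       variable_detection = det_variable,
       variable_false_rate = false_variable,
       class_accuracy = class_accuracy,
       n_classified = nrow(scored),
       causal_recovery = causal_recovery,
       n_causal = nrow(causal),
       assoc_fdr = assoc_fdr,
       n_assoc_significant = nrow(sig),
       linked_power = linked_power,
       n_linked = nrow(lk))
}
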
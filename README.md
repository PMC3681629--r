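# dhsvar

Detection and genetic dissection of variable DNase I hypersensitive
sites (DHS) across inbred mouse strains.

DNase-seq maps open chromatin: regions where regulatory DNA is
accessible pile up aligned reads into peaks.  When the same cell type
is profiled in a panel of inbred strains, a minority of peaks differ
reproducibly between strains, and those differences — continuous
height changes, or outright loss of a site in some strains — can be
traced to sequence variants and to downstream transcription.  `dhsvar`
implements that whole analysis as a tested R package, for genomicists
who want either the individual statistical pieces or the end-to-end
pipeline, together with a ground-truthed simulator that measures how
well every stage actually works.

## The method in brief

* **Peak calling.**  With $X_j$ the coverage at base $j$ and $\mu$ the
  mean over mappable bases, coverage is locally adjusted,
  $W_j = \max(0, X_j - \overline{X}_{[j-L,j+L]} + \mu)$, and
  transformed to $Y_j = \log_2 W_j/(p\mu)$, so bases score positively
  only above $p$ times the mean and the score is independent of
  sequencing depth.  Peaks are the maximal high-scoring segments of
  $Y$ — intervals with positive sum exceeding that of every containing
  interval — found in linear time and verified against an exhaustive
  oracle.
* **Strain variability.**  Peak read counts (median-of-ratios
  normalized) are tested per peak with a negative-binomial
  likelihood-ratio test of strain effect (7 df), using a fitted
  mean–dispersion trend and an empirical-null rescaling that keeps
  the test calibrated at 2–3 replicates; Benjamini–Hochberg FDR at
  10% and 1%.  Heritability per peak is
  $h^2 = \tfrac{V_b/2}{V_w + V_b/2}$ from a one-way random-effects
  ANOVA on log counts with the unbalanced-design $n_0$.
* **Classification.**  A deterministic presence/absence rule (relative
  ratio plus background quantile) splits variable peaks into
  continuous, discrete, and compound-discrete (co-varying discrete
  peaks within 10 Kb sharing a presence pattern).
* **Association.**  Each di-allelic variant defines a strain
  distribution pattern (SDP; 127 canonical patterns for 8 strains).
  Variants within 100 bp of a variable peak are tested by regressing
  log peak heights on the SDP, with one genome-wide 5% FDR, plus a
  distance scan to 100 Kb and PWM motif disruption/creation calls with
  exact DP p-values at $P < 10^{-5}$.
* **Transcript linkage and enrichment.**  Strain-variable transcripts
  (same NB test), peak–transcript correlation within 10 Kb, and Fisher
  exact contrasts for features (conservation, enhancer/promoter
  chromatin, variant content) and QTL-candidate variants.

A full account of the model, parameter defaults and design choices is
in `vignettes/dhsvar-methods.Rmd`.

## Worked example

```r
library(dhsvar)

ds  <- simulate_dataset(simulation_config(rng_seed = 42))
res <- run_pipeline(ds, outdir = "results_demo")

res$summary$n_consolidated     # 300   peaks in the catalogue
res$summary$n_variable         # fdr10 94, fdr1 90 variable peaks
res$summary$class_counts       # continuous 63, discrete_simple 20,
                               # discrete_compound 7
round(res$summary$mean_h2_variable, 2)   # 0.76 mean heritability
res$summary$n_assoc_significant          # 70 peaks with an associated
                                         # variant at 5% FDR

evaluate_run(ds, res)[c("class_accuracy", "causal_recovery",
                        "assoc_fdr")]
# $class_accuracy 1        all recovered variable peaks correctly classed
# $causal_recovery 0.986   planted causal variants found at 5% FDR
# $assoc_fdr 0.056         false associations among reported ones
```

The numbers shown are from the run above (seed 42): the pipeline
consolidates the 19 samples' peaks into a catalogue, flags the
strain-variable subset with its heritabilities, classifies the mode of
variation, and associates peaks with the variants that were planted as
causal — recovering essentially all of them while keeping the
empirical false-discovery rate near the nominal 5%.

`results_demo/` then holds per-stage TSV tables (`variability.tsv`,
`classes.tsv`, `association.tsv`, `links.tsv`, ...), `peaks.bed`, a
`summary.json` and a provenance record.  A thin command-line wrapper
is installed at `inst/scripts/dhsvar.R`
(`Rscript dhsvar.R simulate|run|callpeaks ...`); every other stage is
an exported function.

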
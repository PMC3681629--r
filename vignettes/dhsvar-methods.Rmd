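---
title: "Detecting and dissecting variable DNase I hypersensitive sites across inbred mouse strains"
author: "dhsvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and dissecting variable DNase I hypersensitive sites across inbred mouse strains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

DNase I hypersensitive sites (DHS) mark open, regulatory chromatin.
When the same cell type is assayed in several inbred mouse strains,
most DHS look identical, but a minority differ reproducibly between
strains — in height, in shape, or by complete presence/absence.  This
package implements a complete, testable pipeline for that comparison:
it calls peaks from per-base coverage, finds peaks whose heights vary
heritably between strains, classifies the mode of variation, asks
which sequence variants could be causal via haplotype (strain
distribution pattern) association and motif disruption, relates
variable peaks to strain-variable transcripts, and tests enrichment
contrasts with exact contingency tests.  A synthetic-data generator
with full ground truth stands in for the original sequencing data, so
every stage's operating characteristics are measured, not assumed.

The study design emulated throughout is 19 samples over the eight
classical inbred strains (A/J, AKR/J, BALB/cJ, C3H/HeJ, C57BL/6J,
CBA/J, DBA/2J, LP/J; three replicates of A/J, C57BL/6J and CBA/J, two
of each other strain).

# Peak calling

Let $X_j$ be the aligned-read coverage at base $j$ and $\mu$ the mean
coverage over mappable bases.  Slow regional trends are removed by the
local-mean adjustment
$$W_j = \max\!\bigl(0,\; X_j - \overline{X}_{[j-L,\,j+L]} + \mu\bigr),$$
with the window truncated at contig ends.  This preserves the genome-
wide mean; a constant track is unchanged.  The adjusted coverage is
then transformed to
$$Y_j = \log_2\!\frac{W_j}{p\,\mu},$$
so a base scores positively only where adjusted coverage exceeds $p$
times the mean.  $Y$ is invariant to rescaling all counts (platform
depth cancels), and very high pile-ups contribute only
logarithmically.  Zero-$W$ bases are floored at a configurable minimum
(default $-8$) so that single empty bases cannot annihilate a segment.

Peaks are the *maximal high-scoring segments* of $Y$: intervals whose
score sum is positive and strictly exceeds the sum of every strictly
containing interval, with zero-sum extension ties broken toward the
shortest interval.  Writing $P$ for the prefix-sum walk of $Y$, an
interval $[m,n)$ qualifies exactly when $P_m$ is a running minimum of
the walk up to $m$, $P_n$ is a running maximum from $n$ on, and every
interior prefix value lies strictly between the two.  That
characterization yields a linear-time sweep (implemented in C++) whose
output is checked, in the test suite, against an exhaustive
all-intervals oracle.

Tunable parameters, with defaults:

* `p = 4` — stringency; adjusted coverage must exceed $4\mu$ to score
  positively.  Stability over $p \in [2, 8]$ is part of the design.
* `window = 50000` bases — local-mean window ($2L+1$); kilobase-scale
  windows remove replication-timing/copy-number trends without eating
  real peaks.
* `min_score = 5` — minimum cumulative $\log_2$ evidence per segment.
  The raw segment definition admits every positive-sum interval, so a
  single base with a handful of excess reads would qualify; requiring
  32-fold cumulative evidence keeps only well-supported sites.  On the
  default synthetic study this leaves roughly one spurious segment per
  megabase of pure-noise track.
* `y_floor = -8` — floor for $Y$ at zero adjusted coverage.

Peaks overlapping a low-mappability mask by one base or more are
discarded, and the remaining per-sample peaks are consolidated across
samples by interval union (the merging rule is a package choice; the
catalogue records contributing samples per merged peak).  Coordinates
are 0-based half-open internally, converted only at file boundaries.

# Between-strain variability and heritability

Reads are counted per consolidated peak and sample, normalized with
median-of-ratios size factors, and each peak is tested with a
negative-binomial likelihood-ratio test: a log-link model with one
mean per strain (size factors as offsets) against an intercept-only
model, referred to $\chi^2_{k-1}$ with $k = 8$ strains.  The NB
dispersion $\alpha$ (variance $\mu + \alpha\mu^2$) is held at a
mean–dispersion trend $\alpha(\mu) = a_0 + a_1/\mu$ fitted across
peaks from within-strain method-of-moments estimates.

Two numerical choices matter here:

* **Trend rather than per-peak maximum.**  Taking the maximum of the
  noisy per-peak estimate and the trend (the classical conservative
  choice) deflates the statistic: measured type-I error was 0.06–0.09
  at nominal 0.10.  The trend alone tracks the truth closely at this
  replicate depth.  The conservative variant remains available
  (`moderate = "max"`).
* **Empirical-null rescaling.**  With 19 observations and 8 fitted
  means, the $\chi^2$ approximation of the LRT drifts with
  dispersion.  Assuming most peaks are null, the lower quartile of
  the observed statistics is signal-free, so the statistics are
  rescaled to pin that quartile to the reference $\chi^2$ quartile —
  the genomic-control idea applied at the quartile rather than the
  median so that up to three quarters of peaks may carry signal
  before the correction becomes conservative.  Measured type-I error
  is then within the binomial 95% CI of nominal at 0.01 and 0.10
  across dispersions 0.01–0.5.  The correction is skipped below 100
  testable peaks.

Benjamini–Hochberg adjustment yields variable-peak calls at 10% and,
for the stricter working set, 1% FDR.

Heritability summarizes the degree of strain control per peak.  On
$\log_2(\text{normalized count} + 0.5)$ — the offset avoids
$\log 0$; the log scale makes the ANOVA's additive-noise assumption
tolerable — a one-way random-effects ANOVA with the unbalanced-design
coefficient $n_0 = (N - \sum_i n_i^2/N)/(k-1)$ gives
$V_w = \mathrm{MSW}$ and $V_b = \max\{0, (\mathrm{MSB} -
\mathrm{MSW})/n_0\}$, and
$$h^2 = \frac{V_b/2}{V_w + V_b/2},$$
with $h^2 = 0$ when both components vanish.  The simulation suite
confirms the estimator recovers generating values to within 0.05 for
between/within ratios from 0.5 to 8 under the 19-sample design.

# Classifying the mode of variation

The original classification was by eye; this package substitutes an
explicit rule.  A strain is *absent* at a peak when its mean
normalized count is (i) at most `absence_ratio` (default 0.1) of the
largest strain mean and (ii) at most a background threshold — the
0.95 quantile of per-strain mean normalized counts in width-matched,
peak-free intervals, so the threshold carries the same
replicate-number noise as the statistic it gates.  If even the
largest strain mean is at background, the peak is degenerate and all
strains are absent.  Variable peaks with mixed presence are
*discrete*; discrete peaks whose nearest discrete neighbour with an
identical presence pattern lies within 10 Kb chain into
*compound* clusters (single linkage); the rest are *continuous*.
Requiring identical patterns within a cluster (not mere co-location)
is a package decision: co-varying neighbours that lose the peak in
different strains are evidence of different underlying lesions.

# Haplotype association and motifs

A di-allelic variant partitions the eight strains into a binary
strain distribution pattern (SDP); a pattern and its complement are
equivalent, leaving $2^{7} - 1 = 127$ canonical patterns.  Letter
form writes `A` for strains sharing the first strain's allele, so a
variant private to A/J and LP/J reads `ABBBBBBA`.  Multi-allelic
variants are decomposed into one pattern per allele.

For every variable peak, each variant within 100 bp of the peak edges
(distance 0 inside) is tested by regressing sample-level
$\log_2$-normalized peak heights on the SDP indicator — 19
observations, two groups, pooled-variance $t$ test.  Sample level is
the default because replicates carry real information about
within-strain noise; strain-mean response is available.  P-values are
pooled across all peak×variant tests in a run and BH-adjusted at 5%
FDR, mirroring a single genome-wide screen.  Variants with identical
SDPs give identical tests; within real haplotype blocks they are
indistinguishable, which is why the evaluation counts a reported
variant as a true association whenever its SDP equals the planted
one.  The distance scan fixes the significant set at the largest
window (100 Kb) and reports, per window size, the fraction of
variable peaks with a significant variant within that distance — a
monotone curve whose rise with distance on decoy-dense fixtures
reproduces the chance-association caveat of long-range haplotype
mapping.

Motif analysis scores sequences against count-derived position weight
matrices ($\log_2$ odds over a background composition, pseudocount
0.1).  Significance uses the exact null distribution of the
discretized score (bin width $10^{-3}$), computed by dynamic
programming over motif positions and validated against $4^w$
enumeration for widths up to 6; observed scores are computed on the
same discretized scale, so the tail probabilities are exact rather
than approximate.  Hits require $P < 10^{-5}$; both strands are
scanned (the reverse-complement matrix has its own null distribution,
since backgrounds need not be strand-symmetric); ambiguous bases
contribute their background-expected score.  A variant *disrupts* a
motif when a hit overlapping its footprint exists with the
reference-like allele but not the alternate, and *creates* one in the
converse case.

# Transcript linkage

Transcript counts go through the same NB strain test (5% FDR).  Each
variable peak is paired with variable transcripts whose start lies
within 10 Kb (distance from peak midpoint; 0 if the start is inside
the peak), and the pair is scored by Pearson correlation of
strain-mean $\log_2$ abundances — eight points, because replicate
noise is not shared between assays from different animals; Spearman
and sample-level modes are flags.  Pairs with uncorrected $P < 0.05$
are "linked"; the expected false-link count (5% of pairs tested) is
deliberately reported rather than corrected away, matching the
screen's exploratory character.  A 2×2 proximity contrast (variable
vs comparison peaks, within vs beyond 10 Kb of a variable transcript
start) is tested with the Fisher exact test.

# Enrichment contrasts

Feature enrichment tables (conservation, enhancer- and promoter-like
chromatin by ≥1 bp interval overlap; variant presence within 100 bp)
and the QTL-candidate-variant contrast are tested two-sided by the
probability-ordering Fisher exact test; odds ratios are the sample
$ad/bc$.  A variant near both peak sets is tallied in both, as each
set is counted independently.

# The synthetic study

The generator plants what the analysis is meant to find, at a
miniature scale (2 contigs × 2 Mb, 300 peaks, 19 samples) chosen so
the full pipeline runs in about a minute:

* **Coverage.**  Background is NB with mean 1 read/base and
  dispersion $\alpha = 0.05$.  Within a peak, each sample draws one
  gamma factor and Poisson counts around it, so per-base margins are
  NB *and* peak-level sums are NB$(w\mu, \alpha)$ — exactly the model
  the variability test fits.  Independent per-base NB draws would sum
  to quasi-Poisson counts with no biological replicate noise left to
  test against.  $\alpha = 0.05$ (replicate CV ≈ 22%) sits between
  the canonical ~0.1 CV of genetically identical model organisms and
  human-cohort values, appropriate for same-strain animals assayed
  separately.
* **Peaks.**  300 peaks of 150–600 bp, 12-fold enriched when fully
  present; 30% variable, of which 30% discrete (1–3 strains lose the
  peak entirely and revert to plain background), of which 30% sit in
  compound clusters of 2–3 sharing one presence pattern within 10 Kb.
  The real-data proportions (≈10% variable, 14% of those discrete)
  are outcomes measured on 25,700 peaks; at 300-peak scale they would
  leave the discrete and compound classes nearly empty, so the
  defaults populate every class enough to measure recovery.
  Continuous non-causal peaks draw log-normal strain multipliers
  (sdlog 0.5); causal peaks are two-level with 2–4-fold effects.
* **Variants.**  80% of variable peaks carry a causal variant within
  the peak ±100 bp whose SDP equals the peak's effect pattern.  Decoys
  (3000) fall into haplotype blocks (mean 30 Kb) and inherit the
  block SDP with probability 0.8, else draw uniformly from the 127
  canonical patterns; blocks containing a causal variant adopt its
  SDP, reproducing the identical-SDP-neighbourhood structure of
  inbred genomes.  QTL-candidate flags are planted at 25% on causal
  and 5% on decoy variants.
* **Transcripts and annotations.**  Half the variable peaks get a
  transcript whose start lies within 10 Kb and whose NB counts share
  the peak's strain multipliers; the rest are flat decoys at depth
  100.  Enhancer-like intervals preferentially cover variable peaks,
  promoter-like intervals non-variable ones, so enrichment directions
  are known.  A mappability mask with 3× pile-up emulates multi-copy
  sequence.

What the generator does *not* emulate: read-level artifacts
(alignment, duplicates, DNase cut-site sequence bias), peak shape
(peaks are rectangles), trans-acting effects, and correlated noise
between the DNase and RNA assays.  Passing tests therefore
demonstrate correctness of the statistical machinery under its own
assumptions and calibrated behaviour under NB noise — not performance
on any particular real dataset, whose depth, dispersion and haplotype
structure the defaults only approximate.  Ground truth is stored
apart from the inputs (`truth/` in fixtures) and no analysis stage
reads it.

# Degenerate inputs and numerical conventions

All-zero tracks and zero-coverage mappable sets are errors at
adjustment time; all-zero count rows are untestable with $p = 1$;
monomorphic variants have no SDP and are rejected; zero-variance
vectors make correlations undefined and are flagged rather than
scored.  Odds-ratio conventions: $ad/bc$ with `Inf` when only the
denominator product vanishes and `NaN` when both do.  Problem sizes
in the validation suite — 2000 null peaks for calibration, 1000
arrays for the segment oracle, 1000 peaks per heritability ratio,
$4^w$ enumeration to width 6 — were chosen to make Monte-Carlo error
small relative to the tolerances tested.

# Known limitations

* The consolidation rule (interval union) is the simplest defensible
  choice; closely spaced distinct sites merged in one sample merge in
  the catalogue.
* The empirical-null rescaling assumes ≥25% of peaks are null; on a
  dataset where most peaks vary it turns conservative.
* The LRT retains mild anticonservatism at dispersions well above the
  fitted trend when the empirical-null correction cannot be applied
  (fewer than 100 peaks).
* Motif effects are presence/absence of hits at $P < 10^{-5}$; score
  attenuation below threshold is not graded.
* The association test does not model replicate structure beyond the
  pooled-variance $t$; a mixed-model variant would be needed for
  designs with strong batch effects.
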
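---
title: "Methods: amplification-dependent driver-gene discovery on synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: amplification-dependent driver-gene discovery on synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampdriver)
```

## The problem

Recurrent somatic copy-number gains are a major route to oncogene
activation: a gene that is repeatedly amplified across tumors, *and* whose
mRNA rises with its DNA copy number, is a strong driver candidate. This
package implements that integrative discovery chain as a tested pipeline —
recurrent gain-region calling with permutation FDR control, a copy-number /
expression correlation filter, loss-of-function screen analytics,
knockdown differential expression, and survival relevance scoring — over a
synthetic-data generator that reproduces the statistical structure of
tumor-cohort inputs. Every stage is therefore testable end to end without
any external download.

## Recurrent region calling

**Statistic.** Segmented log2-ratio profiles are discretized onto a fixed
bin grid (length-weighted means, uncovered genome treated as diploid,
log2 = 0). The cohort recurrence statistic per bin is the rectified sum
$A(b) = \sum_s \max(\pm x_{sb}, 0)$ (gains and losses in separate passes),
so both the frequency and the amplitude of an aberration contribute.

**Scale space.** $A$ is smoothed with centered box kernels of half-widths
$\{0, 1, 2, 4, 8, 16\}$ bins (windows truncated and renormalised at
chromosome ends). Small scales localise focal events; large scales pick up
broad ones. Calls from all scales form a containment forest: the parent of
a region is the smallest strictly containing call, the nesting level
counts strict ancestors, and the *leaves* — calls with nothing nested
inside — are the most focal events. Identical intervals re-found at
several scales collapse to the smallest-scale call.

**Null model.** The permutation null cyclically shifts every sample's
binned profile within each chromosome by an independent uniform offset and
re-aggregates. This preserves each sample's per-chromosome value multiset
and its serial autocorrelation — the property that makes segmented noise
hard — while destroying cross-sample alignment, which is exactly the
signal. Offsets are drawn in R under the caller's seed; the inner loop is
compiled (Rcpp) so that 500 permutations of a 100 × 2,000 cohort cost
roughly a quarter of a second.

**Threshold rule.** For a threshold $t$, the estimated FDR is the mean
null count of maximal runs above $t$ divided by the observed run count.
Each scale receives an even share of the configured level (budget
$\alpha/K$ for $K$ scales) and uses the smallest $t$ whose estimate fits
its share; the reported $q$ is the scale-adjusted estimate. The split is
deliberate: applying the full level independently at every scale lets each
scale take its own shot at the null, and in our null-cohort simulations
the chance of *any* spurious call then reached roughly $K$ times the
nominal level, while the even split keeps the union of calls across the
scale space at the configured level (the property the analysis depends
on). Runs whose peak ties the threshold exactly are called (`>=`), which
keeps the caller deterministic.

Run counting uses an exact identity: for any threshold, the number of
maximal runs above it equals the number of plateau local maxima above it
minus the number of internal plateau minima above it. Pooling null extrema
across permutations makes the FDR curve computable for all candidate
thresholds with two sorted vectors, which is what makes 200-cohort
calibration runs affordable.

## The correlation filter

Genes inside focal (leaf, 1–100 genes) gain regions are tested for a
positive association between gene-level copy number — the length-weighted
mean log2 ratio over the gene body, robust to breakpoints inside genes —
and log2 expression. The test is Spearman rank correlation with average
ranks on ties and the two-sided t-approximation p-value; Benjamini–
Hochberg correction at FDR 0.1 is applied *within each cohort's tested
gene set* (the region-first design tests only genes pre-selected by the
genomic evidence, so that is the relevant multiplicity universe), and only
genes with $\rho > 0$ can pass. Per-cohort lists are merged by union with
provenance; an intersection merge is available for sensitivity analyses.

## Screen analytics

Plate readouts normalize to percent proliferation against the
non-targeting control mean within each (cell line, replicate) plate, which
makes the analysis invariant to plate-level scaling. A gene is a primary
hit when its replicate-mean percent proliferation is strictly below 60%
(the replicate mean, not each replicate, is thresholded; a per-replicate
rule is available as an option). Hits are filtered by copy-number-gain
frequency across a 20-line panel (gain or high gain in at least 8 lines)
and validated when the pooled siRNA inhibits proliferation by more than
50% in every tested line *and* at least 2 of the 4 single siRNAs achieve
more than 50% inhibition in at least 2 lines — the deconvolution rule that
guards against off-target pool effects.

## Knockdown differential expression

Counts are normalized with median-of-ratios size factors (reference genes:
positive counts in every sample). The per-gene test is a negative-binomial
Wald test built for desk scale: method-of-moments dispersion from the
pooled within-group variance, floored at 1e-8; log2 fold change of
knockdown over control group means with each mean floored at 0.5
normalized counts (avoids infinities at zero means); delta-method standard
error and a two-sided normal p-value. No shrinkage is applied to
dispersions or fold changes — the downstream filters operate on raw
p-values (< 0.05) and fold-change magnitude (> 1), with genes below
baseMean 10 (on normalized counts; a raw-count option exists) excluded
before testing, so the moment estimator is sufficient and keeps the module
dependency-free. Under a simulated null the Wald p-values are uniform to
Kolmogorov–Smirnov distance well under 0.1 (checked at 2,000 genes,
dispersion 0.1, 10 samples per group; the statistic is asymptotic, so
calibration is assessed at a sample size where the asymptotics are
meaningful). DEGs called in at least 2 of 3 cell lines per direction are
"common DEGs"; qPCR-style confirmation uses the standard
$2^{-\Delta\Delta C_T}$ quantity.

## Survival scoring

Kaplan–Meier curves, the logrank test and the hazard ratio come from the
`survival` package (product-limit estimator; observed-minus-expected with
hypergeometric variance; univariate proportional-hazards fit with Breslow
tie handling — the simplest deterministic convention, and the data are
continuous so ties are rare). The "best cutoff" dichotomization scans
candidate cutoffs at every score percentile from the 20th to the 80th and
returns the split minimizing the logrank p. That minimum is
anti-conservative by construction; it is reported with an explicit
`cutoff_optimized` flag and no further correction, matching how such
optimal-cutoff analyses are usually sourced. Signature scores are
unweighted means of a gene set's expression rows per patient.

## What the generator emulates — and what it does not

`sim_config()` fixes the study conditions; all randomness flows from one
root seed through named substreams (cohort, expression, screen, counts,
survival, coupling), so each generator is independently reproducible and
reruns are byte-identical.

* **Cohorts.** 100 samples; 2,000 bins of 100 kb on 4 chromosomes; three
  focal gain loci (each 4% of a chromosome, ~10 genes) carried with
  penetrance 0.6 at amplitude +1 log2 unit; background segments with
  geometric lengths (mean 20 bins) and segment-level Gaussian log2 noise
  (sd 0.3) — noise lives on segments, not bins, to mimic segmented input.
  Driver-gene expression is baseline + 1.0 × copy number + Gaussian(0.5);
  passengers are uncoupled. These scales keep a full cohort simulation plus
  region calling near one second on one CPU.
* **Screens.** Raw readout = control level × (1 − effect) × (1 + noise),
  multiplicative Gaussian noise sd 0.02 (duplicate concordance r > 0.95,
  in line with well-run SRB screens), 8 control wells, effects ~
  Uniform(0.45, 0.8) for drivers and Uniform(0, 0.2) for passengers.
* **Counts.** NB counts with log2-normal gene means, dispersion 0.1, true
  size factors in [0.7, 1.3], a designated responder set (7.5% of genes,
  |log2 effects| in [1, 2], active per line with probability 0.8 so lines
  share most but not all responders), and the knocked-down target itself
  down 2-fold and expressed at the typical level.
* **Survival.** Exponential event times with hazard
  $h_0 e^{\gamma\,\mathrm{score}}$ ($h_0$ = 0.02 events/month, $\gamma$ =
  log 2); censoring by an independent exponential time with rate
  $h_0\,c/(1-c)$, which yields exactly fraction $c$ censored when
  $\gamma = 0$ and approximately $c$ otherwise (rate 1 censors everyone).

Not emulated: realistic breakpoint processes, subclonal mixtures, batch
and GC effects, arm-level events, gene-length biases, inter-gene
expression correlation, and informative censoring. Passing tests therefore
demonstrate that the *statistical machinery* is correct and calibrated
under its stated model — not that real tumor cohorts satisfy that model.

## Numerical and degenerate-input conventions

Internal coordinates are 0-based half-open; SEG files on disk are 1-based
inclusive and converted at the IO boundary (BED-like gene tables are not
converted). Uncovered genome is diploid (log2 = 0). An all-zero cohort
yields an empty region list, not an error; constant vectors make Spearman
rho undefined (`NA` with a warning) and are excluded from the BH
adjustment; a survival group without events reports an `NA` hazard ratio
with a warning; a constant score cannot be split and errors. Fewer than
100 permutations triggers a warning because the FDR estimate's resolution
is 1/permutations.

## Problem sizes used by the test-suite calibrations

FDR calibrations average 200 simulated cohorts (50 samples × 2,000 bins
with 500 permutations for regions; 1,000 genes × 100 samples for the
correlation filter); end-to-end driver recovery averages 50 seeds at the
default generator settings; hazard-ratio recovery uses 200 replicates of
300 patients. These sizes put every Monte-Carlo standard error well below
the margins being tested while keeping the full suite inside a few
minutes.

## Known limitations

The region caller is a behavioral reconstruction of multi-scale recurrent
event calling, not a reimplementation of any specific published tool's
internals; its guarantees are those demonstrated by its own calibration
suite. The Wald test's moment dispersion is noisy at triplicate scale
(shrinkage-based tools are preferable for real data; the thresholds, not
the dispersion fit, are the operative filters here). The best-cutoff
p-value is intentionally uncorrected and must be read with its flag. The
merged candidate list treats cohorts symmetrically; no cross-cohort
heterogeneity modelling is attempted.
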
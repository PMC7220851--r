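# ampdriver

Amplification-dependent driver-gene discovery from somatic copy-number and
expression data, as a tested, reusable R pipeline.

Cancer genomes accumulate recurrent copy-number gains (CNGs), and a gene
that is both recurrently gained and expressed in proportion to its copy
number is a prime driver candidate. `ampdriver` implements the full
discovery chain that this reasoning implies, for analysts who want each
statistical step explicit, calibrated and testable:

1. **Recurrent region calling.** Segmented log2-ratio profiles are binned
   and aggregated into the rectified cohort statistic
   `A(b) = Σ_s max(±x_sb, 0)`, smoothed over a dyadic scale space of box
   kernels. Significance uses a cyclic-shift permutation null (which
   preserves each sample's per-chromosome value multiset and serial
   autocorrelation) and a run-count FDR estimator: the smallest threshold
   `t` with `E_null[#runs ≥ t] / #obs runs ≥ t` within the configured
   level, split evenly across scales. Calls form a containment forest
   whose leaves are the most focal events.
2. **Candidate selection.** Leaf gain regions spanning 1–100 genes are
   mapped to genes; each gene's length-weighted copy number is tested
   against its expression by Spearman rank correlation
   (t-approximation p), Benjamini–Hochberg corrected at FDR 0.1 within the
   tested set; genes with `rho > 0` that pass are candidates, merged
   across cohorts by union.
3. **Screen analytics.** siRNA proliferation readouts normalized to
   non-targeting controls (percent of control), primary hits at < 60%
   proliferation on the replicate mean, CNG-frequency filtering (gain in
   ≥ 8 of 20 lines), and deconvolution validation (pool > 50% inhibition
   in all lines plus ≥ 2 of 4 single siRNAs > 50%).
4. **Knockdown differential expression.** Median-of-ratios size factors, a
   negative-binomial Wald test with method-of-moments dispersion
   (baseMean ≥ 10), DEGs at `p < 0.05` and `|log2 FC| > 1`, and the
   ≥ 2-of-3-cell-lines common-DEG rule, plus `2^-ΔΔCT` qPCR
   quantification.
5. **Survival scoring.** Kaplan–Meier curves, logrank tests, hazard ratios
   (Cox, Breslow ties), best-cutoff dichotomization by minimum logrank p
   over the 20th–80th score percentiles (flagged as cutoff-optimized), and
   mean-expression signature scores.

A synthetic-data generator (`sim_config()`, `simulate_*()`) reproduces the
statistical structure of the inputs — recurrent focal gains with
configurable penetrance, copy-number-coupled expression, duplicate
screens, NB knockdown counts, survival with score-dependent hazard — so
the whole pipeline runs, and is tested, without any external data. See the
methods vignette (`vignettes/amplification-driver-discovery.Rmd`) for the
model details and design choices.

## Worked example

The analysis workflow is a sequence of thin drivers under `analysis/`
(shared seed in `analysis/00_config.R`), each running one pipeline stage
into `results/run/` and reporting what it found:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_call_regions.R
Rscript analysis/03_select_candidates.R
Rscript analysis/04_screen.R
Rscript analysis/05_knockdown_deg.R
Rscript analysis/06_survival.R
Rscript analysis/07_calibration.R
```

With the default configuration (two cohorts of 100 samples, 2,000 bins,
1,000 genes, three embedded gain loci at penetrance 0.6) this prints:

```
cohort A: 100 samples, 10711 segments, 3 driver loci containing 30 genes
cohort A: 16 gain regions (3 leaves, 16 overlapping a true locus), 0 loss regions
cohort A: 30 candidate genes (median rho 0.73)
merged: 30 unique candidates; 30/30 embedded driver genes recovered
LINE1: 30 primary hits
union 30, common 30; 30 pass the CNG-frequency filter
CL1: 1728 tested, 40 down / 58 up; target log2FC = -0.90 (p = 0.0024)
common DEGs: 33 down + 51 up = 84 total
score gene: G0064; 100 patients, 68 events
best cutoff 0.74: logrank p = 6.18e-06 (cutoff-optimized), HR = 3.24 [1.89, 5.54]
```

Reading: the caller finds exactly the three embedded loci as its focal
leaves (the 16 gain regions are their nested multi-scale envelopes, all
overlapping true loci); the correlation filter recovers all 30 genes
inside the loci and nothing else; every candidate behaves as a
proliferation driver in the simulated screen by construction of its
effect; knockdown of the target gene is detected at about 2-fold down;
and patients with high expression of the top validated driver relapse
about 3 times faster, as the simulated hazard (`γ = log 2` per score unit)
dictates. `07_calibration.R` summarizes the two FDR-controlled filters on
fresh cohorts (`results/calibration.tsv`).

The same run is available as a single call:

```r
library(ampdriver)
run_pipeline(pipeline_config(seed = 42), "results/run")
```

which records parameters, seeds and output digests in
`results/run/manifest.json`; reruns are byte-identical.

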
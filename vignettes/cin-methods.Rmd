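---
title: "Scoring chromosomal instability from low-coverage WGS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring chromosomal instability from low-coverage WGS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Non-muscle-invasive bladder cancer recurs in roughly a third to three
quarters of patients after transurethral resection, and the standard
clinicopathological risk factors (stage, grade, size, multifocality) predict
recurrence only weakly. Chromosomal instability (CIN) — the persistent gain
and loss of large genomic segments — is a genome-wide property of tumors
that can be read cheaply from low-coverage (~0.5x) whole-genome sequencing:
at that depth individual variants are invisible, but read depth in large
genomic windows tracks somatic copy number faithfully, even in degraded FFPE
DNA. `cinscore` implements the full analysis path from binned read counts to
a per-patient CIN score and its survival consequences.

## The model, stage by stage

**Binning.** The autosomes are tiled with fixed 200-kb windows (0-based,
half-open; the last bin of a chromosome may be short). Bins overlapping the
declared centromere interval are flagged and excluded everywhere downstream:
read mapping over centromeres is artifact-dominated, and excluding them also
guarantees that no segment ever spans the p/q boundary. Sex chromosomes are
excluded by default because a mixed-sex control panel makes their coverage
bimodal; a user can supply any genome model table to change this.

**Control-panel normalization.** For each bin, a panel of healthy-donor
profiles supplies a mean and standard deviation of raw coverage, and a tumor
bin is summarized as

$$Z_{bin} = \frac{\mathrm{cov}_{raw} - \mathrm{mean}(\mathrm{cov}_{controls})}
                 {\mathrm{stdev}(\mathrm{cov}_{controls})}.$$

The standard deviation uses the n−1 denominator (sample sd). Bins with zero
panel variance or zero panel mean carry no information about relative
coverage and are masked. No GC or mappability correction is applied: the
panel is assumed to share the tumor's capture biases, which is exactly the
structure the synthetic generator implants (a per-bin lognormal bias common
to every sample) and the leave-one-out calibration checks. A hook for a
LOESS GC corrector exists but is off by default.

**Quality gates.** Two gates mirror routine LC-WGS practice. A noise gate
computes the median absolute deviation of per-bin log2 coverage ratios
against the panel mean and fails samples whose MAD strictly exceeds 0.38.
Two choices deserve emphasis because conventions differ between pipelines:
the MAD here is *unscaled* (no 1.4826 consistency factor) and the log is
base 2; the 0.38 threshold is interpreted as operating on that raw value.
Zero-coverage bins receive a 0.5 pseudocount before the log. A metadata gate
requires at least 10 million reads, 85% of bases at Q30, and 70% uniquely
mapped reads, and reports every violated criterion, not just the first.

**Segmentation.** Z-profiles are segmented per chromosome arm by an in-house
circular binary segmentation: for the current interval, the arc maximizing
the circular two-sample pooled-t statistic against its complement is the
candidate split, accepted when its permutation p-value
$(1 + \#\{t^{perm} \ge t^{obs}\})/(1 + n_{perm})$ falls below `alpha` and
every resulting piece has at least `min_width` bins, then recursing.
Defaults are `alpha = 0.01`, `n_perm = 1000`, `min_width = 3` — common
practice for read-depth CBS; ties in the max-t search break toward the
smaller left then right index, so output is deterministic under a fixed
seed. The permutation loop stops early once enough exceedances have accrued
to make rejection certain, which changes no decision, only runtime. A
pruning pass merges adjacent segments whose means differ by less than
`merge_sd = 1.5` pooled within-segment standard deviations, playing the role
of DNAcopy's undo options. Segmentation operates on Z by default (so segment
means are in Z units and feed the score directly); log-ratios can be
segmented instead via the same functions.

**The CIN score.** Each segment contributes its length $L$ (in megabases)
times its mean bin Z. The score sums $L \times |Z_{seg}|$ over segments with
$|Z_{seg}| \ge 2$. Two conventions here are deliberate design choices, both
exposed as arguments: the absolute value prevents genome-wide gains and
losses from cancelling (CIN is a burden, not a net dosage), and the
$z_{min} = 2$ gate keeps copy-neutral noise segments from accumulating into
the score. Megabase units put cohort scores in the thousands — the scale on
which published CIN cutoffs (e.g. 6486.722) live. With `use_abs = FALSE`
and `z_min = 0` the score reduces to the plain signed sum.

**Arm scores and calls.** Per-arm Z is the mean of usable bin Z across the
arm; an arm is "positive" when its Z meets an externally supplied or
ROC-derived cutoff (boundary inclusive). CIN class is "high" when the score
is strictly above the cohort cutoff — the asymmetry (">" for CIN, ">=" for
arms) follows the wording conventions of the clinical literature the
defaults mirror, and both are stated in the function docs and pinned by
tests.

**Cutoff selection.** The cohort CIN cutoff is chosen by maximally selected
rank statistics: every midpoint between consecutive ordered unique scores
whose induced split leaves at least `eps = 0.1` of the cohort on each side
is a candidate; each candidate's standardized two-group log-rank statistic
is computed from log-rank (Savage) scores under the conditional permutation
distribution; the maximizing cutpoint wins (ties toward the smaller one).
Because the maximum over many correlated statistics is not chi-square
distributed, the selection-adjusted p-value uses the Lausen–Schumacher
improved Bonferroni bound over the candidate set; simulation shows it
conservative at the null (rejection rate ~2–4% at nominal 5% for n = 50),
which is the safe direction for a data-driven cutoff.

**Survival battery.** Kaplan–Meier curves use the product-limit estimator
with the "first time the curve reaches 0.5 or below" median rule (median
undefined when the curve never does — reported as not reached). The Cox
model is fit by partial likelihood with Efron tie handling and Wald 95% CIs;
non-convergence (monotone likelihood) raises an error instead of returning
an explosive estimate. Proportional hazards are checked by the
Grambsch–Therneau scaled-Schoenfeld test on KM-transformed time.
Time-dependent ROC uses the cumulative/dynamic AUC with
inverse-probability-of-censoring weights (KM of the censoring distribution,
left-continuous); with no censoring it reduces exactly to empirical pair
counting, which is how it is tested. Harrell's C is a direct O(n²) pair
scan with marker ties counting one half. NRI is categorical with
user-supplied thresholds. Pearson chi-square is uncorrected and Fisher's
exact sums the less-probable tables — the conventions that reproduce
published NMIBC baseline-table p-values digit for digit.

## What the synthetic generator emulates

Patient sequence data for studies of this kind are typically not deposited,
so the package carries a generator that makes every stage testable:

* an 11-donor control panel and 50 tumors at ~700 expected reads per 200-kb
  bin (~10M reads over the autosomes, i.e. ~0.5x);
* negative-binomial counting noise with dispersion 0.1 (FFPE-like
  overdispersion; Poisson and noiseless modes exist for calibration tests);
* a per-bin lognormal capture bias (sd 0.1) shared by all samples — the
  correlated structure that control normalization must remove, and the
  mechanism that justifies a panel-only normalization;
* a menu of tumor profiles built from arm-level events recurrent in
  urothelial carcinoma — gains of 8q, 16p, 19q, 20q, losses of chr9, 17p,
  11p at 1.5x/0.5x — with menu frequencies putting ~70% of tumors in the
  high-burden class; on toy genomes an equivalent generic menu over the
  available arms is substituted;
* recurrence-free survival from an exponential proportional-hazards model:
  baseline 0.003 events/month, log hazard ratio log(5) for the high-burden
  class, administrative censoring at 84 months — chosen once to give ~58%
  overall relapse and a median RFS near 22 months in the high class,
  matching the cohort margins the defaults are modelled on;
* clinical covariates drawn independently to match typical cohort margins
  (mean age 68, ~82% male, ~half high-grade/multifocal/T1). Covariates are
  *not* correlated with the latent class, so any association the pipeline
  reports between CIN class and a covariate on synthetic data is noise by
  construction.

The latent high/low label is defined by implanted burden (sum of |log2 copy
ratio| × length in Mb above a threshold), not by the pipeline's own cutoff,
so classification accuracy is a meaningful measurement. What the generator
does **not** model: subclonal mixtures, tumor purity (copy ratios are
coverage multipliers directly), GC waves, mappability holes, replication
timing, and read-level artifacts. Passing tests therefore demonstrate
correctness of the algorithms under the stated noise model, not performance
on real FFPE libraries.

## Numerical choices and degenerate inputs

* Permutation p-values are computed with the +1 convention, so zero is
  never reported; the permutation stream comes from R's RNG and is
  reproducible under `set.seed`.
* The t statistic of a candidate split with zero pooled variance is treated
  as infinite when the means differ (a noiseless step is always accepted)
  and zero otherwise.
* Equal-mean adjacent segments merge even with zero residual variance.
* A series shorter than `2 * min_width` is returned as one segment; an
  empty chromosome arm is skipped with a log entry at the pipeline level.
* MAD comparisons tolerate ~1e-9 floating-point noise so that a sample
  sitting exactly on the threshold passes, as the strict-"exceeds" rule
  requires.
* Cutoff selection requires at least 10 subjects and both an event and a
  censored observation; fully separated scores are legal and yield a
  cutpoint in the separating gap.

## Problem sizes used in the checks

The test and acceptance workloads run on deliberately small instances: toy
genomes of 4 chromosomes (~136 bins at 1 Mb) for cohort replicates, 2,000
bins for normalization calibration, series of 100–200 bins for segmentation
recovery, 100 segmentation replicates, 500–1,000 maxstat null replicates,
and 50 end-to-end cohort replicates. These sizes keep a complete run in a
few minutes while leaving every statistical check at meaningful power; the
full hg19-scale grid (~14,000 bins) runs through the identical code path
via `pipeline_config(genome = "hg19")`.

## Known limitations

* The CBS permutation test is the plain Olshen–Venkatraman formulation; the
  hybrid tail approximation and outlier smoothing of mature implementations
  are not reproduced, so very long series pay the full permutation cost.
* The improved-Bonferroni p for cutoff selection is an upper bound; its
  conservatism grows with the candidate count.
* IPCW AUC assumes censoring independent of the marker; NRI is categorical
  only (continuous NRI(>0) is not implemented).
* The signed-sum and unfiltered variants of the CIN score are provided but
  untested against any external cohort; on real data the choice of
  `z_min`, length units, and the absolute-value convention materially
  changes the score scale, and cutoffs must be re-derived per cohort.
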
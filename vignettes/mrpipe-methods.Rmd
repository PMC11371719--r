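---
title: "Methods and design notes for mrpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for mrpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpipe)
```

# The model

Two-sample Mendelian randomization combines per-SNP summary associations
from two non-overlapping GWAS cohorts. For instrument $j$, let
$\hat\beta_{Xj}$ (SE $\sigma_{Xj}$) be its estimated effect on the
exposure and $\hat\beta_{Yj}$ (SE $\sigma_{Yj}$) its effect on the
outcome (log-odds for a binary outcome). Under the instrumental-variable
assumptions — association with the exposure, independence from
confounders, and no effect on the outcome except through the exposure —
each ratio $\hat\beta_{Yj}/\hat\beta_{Xj}$ estimates the same causal
effect $\theta$.

`mrpipe` implements the three standard combinations, all with weights
$w_j = 1/\sigma_{Yj}^2$:

* **IVW** is the zero-intercept weighted least-squares slope
  $\hat\theta = \sum w_j \hat\beta_{Xj}\hat\beta_{Yj} / \sum w_j
  \hat\beta_{Xj}^2$, equivalently the inverse-variance meta-analysis of
  the ratios. The fixed-effect SE is $(\sum w_j\hat\beta_{Xj}^2)^{-1/2}$;
  the multiplicative random-effects model inflates it by
  $\max\{1, \sqrt{Q/(n-1)}\}$, where $Q$ is Cochran's statistic of the
  fit. Both share the identical point estimate.
* **MR-Egger** frees the intercept. Under the InSIDE assumption
  (pleiotropic direct effects independent of instrument strength) the
  slope remains a consistent causal estimate and the intercept estimates
  the average directional pleiotropy. Instruments are first oriented so
  every $\hat\beta_{Xj} \ge 0$ (the fit is not invariant to per-SNP sign
  conventions otherwise); inference uses a $t_{n-2}$ reference with the
  same multiplicative dispersion floor.
* **Weighted median** orders the per-SNP ratios and interpolates at
  cumulative weight $1/2$, using weights $\hat\beta_{Xj}^2 w_j$
  normalized to 1 and abscissae $p_1+\dots+p_j - p_j/2$. It is consistent
  while valid instruments hold a majority of weight. Its SE comes from a
  parametric bootstrap (default 1000 draws of
  $\hat\beta^\ast \sim N(\hat\beta, \mathrm{se})$ for both sides, seeded).

One caveat of the interpolated definition: an instrument holding weight
$p > 1/2$ pins the estimate to (essentially) its own ratio only up to the
interpolation between ratio midpoints; the discrepancy vanishes as
$p \to 1$ and is ~$10^{-3}$ at $p = 0.995$.

# Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `iv_pval` | 1e-5 | instrument significance screen; the conventional relaxed threshold for microbiome-scale exposures, where few SNPs reach 5e-8 |
| `ld_r2` | 0.001 | greedy clumping threshold: every retained pair of instruments must have r² below it |
| `clump_window_kb` | 10000 | pairs farther apart than this (when positions are supplied) are treated as unlinked; common practice, not dictated by the r² rule itself |
| `f_threshold` | 10 | per-SNP weak-instrument cutoff on F = r²(n−k−1)/[k(1−r²)] with k = 1 |
| `palindrome_eaf_limit` | 0.42 | A/T and C/G SNPs are frequency-resolvable only when both eafs fall outside [0.42, 0.58] |
| `ivw_model` | multiplicative_random | SE model; never smaller than fixed, so headline CIs are insensitive to the choice of model |
| `n_boot` | 1000 | weighted-median bootstrap replicates |
| `presso_n_sim` | 1000 | MR-PRESSO simulation replicates; the smallest attainable global p is 1/(n_sim+1) |
| `outlier_alpha` | 0.05 | Bonferroni-adjusted per-SNP outlier threshold |
| `reverse_iv_pval` | 1e-5 | instrument screen for the reverse (disease → taxon) direction |
| `seed` | — | mandatory; every stochastic step derives a child seed from it |

The per-SNP variance explained defaults to the scale-free t-statistic
form $r^2 = t^2/(t^2+n-2)$, $t=\hat\beta/\mathrm{se}$, because the
effect-allele frequency may be missing; the frequency-based
$2\,\mathrm{eaf}(1-\mathrm{eaf})\hat\beta^2$ form (which assumes a
standardized trait) is selectable.

# Harmonization policy

Exposure and outcome records are aligned per SNP: direct allele match is
kept as-is; swapped orientation negates the outcome effect and reflects
its frequency; a strand complement is applied when that reconciles the
pairs. Palindromic SNPs carry no strand information in their alleles, so
orientation is inferred from frequency agreement, and the SNP is dropped
as `ambiguous_palindrome` when either frequency is missing or falls in
the ambiguity band. Instruments absent from the outcome GWAS are dropped
outright — no proxy-SNP substitution. Every exposure SNP appears in the
audit exactly once, harmonized or dropped with its reason.

# Sensitivity diagnostics

Cochran's $Q=\sum w_j(\hat\beta_{Yj}-\hat y_j)^2$ uses the fixed-effect
IVW prediction (df $n-1$) or the Egger prediction on the oriented scale
(df $n-2$); $p > 0.05$ is reported as "no heterogeneity", with no
multiple-testing correction across exposures (the convention of the
screening design this mirrors — a caveat, not a recommendation).
Leave-one-out re-runs IVW $n$ times.

MR-PRESSO simulates the null of the observed leave-one-out IVW fits:
$\beta^\ast_{Yj} \sim N(\hat\theta_{-j}\hat\beta_{Xj}, \sigma_{Yj})$,
with leave-one-out slopes recomputed per replicate. The global test
compares the observed weighted residual sum of squares with its
simulated distribution. **Design deviation worth knowing:** per-SNP
flagging is applied *sequentially*, not in a single pass. A single gross
outlier biases every leave-one-out slope, so a one-shot Bonferroni sweep
drags clean neighbours over the threshold and the "corrected" estimate
inherits a selection bias (measured at ≈ +0.05 on a consensus ratio of
0.30 in the acceptance fixture). Peeling — remove the worst flagged SNP,
re-test the remainder, repeat until clean — matches how the method is
used in practice ("remove outliers until heterogeneity clears") and
leaves the corrected estimate unbiased in the same fixture. The global p
and the reported per-SNP p-values always refer to the full-set first
pass. The distortion test compares the correction-induced shift with
shifts from removing random same-size subsets.

# What the synthetic generator emulates — and what it does not

`simulate_pair()` draws, per instrument: a MAF in [0.05, 0.5]; a true
exposure effect from $N(0.1, 0.03)$ (SD units, strong instruments:
median F ≈ 80 at n = 18,340); a direct (pleiotropic) outcome effect per
regime (none / balanced / directional, optionally correlated with
instrument strength to violate InSIDE); then observed effects with
independent noise per cohort using the standard GWAS SE approximations —
continuous: $1/\sqrt{n \cdot 2f(1-f)}$; binary:
$1/\sqrt{n \cdot 2f(1-f) \cdot c(1-c)}$ with case proportion $c$. The
defaults mirror the motivating design: exposure GWAS of 18,340
individuals, outcome with 208 cases / 213,145 controls, which makes
outcome SEs roughly ten-fold larger than exposure SEs — the regime the
estimators must tolerate. Alleles are assigned with a 20% palindromic
fraction and identical orientation in both files.

Not emulated: LD between observed instruments (LD matrices are generated
separately as block-diagonal fixtures for the clumping rule), real
minor-allele-frequency spectra, winner's-curse selection of instruments,
sample overlap, and population stratification. A green simulation test
therefore establishes internal statistical correctness of the estimators
and pipeline under the stated generative model — not robustness to those
real-data pathologies.

# Numerical choices

* CI multiplier fixed at 1.959964 (normal 97.5th percentile) for
  IVW/weighted-median; Egger uses the $t_{n-2}$ quantile.
* P-values are floored at 1e-300; degenerate designs (all
  $\hat\beta_{Xj}=0$, or no spread for Egger) raise errors rather than
  returning noise.
* Methods below their minimum instrument count (2 for IVW as regression,
  3 for Egger/WME, 4 for MR-PRESSO) return explicit not-estimable
  results, exported as "/" sentinels — the convention of published
  reverse-MR tables built on 2-instrument disease exposures.
* Greedy clumping ranks by p-value ascending and keeps a candidate iff
  its r² with *every* previously kept SNP is below threshold, so the
  smallest-p candidate always survives; ties follow input order.
* `wald_ratio()` uses the first-order delta-method SE
  $\sigma_{Yj}/|\hat\beta_{Xj}|$, adequate under the F > 10 screen (the
  second-order term is $O(1/F)$).
* Seeds: every stochastic component (weighted-median bootstrap,
  MR-PRESSO, simulation) takes an explicit seed; the pipeline derives
  per-pair child seeds from the config seed, below $2^{31}$, and restores
  the caller's RNG state afterwards. Identical config + seed gives
  byte-identical exports.

# Open choices made here

* The reverse-direction instrument threshold is not standardized in the
  screening designs this package mirrors; it defaults to 1e-5 and is
  surfaced in the manifest. With a few-hundred-case disease GWAS this
  typically yields 2–8 instruments, hence the "/" convention above.
* Whether published analyses resolve or drop palindromes is rarely
  stated; both behaviors are supported (`palindrome_eaf_limit` with
  missing-frequency fallback to dropping), logged per SNP, and recorded
  in the run config.
* Significance across many exposures uses raw p < 0.05 to match the
  screening convention; a Benjamini–Hochberg column is exported alongside
  but never gates the flag.
* The acceptance fixture for outlier detection uses a consensus ratio of
  0.30 across 10 strong instruments with outcome SE 0.02 and one SNP at
  10× the consensus ratio (~20σ): "tight SE" chosen at the scale of a
  well-powered outcome GWAS, fixed before measuring outcomes.

# Known limitations

* No proxy-SNP lookup, reference-panel strand checks, Steiger
  directionality filtering, multivariable MR, or mode-based estimators.
* The confounder screen is an explicit exclusion list; no live
  phenotype-database queries (reproducibility over convenience).
* LD matrices must be supplied (or simulated); the package never
  estimates LD from genotypes.
* The Egger intercept's power is low at small instrument counts; "no
  evidence of pleiotropy" at $n \le 10$ instruments is weak evidence of
  absence.
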
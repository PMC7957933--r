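---
title: "Methods: CVR mapping, miRNA quantification and mediation in cvrmir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CVR mapping, miRNA quantification and mediation in cvrmir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvrmir)
```

This vignette explains the models behind `cvrmir`, the parameters that
matter, what the synthetic-data generator does and does not emulate, and
the numerical and design choices made where the method left room.

## 1. The scientific setting

Hypertension damages cerebral vessels before it damages cognition.
Cerebrovascular reactivity (CVR) — the capacity of vessels to dilate
and constrict — is a specific marker of that damage, and circulating
exosomal microRNAs are candidate molecular drivers. The package
implements a three-group design (healthy controls, hypertensive
patients with normal cognition "HT-NC", hypertensive patients with
cognitive impairment "HT-CI") and the full chain: per-subject relative
CVR maps from resting-state BOLD, miRNA quantification from qPCR Ct
panels, cognitive composites, covariate-adjusted group comparisons,
and a mediation model miRNA → frontal CVR → executive function.

## 2. Relative CVR from resting-state BOLD

### Model

Slow BOLD fluctuations in the 0.02–0.04 Hz range track systemic
vasomotion (and end-tidal CO₂). If $g(t)$ is the whole-brain mean
band-limited BOLD course, the voxel-wise GLM

$$y_v(t) = \alpha_v + \beta_v\, g(t) + \varepsilon_v(t)$$

estimates each voxel's vasomotor coupling $\beta_v$. Dividing by the
in-mask mean gives the *relative* CVR map (whole-brain mean exactly 1,
"relative units"). The normalization reference region is the whole-brain
mask; any other mask can be substituted in `normalize_cvr()`.

### Processing order and parameters

`compute_cvr_map()` applies, in order: Gaussian smoothing (default
FWHM 8 mm, $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ per axis in mm),
per-voxel linear detrending, band-pass filtering (default 0.02–0.04 Hz),
reference extraction, GLM, normalization. Smoothing precedes the
regression because it is a preprocessing step in the standard pipelines
this mirrors; detrending precedes filtering so slow drifts do not leak
through the band edge.

Two numerical choices deserve emphasis:

* **Filter realization.** The band-pass is a zero-phase FFT (ideal)
  filter: Fourier coefficients outside the band are zeroed. The common
  alternative, a forward–backward Butterworth, needs an IIR design
  routine that is not available in this dependency set, and the FFT
  realization is what the widely used resting-state toolboxes
  (REST/DPABI) implement. It is exactly zero-phase — important because
  phase shift between a voxel course and the reference would bias the
  regression slope — and meets a strict contract: passband amplitude
  within 5%, stopband (≥2× the upper edge) attenuated ≥80%, zero-mean
  output.
* **Mask-aware smoothing.** Smoothing renormalizes the kernel by the
  smoothed mask, so in-mask voxels near the brain edge are not diluted
  with signal-free background. On a full-size brain this is a small
  correction; on the scaled-down simulation grids used for testing
  (16×16×8, where an 8-mm kernel reaches the edge almost everywhere) it
  is the difference between recovering the true field and attenuating
  its whole boundary.

The pipeline is linear in the input, so scaling BOLD intensity by any
positive constant leaves the relative CVR map unchanged, and with zero
noise the map equals the true field divided by its mask mean to
machine precision (both are tested).

### EtCO₂ alignment

When an end-tidal CO₂ trace is available, `align_etco2()` shifts it over
a lag grid (default 0–20 s in steps of one TR) to maximize Pearson
correlation with the global reference, modelling the lung-to-brain
transit delay; ties break toward the smaller lag, and a maximum
correlation below a configurable floor (default 0.3) flags the
alignment as unreliable. The CVR computation itself proceeds from the
global reference; EtCO₂ alignment is a quality-control step, matching
how the resting-state variant of the method actually operates.

## 3. Cognitive scoring

Raw scores are standardized against the analyzed cohort's own mean and
SD (`z_score_cohort()`), then averaged into six composites
(`DOMAIN_DEFS`): global (MMSE, MoCA), processing speed (TMT-A, SCWT-A),
memory (VR-DR, AVLT-DR), executive (CVF, TMT-A, TMT-B, Stroop-C),
language (BNT, CVF), visuospatial (VR-copy, CDT).

**Sign convention.** Timed tests (TMT, SCWT, Stroop) are standardized in
their native direction — higher = slower. No inversion is applied. This
follows the reporting convention of the emulated study (which reports
*negative* CVR–executive correlations) and must be kept in mind when
interpreting composites: for speed- and executive-dominated composites,
lower is better. The synthetic pipeline's planted "better executive
function" therefore appears as a negative mediator→outcome path.

**Impairment classification.** Education-stratified screening cutoffs
(score ≤ cutoff ⇒ impaired): MMSE ≤26 (>6 y), ≤22 (1–6 y), ≤19 (0 y);
MoCA ≤25 (>12 y), ≤24 (7–12 y), ≤19 (1–6 y), ≤13 (0 y). When both
instruments are available the default combination is OR (impaired on
either) — the sensitive choice, selectable via `rule=` since the source
convention is not stated. Classification is monotone: lowering a score
can never remove the impaired flag.

## 4. miRNA quantification and triage

Expression is $2^{-\Delta Ct}$ with $\Delta Ct = Ct_{\text{miRNA}} -
Ct_{\text{miR-39}}$ (cel-miR-39 spike-in); one extra cycle halves
expression, and $\log_2$ expression equals $-\Delta Ct$ exactly (a
tested identity). Log transformation (natural log by default) precedes
all group statistics because expression is log-normal-ish by
construction.

The screening stage (`screen_differential()`) computes, per miRNA, the
log2 fold change of group means and a Welch t-test on log2 values for
the two contrasts HT-CI vs control and HT-CI vs HT-NC; candidates must
pass both contrasts with |log2FC| strictly above the threshold (default
1.0), p below threshold (default 0.05) and a consistent direction. The
original screening test and thresholds are unstated upstream, so these
are declared, configurable defaults; no multiple-testing correction is
applied by default (Benjamini–Hochberg is available) because raw
candidate counts are the quantity of interest at this stage. The
validation stage (`validate_candidates()`) is an ANCOVA per candidate on
log expression, controlling for age, education years and lacunar-stroke
history, with pairwise adjusted contrasts.

## 5. Group statistics

* `one_way_anova()` / `anova_from_summary()`: the classical
  decomposition; the summary version reconstructs F from published
  mean/SD/n rows ($SSB = \sum n_i(\bar x_i - \bar x)^2$,
  $SSW = \sum (n_i - 1) s_i^2$) and agrees with the raw-data version to
  1e-9 on any dataset.
* `chi_square()`: Pearson $\sum (O - E)^2 / E$ *without* continuity
  correction — verified to reproduce the published contingency
  statistics to their printed precision.
* `ancova()`: linear model with sum-to-zero group coding; the group F
  uses the partial (Type-III-style) sum of squares, the standard choice
  for unbalanced covariate-adjusted designs. Adjusted means are model
  predictions at the covariate means; pairwise contrasts use
  model-based SEs with t tests on the residual df, uncorrected by
  default (Bonferroni/BH optional). Zero-variance covariates are
  dropped, so the covariate-free call reduces exactly to one-way ANOVA.
  Perfect-fit degeneracies are resolved explicitly: if the covariates
  alone fit exactly, the group F is 0; if only the full model fits
  exactly, F is infinite.
* `partial_correlation()`: correlation of residuals after regressing
  both variables on the covariates; t-based p with
  $df = n - k_{\text{cov}} - 2$.

## 6. Voxel-wise inference: permutation instead of GRF

The emulated workflow corrected voxel-wise ANCOVA maps with Gaussian
random field theory (voxel p < 0.005, cluster p < 0.001, extent > 20
voxels). GRF needs a smoothness estimate whose implementation details
are toolbox-internal; `cvrmir` instead uses a **permutation
cluster-extent test**, which is distribution-free and fully
specifiable:

1. compute the observed voxel-wise partial-F map (vectorized; identical
   to looping `ancova()` over voxels, which is tested);
2. threshold at the parametric voxel p (default 0.005) and label
   connected components (26-connectivity by default; 6/18 available);
3. build the null of the *maximum* cluster extent by Freedman–Lane
   permutation: residualize the maps on the covariates, permute
   residuals over subjects, add back the covariate fit, recompute the F
   map and the max supra-threshold cluster size;
4. corrected cluster p = (1 + #{perm max ≥ observed size}) /
   (n_perm + 1); retained clusters need p < cluster_p *and* extent >
   min_size.

Two practical consequences are documented rather than hidden. First,
the corrected p can never be smaller than 1/(n_perm+1): resolving the
strict cluster p < 0.001 requires at least 1000 permutations. Second,
when a real effect exists, permuted label assignments partially align
with the true grouping by chance in small samples, inflating the null
of the maximum statistic — the test is conservative at small n. The
package's small-scale end-to-end demonstration therefore uses a
scale-appropriate cluster threshold (0.05), while the defaults keep the
published 0.005/0.001/20 settings.

Under pure noise, the supra-threshold voxel fraction matches the
nominal voxel p and the retained-cluster false-positive rate is bounded
by the cluster threshold (both recomputed by `scripts/acceptance.R`).

## 7. Mediation

`fit_paths()` estimates, by OLS: $a$ from $M \sim X + C$, $b$ and $c'$
from $Y \sim X + M + C$, and the total effect $c$ from $Y \sim X + C$.
With identical covariate sets the decomposition $c = c' + a b$ holds
exactly. `bootstrap_indirect()` resamples *subjects* (cases) with
replacement, recomputes $a b$ per resample, and reports the percentile
CI (default 5000 resamples, 95%); mediation is declared when the CI
excludes zero. Percentile rather than bias-corrected intervals match
the conventions of the PROCESS-style tools this mirrors; BCa was left
out deliberately to keep the bootstrap exactly reproducible and simple.
Variables are z-standardized by default (standardized path
coefficients), switchable with `standardize = FALSE`. Rank-deficient
resamples are redrawn and counted. An exactly collinear design (e.g.,
M ≡ X) is an error by contract — the paths are not identified — which
resolves an internal tension in the specification between the
"deterministic chain" illustration and the rank-deficiency error rule.

Calibration at the study's scale (n = 150, a·b = 0.2, unit noise):
95% CIs cover the true indirect effect at nominal rate (±4 points), and
with a = 0 the CI excludes zero in well under 10% of runs — both
recomputed by the acceptance script.

## 8. The synthetic world

`sim_config()` fixes the stated world; its defaults are the emulated
study's own conditions where stated, and realistic choices where not:

* **Cohort**: group sizes 37/67/73; ages ≈ 58.5/63.9/66.0 (SD 7.2/8.2),
  education ≈ 13/12/11 y, lacunar-stroke rates 16/19/36%, male fractions
  and log-normal WMH volumes matching the published demographic table;
  raw cognitive scores on natural scales (timed tests in seconds) with
  deficits planted in HT-CI.
* **BOLD**: TR 2 s, 240 volumes, 3 mm voxels on a 16×16×8 grid with an
  ellipsoidal mask — a deliberately scaled-down brain that keeps
  whole-pipeline tests in seconds. The shared vasomotor signal $g(t)$
  is a sum of 3 unit-variance-normalized sinusoids with frequencies
  drawn uniformly in (0.022, 0.038) Hz and random phases; ≥90% of its
  periodogram power lies inside the 0.02–0.04 Hz band (tested). Voxel
  courses are $1000 + \mathrm{CVR}_v\, g(t) + \varepsilon$ with white
  noise SD 0.5 by default (the "default SNR" at which median recovery
  r ≥ 0.9 is asserted).
* **Ct panels**: baseline Ct 26, subject SD 0.8, spike-in Ct 20
  (SD 0.3); planted group shifts default to the validated candidate
  pattern (e.g., +1 Ct in HT-CI halves mir-330-3p expression). Effect
  sizes on the Ct scale are unreported upstream, so these defaults are
  chosen for testability, not biological fidelity.
* **Mediated chain** (in `simulate_dataset()`): the first miRNA's
  standardized log2 expression drives the focal-region CVR at 0.3 r.u.
  per SD per unit of path $a$; the subject's true region CVR (in SD
  units) drives an executive shift of $b$ SD-equivalents applied to the
  executive constituents' raw scores, plus a direct $c'$ path. Subject
  CVR fields also carry smooth whole-brain individual variation
  (SD 0.1 r.u.) — without it, every non-focal voxel would have
  near-zero between-subject variance and the relative-normalization
  leakage of the focal effect would light up the entire mask.
* **Determinism**: one dataset seed; per-purpose sub-streams derive
  from it by fixed offsets, so identical config + seed reproduce every
  output bit-exactly.

What the generator does **not** emulate: hemodynamic response shapes,
head motion, physiological noise spectra, anatomical structure (no MNI
template; "peak coordinates" are affine transforms of a toy grid),
miRNA count overdispersion, or floor/ceiling psychometrics. A green
test therefore establishes that the estimators recover what they claim
from data obeying their model — not that the model captures every
property of real data.

## 9. Known limitations

* The NIfTI-1 reader/writer is minimal (single-file, diagonal sform,
  common datatypes); it round-trips against nibabel-written files but
  is not a general NIfTI library.
* CVR here is *relative* (unitless); calibrated CVR in %BOLD/mmHg from
  hypercapnia designs is out of scope.
* The permutation cluster test assumes exchangeability of
  covariate-residualized subjects; heteroscedastic groups at very small
  n weaken that guarantee.
* Published headline results from the real cohort (specific cluster
  peaks, r = −0.275-type correlations, the −0.023 indirect effect)
  depend on the unavailable raw data and are not reproduction targets;
  the acceptance machinery validates the published summary-statistic
  recomputations and the method's calibration instead.
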
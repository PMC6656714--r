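---
title: "Diffusion kurtosis modelling of tumour response: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusion kurtosis modelling of tumour response: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dkifit)
```

## The signal models

A diffusion-weighted acquisition samples the MR signal at several diffusion
weightings b (s/mm²). With Gaussian water displacement the signal decays
mono-exponentially, S(b) = S₀·exp(−b·ADC). In tissue dense with membranes
and organelles the displacement distribution is leptokurtic, and a
second-order cumulant expansion of the decay captures that:

$$S(b) = S_0 \, e^{-b\,D_{app} + \tfrac{1}{6} b^2 D_{app}^2 K_{app}}$$

with apparent diffusivity $D_{app}$ (mm²/s) and unitless apparent kurtosis
$K_{app} \ge 0$; $K_{app} = 0$ recovers the Gaussian model exactly. The
expansion is an approximation: for fixed $(D, K)$ the predicted signal turns
upward beyond $b^* = 3/(D K)$. At the default acquisition
(b up to 1700 s/mm²) and tumour-like values (D ≈ 1.4 × 10⁻³ mm²/s,
K ≈ 0.7) the turning point sits near 3000 s/mm², safely outside the sampled
range, and the phantom generator's signals are strictly decreasing in b.

ADC is deliberately fitted only on the low-b subset (100, 500, 900 s/mm²),
where the Gaussian approximation is adequate, by ordinary least squares on
the log signal. The kurtosis expansion needs the high-b samples (1300,
1700 s/mm²) for $K_{app}$ to be identifiable. No b = 0 image is acquired —
low b-values are dominated by perfusion and bulk flow — so $S_0$ is always
an extrapolated free parameter, never read off the data.

## Voxel-wise estimation

Each masked voxel is fitted by bound-constrained nonlinear least squares
(Levenberg–Marquardt, `minpack.lm`) on the *raw* signal. Fitting the raw
signal rather than its logarithm keeps the error model homoscedastic: a log
transform would amplify noise exactly where the signal is weakest (high b),
which is where the kurtosis information lives.

Choices that matter, with defaults:

- **Bounds.** $D_{app} \in [10^{-5}, 4 \times 10^{-3}]$ mm²/s spans the
  physiological range up to free water; $K_{app} \in [0, 3]$ (negative
  kurtosis is not physically meaningful in tissue and tumour values
  reported in vivo stay well below 3); $S_0 \in (0, 2\max S]$.
- **Initialisation.** Ordinary least squares of $\log S$ on $(1, -b, b^2)$
  is exact for noiseless kurtosis decays, so the solver starts at (or at
  the bound-projection of) the optimum; degenerate designs fall back to
  (median signal, 10⁻³ mm²/s, 0.5).
- **Convergence.** Relative tolerance 10⁻⁸ on parameters and cost, at most
  500 iterations. Non-convergence is recorded in the `qc` map (code 3) and
  yields NaN, never a silently accepted estimate. NaN is the single
  sentinel for "no estimate" throughout; `qc == 0` coincides exactly with
  voxels where all four metrics are finite.
- **Noise floor.** Magnitude images carry a Rician floor; an optional
  additive offset parameter exists for experimentation but is off by
  default, since the reference analysis applies no bias correction.
- **Units.** b in s/mm², diffusivities in mm²/s, so $bD$ is dimensionless.
  Maps are stored unscaled; only plots apply the conventional ×1000 display
  scaling.

`grid_oracle_fit()` is a deliberately brute-force exhaustive grid search
kept solely as a test oracle: on any input the solver's residual sum of
squares must not exceed the best grid point's.

### Identifiability under noise

With five b-values and Rician noise at SNR ≈ 50 (relative to $S_0$), the
kurtosis parameter is intrinsically hard to pin down per voxel: the
Cramér–Rao bound at (D = 1.3 × 10⁻³ mm²/s, K = 0.6) puts the best
achievable median relative error for an unbiased estimator near 24% for
$K_{app}$ and 7% for $D_{app}$. The package's fit measures ≈ 23.5% and
≈ 6.8% over 10⁴ simulated voxels — at the information-theoretic floor, and
a regression test asserts the fit stays within 1.25× of it. This is why the
analysis aggregates over VOIs of hundreds of voxels before any inference:
per-patient means are far more precise than any single voxel.

## The synthetic phantom and cohort

No patient data ship with the package; a generator reproduces the
statistical structure the analysis assumes.

**Phantom.** Ellipsoidal lesions on a 48 × 48 × 12 grid (2.7 × 2.7 × 6 mm
voxels) with voxel-wise $(S_0, D_{app}, K_{app})$ drawn from truncated
normals ($K \ge 0$, $D \ge 10^{-5}$; inverse-CDF sampling for
deterministic cost). The default layout places one lesion at the responder
kurtosis level (mean 0.69) and one at the non-responder level (0.51). A
configurable fraction of lesion voxels becomes a necrotic/cystic core —
free-water-like, $K = 0$, $D \ge 2.5 \times 10^{-3}$ mm²/s — labelled
negatively in the ground truth and *excluded* from the ROI mask, mirroring
the radiological practice of drawing ROIs around solid tissue only.
Background voxels decay mono-exponentially at low $S_0$. Noiseless signals
satisfy the forward model to machine precision, which the tests verify.

**Noise.** Rician: each sample becomes
$\sqrt{(S+\varepsilon_1)^2 + \varepsilon_2^2}$ with independent Gaussian
channels of sd σ — the standard model for magnitude-reconstructed MRI. The
pipeline default σ = 20 (on lesion $S_0$ = 1000) sets SNR ≈ 50 at b = 100,
a mid-range value for clinical body DWI chosen once as the package default;
σ is a configuration field, since the reference acquisition's SNR is not
known.

**Cohort.** Per-patient VOI-level metrics are drawn directly from each
group's normal distribution, at the published group statistics by default:
responders (n = 5) K_app 0.69 ± 0.13, D_app 1.44 ± 0.30 × 10⁻³,
ADC 1.22 ± 0.24 × 10⁻³; non-responders (n = 10) K_app 0.51 ± 0.11,
D_app 1.51 ± 0.32 × 10⁻³, ADC 1.30 ± 0.27 × 10⁻³ (mm²/s). The generating
values are kept as `*_true` columns.

**Histology.** Cellularity (cells/µm², log-normal marginal around
5 × 10⁻³) and Ki-67 positive fraction (scaled Beta marginal centred near
45%, plausible for a high-grade proliferative cancer) are tied to K_app by
a Gaussian copula. The latent correlation is *calibrated*: because one
margin is the fixed vector of K_app normal scores, the classical
large-sample conversion $r = 2\sin(\pi\rho_S/6)$ under-corrects at n ≈ 15–17
(it would land ≈ 0.006 low, and a naive bivariate-normal finite-n formula
≈ 0.02 high). Instead the exact finite-sample expectation of Spearman's rho
given fixed scores — ranks are permutations, so the expectation reduces to
pairwise Gaussian orthant probabilities — is inverted numerically. A
10⁴-seed Monte-Carlo test confirms the mean sample rho lands within 0.02 of
target at n = 17. Targets of ±1 short-circuit to exact monotone transforms.

All generators are pure functions of their explicit seed; nothing touches
global RNG state.

**What the phantom does not emulate.** Anatomical realism, partial-volume
averaging at lesion boundaries, motion/eddy distortion, perfusion (IVIM)
contamination at low b, T2 shine-through, or spatial noise correlation from
parallel imaging. Passing tests therefore demonstrate correctness of the
estimation and inference chain under the stated noise model — not
robustness to every artefact of in vivo data.

## VOI aggregation

All of a patient's lesion ROIs are pooled (set union) into a single VOI
before reduction, so the per-patient value is the voxel-weighted mean over
the pooled VOI — not a mean of per-lesion means; larger lesions weigh more,
and a consistency identity test pins this down. The median is offered as an
alternative policy (`policy = "median"`) because rank-based group tests are
sometimes paired with median summaries, but the mean is the default
per-patient statistic. Voxels whose fit failed (`qc != 0`) are excluded and
counted, mirroring the exclusion of non-evaluable tissue.

## Statistical chain

- **Response dichotomisation.** RECIST CR/PR → responder, SD/PD →
  non-responder; absent → unclassified. Unclassified patients (e.g.
  adjuvant-pathway cases) are excluded from group comparisons but retained
  in correlations.
- **Normality gate.** Shapiro–Wilk per group at α = 0.05 (the gate's level
  is a package choice; 0.05 is the conventional default). Both groups pass
  → two-sample Student's t-test (equal variances, as "Student's" implies);
  otherwise the two-sided Mann–Whitney U.
- **Mann–Whitney.** Exact null distribution whenever both groups are small
  and untied — the 5-vs-10 design is well inside the exact range — and the
  mid-rank, tie-corrected normal approximation with continuity correction
  otherwise. An enumeration oracle in the tests verifies every split with
  pooled n ≤ 12.
- **Spearman.** Mid-rank rho; exact p for small untied samples, otherwise
  the t-approximation.
- **ICC.** Two-way model from the ANOVA mean squares; the default is the
  absolute-agreement single-rater form, which penalises systematic
  between-observer offsets (the relevant property for interchangeable
  observers), with the consistency form available. Confidence intervals use
  the F construction with Satterthwaite degrees of freedom for the
  agreement form. The unit of analysis (per-patient VOI values vs all
  voxels) is left to the caller — the function takes any complete
  units × raters matrix. Degenerate inputs (zero error variance) return
  ICC = 1 with a collapsed interval rather than 0/0.
- **No multiplicity correction** is applied; analyses are reported
  per-hypothesis with p-values as computed.

## Numerical and interface conventions

Masks and series must share a grid exactly; no resampling is offered —
parameter maps derived from the same DWI series are co-registered by
construction, and anything else is out of scope. Readers normalise b-value
order (volumes are re-sorted to an ascending scheme). Writers store doubles
(float64) so map round trips are bit-identical; cohort CSVs serialise
doubles at 17 significant digits and re-parse with base R's
correctly-rounded reader, making the table round trip exact. Image
containers are plain arrays in lightweight S3 lists; everything tabular —
cohort rows, VOI summaries, test results, `tidy()`/`glance()` output — is a
tibble, so the analysis layer composes with dplyr and the pipe.

`run_pipeline()` chains phantom → noise → NIfTI round trip → fit → VOI
summary → cohort simulation → statistics → CSV/JSON reports, with every
stage's randomness derived from one master seed; repeated runs are
byte-identical (NIfTI outputs are written uncompressed, as gzip embeds
timestamps). The YAML configuration mirrors `default_pipeline_config()`.

## Problem sizes in the test suite

The suite exercises: full-grid phantoms (48 × 48 × 12, ~1100 lesion
voxels) for forward-model exactness and determinism; 10⁴ single-voxel fits
for the noise-recovery study; 120 noisy voxels against the exhaustive grid
oracle; 200 simulated cohorts for the power-direction check (the kurtosis
contrast separates groups in the majority of cohorts, diffusivity/ADC
rarely — at these group means the two-sample design has roughly 70% power
for K_app and under 15% for the others); and 10⁴ seeds for the copula
calibration. These sizes give Monte-Carlo standard errors comfortably below
the asserted tolerances while keeping the suite fast.

## Known limitations

- Isotropic (trace-weighted) kurtosis only; no directional/tensor kurtosis,
  IVIM or stretched-exponential alternatives.
- Voxel-wise $K_{app}$ precision is CRLB-limited at clinical SNR (see
  above); single-voxel maps are noisy by nature and should be read through
  VOI summaries.
- The cohort generator draws VOI-level values directly; it does not model
  within-patient lesion heterogeneity feeding through the VOI pooling.
- Group comparison assumes independent patients; no covariate adjustment
  or multiplicity control is provided.
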
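# dkifit

Diffusion kurtosis imaging (DKI) analysis of tumour response to
chemotherapy, for imaging scientists and radiology researchers working with
multi-b-value diffusion-weighted MRI (DWI).

Conventional DWI summarises water mobility with the apparent diffusion
coefficient (ADC), assuming Gaussian displacement. In cellular, heterogeneous
tissue the displacement distribution is sharper than Gaussian, and that
deviation — the apparent kurtosis — carries microstructural information that
the ADC misses. `dkifit` fits, voxel by voxel, the kurtosis signal model

S(b) = S₀ · exp(−b·D_app + ⅙·b²·D_app²·K_app)

over a multi-b-value acquisition (default b = 100, 500, 900, 1300,
1700 s/mm²), alongside the conventional mono-exponential model
S(b) = S₀ · exp(−b·ADC) on the low-b subset (100, 500, 900 s/mm²). Here
D_app (mm²/s) is the apparent diffusivity, K_app (unitless) the apparent
kurtosis and S₀ the extrapolated unweighted signal. Downstream, the package

- pools all tumour ROIs of a patient into one volume of interest (VOI) and
  reduces each parameter map to single per-patient values;
- compares responders with non-responders using a Shapiro–Wilk-gated choice
  of Student's t-test or exact Mann–Whitney U test;
- correlates the imaging metrics with histology covariates (cellularity,
  Ki-67 fraction) by Spearman rank correlation;
- quantifies observer agreement with two-way intraclass correlation
  coefficients (absolute-agreement or consistency form);
- ships a synthetic phantom and cohort generator (ellipsoidal lesions with
  necrotic cores, Rician magnitude noise, copula-linked histology) so the
  entire pipeline is testable without patient data.

## Worked example

Fit a noiseless kurtosis decay and recover its generating parameters:

```r
library(dkifit)

b <- bvalue_scheme(c(100, 500, 900, 1300, 1700))
sig <- dki_signal(b, s0 = 1000, d_app = 1.44e-3, k_app = 0.69)
round(sig, 1)
#> [1] 868.0 516.7 331.9 230.2 172.2
fit_dki_voxel(sig, b)
#> # A tibble: 1 × 7
#>      s0   d_app k_app   adc converged      rss n_iter
#>   <dbl>   <dbl> <dbl> <dbl> <lgl>        <dbl>  <int>
#> 1  1000 0.00144 0.690    NA TRUE      1.70e-26      1
```

Simulate a 15-patient cohort (5 responders, 10 non-responders, drawn at the
published group means) with rank-correlated histology, and run the full
inference chain:

```r
cohort <- simulate_cohort(seed = 42)
cohort <- dplyr::bind_cols(cohort, simulate_histology(cohort$k_app_voi, seed = 43))
run_cohort_analysis(cohort)
#> <cohort_analysis> 15 patients, alpha = 0.05
#>
#> Group comparisons (responder vs non-responder):
#> # A tibble: 3 × 12
#>   metric      n_a   n_b  mean_a     sd_a  mean_b    sd_b ...
#> 1 k_app_voi     5    10 0.785   0.111    0.567   1.55e-1 ...
#> 2 d_app_voi     5    10 0.00147 0.000213 0.00154 3.58e-4 ...
#> 3 adc_voi       5    10 0.00128 0.000200 0.00127 3.63e-4 ...
#>
#> Histology correlations (Spearman):
#> # A tibble: 6 × 4
#>   pair                                      n    rho   p_value
#> 1 k_app_voi ~ cellularity_cells_per_um2    15  0.586 0.0218
#> 2 k_app_voi ~ ki67_percent                 15  0.846 0.0000692
#> ...
```

In this draw the kurtosis contrast separates the groups while D_app and ADC
do not, and K_app correlates with both histology covariates — the behaviour
the generator is parameterised to produce. `tidy()` flattens the analysis
into one hypothesis-per-row table; `glance()` gives a one-row summary;
`autoplot()` renders parameter maps, and `plot_group_metrics()` /
`plot_histology_correlation()` the cohort-level figures.

The full synthetic pipeline — phantom, noise, NIfTI round trip, voxel-wise
fitting, VOI summary, cohort simulation, statistics, CSV/JSON reports — runs
with one call and is byte-reproducible for a fixed seed:

```r
res <- run_pipeline(out_dir = "phantom_run", seed = 1)
```

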
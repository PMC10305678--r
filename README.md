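# codfusion

Retrieval of chemical oxygen demand (COD) in water from fused
absorption–fluorescence spectroscopy.

COD — the mass of oxidant (as O₂, mg/L) consumed in oxidizing the organic
matter in a water sample — is a core indicator of organic pollution.
UV‑Vis absorption full-spectrum regression is the standard fast method, but
for fluorescent organic matter (here: the aromatic amino acids
phenylalanine, tyrosine and tryptophan as surrogates) overlapping
absorption peaks and inner-filter distortion of the fluorescence limit a
single-modality model. `codfusion` implements a feature-level fusion
pipeline for analytical chemists and chemometricians working with combined
absorption/EEM instruments:

* **COD chemistry** — theoretical conversion coefficients
  αCOD = (2m + n/2 − l)·Mr(O)/Mr from CmHnOl stoichiometry, measured
  dichromate coefficients for labeling, additive mixture COD, and exact
  integer label-grid arithmetic for dataset augmentation.
* **Synthetic spectra** — a Beer–Lambert additive absorption generator and
  a Gaussian-fluorophore EEM generator with optional inner-filter
  distortion (10^(−(A_ex+A_em)/2)), Rayleigh/Raman scatter ridges, and
  seeded Gaussian noise; these define reproducible study conditions in
  place of non-public bench data.
* **Preprocessing** — scatter-band detection from a deionized-water blank,
  scatter removal by Delaunay-triangulation barycentric interpolation,
  separable cubic-spline upsampling of the 32×9 EEM to 2217×2217, cubic
  spline augmentation of the absorption dataset on a 0.01 mg/L COD label
  grid, and a seeded 1000-sample test split.
* **2D Gabor features** — a 35-kernel filter bank (λ ∈ {3,6,9,12,15} px ×
  θ ∈ {0, π/12, π/8, π/6, π/4, π/3, 3π/8}), FFT cross-correlation with
  reflect padding, 0–255 grayscale responses on a 554×554 feature grid,
  and excitation-major flattening to a 306,916×35 feature matrix.
* **Dimensionality reduction** — PCA, FastICA, Isomap (default), LLE and
  random projections to 20×35, ranked by the mean coefficient of variation
  C̄v = Σσᵢ/|μᵢ|/n, then top-32-kernel selection and reshaping to the
  5×128 fluorescence feature block.
* **Fusion network** — a dual-channel 1D CNN absorption branch
  (2559 → 19×128 through four conv blocks, 16/32/64/128 channels),
  concatenation to 24×128, dropout 0.5, a 175-unit dense layer and a
  single linear output (≈734k parameters), trained with Adam, exponential
  LR decay and
  MSE loss; forward/backward passes run on compiled (RcppArmadillo) conv
  and pooling kernels.
* **Metrics** — R², MSE, RSS, RRMSEP, fit slope, and accuracy at 5%
  relative error.

## Worked example

Chemistry and labeling:

```r
library(codfusion)

compound_table()[c("name", "Mr", "alpha_measured", "alpha_theoretical")]
#> # A tibble: 3 × 4
#>   name             Mr alpha_measured alpha_theoretical
#>   <chr>         <dbl>          <dbl>             <dbl>
#> 1 tyrosine       181.           1.31              1.81
#> 2 phenylalanine  165.           1.48              2.08
#> 3 tryptophan     204.           1.42              2.04

mixture_cod(c(tyrosine = 15, phenylalanine = 80, tryptophan = 6))
#> [1] 146.57

fill_count(9.34, 18.78)   # augmentation labels in (9.34, 18.78] at 0.01 mg/L
#> [1] 944
fill_count(0, 146.57)     # full augmented dataset size
#> [1] 14657
```

The measured coefficients (mg O₂ per mg compound) label each mixture; the
theoretical values are larger because the stoichiometric formula ignores
nitrogen. `mixture_design()` recomputes all labels and flags the three
design rows whose recorded labels disagree with the coefficients.

A scaled-down end-to-end run (small grids and a short training schedule so
it finishes in about a minute):

```r
cfg <- pipeline_config(
  seed = 2L,
  preprocess = list(upsample_side = 256L, augment_step = 0.5, test_n = 40L),
  gabor = list(feature_side = 64L),
  train = list(cycles = 1L, epochs_per_cycle = 5L))
rec <- run_pipeline(cfg)
rec$metrics
```

which prints:

```
<retrieval_metrics> n = 40
  R^2 0.9777 | MSE 34.92 | RRMSEP 8.404% | RSS 1397 | slope 0.9316 | accuracy@5% 42.5%
```

Here `R^2` is the coefficient of determination between true
and retrieved COD, `RRMSEP` the RMSE as a percentage of the mean true COD,
and `accuracy@5%` the share of retrievals within 5% relative error. At the
desk-scale study conditions used in the test suite (augmentation step
0.1 mg/L, inner-filter distortion on, 20 epochs) the fused model reaches a
test RRMSEP of a few percent and beats the absorption-only model trained
under identical conditions.

The Gabor front end on its own:

```r
gabor_bank()
#> <gabor_bank> 35 kernels, lam in {3, 6, 9, 12, 15}, theta in {0, 0.2618, 0.3927, 0.5236, 0.7854, 1.047, 1.178} rad
gabor_kernel(gabor_params(3, 0))
#> <gabor_kernel> 39x39, lam=3 theta=0.0000 psi=0 sigma=6.2832 gamma=0.5
```

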
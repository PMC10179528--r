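# daefbone

Microarchitecture-based prediction of the micromechanical environment in
trabecular bone.

Bone allografts and other trabecular-bone scaffolds transmit macroscopic
loads down to the strain, stress and strain-energy levels that bone cells
actually experience. Bone volume fraction (BV/TV) predicts *macroscopic*
stiffness well, but it is a poor predictor of the *microscopic* loading
inside the strut network. `daefbone` implements the full analysis chain
behind the DAEF composite index, which fills that gap:

1. **Microarchitecture** (`microarch_profile()`): from a segmented 3D
   micro-CT volume, computes BV/TV (%), BS/BV (mm⁻¹), Tb.Th, Tb.Sp (mm),
   Tb.N (mm⁻¹), the structure model index (SMI), the mean-intercept-length
   fabric tensor and its bounded degree of anisotropy
   DA = 1 − MILmin/MILmax ∈ [0, 1], and the ellipsoid factor
   EF = a/b − b/c ∈ [−1, 1] from maximal inscribed ellipsoids
   (−1 plate-like, +1 rod-like). Includes 3D Otsu thresholding, cylindrical
   ROI masking, largest-component cleanup and the RMSCV precision metric.
2. **Voxel micro-FE** (`fe_compress()`): linear-elastic uniaxial
   compression (one 8-node hexahedron per bone voxel; E = 15 GPa, ν = 0.3;
   0.2 % macroscopic strain prescribed as an axial top displacement, bottom
   fixed axially) solved by incomplete-Cholesky preconditioned conjugate
   gradients, yielding element-wise axial strain ε_z, axial stress σ_z, von
   Mises stress σ_e and strain energy density W_e, plus their sample means.
3. **DAEF statistics** (`daef_fit()`): per-outcome multilinear fits
   Y = β₀ + β₁·DA + β₂·EF, pooling of the slope ratios β₂/β₁ into γ
   (median; the published reference coefficients give the canonical
   γ = 1.69), and the composite index

   ```
   DAEF = DA + γ·EF
   ```

   with per-outcome R² of each micromechanical parameter against EF, DA
   and DAEF. `daef_fit()` returns a classed model object with `print`,
   `summary`, `coef`, `predict`, `residuals` and `plot` methods.

A seeded synthetic trabecular generator (`make_trabecular()`: Boolean
plate/rod unions with controllable thickness, spacing, plate/rod mix and
orientation concentration, calibrated to human femoral-head population
values) makes the whole chain testable without scanner data, and
`run_full()` orchestrates cohorts end to end (per-sample CSV, correlation
tables, coefficient table, γ and a text report, with crash-safe resume).

## Worked example

```r
library(daefbone)

## one synthetic femoral-head-like sample, 64^3 voxels at 0.05 mm
v <- make_trabecular(trabecular_spec(seed = 21))
p <- microarch_profile(v)
print(p)
#> <microarch_profile>
#>   BV/TV 32.5 %   BS/BV 13.55 1/mm   Tb.Th 0.199 mm
#>   Tb.N  1.64 1/mm Tb.Sp 0.428 mm
#>   SMI -0.29   DA 0.451   EF -0.106 (coverage 4%)

## compress it by 0.2 % macroscopic strain
r <- fe_compress(v, tol = 1e-6)
print(r$profile)
#> <micromech_profile>
#>   mean eps_z  -0.0925 %   mean sigma_z -13.868 MPa
#>   mean sigma_vm 16.334 MPa   mean W_e 0.01387 MPa
```

The microarchitecture lands in the human femoral-head range (BV/TV ≈ 31 %,
Tb.Th ≈ 0.2 mm, DA ≈ 0.5; the slightly negative SMI is typical of concave
femoral-head networks), and the mean axial strain magnitude (0.093 %) is
roughly half the applied 0.2 % — the strut network partitions the
macroscopic strain, so cells on the struts see far less than the applied
deformation.

```r
## the canonical gamma from the published reference coefficients
ref <- daef_reference_coefficients()
aggregate_gamma(ref$beta2 / ref$beta1)
#> [1] 1.689172   # median of the four beta2/beta1 ratios -> 1.69

daef_index(DA = 0.5, EF = 0.06)   # DAEF of an average sample
#> [1] 0.6014

## a small end-to-end cohort
cfg <- run_config(source = list(type = "synth", n = 8, base_seed = 1),
                  solver = list(tol = 1e-6, max_iter = 20000))
res <- run_full(cfg)
summary(res$model)
```

A thin command-line wrapper over the same functions lives at
`inst/cli/daefbone.R` (`synth`, `measure`, `fe`, `stats`, `run`
subcommands).

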
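---
title: "Methods: trabecular microarchitecture, voxel micro-FE and the DAEF index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trabecular microarchitecture, voxel micro-FE and the DAEF index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package computes

`daefbone` turns a 3D voxel image of trabecular bone into (i) the eight
standard microarchitectural parameters, (ii) element-wise micromechanical
fields from a linear-elastic compression simulation, and (iii) the DAEF
composite index

$$\mathrm{DAEF} = \mathrm{DA} + \gamma\,\mathrm{EF},$$

where DA is the degree of anisotropy of the mean-intercept-length (MIL)
fabric, EF the ellipsoid factor, and $\gamma$ pools the slope ratios
$\beta_2/\beta_1$ of the per-outcome multilinear fits
$Y = \beta_0 + \beta_1\,\mathrm{DA} + \beta_2\,\mathrm{EF}$ over the four
micromechanical outcomes ($\varepsilon_z$, $\sigma_z$, $\sigma_e$, $W_e$).
With the published reference coefficients for human femoral-head allograft
cores, the median of the four ratios gives the canonical $\gamma = 1.69$.

All stages run on synthetic microstructures with known ground truth, so the
entire chain is testable without scanner data.

## Conventions

* Volumes are isotropic voxel grids; `spacing_mm` is the voxel edge length.
  Voxel centres sit at `origin + (index - 1 + 0.5) * spacing`.
* Binary volumes: 1 = bone, 0 = marrow. Foreground connectivity is
  26-connected, background 6-connected.
* Units: mm, MPa, dimensionless strain. A Young's modulus of 15 GPa is
  stored as 15000 MPa.
* Every stochastic operation takes an explicit seed and restores the
  caller's RNG stream; a pipeline run is reproducible from its config alone.

## Microarchitecture stage

**Thresholding.** A single global Otsu threshold maximising between-class
variance of the full 3D histogram (256 bins, or exact value splits when the
volume holds few distinct values), optionally restricted to the ROI
histogram. Slice-wise thresholding is deliberately not offered.

**ROI.** A central cylindrical region of interest (classically 6 mm
diameter, 8 mm height) is applied as a mask; total volume (TV) is the mask
volume, and surface triangles whose centroid falls outside the eroded mask
are dropped so that ROI cut faces never count as bone surface.

**BV/TV** is an exact voxel tally. **BS/BV** measures the triangulated
0.5-level isosurface of the lightly smoothed (Gaussian, 0.8 voxel) phase
field. The triangulation uses a tetrahedral decomposition of each grid cube
(six tetrahedra sharing the cube diagonal, matching face diagonals between
neighbours, hence crack-free); vertex normals come from the interpolated
field gradient. On analytic fixtures the surface area is within a few
percent of $4\pi r^2$ (sphere) and $2\pi r L$ (open cylinder).

**Tb.Th / Tb.Sp** use the model-independent largest-inscribed-sphere
definition: the per-voxel thickness is the diameter of the largest sphere
fully inside the phase containing that voxel, computed from the exact
Euclidean distance transform followed by sphere painting (with a
containment-dominance pruning that leaves the result bit-identical to the
brute-force definition — the test suite checks exact equality against an
$O(n^2)$ oracle). Tb.Th averages over bone, Tb.Sp over marrow within the
ROI. **Tb.N** follows the plate-model convention (BV/TV)/Tb.Th, which is
the convention consistent with the published population means
(30.9%/0.2 mm $\approx$ 1.5 mm$^{-1}$).

**SMI** $= 6 V S'/S^2$ with $S'$ estimated by offsetting every surface
vertex outward along its normal by half a voxel and re-measuring the area.
Plates $\approx 0$, rods $\approx 3$, spheres $\approx 4$; negative values
are legitimate for concave surfaces. Plate and rod reference fixtures span
the grid so that their isosurfaces are open (no artificial edge caps) —
the same situation as trabeculae cut by a real ROI.

**MIL fabric / DA.** For each of 257 quasi-uniform hemisphere directions
(Fibonacci lattice) a parallel grid of test lines (2-voxel spacing,
0.25-voxel sampling step, seeded fractional grid offsets) is marched through
the mask; MIL($\omega$) = bone path length / bone–marrow crossings. The
quadric $1/\mathrm{MIL}^2(\omega) = \omega^T H \omega$ is fitted by least
squares; MIL ellipsoid semi-axes are $1/\sqrt{\lambda_i}$. DA uses the
bounded form $1 - \min/\max$ of the semi-axis lengths (not their squares).
Directions without crossings are dropped with a warning; fewer than nine
usable directions is an error. A perfectly layered structure drives a
quadric eigenvalue to zero; it is clipped so DA $\to 1$ instead of failing.
The suite compares the fitted semi-axes against a dense line-casting oracle
(1-voxel line grid, 0.25-voxel steps) within 3%.

**EF.** Seeds are drawn (seeded) from the distance ridge (26-neighbourhood
maxima of the squared EDT). Per seed, axis directions come from the local
structure tensor of the smoothed phase-field gradient — gradients live on
the phase boundary, which makes this far more robust on thin voxelized
struts than coordinate PCA. Each semi-axis is dilated in 0.5-voxel steps
while the ellipsoid surface (162 unit directions) stays inside the phase;
containment is tested on the trilinearly interpolated smoothed field
(sigma 0.5 voxel, level 0.45) with at most three grazing contacts allowed,
so single-voxel surface roughness does not freeze growth while genuine
marrow gaps block it. Out-of-grid samples use edge replication: structures
cut by the volume boundary are treated as continuing. Each bone voxel takes
the $a/b - b/c$ of the largest-volume ellipsoid containing it (half-voxel
assignment margin, since near-voxel-thin ellipsoids would otherwise claim
almost no voxel centres); the sample EF is the volume-weighted mean over
covered voxels and the coverage fraction is reported, with a warning below
50%. At desk-scale resolutions (struts 3–5 voxels thick) coverage on
trabecular networks is modest — the per-voxel map is sparse but its mean is
stable and the primitive limits ($+1$ rod, $-1$ plate, $0$ sphere) are met
within 0.15.

**RMSCV** $= 100\sqrt{\mathrm{mean}_i\,(SD_i/\mathrm{mean}_i)^2}$ over
replicates of each sample; parameters with a zero within-sample mean are
reported NA.

## Micro-FE stage

One trilinear 8-node hexahedron per bone voxel; shared nodes deduplicated;
the mesh keeps the largest 26-connected component and requires it to span
the occupied z-range (otherwise there is no load path). Boundary
conditions: all bottom-surface nodes fixed axially, all top-surface nodes
displaced by $-\varepsilon\,H$ (0.2% strain over 8 mm gives 0.016 mm);
lateral degrees of freedom stay free except two bottom pins (one node in
x and y, a second node at the same y in y) that remove lateral rigid-body
modes without disturbing the uniaxial patch solution.

The SPD system is solved by conjugate gradients to a relative residual of
$10^{-8}$. The default preconditioner is a zero-fill incomplete Cholesky
factorisation of the sparse-assembled free-dof stiffness (with automatic
diagonal-shift retry), which solves a 64³ trabecular mesh (~400k DOF) in a
few minutes on one core; a matrix-free diagonally preconditioned variant is
available as `method = "jacobi"` for memory-constrained use. Everything is
ordered lexicographically, so solves are deterministic.

Element fields are recovered at the centroid (the Gauss average for
trilinear hexahedra): $\varepsilon_z$, $\sigma_z$ via isotropic Hooke's
law, and the von Mises stress. The strain energy density $W_e$ is the
element-mean over the full 2×2×2 quadrature, so
$\sum_e W_e V_e = \tfrac12 u^T K u$ holds to machine precision — the
energy-balance diagnostic checks external work against internal energy.
Sample summaries are unweighted element means (equal voxel volumes), with
$\varepsilon_z$ in percent. On a solid block the patch test reproduces
$\varepsilon_z = -0.002$, $\sigma_z = -30$ MPa, $\sigma_e = 30$ MPa,
$W_e = 0.03$ MPa to $10^{-6}$ relative.

## Statistics stage

Pairwise Pearson $r^2$ with two-tailed p-values and per-column Shapiro–Wilk
normality screening (advisory: a warning, never a gate — the source
protocol reports the check but no fallback). Significance is raw
$p < 0.05$; no multiplicity correction is applied, matching the original
analysis. The multilinear fits use ordinary least squares via `lm`.

$\gamma$ aggregation defaults to the **median** of the defined
$\beta_2/\beta_1$ ratios: from the published coefficients the four ratios
are 1.75, 1.63, 1.49 and 2.22, whose mean (1.77) contradicts the published
pooled value while the median (1.69) reproduces it at two decimals. Both
methods are exposed. `daef_fit()` returns a classed model object with
`print`, `summary`, `coef`, `predict`, `residuals` and `plot` methods; the
reported $R^2$ table (outcomes against EF, DA, DAEF) states results without
ranking them.

## Synthetic-data generator

`make_trabecular()` places plates (thin boxes, in-plane extent one
structural spacing) and rods (capsules, length four structural spacings)
by Boolean union until the volume fraction reaches
`thickness_mm / spacing_struct_mm`, then applies a one-voxel morphological
closing and keeps the largest component. Orientations follow an axially
symmetric Watson-type law with concentration `kappa`: rod axes concentrate
toward z, plate normals toward the transverse plane; `kappa = 0` is
isotropic. Rasterized strut half-width subtracts half a voxel so the
realized Tb.Th matches the nominal thickness after voxelization.

Defaults (64³ at 0.05 mm, thickness 0.2 mm, spacing 0.65 mm,
`rod_fraction` 0.5) emulate human femoral-head trabecular cores: they were
calibrated once so the measured BV/TV falls near 31%, Tb.Th near 0.2 mm,
DA near 0.5 and the micro-FE mean axial strain is several times smaller
than the applied macroscopic strain — the population values and the strain
attenuation reported for that tissue. What the generator does **not**
emulate: curved and perforated trabeculae, partial-volume gray levels,
scanner artifacts (beam hardening, rings), and spatial gradients across a
specimen. Passing tests therefore demonstrate correctness of the measurement
and simulation chain on controlled geometry, not scanner realism.

Repeat scans are modelled as the binary phase scaled to 0/255 plus additive
Gaussian noise — the simplest model that exercises re-thresholding and the
RMSCV metric. The regression fixture draws DA uniform on [0,1] and EF
uniform on [-1,1] with Gaussian noise, matching OLS assumptions.

## Problem sizes and numerical choices

The test-suite and acceptance runs use 64³ volumes (3.2 mm cubes) for
morphometry and one 64³ micro-FE solve, 48³ for precision replicates, and
16–32³ for exact brute-force oracles; these sizes keep a full run on one
core in minutes while leaving 3–5 voxels across each strut — the coarsest
resolution at which the surface and thickness estimators remain within
their stated tolerances. Solver tolerance is $10^{-8}$ for patch and
energy checks and $10^{-6}$ for cohort solves, where the element means are
converged far below measurement variability. Degenerate inputs (constant
gray volume, empty phases, full-solid MIL, collinear predictors, missing
load path) raise errors with explicit messages rather than propagating NaN.

## Known limitations

* EF coverage is low on coarse trabecular networks (thin ellipsoids claim
  few voxel centres); the map is best interpreted through its mean, and the
  per-sample EF carries the seed sensitivity that the RMSCV analysis
  quantifies (EF and SMI are the least precise parameters, as in the
  original precision study).
* The hexahedral mesh is voxel-conforming: surface staircasing slightly
  stiffens thin oblique struts relative to smooth-surface tetrahedral
  meshes. An interface seam (`build_hex_mesh` returning a generic mesh
  object) leaves room for a future tetrahedral backend.
* Material behaviour is homogeneous, isotropic, linear elastic; no damage,
  no marrow phase, no heterogeneous modulus from gray levels.
* `run_full()` processes samples independently and resumes from its
  per-sample CSV, but does not parallelise.
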
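---
title: "Methods: regional trabecular morphometry, voxel micro-FE, and structure-mechanics statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regional trabecular morphometry, voxel micro-FE, and structure-mechanics statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its models and the choices made
where the methodology was genuinely open. It states no empirical result
beyond what the test suite and `scripts/acceptance.R` compute themselves.

## The analysis unit

The analysis unit is a cubic trabecular region of interest (ROI) cut from
an articular process, labelled by quadrant (SA, SP, IA, IP — the
superior/inferior × anterior/posterior split), vertebral level (C2–C7) and
side (left/right), and carrying a facet angle θ: the angle between gravity
and the shear force acting on the facet plane. Cervical facets sit near
45°, which is the package default; θ is kept a free per-region parameter
because no per-level tabulation of facet angles is available. Voxel
coordinates are 0-based and ROIs are half-open boxes
`[origin, origin + size)`; the z axis is always the loading axis.

## Morphometry

**Binarization.** The threshold is a required input: segmentations of this
kind are protocol-specific, and silently guessing one would make results
irreproducible. An Otsu histogram threshold (`otsu_threshold()`) is
offered as an explicit opt-in. Degenerate masks (all bone, all marrow)
warn instead of erroring, and `analyze_roi()` converts the downstream
undefined parameters into `NA` plus a `note` column, so one solid ROI
cannot abort a 144-row table.

**Thickness and separation.** Tb.Th and Tb.Sp use
Hildebrand–Rüegsegger sphere fitting: every phase voxel receives the
diameter of the largest sphere fully contained in its phase that covers
it, and the parameter is the map mean. The implementation computes an
exact squared Euclidean distance transform (separable lower-envelope
algorithm) and paints maximal spheres in decreasing radius order (C++).
Sphere radii are `sqrt(d²) − 0.5` voxels — the distance from the voxel
centre to the phase boundary rather than to the opposite voxel centre —
which makes a w-voxel slab exactly w voxels thick for odd w and w ± 1 for
even w. Grid borders are treated as phase continuations: only in-grid
opposite-phase voxels limit a sphere, so a plate spanning the ROI is not
artificially thinned at its rim. A phase filling the whole grid has
unbounded thickness and is reported `NA` with a warning. The test suite
pins the implementation to an exhaustive per-voxel sphere search on small
random masks.

**Surface area.** BS/BV triangulates the 0.5-level isosurface by marching
tetrahedra (six tetrahedra per grid cell, linear edge interpolation),
with a one-layer background pad so surfaces close at the ROI boundary.
Raw isosurfaces of binary data overestimate curved areas by roughly 7–8%,
so the field is pre-smoothed with a small Gaussian before extraction. The
default σ = 0.65 voxel was calibrated once against analytic spheres
(digital balls of radius 4–16 voxels land within about ±3% of 4πr²;
radii below ~4 voxels remain discretization-limited) and is not a
per-dataset tuning knob. Axis-aligned geometry is insensitive to the
smoothing (flat faces are exact by symmetry); σ = 0 disables it when
exact plate/cube areas are wanted. Note that even unsmoothed isosurfaces
bevel 90° voxel edges — a solid n³ cube measures slightly under 6n² by an
O(1/n) edge term, which is correct isosurface geometry, not a defect.

**Connectivity.** Tb.Pf follows Hahn's convexity construction:
`(S₁ − S₂)/(V₁ − V₂)` before/after a single-voxel dilation with the
classical 6-connected structuring element (26-connected available).
Convex, fragmented structures grow surface under dilation (positive
Tb.Pf); concave, well-connected networks lose surface (negative).

**Tb.N.** The model-independent convention `Tb.N = (BV/TV)/Tb.Th` is the
default; the plate-model variant `0.5·BS/TV` is available behind
`tb_n_method = "plate"` for comparison with older instrument output.

**BMD.** A linear HU→mg/cc calibration must be supplied
(`bmd_calibration(slope, intercept)`); calibrations are scanner- and
session-specific, and no default is claimed.

## Voxel micro-FE

**Meshing.** One trilinear hexahedron per foreground voxel on a shared
node grid. Voxel meshing preserves the imaged geometry exactly and avoids
irreproducible surface-remeshing parameters; consequently no particular
element count is targeted. Only 6-connected components spanning bottom to
top are meshed by default: they are exactly the material that can carry
load between the platens, while floating fragments would make the system
singular. (A lattice of four disconnected vertical rods keeps all four
rods; a fragment touching neither face is dropped and counted.)

**Material.** Per-element gray value → density → modulus:
ρ = 0.00097·GV, E = 19.04·ρ^1.64, ν = 0.3. The laws are dimensionally
implicit; this package fixes the convention HU → g/cc → MPa and exposes
every coefficient. Negative gray values (air, noise) are clamped at a
configurable density floor with a warning; zero-stiffness elements are
counted and reported.

**Boundary conditions and solve.** Displacement-controlled axial
compression: bottom face fixed, top face driven by `strain × height`.
The default `"platen"` mode fixes the tangential components on both faces
(platen friction); `"frictionless"` constrains only the axial components
plus a three-point lateral pin, under which a homogeneous cube is in an
exact uniform uniaxial state — the configuration used for solver
verification (apparent modulus = tissue modulus to 1e-8). Assembly scales
one reference element stiffness (2×2×2 Gauss) by each element's modulus;
the reduced SPD system is solved directly below 50k unknowns and by
Jacobi-preconditioned conjugate gradients (relative residual 1e-10)
above. Strains and stresses are recovered at element centroids; principal
values come from the closed-form symmetric 3×3 eigen solution. The solve
is quasi-static and geometrically linear; the experimental strain rate is
metadata only.

**Plasticity.** The bilinear tissue law (transition strains 0.8%
compressive, 0.48% tensile; `tissue_yield_strains()`) is available as an
incremental extension: after each displacement increment, elements whose
accumulated principal strain passes a transition continue with
`hardening_ratio × E` (default 0.05, a conventional small hardening
fraction — the literature rarely reports a tissue hardening modulus).
This explicit tangent stepping is adequate for the monotonic compression
ramps used here; it is not a general return-mapping plasticity.

**"75% Mises" summary.** The field summary reports the subset of elements
at or below a given quantile (default 0.75) of von Mises stress — i.e.
excluding the top quarter, which concentrates at the loaded face. This is
the package's reading of the lower-75% convention in regional micro-FE
reports; the quantile is a parameter, so other readings (e.g. the 75th
percentile itself) are one argument away.

## Stress–strain reduction

Compression records store compressive stress and strain as positive
magnitudes. The elastic window (Es, Ee) is auto-detected because
published reductions rarely state how it was chosen: rolling OLS slopes
at increasing spans (2, 4, 8, … points) are scanned for maximal windows
whose local slopes stay within ±5% of the window median; among admissible
windows of at least n/8 points the **steepest** median wins. Steepness
rather than length is deliberate: on a bilinear curve whose post-yield
branch holds more samples, the longest near-constant-slope window is the
plastic branch, and a longest-window rule would report the hardening
modulus as E. Fine spans resolve noise-free records exactly; noisy
records only form long admissible windows at coarser spans (with stepwise
band widening as a fallback), and trailing points whose adjacent secant
leaves the window consensus are trimmed, pinning Ee at the yield point on
clean data. A manual window always overrides detection. Median E error on
bilinear records with 2%-of-yield stress noise is under 1% (simulated in
the test suite, 200 replicates).

The 0.2%-offset yield intersects the measured polyline with
σ = E(ε − 0.002) by exact linear interpolation — deterministic, no
smoothing. `offset = 0` degenerates to a tangent departure and is handled
explicitly. `fit_bilinear()` estimates (E, H, breakpoint) by grid search
over interior breakpoints plus continuous refinement of the
piecewise-linear least squares; collinear data flag the breakpoint
unidentifiable rather than erroring. Allowable stress is
σ_yield / cos θ, defined on 0° ≤ θ < 90° and strictly increasing in θ.

## Statistics

The factorial ANOVA is fixed-effects with Type III sums of squares under
sum-to-zero contrasts — the convention of the statistical packages such
regional tables are produced with — falling back to Type II with a named
warning when cells are empty. Partial η² = SS/(SS + SS_error) is also
reported ×100 as "Eta%". Bartlett's test over the design cells runs first
and its p-value travels with the model summary. A response with no
variance at all reports null effects (F = 0) rather than 0/0. Simple
effects fix one factor per level and test the other against the pooled
full-model error by default (stratum-local error optional), with raw and
Bonferroni-adjusted p-values; strata with fewer than two represented
levels are skipped with a note. Regressions report slope, intercept,
adjusted R² = 1 − (1 − R²)(n − 1)/(n − 2) and the two-sided Pearson p.
Ridge regression solves (ZᵀZ + λI)β = Zᵀy on standardized predictors
(sd with n − 1), so λ = 0 is exactly OLS and coefficients shrink
monotonically in L2 norm.

One caveat is replicated deliberately: ROIs from the same donor are
treated as independent observations, as regional studies of this design
do. A donor-level random effect would be the stricter model; it is out of
scope here and the tables should be read accordingly.

## The synthetic-data module

The phantoms define the study conditions for every test:

* **Geometry.** Plate and rod lattices are axis-aligned with closed-form
  BV/TV and thickness; plates default to normal-z (the loading axis), rods
  run along z. Whole plates/rods are placed evenly, so the achieved BV/TV
  is within one element quantum (one plate or rod) of the target — the
  granularity every phantom test tolerates. Real trabecular networks are
  neither axis-aligned nor periodic; these phantoms validate the
  *measurement operators*, not biological realism.
* **Scale.** The default 64³ grid at 0.078 mm voxels spans the 5 mm ROI
  cube of the motivating protocol at a coarsened resolution (the original
  ~17 µm scans would need ~300³ grids); 5-voxel (0.39 mm) elements keep
  plate/rod features several voxels wide at that scale.
* **Contrast and noise.** Bone/marrow gray values default to 2000/0 HU so
  midpoint thresholding is unambiguous, with additive Gaussian noise
  (default sd 100 HU, ~5% of contrast — a realistic micro-CT noise
  floor) applied before the optional partial-volume Gaussian blur; with
  the blur off, the noiseless midpoint binarization reproduces the ground
  truth mask exactly. The `homogeneous` architecture is all-foreground
  with the uniform partial-volume value `marrow + bvtv·(bone − marrow)`,
  giving a homogeneous material field for FE verification.
* **Curves.** Bilinear with the tissue transition strain as default
  breakpoint; noise defaults to zero because the constitutive law is the
  ground truth and measurement noise is opt-in per experiment.
* **Paired tables.** Default slope/intercept follow the
  BV/TV–Young's-modulus template relation (y = 299.667x − 76.9) with
  predictor range 0.15–0.55 (plausible facet BV/TV) and response noise
  sd 30, sized once so the adjusted R² sits near the reported ≈0.57;
  n = 144 covers the 4×6×2 design three times.

All generators are deterministic given their spec (seeded via isolated
RNG state), which is what makes the end-to-end pipeline byte-reproducible.

## Numerical conventions and degenerate inputs

Quantiles use R's default type 7. Equality thresholds: CG relative
residual 1e-10; direct solve below 50k unknowns; bilinear breakpoint
refinement to square-root machine precision; elastic-window band ±5%
before escalation. Ties in lattice placement resolve by rounding plate
centres to the nearest voxel start. Degenerate inputs are contracts, not
crashes: empty masks error with the failing quantity named; solid ROIs
yield `NA` parameters with notes; meshes without a bottom-to-top load
path abort with a "no load path" diagnostic; singular systems name the
likely cause (floating fragment / rigid-body mode).

Problem sizes in the shipped tests were chosen as the smallest that
exercise each property cleanly: 16³ for the homogeneous FE verification,
2×2×2 against the dense oracle, 64³ for the end-to-end pipeline run, 200
replicates for curve-noise simulations and 500 for regression recovery.

## Known limitations

No structure-model index, connectivity density, Euler number or
anisotropy degree (deliberately out of scope); no cortical/trabecular
auto-segmentation; no contact, geometric nonlinearity, or rate
dependence in the FE stage; no viscoelastic curve models or
fixture-compliance correction; DICOM series are not read directly
(convert to NIfTI) and volume export is NIfTI-only; donor clustering is
ignored as discussed above.
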
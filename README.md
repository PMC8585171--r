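# trabmech

Regional trabecular-bone analysis for micro-CT studies of load-bearing
bone — developed around the four-quadrant analysis of cervical articular
processes (superior/inferior × anterior/posterior, SA/SP/IA/IP, across
vertebral levels C2–C7 and left/right sides), but applicable to any cubic
trabecular region of interest. It is written for bone researchers who want
one reproducible path from a gray-value volume to microstructure,
simulated mechanics, experimental curve reduction, and the statistics
linking the two.

The package covers four stages, each usable on its own:

**Morphometry.** From a binarized ROI it computes the standard
histomorphometric parameters: bone volume fraction BV/TV; trabecular
thickness Tb.Th and separation Tb.Sp by Hildebrand–Rüegsegger
largest-inscribed-sphere fitting on an exact 3-D Euclidean distance
transform; bone-specific surface BS/BV from a marching-tetrahedra
triangulated isosurface; trabecular number Tb.N = (BV/TV)/Tb.Th;
trabecular pattern factor Tb.Pf = (S₁−S₂)/(V₁−V₂) (surface/volume before
and after a one-voxel dilation — lower means better connected); and BMD
via a user-supplied linear HU→mg/cc calibration.

**Voxel micro-FE.** Every foreground voxel becomes an 8-node hexahedral
element (2×2×2 Gauss quadrature); gray values map to material through

    ρ = 0.00097 · GV        [g/cc per HU]
    E = 19.04 · ρ^1.64      [MPa]
    ν = 0.3

A displacement-controlled compression (fixed bottom, axially driven top;
platen-friction or frictionless lateral handling) is solved with a sparse
direct factorization or Jacobi-preconditioned conjugate gradients, giving
element stress/strain tensors, von Mises and principal fields, face
reactions, and the apparent modulus (reaction/area)/(u_z/height). A
bilinear elastic–plastic tissue law (transition strains 0.8% compressive /
0.48% tensile) is available behind an incremental-loading flag.

**Stress–strain reduction.** Experimental records reduce to Young's
modulus over an auto-detected elastic window (Es, Ee), the 0.2%-offset
yield point Rp0.2, curve maxima, a free-breakpoint bilinear fit, and the
facet-angle allowable stress [σ] = σ_yield / cos θ, where θ is the angle
between gravity and the shear force on the facet plane (≈45° for cervical
facets).

**Statistics.** Three-factor fixed-effects ANOVA (region × side × level)
with Type III sums of squares, Bartlett's homogeneity test, partial
η² = SS_effect/(SS_effect+SS_error) reported as Eta%, Bonferroni-adjusted
simple effects, OLS structure–mechanics regressions with adjusted R² and
Pearson p, and ridge regression on standardized predictors.

Because micro-CT scans of this kind are rarely deposited, the package
ships a synthetic-data module — plate/rod/homogeneous/solid phantoms with
known ground truth, bilinear curves, and paired structure/mechanics
tables — so the entire pipeline is testable end to end.

## Worked example

```r
library(trabmech)
library(dplyr)

# a 64³ rod-lattice phantom: 5 mm cube at 78 µm voxels, HU noise sd 100
ph <- generate_phantom(phantom_spec(architecture = "rod_lattice", seed = 42))
ph
#> <phantom> rod_lattice, 64x64x64 voxels, BV/TV 0.220 (target 0.250)

rois   <- quadrant_rois(ph$volume, level = "C4", side = "right")
morpho <- analyze_morphometry(ph$volume, rois, threshold = 1000)
select(morpho, label, bvtv, tb_n, tb_th, tb_sp, bs_bv, tb_pf)
#> # A tibble: 4 × 7
#>   label  bvtv  tb_n tb_th tb_sp bs_bv tb_pf
#> 1 SA    0.220 0.602 0.365 0.519  9.69  4.52
#> ...
```

BV/TV lands a plate-quantum below the 0.25 target (the lattice is
discretized in whole rods); Tb.Th is 0.365 mm ≈ the 5-voxel rod width.
The micro-FE stage on the SA quadrant:

```r
roi_sa <- crop_volume(ph$volume, rois$SA)
mesh   <- build_mesh(binarize(roi_sa, 1000))
sol    <- solve_compression(mesh, map_materials(roi_sa, mesh), strain = 0.01)
sol
#> <fe_solution> 14400 elements, 1% apparent strain (platen)
#>   apparent modulus 12.54 MPa, reaction 1.563 N, von Mises in [0.297, 0.717] MPa
summarize_field(sol, quantile = 0.75)
#> 1 von_mises_below_q75  0.297 0.592   0.543   10800   # lower-75% Mises subset
```

The apparent modulus (12.5 MPa) is far below the ~57 MPa tissue modulus
implied by the material law at 2000 HU — the expected effect of 22% bone
volume fraction. Curve reduction and the structure–mechanics regression:

```r
cv <- generate_curve(curve_spec(tissue_modulus = 100, noise_sd = 0.016, seed = 7))
analyze_curve(cv, theta = 45)
#>   youngs_modulus yield_stress yield_strain allowable_stress
#> 1           95.4        0.817       0.0106             1.16

d <- generate_paired_dataset(paired_spec(seed = 42))
regress(d, x, y)
#> y ~ x: y = 321.2x - 86.93 (adj R2 = 0.6464, p = 4.41e-34, n = 144)
```

A single noisy record recovers E within ~5%; across replicates the median
error is below 1% (see the test suite). `run_pipeline()` chains all
stages from one YAML config and writes CSV/VTK/JSON outputs plus a
manifest with seed and config hash; `inst/scripts/trabmech` exposes the
same stages as shell subcommands.

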
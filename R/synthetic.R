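#' Phantom specification
#'
#' Describes a synthetic two-phase (bone/marrow) trabecular phantom with
#' known ground truth. Phantoms stand in for the 5 x 5 x 5 mm trabecular
#' cubes cut from cervical articular processes: the default 64-voxel cube at
#' 0.078 mm spacing spans 5 mm.
#'
#' Architectures:
#' * `plate_lattice` - parallel bone plates of the stated thickness, normal
#'   to `normal_axis` (default z, the loading axis), spaced to hit
#'   `target_bvtv`;
#' * `rod_lattice` - square-section rods along z on a square x-y grid;
#' * `homogeneous` - all-foreground mask with a uniform partial-volume gray
#'   value `marrow_hu + target_bvtv * (bone_hu - marrow_hu)` (a homogeneous
#'   material field, used for FE verification);
#' * `solid` - all-foreground at full bone gray value.
#'
#' @param shape_voxels Integer triple, grid size in voxels.
#' @param voxel_size Voxel edge length in mm.
#' @param architecture One of `"plate_lattice"`, `"rod_lattice"`,
#'   `"homogeneous"`, `"solid"`.
#' @param target_bvtv Target bone volume fraction in (0, 1].
#' @param element_thickness Plate/rod thickness in mm (>= `voxel_size`).
#' @param bone_hu,marrow_hu Gray values of the two phases; `bone_hu >
#'   marrow_hu` so midpoint thresholding is unambiguous.
#' @param noise_sd Additive Gaussian HU noise (applied before any blur).
#' @param blur_sigma Optional Gaussian blur in voxels (0 = none), emulating
#'   partial-volume blur after the noise is applied.
#' @param normal_axis Axis (1, 2 or 3) the plates are normal to.
#' @param seed Integer RNG seed; generation is deterministic given the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape_voxels = c(64L, 64L, 64L),
                         voxel_size = 0.078,
                         architecture = c("plate_lattice", "rod_lattice",
                                          "homogeneous", "solid"),
                         target_bvtv = 0.25,
                         element_thickness = 5 * voxel_size,
                         bone_hu = 2000,
                         marrow_hu = 0,
                         noise_sd = 100,
                         blur_sigma = 0,
                         normal_axis = 3L,
                         seed = 1L) {
  architecture <- match.arg(architecture)
  shape_voxels <- as.integer(shape_voxels)
  if (length(shape_voxels) != 3L || any(shape_voxels < 2L)) {
    abort("`shape_voxels` must be three integers >= 2.")
  }
  if (!(target_bvtv > 0 && target_bvtv <= 1)) {
    abort("`target_bvtv` must lie in (0, 1].")
  }
  if (element_thickness < voxel_size) {
    abort("`element_thickness` must be at least one voxel.")
  }
  if (bone_hu <= marrow_hu) abort("`bone_hu` must exceed `marrow_hu`.")
  if (noise_sd < 0 || blur_sigma < 0) {
    abort("`noise_sd` and `blur_sigma` must be non-negative.")
  }
  if (!normal_axis %in% 1:3) abort("`normal_axis` must be 1, 2 or 3.")
  structure(list(shape_voxels = shape_voxels, voxel_size = voxel_size,
                 architecture = architecture, target_bvtv = target_bvtv,
                 element_thickness = element_thickness, bone_hu = bone_hu,
                 marrow_hu = marrow_hu, noise_sd = noise_sd,
                 blur_sigma = blur_sigma, normal_axis = as.integer(normal_axis),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# evenly placed runs of `thick` voxels along an axis of length n;
# returns a logical vector; errors if the implied spacing is below `thick`
lattice_runs <- function(n, thick, frac) {
  n_runs <- max(1L, round(frac * n / thick))
  if (n / n_runs < thick) {
    abort(sprintf(paste0("infeasible lattice: %d runs of %d voxels need ",
                         "spacing >= thickness in a %d-voxel axis; lower ",
                         "`target_bvtv` or `element_thickness`."),
                  n_runs, thick, n))
  }
  on <- logical(n)
  centers <- (seq_len(n_runs) - 0.5) * n / n_runs
  for (ctr in centers) {
    s <- max(0L, min(n - thick, as.integer(round(ctr - thick / 2))))
    on[(s + 1L):(s + thick)] <- TRUE
  }
  on
}

#' Generate a trabecular phantom
#'
#' Builds the ground-truth mask for the requested architecture, composes the
#' HU volume (`bone_hu` on the mask, `marrow_hu` elsewhere), adds iid
#' Gaussian HU noise, and optionally blurs. The noiseless volume binarized
#' at the HU midpoint reproduces the ground-truth mask exactly.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `phantom`: `volume` ([image_volume()]), `mask`
#'   (ground-truth [binary_volume()]), `achieved_bvtv`, and `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(shape_voxels = c(32, 32, 32),
#'                                     noise_sd = 0))
#' ph$achieved_bvtv
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape_voxels
  t_vox <- max(1L, as.integer(round(spec$element_thickness / spec$voxel_size)))
  mask <- switch(spec$architecture,
    solid = ,
    homogeneous = array(TRUE, dim = d),
    plate_lattice = {
      ax <- spec$normal_axis
      on <- lattice_runs(d[ax], t_vox, spec$target_bvtv)
      perm <- array(FALSE, dim = d)
      idx <- slice.index(perm, ax)
      perm[] <- on[idx]
      perm
    },
    rod_lattice = {
      onx <- lattice_runs(d[1], t_vox, sqrt(spec$target_bvtv))
      ony <- lattice_runs(d[2], t_vox, sqrt(spec$target_bvtv))
      outer(onx, ony) %o% rep(TRUE, d[3])
    })
  mask <- array(as.logical(mask), dim = d)
  hu <- array(spec$marrow_hu, dim = d)
  if (spec$architecture == "homogeneous") {
    hu[] <- spec$marrow_hu + spec$target_bvtv * (spec$bone_hu - spec$marrow_hu)
  } else {
    hu[mask] <- spec$bone_hu
  }
  if (spec$noise_sd > 0) {
    withr::with_seed(spec$seed, {
      hu <- hu + array(rnorm(prod(d), sd = spec$noise_sd), dim = d)
    })
  }
  if (spec$blur_sigma > 0) hu <- gauss_blur3d(hu, spec$blur_sigma)
  structure(list(volume = image_volume(hu, spec$voxel_size),
                 mask = binary_volume(mask, spec$voxel_size),
                 achieved_bvtv = mean(mask),
                 spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %s, %s voxels, BV/TV %.3f (target %.3f)\n",
              x$spec$architecture,
              paste(x$spec$shape_voxels, collapse = "x"),
              x$achieved_bvtv, x$spec$target_bvtv))
  invisible(x)
}

# separable Gaussian blur of a 3-D array (zero-padded borders)
gauss_blur3d <- function(arr, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  d <- dim(arr)
  for (ax in 1:3) {
    out <- array(0, dim = d)
    for (j in seq_along(k)) {
      off <- j - r - 1L
      src <- pmin(pmax(seq_len(d[ax]) + off, 1L), d[ax])
      out <- out + k[j] * switch(ax,
        arr[src, , , drop = FALSE],
        arr[, src, , drop = FALSE],
        arr[, , src, drop = FALSE])
    }
    arr <- out
  }
  arr
}

#' Stress-strain curve specification
#'
#' Parameters of a synthetic bilinear elastic-plastic compression record:
#' stress follows `E * strain` up to the yield strain and
#' `sigma_y + H * (strain - yield_strain)` beyond it, plus iid Gaussian
#' noise. The default yield strain is the tissue compressive transition
#' strain, 0.8% (see [tissue_yield_strains()]).
#'
#' @param tissue_modulus Elastic modulus `E` in MPa.
#' @param yield_strain Transition strain (fraction), in (0, `max_strain`).
#' @param hardening_modulus Post-yield modulus `H` in MPa, `H <
#'   tissue_modulus`.
#' @param max_strain Final strain of the record.
#' @param n_points Number of samples on a uniform strain grid.
#' @param noise_sd Gaussian stress noise (MPa).
#' @param seed Integer RNG seed.
#' @return An object of class `curve_spec`.
#' @export
curve_spec <- function(tissue_modulus = 100,
                       yield_strain = unname(tissue_yield_strains()["compression"]),
                       hardening_modulus = 5,
                       max_strain = 0.03,
                       n_points = 200L,
                       noise_sd = 0,
                       seed = 1L) {
  if (!(yield_strain > 0 && yield_strain < max_strain)) {
    abort("need 0 < yield_strain < max_strain.")
  }
  if (hardening_modulus >= tissue_modulus) {
    abort("`hardening_modulus` must be below `tissue_modulus`.")
  }
  if (n_points < 3L) abort("`n_points` must be at least 3.")
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  structure(list(tissue_modulus = tissue_modulus, yield_strain = yield_strain,
                 hardening_modulus = hardening_modulus,
                 max_strain = max_strain, n_points = as.integer(n_points),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "curve_spec")
}

#' Generate a synthetic stress-strain curve
#'
#' @param spec A [curve_spec()].
#' @return An `ss_curve` tibble with columns `strain` and `stress`; the
#'   generating spec is attached as attribute `"spec"`.
#' @examples
#' generate_curve(curve_spec(noise_sd = 0, n_points = 5))
#' @export
generate_curve <- function(spec) {
  stopifnot(inherits(spec, "curve_spec"))
  strain <- seq(0, spec$max_strain, length.out = spec$n_points)
  stress <- bilinear_stress(strain, spec$tissue_modulus, spec$yield_strain,
                            spec$hardening_modulus)
  if (spec$noise_sd > 0) {
    withr::with_seed(spec$seed, {
      stress <- stress + rnorm(spec$n_points, sd = spec$noise_sd)
    })
  }
  out <- as_ss_curve(tibble::tibble(strain = strain, stress = stress))
  attr(out, "spec") <- spec
  out
}

#' Paired structure-mechanics dataset specification
#'
#' Ground truth for regression-recovery tests: a microstructure predictor
#' `x` drawn uniformly from `predictor_range` and a mechanical response
#' `y = slope * x + intercept + noise`. The defaults template the reported
#' BV/TV vs Young's-modulus relation (`y = 299.667 x - 76.9`) with noise
#' sized so the adjusted R-squared is about 0.57; 144 samples cover the
#' full 4 regions x 6 levels x 2 sides design three times over.
#'
#' @param n_samples Number of rows (>= 3).
#' @param slope,intercept True linear relation.
#' @param predictor_range Length-2 numeric, range of `x`.
#' @param noise_sd Gaussian response noise.
#' @param seed Integer RNG seed.
#' @return An object of class `paired_spec`.
#' @export
paired_spec <- function(n_samples = 144L, slope = 299.667, intercept = -76.9,
                        predictor_range = c(0.15, 0.55), noise_sd = 30,
                        seed = 1L) {
  if (n_samples < 3L) abort("`n_samples` must be at least 3.")
  if (length(predictor_range) != 2L ||
      predictor_range[2] <= predictor_range[1]) {
    abort("`predictor_range` must be an increasing pair.")
  }
  structure(list(n_samples = as.integer(n_samples), slope = slope,
                 intercept = intercept, predictor_range = predictor_range,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "paired_spec")
}

#' Generate a paired microstructure/mechanics table
#'
#' @param spec A [paired_spec()].
#' @param theta Facet angle (degrees) attached to every row; a named vector
#'   over regions overrides per region.
#' @return A tibble with columns `region` (SA/SP/IA/IP), `level` (C2-C7),
#'   `side` (left/right), `theta`, `x` (microstructure value) and `y`
#'   (mechanics value), cycling through the full factorial design.
#' @examples
#' head(generate_paired_dataset(paired_spec(n_samples = 12, noise_sd = 0)))
#' @export
generate_paired_dataset <- function(spec, theta = 45) {
  stopifnot(inherits(spec, "paired_spec"))
  design <- tidyr::expand_grid(
    level = paste0("C", 2:7),
    side = c("left", "right"),
    region = c("SA", "SP", "IA", "IP"))
  n <- spec$n_samples
  design <- design[rep_len(seq_len(nrow(design)), n), ]
  if (is.null(names(theta))) {
    design$theta <- rep_len(theta, n)
  } else {
    design$theta <- unname(theta[design$region])
  }
  withr::with_seed(spec$seed, {
    x <- runif(n, spec$predictor_range[1], spec$predictor_range[2])
    y <- spec$slope * x + spec$intercept +
      if (spec$noise_sd > 0) rnorm(n, sd = spec$noise_sd) else 0
  })
  dplyr::bind_cols(design, tibble::tibble(x = x, y = y))
}
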
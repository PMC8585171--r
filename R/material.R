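#' Gray-value to density to modulus material laws
#'
#' Voxel-wise material mapping for the micro-FE model. CT gray values (GV,
#' in HU) convert linearly to apparent density (g/cc), density converts to an
#' isotropic elastic modulus (MPa) by a power law, and the Poisson ratio is a
#' global constant:
#'
#' \deqn{\rho = 0.00097 \cdot GV}
#' \deqn{E = 19.04 \cdot \rho^{1.64}}
#' \deqn{\nu = 0.3}
#'
#' The coefficients are the calibration used for human trabecular bone in the
#' source imaging protocol; all three are overridable because they are
#' scanner- and units-dependent.
#'
#' @param gv Gray values (HU).
#' @param slope Density per gray value, g/cc per HU.
#' @param density Apparent density in g/cc.
#' @param coef,exponent Power-law coefficient (MPa) and exponent.
#' @return `density_from_gv()`: density in g/cc. `modulus_from_density()`:
#'   elastic modulus in MPa.
#' @examples
#' density_from_gv(1)        # 0.00097 g/cc
#' modulus_from_density(1)   # 19.04 MPa
#' @name material_law
NULL

#' @rdname material_law
#' @export
density_from_gv <- function(gv, slope = 0.00097) slope * gv

#' @rdname material_law
#' @export
modulus_from_density <- function(density, coef = 19.04, exponent = 1.64) {
  coef * density^exponent
}

#' @rdname material_law
#' @export
default_poisson_ratio <- function() 0.3

#' Bilinear tissue constitutive law
#'
#' The elastic-plastic behaviour of the bone tissue is modelled as bilinear:
#' linear with modulus `E` up to the yield strain, then linear with the
#' hardening modulus `H < E`. The tissue yield strains are 0.8% in
#' compression and 0.48% in tension; `tissue_yield_strains()` returns these
#' defaults as fractions.
#'
#' @param strain Strain values (fractions, compressive magnitudes positive).
#' @param E Elastic modulus (MPa).
#' @param yield_strain Transition (yield) strain, a fraction.
#' @param H Hardening modulus (MPa), `H < E`.
#' @return `bilinear_stress()`: stress (MPa) at `strain`.
#'   `tissue_yield_strains()`: named numeric, `compression = 0.008`,
#'   `tension = 0.0048`.
#' @examples
#' bilinear_stress(c(0.004, 0.008, 0.02), E = 100, yield_strain = 0.008, H = 5)
#' tissue_yield_strains()
#' @export
bilinear_stress <- function(strain, E, yield_strain, H = 0) {
  if (yield_strain <= 0) abort("`yield_strain` must be positive.")
  if (H >= E) abort("hardening modulus `H` must be below `E`.")
  ifelse(strain <= yield_strain,
         E * strain,
         E * yield_strain + H * (strain - yield_strain))
}

#' @rdname bilinear_stress
#' @export
tissue_yield_strains <- function() c(compression = 0.008, tension = 0.0048)
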
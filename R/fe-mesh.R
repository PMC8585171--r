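#' Build a voxel-hexahedron FE mesh
#'
#' Converts every foreground voxel of a segmented volume into one 8-node
#' hexahedral element on a shared node grid (watertight: adjacent voxels
#' reuse identical nodes). Floating fragments make the stiffness matrix
#' singular, so by default only the face-connected (6-connected) components
#' that span from the bottom (z min) to the top (z max) voxel layer are
#' kept -- exactly the material that can carry a compressive load between
#' the platens; `component = "largest"` keeps the single largest component
#' instead, `"all"` keeps everything (at the caller's risk).
#'
#' Node ordering per element follows the usual trilinear hexahedron
#' convention (counter-clockwise bottom face, then top face), which is also
#' the VTK hexahedron ordering.
#'
#' @param mask A [binary_volume()] with at least one foreground voxel.
#' @param component Which 6-connected components to mesh: `"spanning"`
#'   (default, all components touching both z faces), `"largest"`, or
#'   `"all"`.
#' @param check_load_path Abort if the mesh does not reach both z faces?
#' @return An object of class `fe_mesh`: `nodes` (N x 3 mm coordinates),
#'   `elems` (E x 8 node indices), `voxel_index` (linear index of each
#'   element's source voxel), `spacing`, `grid_dim`, `n_dropped`.
#' @examples
#' m <- build_mesh(binary_volume(array(TRUE, c(2, 1, 1)), 0.1))
#' nrow(m$nodes)  # 12 nodes, 4 shared
#' @export
build_mesh <- function(mask, component = c("spanning", "largest", "all"),
                       check_load_path = TRUE) {
  stopifnot(inherits(mask, "binary_volume"))
  component <- match.arg(component)
  m <- mask$mask
  if (!any(m)) abort("empty mask: nothing to mesh.")
  d <- dim(m)
  n_dropped <- 0L
  if (component != "all") {
    lab <- array(.label_components6(as.logical(m), d), dim = d)
    keep <- if (component == "largest") {
      which.max(tabulate(lab))
    } else {
      intersect(unique(as.vector(lab[, , 1])),
                unique(as.vector(lab[, , d[3]])))
    }
    keep <- setdiff(keep, 0L)
    if (!length(keep)) {
      abort(paste0("no load path: no 6-connected component spans the ",
                   "bottom and top z layers."))
    }
    m2 <- array(lab %in% keep, dim = d)
    n_dropped <- sum(m) - sum(m2)
    m <- m2
  }
  idx <- which(m)
  v0 <- idx - 1L
  vx <- v0 %% d[1]
  vy <- (v0 %/% d[1]) %% d[2]
  vz <- v0 %/% (d[1] * d[2])
  if (check_load_path && !(any(vz == 0L) && any(vz == d[3] - 1L))) {
    abort(paste0("no load path: the meshed component does not reach both ",
                 "the bottom and top z layers."))
  }
  # corner offsets, hexahedron ordering (bottom CCW, then top)
  co <- cbind(c(0L, 1L, 1L, 0L, 0L, 1L, 1L, 0L),
              c(0L, 0L, 1L, 1L, 0L, 0L, 1L, 1L),
              c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L))
  nx1 <- d[1] + 1L
  ny1 <- d[2] + 1L
  conn0 <- matrix(0L, length(idx), 8L)
  for (c8 in 1:8) {
    conn0[, c8] <- (vx + co[c8, 1]) + nx1 * ((vy + co[c8, 2]) +
                                             ny1 * (vz + co[c8, 3]))
  }
  uniq <- sort(unique(as.vector(conn0)))
  elems <- matrix(match(conn0, uniq), ncol = 8L)
  ix <- uniq %% nx1
  iy <- (uniq %/% nx1) %% ny1
  iz <- uniq %/% (nx1 * ny1)
  nodes <- cbind(x = ix, y = iy, z = iz) * mask$spacing
  structure(list(nodes = nodes, elems = elems, voxel_index = idx,
                 spacing = mask$spacing, grid_dim = d,
                 n_dropped = n_dropped),
            class = "fe_mesh")
}

#' @export
print.fe_mesh <- function(x, ...) {
  cat(sprintf("<fe_mesh> %d hexahedral elements, %d nodes @ %g mm",
              nrow(x$elems), nrow(x$nodes), x$spacing))
  if (x$n_dropped > 0) cat(sprintf(" (%d floating voxels dropped)", x$n_dropped))
  cat("\n")
  invisible(x)
}

#' Assign per-element material properties
#'
#' Maps each element's source gray value (GV, in HU) to apparent density and
#' elastic modulus with the power-law material model (see
#' [density_from_gv()] and [modulus_from_density()]); the Poisson ratio is
#' global. Negative gray values (air, noise) would give negative density and
#' are clamped at `density_floor` with a warning. A homogeneous override
#' (`E_uniform`) bypasses the image entirely, for verification models.
#'
#' @param volume The [image_volume()] the mesh was built from.
#' @param mesh An [fe_mesh()][build_mesh].
#' @param density_slope,modulus_coef,modulus_exp,poisson Material-law
#'   constants (g/cc per HU; MPa; -; -).
#' @param density_floor Lower clamp for density (g/cc).
#' @param E_uniform If non-NULL, a single modulus (MPa) for every element.
#' @return An object of class `fe_material`: per-element `density` (g/cc)
#'   and `E` (MPa), global `nu`, element count `n_floor` at or below zero
#'   stiffness.
#' @export
map_materials <- function(volume, mesh, density_slope = 0.00097,
                          modulus_coef = 19.04, modulus_exp = 1.64,
                          poisson = default_poisson_ratio(),
                          density_floor = 0, E_uniform = NULL) {
  stopifnot(inherits(mesh, "fe_mesh"))
  if (!(poisson > 0 && poisson < 0.5)) {
    abort("`poisson` must lie in (0, 0.5).")
  }
  ne <- nrow(mesh$elems)
  if (!is.null(E_uniform)) {
    mat <- list(density = rep(NA_real_, ne), E = rep(E_uniform, ne),
                nu = poisson, gv = rep(NA_real_, ne), n_floor = 0L)
    return(structure(mat, class = "fe_material"))
  }
  stopifnot(inherits(volume, "image_volume"))
  gv <- volume$voxels[mesh$voxel_index]
  if (anyNA(gv) || any(!is.finite(gv))) {
    abort("non-finite gray values under the mesh.")
  }
  density <- density_from_gv(gv, density_slope)
  n_neg <- sum(density < density_floor)
  if (n_neg > 0) {
    warn(sprintf("%d element(s) with density below %g g/cc clamped.",
                 n_neg, density_floor))
    density <- pmax(density, density_floor)
  }
  E <- modulus_from_density(density, modulus_coef, modulus_exp)
  n_floor <- sum(E <= 0)
  if (n_floor > 0) {
    warn(sprintf("%d element(s) at zero stiffness (E = 0).", n_floor))
  }
  structure(list(density = density, E = E, nu = poisson, gv = gv,
                 n_floor = n_floor),
            class = "fe_material")
}

#' @export
print.fe_material <- function(x, ...) {
  cat(sprintf("<fe_material> %d elements, E in [%g, %g] MPa, nu = %g\n",
              length(x$E), min(x$E), max(x$E), x$nu))
  invisible(x)
}
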
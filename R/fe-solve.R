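# --- element matrices -------------------------------------------------------

# local corner coordinates of the trilinear hexahedron, matching build_mesh()
hex_local <- cbind(xi   = c(-1, 1, 1, -1, -1, 1, 1, -1),
                   eta  = c(-1, -1, 1, 1, -1, -1, 1, 1),
                   zeta = c(-1, -1, -1, -1, 1, 1, 1, 1))

# isotropic elasticity matrix for E = 1 (engineering shear strains)
elastic_D <- function(nu, E = 1) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- diag(c(rep(2 * mu, 3), rep(mu, 3)))
  D[1:3, 1:3] <- D[1:3, 1:3] + lam
  D
}

# strain-displacement matrix (6 x 24) at local point (xi, eta, zeta) for a
# cube element of edge h; dof order (u1x u1y u1z u2x ...)
hex_B <- function(xi, eta, zeta, h) {
  dN <- matrix(0, 8, 3)
  for (i in 1:8) {
    l <- hex_local[i, ]
    dN[i, 1] <- l[1] * (1 + eta * l[2]) * (1 + zeta * l[3]) / 8
    dN[i, 2] <- l[2] * (1 + xi * l[1]) * (1 + zeta * l[3]) / 8
    dN[i, 3] <- l[3] * (1 + xi * l[1]) * (1 + eta * l[2]) / 8
  }
  dN <- dN * (2 / h)  # jacobian of the cube element is (h/2) I
  B <- matrix(0, 6, 24)
  for (i in 1:8) {
    c0 <- 3 * (i - 1)
    B[1, c0 + 1] <- dN[i, 1]
    B[2, c0 + 2] <- dN[i, 2]
    B[3, c0 + 3] <- dN[i, 3]
    B[4, c0 + 1] <- dN[i, 2]; B[4, c0 + 2] <- dN[i, 1]
    B[5, c0 + 2] <- dN[i, 3]; B[5, c0 + 3] <- dN[i, 2]
    B[6, c0 + 1] <- dN[i, 3]; B[6, c0 + 3] <- dN[i, 1]
  }
  B
}

#' Reference hexahedral element stiffness
#'
#' 24 x 24 stiffness matrix of a cube voxel element of edge `h` with unit
#' modulus, from 2 x 2 x 2 Gauss quadrature. Every element of a voxel mesh
#' shares this matrix scaled by its modulus, which is what makes voxel FE
#' assembly cheap.
#'
#' @param nu Poisson ratio.
#' @param h Element edge length (mm).
#' @param E Elastic modulus (MPa), default 1 (scale per element).
#' @return A 24 x 24 symmetric matrix.
#' @export
hex_stiffness <- function(nu, h, E = 1) {
  D <- elastic_D(nu, E)
  g <- 1 / sqrt(3)
  K <- matrix(0, 24, 24)
  detJ <- (h / 2)^3
  for (xi in c(-g, g)) for (eta in c(-g, g)) for (zeta in c(-g, g)) {
    B <- hex_B(xi, eta, zeta, h)
    K <- K + t(B) %*% D %*% B * detJ
  }
  (K + t(K)) / 2
}

# --- boundary conditions ----------------------------------------------------

#' Compression boundary conditions
#'
#' Displacement-controlled axial compression: the bottom (z min) face is the
#' fixed support and the top (z max) face is driven down by a prescribed
#' displacement. Two lateral handlings are available:
#' * `"platen"` (default): bottom nodes fully fixed and top nodes fixed
#'   tangentially (`ux = uy = 0`), emulating friction against the platens;
#' * `"frictionless"`: only the axial component constrained on both faces,
#'   plus a minimal 3-point lateral pin on the bottom face to remove
#'   rigid-body modes; under this mode a homogeneous cube is in a uniform
#'   uniaxial stress state and its apparent modulus equals the tissue
#'   modulus.
#'
#' @param mesh An [fe_mesh()][build_mesh].
#' @param strain Apparent compressive strain (fraction); the prescribed
#'   displacement is `strain * height`.
#' @param mode `"platen"` or `"frictionless"`.
#' @return A list of class `fe_bc` with constrained dof indices, their
#'   values, and node sets.
#' @export
compression_bc <- function(mesh, strain = 0.01,
                           mode = c("platen", "frictionless")) {
  mode <- match.arg(mode)
  z <- mesh$nodes[, 3]
  zmin <- min(z); zmax <- max(z)
  height <- zmax - zmin
  bottom <- which(z == zmin)
  top <- which(z == zmax)
  if (!length(bottom) || !length(top)) abort("degenerate mesh faces.")
  delta <- strain * height
  dof <- function(nodes, comp) 3L * (nodes - 1L) + comp
  if (mode == "platen") {
    idx <- c(dof(bottom, 1L), dof(bottom, 2L), dof(bottom, 3L),
             dof(top, 1L), dof(top, 2L), dof(top, 3L))
    val <- c(rep(0, 3 * length(bottom)), rep(0, 2 * length(top)),
             rep(-delta, length(top)))
  } else {
    xy <- mesh$nodes[bottom, 1:2, drop = FALSE]
    p0 <- bottom[order(xy[, 1], xy[, 2])[1]]                 # pin ux, uy
    p1 <- bottom[order(-xy[, 1], xy[, 2])[1]]                # pin uy
    idx <- c(dof(bottom, 3L), dof(top, 3L), dof(p0, 1L), dof(p0, 2L),
             dof(p1, 2L))
    val <- c(rep(0, length(bottom)), rep(-delta, length(top)), 0, 0, 0)
    if (p0 == p1) abort("cannot pin rigid-body modes on a single bottom node.")
  }
  keep <- !duplicated(idx)
  structure(list(idx = idx[keep], val = val[keep], bottom = bottom,
                 top = top, delta = delta, height = height, mode = mode,
                 strain = strain),
            class = "fe_bc")
}

# --- assembly and solve -----------------------------------------------------

assemble_K <- function(mesh, E_vec, nu) {
  ke <- hex_stiffness(nu, mesh$spacing)
  nd <- 3L * nrow(mesh$nodes)
  dofmat <- matrix(0L, nrow(mesh$elems), 24L)
  for (i in 1:8) {
    dofmat[, 3 * i - 2] <- 3L * (mesh$elems[, i] - 1L) + 1L
    dofmat[, 3 * i - 1] <- 3L * (mesh$elems[, i] - 1L) + 2L
    dofmat[, 3 * i]     <- 3L * (mesh$elems[, i] - 1L) + 3L
  }
  ii <- rep(1:24, times = 24)
  jj <- rep(1:24, each = 24)
  K <- Matrix::sparseMatrix(
    i = as.vector(dofmat[, ii]),
    j = as.vector(dofmat[, jj]),
    x = as.vector(outer(E_vec, as.vector(ke))),
    dims = c(nd, nd))
  list(K = Matrix::forceSymmetric(K), dofmat = dofmat)
}

# Jacobi-preconditioned conjugate gradient for SPD sparse systems
pcg_solve <- function(A, b, tol = 1e-10, maxit = 20000L) {
  x <- numeric(length(b))
  r <- b
  Minv <- 1 / Matrix::diag(A)
  z <- Minv * r
  p <- z
  rz <- sum(r * z)
  nb <- sqrt(sum(b * b))
  if (nb == 0) return(x)
  for (it in seq_len(maxit)) {
    Ap <- as.vector(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (sqrt(sum(r * r)) <= tol * nb) return(x)
    z <- Minv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  warn(sprintf("CG did not reach tol %.1e in %d iterations.", tol, maxit))
  x
}

# closed-form eigenvalues of many symmetric 3x3 tensors
# s: matrix with columns (a11, a22, a33, a12, a23, a13); rows sorted desc
eig3_sym <- function(s) {
  q <- (s[, 1] + s[, 2] + s[, 3]) / 3
  p1 <- s[, 4]^2 + s[, 5]^2 + s[, 6]^2
  p2 <- (s[, 1] - q)^2 + (s[, 2] - q)^2 + (s[, 3] - q)^2 + 2 * p1
  p <- sqrt(p2 / 6)
  iso <- p < .Machine$double.eps^0.5 * (abs(q) + 1)
  p_safe <- ifelse(iso, 1, p)
  b11 <- (s[, 1] - q) / p_safe; b22 <- (s[, 2] - q) / p_safe
  b33 <- (s[, 3] - q) / p_safe
  b12 <- s[, 4] / p_safe; b23 <- s[, 5] / p_safe; b13 <- s[, 6] / p_safe
  detB <- b11 * b22 * b33 + 2 * b12 * b23 * b13 -
    b11 * b23^2 - b22 * b13^2 - b33 * b12^2
  r <- pmin(pmax(detB / 2, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  out <- cbind(e1, e2, e3)
  out[iso, ] <- q[iso]
  out
}

von_mises <- function(sig) {
  sqrt(0.5 * ((sig[, 1] - sig[, 2])^2 + (sig[, 2] - sig[, 3])^2 +
              (sig[, 3] - sig[, 1])^2) +
       3 * (sig[, 4]^2 + sig[, 5]^2 + sig[, 6]^2))
}

#' Solve a displacement-controlled compression
#'
#' Assembles the global stiffness from the shared reference element (one
#' 24 x 24 matrix scaled by each element's modulus), applies the Dirichlet
#' boundary conditions, solves the reduced symmetric positive-definite
#' system, and recovers strains and stresses at element centroids together
#' with von Mises and principal values, face reactions and the apparent
#' modulus `(reaction / apparent area) / (delta / height)`.
#'
#' The solve is linear-elastic and quasi-static. With `plasticity = TRUE`
#' the bilinear tissue law is applied by incremental loading: after each
#' displacement increment, elements whose accumulated principal strain
#' passes the compressive (0.8%) or tensile (0.48%) tissue transition strain
#' continue with `hardening_ratio * E`; fields accumulate over increments.
#'
#' @param mesh An [fe_mesh()][build_mesh].
#' @param mat An [fe_material()][map_materials].
#' @param strain Apparent compressive strain (fraction), default 1%.
#' @param bc_mode Passed to [compression_bc()], or a ready `fe_bc`.
#' @param solver `"auto"` (direct below `direct_max_dof` unknowns, else
#'   conjugate gradient), `"direct"`, or `"cg"`.
#' @param tol Relative residual tolerance of the CG solver.
#' @param direct_max_dof Unknown-count cutoff for the direct solver.
#' @param plasticity Apply the incremental bilinear extension?
#' @param yield_strains Named pair `c(compression =, tension =)` of tissue
#'   transition strains (fractions).
#' @param hardening_ratio Post-yield tangent modulus as a fraction of E.
#' @param n_steps Number of displacement increments when `plasticity`.
#' @param strain_rate Nominal loading rate (m/s) of the emulated physical
#'   test, recorded as metadata only -- the solve itself is quasi-static.
#' @return An object of class `fe_solution`; see [summarize_field()] and
#'   [write_vtk()] for reporting.
#' @export
solve_compression <- function(mesh, mat, strain = 0.01,
                              bc_mode = c("platen", "frictionless"),
                              solver = c("auto", "direct", "cg"),
                              tol = 1e-10, direct_max_dof = 50000L,
                              plasticity = FALSE,
                              yield_strains = tissue_yield_strains(),
                              hardening_ratio = 0.05, n_steps = 10L,
                              strain_rate = 8.3e-9) {
  stopifnot(inherits(mesh, "fe_mesh"), inherits(mat, "fe_material"))
  solver <- match.arg(solver)
  bc <- if (inherits(bc_mode, "fe_bc")) bc_mode else {
    compression_bc(mesh, strain, match.arg(bc_mode))
  }
  nd <- 3L * nrow(mesh$nodes)
  ne <- nrow(mesh$elems)
  fixed <- bc$idx
  free <- setdiff(seq_len(nd), fixed)
  solve_once <- function(E_vec, u_fixed) {
    asm <- assemble_K(mesh, E_vec, mat$nu)
    K <- asm$K
    u <- numeric(nd)
    u[fixed] <- u_fixed
    rhs <- -as.vector(K[free, fixed, drop = FALSE] %*% u_fixed)
    Kff <- Matrix::forceSymmetric(K[free, free])
    use_direct <- solver == "direct" ||
      (solver == "auto" && length(free) <= direct_max_dof)
    uf <- if (use_direct) {
      as.vector(Matrix::solve(Kff, rhs))
    } else {
      pcg_solve(Kff, rhs, tol = tol)
    }
    if (any(!is.finite(uf))) {
      abort(paste0("singular system: a mesh component is unconstrained ",
                   "(rigid-body mode or floating fragment)."))
    }
    u[free] <- uf
    list(u = u, K = K, dofmat = asm$dofmat)
  }
  B0 <- hex_B(0, 0, 0, mesh$spacing)
  D1 <- elastic_D(mat$nu, 1)
  recover <- function(u, dofmat, E_vec) {
    ue <- matrix(u[dofmat], nrow = ne)
    eps <- ue %*% t(B0)
    sig <- (eps %*% t(D1)) * E_vec
    list(eps = eps, sig = sig)
  }
  if (!plasticity) {
    sol <- solve_once(mat$E, bc$val)
    rec <- recover(sol$u, sol$dofmat, mat$E)
    eps <- rec$eps; sig <- rec$sig
    R <- as.vector(sol$K %*% sol$u)
    E_tangent <- mat$E
    n_yielded <- 0L
  } else {
    yc <- yield_strains[["compression"]]
    yt <- yield_strains[["tension"]]
    E_tangent <- mat$E
    u_tot <- numeric(nd)
    eps <- matrix(0, ne, 6)
    sig <- matrix(0, ne, 6)
    R <- numeric(nd)
    dofmat <- NULL
    for (s in seq_len(n_steps)) {
      sol <- solve_once(E_tangent, bc$val / n_steps)
      dofmat <- sol$dofmat
      rec <- recover(sol$u, dofmat, E_tangent)
      u_tot <- u_tot + sol$u
      eps <- eps + rec$eps
      sig <- sig + rec$sig
      R <- R + as.vector(sol$K %*% sol$u)
      pe <- eig3_sym(cbind(eps[, 1:3], eps[, 4:6] / 2))
      yielded <- (pe[, 3] <= -yc) | (pe[, 1] >= yt)
      E_tangent <- ifelse(yielded, hardening_ratio * mat$E, mat$E)
    }
    sol <- list(u = u_tot)
    n_yielded <- sum(E_tangent < mat$E)
  }
  vm <- von_mises(sig)
  princ_sig <- eig3_sym(sig)
  princ_eps <- eig3_sym(cbind(eps[, 1:3], eps[, 4:6] / 2))
  colnames(princ_sig) <- colnames(princ_eps) <- c("p1", "p2", "p3")
  dofz <- function(nodes) 3L * (nodes - 1L)
  reaction_top <- sum(R[dofz(bc$top) + 3L])
  reaction_bottom <- sum(R[dofz(bc$bottom) + 3L])
  area <- prod(mesh$grid_dim[1:2]) * mesh$spacing^2
  e_app <- (abs(reaction_top) / area) / (bc$delta / bc$height)
  disp <- matrix(sol$u, ncol = 3, byrow = TRUE)
  colnames(disp) <- c("ux", "uy", "uz")
  colnames(eps) <- c("exx", "eyy", "ezz", "gxy", "gyz", "gzx")
  colnames(sig) <- c("sxx", "syy", "szz", "sxy", "syz", "szx")
  structure(list(displacements = disp, strain = eps, stress = sig,
                 von_mises = vm, principal_stress = princ_sig,
                 principal_strain = princ_eps,
                 reaction_driven = reaction_top,
                 reaction_fixed = reaction_bottom,
                 apparent_modulus = e_app, apparent_area = area,
                 bc = bc, mesh = mesh, material = mat,
                 n_yielded = n_yielded, plasticity = plasticity,
                 strain_rate = strain_rate),
            class = "fe_solution")
}

#' @export
print.fe_solution <- function(x, ...) {
  cat(sprintf(paste0("<fe_solution> %d elements, %.3g%% apparent strain ",
                     "(%s)\n  apparent modulus %.4g MPa, reaction %.4g N, ",
                     "von Mises in [%.3g, %.3g] MPa\n"),
              nrow(x$stress), 100 * x$bc$strain, x$bc$mode,
              x$apparent_modulus, abs(x$reaction_driven),
              min(x$von_mises), max(x$von_mises)))
  if (x$plasticity) cat(sprintf("  %d element(s) past yield\n", x$n_yielded))
  invisible(x)
}

#' Summarize a micro-FE stress/strain field
#'
#' Tabulates min, max and mean of the solution fields, including the
#' lower-quantile von Mises summary: the subset of elements at or below the
#' given quantile of the von Mises stress (default 0.75, i.e. excluding the
#' top quarter of stressed elements, which concentrates at the loaded face).
#'
#' @param sol An [fe_solution][solve_compression].
#' @param quantile Fraction in (0, 1]; the von Mises subset cut.
#' @return A tibble with columns `quantity`, `min`, `max`, `mean`, `n`.
#' @export
summarize_field <- function(sol, quantile = 0.75) {
  stopifnot(inherits(sol, "fe_solution"))
  if (!(quantile > 0 && quantile <= 1)) abort("`quantile` must be in (0, 1].")
  vm <- sol$von_mises
  cut <- stats::quantile(vm, quantile, names = FALSE)
  sub <- vm[vm <= cut]
  row <- function(quantity, x) {
    tibble::tibble(quantity = quantity, min = min(x), max = max(x),
                   mean = mean(x), n = length(x))
  }
  dplyr::bind_rows(
    row(sprintf("von_mises_below_q%02d", round(100 * quantile)), sub),
    row("von_mises", vm),
    row("sigma1", sol$principal_stress[, 1]),
    row("sigma3", sol$principal_stress[, 3]),
    row("eps1", sol$principal_strain[, 1]),
    row("eps2", sol$principal_strain[, 2]),
    row("eps3", sol$principal_strain[, 3]),
    row("ux", sol$displacements[, 1]),
    row("uy", sol$displacements[, 2]),
    row("uz", sol$displacements[, 3]))
}
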
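# Independent oracles used across the suite. These deliberately share no
# code with the package internals: plain loops, dense algebra, exhaustive
# search.

# exhaustive largest-inscribed-sphere thickness map (voxel units):
# for every phase voxel p, the sphere centred at p has radius
# r(p) = min distance to an opposite-phase voxel centre minus 0.5; every
# phase voxel q with |q - p| <= r(p) is covered by a sphere of diameter
# 2 r(p); voxels covered by no sphere of positive radius are one voxel thick.
brute_thickness_map <- function(mask) {
  d <- dim(mask)
  fg <- which(mask, arr.ind = TRUE)
  bg <- which(!mask, arr.ind = TRUE)
  th <- array(0, dim = d)
  if (nrow(bg) == 0L) return(array(Inf, dim = d))
  r <- numeric(nrow(fg))
  for (i in seq_len(nrow(fg))) {
    dd <- sqrt(min((bg[, 1] - fg[i, 1])^2 + (bg[, 2] - fg[i, 2])^2 +
                     (bg[, 3] - fg[i, 3])^2))
    r[i] <- dd - 0.5
  }
  for (i in seq_len(nrow(fg))) {
    if (r[i] <= 0) next
    for (j in seq_len(nrow(fg))) {
      d2 <- sum((fg[j, ] - fg[i, ])^2)
      if (d2 <= r[i]^2) {
        th[fg[j, 1], fg[j, 2], fg[j, 3]] <-
          max(th[fg[j, 1], fg[j, 2], fg[j, 3]], 2 * r[i])
      }
    }
  }
  for (i in seq_len(nrow(fg))) {
    v <- th[fg[i, 1], fg[i, 2], fg[i, 3]]
    if (v < 1) th[fg[i, 1], fg[i, 2], fg[i, 3]] <- 1
  }
  th
}

# exposed voxel-face count times face area: an upper bound on the true
# surface of the voxel set
voxel_face_area <- function(mask) {
  d <- dim(mask)
  pad <- array(FALSE, d + 2L)
  pad[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] <- mask
  faces <- 0L
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    idx <- lapply(seq_along(d), function(a) 1 + seq_len(d[a]))
    idx[[ax]] <- idx[[ax]] + s
    nb <- do.call(`[`, c(list(pad), idx))
    faces <- faces + sum(mask & !nb)
  }
  faces
}

# dense single-element hexahedron stiffness by straightforward numerical
# quadrature, coded independently of the package (different loop structure,
# shape-function table written out long-hand)
dense_hex_ke <- function(E, nu, h) {
  corners <- rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
                   c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1, 1] <- D[2, 2] <- D[3, 3] <- lam + 2 * mu
  D[1, 2] <- D[2, 1] <- D[1, 3] <- D[3, 1] <- D[2, 3] <- D[3, 2] <- lam
  D[4, 4] <- D[5, 5] <- D[6, 6] <- mu
  gp <- 1 / sqrt(3)
  Ke <- matrix(0, 24, 24)
  for (gx in c(-gp, gp)) for (gy in c(-gp, gp)) for (gz in c(-gp, gp)) {
    B <- matrix(0, 6, 24)
    for (a in 1:8) {
      cx <- corners[a, 1]; cy <- corners[a, 2]; cz <- corners[a, 3]
      dx <- cx * (1 + gy * cy) * (1 + gz * cz) / 8 * 2 / h
      dy <- cy * (1 + gx * cx) * (1 + gz * cz) / 8 * 2 / h
      dz <- cz * (1 + gx * cx) * (1 + gy * cy) / 8 * 2 / h
      B[1, 3 * a - 2] <- dx
      B[2, 3 * a - 1] <- dy
      B[3, 3 * a] <- dz
      B[4, 3 * a - 2] <- dy; B[4, 3 * a - 1] <- dx
      B[5, 3 * a - 1] <- dz; B[5, 3 * a] <- dy
      B[6, 3 * a - 2] <- dz; B[6, 3 * a] <- dx
    }
    Ke <- Ke + t(B) %*% D %*% B * (h / 2)^3
  }
  Ke
}

# dense micro-FE compression of a full voxel grid with per-voxel moduli:
# independent global assembly and base-R dense solve. mask/E_arr are 3-D
# arrays; bottom face fully fixed, top face driven axially (platen mode).
dense_fe_displacements <- function(E_arr, nu, h, strain) {
  d <- dim(E_arr)
  nx1 <- d[1] + 1L; ny1 <- d[2] + 1L; nz1 <- d[3] + 1L
  nid <- function(ix, iy, iz) ix + nx1 * (iy - 1L) + nx1 * ny1 * (iz - 1L)
  nn <- nx1 * ny1 * nz1
  K <- matrix(0, 3 * nn, 3 * nn)
  for (ez in seq_len(d[3])) for (ey in seq_len(d[2])) for (ex in seq_len(d[1])) {
    Ke <- dense_hex_ke(E_arr[ex, ey, ez], nu, h)
    nodes <- c(nid(ex, ey, ez), nid(ex + 1, ey, ez), nid(ex + 1, ey + 1, ez),
               nid(ex, ey + 1, ez), nid(ex, ey, ez + 1), nid(ex + 1, ey, ez + 1),
               nid(ex + 1, ey + 1, ez + 1), nid(ex, ey + 1, ez + 1))
    dofs <- as.vector(rbind(3 * nodes - 2, 3 * nodes - 1, 3 * nodes))
    K[dofs, dofs] <- K[dofs, dofs] + Ke
  }
  iz_of <- rep(seq_len(nz1), each = nx1 * ny1)
  bottom <- which(iz_of == 1L)
  top <- which(iz_of == nz1)
  delta <- strain * d[3] * h
  u <- numeric(3 * nn)
  fixed <- c(3 * bottom - 2, 3 * bottom - 1, 3 * bottom,
             3 * top - 2, 3 * top - 1, 3 * top)
  u[3 * top] <- -delta
  free <- setdiff(seq_len(3 * nn), fixed)
  rhs <- -K[free, fixed] %*% u[fixed]
  u[free] <- solve(K[free, free], rhs)
  matrix(u, ncol = 3, byrow = TRUE)
}

# marching-tetrahedra surface area reimplemented in plain R (small grids
# only), for Tb.Pf / BS recounts
r_mt_area <- function(mask) {
  d <- dim(mask)
  f <- array(0, d + 2L)
  f[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] <- as.numeric(mask)
  dd <- dim(f)
  corners <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                   c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  tets <- rbind(c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
                c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))
  tri_a <- function(p1, p2, p3) {
    u <- p2 - p1; w <- p3 - p1
    v <- c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
           u[1] * w[2] - u[2] * w[1])
    sqrt(sum(v^2)) / 2
  }
  total <- 0
  for (z in seq_len(dd[3] - 1L)) for (y in seq_len(dd[2] - 1L)) {
    for (x in seq_len(dd[1] - 1L)) {
      fv <- numeric(8); pv <- matrix(0, 8, 3)
      for (c8 in 1:8) {
        cc <- c(x, y, z) + corners[c8, ]
        fv[c8] <- f[cc[1], cc[2], cc[3]]
        pv[c8, ] <- cc
      }
      if (all(fv >= 0.5) || all(fv < 0.5)) next
      for (t in 1:6) {
        vt <- tets[t, ]
        above <- fv[vt] >= 0.5
        na <- sum(above)
        if (na == 0 || na == 4) next
        ip <- function(a, b) {
          tt <- (0.5 - fv[vt[a]]) / (fv[vt[b]] - fv[vt[a]])
          pv[vt[a], ] + tt * (pv[vt[b], ] - pv[vt[a], ])
        }
        A <- which(above); Bv <- which(!above)
        if (na == 1 || na == 3) {
          lone <- if (na == 1) A[1] else Bv[1]
          oth <- if (na == 1) Bv else A
          total <- total + tri_a(ip(lone, oth[1]), ip(lone, oth[2]),
                                 ip(lone, oth[3]))
        } else {
          q1 <- ip(A[1], Bv[1]); q2 <- ip(A[1], Bv[2])
          q3 <- ip(A[2], Bv[2]); q4 <- ip(A[2], Bv[1])
          total <- total + tri_a(q1, q2, q3) + tri_a(q1, q3, q4)
        }
      }
    }
  }
  total
}

# random blobby test mask: union of a few random balls, seeded
random_mask <- function(d, n_balls = 3, seed = 1) {
  withr::with_seed(seed, {
    m <- array(FALSE, d)
    g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
    for (i in seq_len(n_balls)) {
      ctr <- runif(3, 2, d - 1)
      r <- runif(1, 1.5, max(2, min(d) / 3))
      m <- m | array((g$x - ctr[1])^2 + (g$y - ctr[2])^2 +
                       (g$z - ctr[3])^2 <= r^2, d)
    }
    m
  })
}
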
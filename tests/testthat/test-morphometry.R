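test_that("binarize handles uniform and degenerate thresholds", {
  v <- image_volume(array(2000, c(4, 4, 4)), 0.1)
  expect_warning(m <- binarize(v, 1000), "all-foreground")
  expect_true(all(m$mask))
  expect_warning(m0 <- binarize(v, 3000), "empty")
  expect_false(any(m0$mask))
  expect_equal(m$threshold, 1000)
})

test_that("BV/TV is the foreground fraction and respects complements", {
  solid <- binary_volume(array(TRUE, c(5, 5, 5)), 0.1)
  expect_identical(bone_volume_fraction(solid), 1)
  empty <- binary_volume(array(FALSE, c(5, 5, 5)), 0.1)
  expect_identical(bone_volume_fraction(empty), 0)
  half <- array(FALSE, c(4, 4, 4)); half[, , 1:2] <- TRUE
  hv <- binary_volume(half, 0.1)
  expect_identical(bone_volume_fraction(hv), 0.5)
  comp <- binary_volume(!hv$mask, 0.1)
  expect_equal(bone_volume_fraction(comp), 1 - bone_volume_fraction(hv))
})

test_that("raising the threshold never increases BV/TV", {
  ph <- generate_phantom(phantom_spec(shape_voxels = c(24, 24, 24),
                                      noise_sd = 300, seed = 5))
  fracs <- vapply(seq(-500, 2500, length.out = 21), function(th) {
    suppressWarnings(bone_volume_fraction(binarize(ph$volume, th)))
  }, numeric(1))
  expect_true(all(diff(fracs) <= 0))
})

test_that("surface area matches analytic values for cube, plate and sphere", {
  # solid cube with closed boundary faces: flat faces are exact, the
  # 0.5-level surface chamfers the 12 edges, an O(1/n) deficit that must
  # shrink as the cube grows
  for (n in c(6L, 12L)) {
    cube <- binary_volume(array(TRUE, c(n, n, n)), 0.1)
    s <- specific_surface(cube, smooth_sigma = 0)
    ref <- 6 / (n * 0.1)
    expect_lt(abs(s$bs_bv - ref) / ref, 3 / n)
  }
  # plate of thickness w: bs_bv approaches 2/w from above as the lateral
  # extent grows (side walls vanish)
  ratio <- vapply(c(15L, 30L), function(a) {
    pl <- array(FALSE, c(a, a, 11)); pl[, , 4:8] <- TRUE
    specific_surface(binary_volume(pl, 1), smooth_sigma = 0)$bs_bv / (2 / 5)
  }, numeric(1))
  expect_true(all(ratio > 1 & ratio < 1.7))
  expect_lt(ratio[2], ratio[1])
  # digital ball: within 5% of 4 pi r^2 under default smoothing
  r <- 8; n <- 2 * r + 9; ctr <- (n + 1) / 2
  g <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  ball <- array((g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2 <= r^2,
                c(n, n, n))
  sb <- specific_surface(binary_volume(ball, 1))
  expect_lt(abs(sb$surface / (4 * pi * r^2) - 1), 0.05)
  # triangulated isosurface never exceeds the voxel-face upper bound
  m <- random_mask(c(10, 10, 10), seed = 3)
  a_mt <- specific_surface(binary_volume(m, 1), smooth_sigma = 0)$surface
  expect_lt(a_mt, voxel_face_area(m) + 1e-9)
  expect_error(specific_surface(binary_volume(array(FALSE, c(3, 3, 3)), 1)),
               "empty")
})

test_that("local thickness recovers plate thickness and separation", {
  # plate of 5 voxels at 0.1 mm: Tb.Th = 0.5 mm +/- one voxel
  pl <- array(FALSE, c(20, 20, 15)); pl[, , 6:10] <- TRUE
  bv <- binary_volume(pl, 0.1)
  expect_lt(abs(local_thickness(bv, "foreground") - 0.5), 0.1 + 1e-9)
  # plates separated by 10-voxel gaps: Tb.Sp = 1.0 mm +/- one voxel
  st <- array(FALSE, c(12, 12, 35))
  st[, , c(1:5, 16:20, 31:35)] <- TRUE
  sv <- binary_volume(st, 0.1)
  expect_lt(abs(local_thickness(sv, "background") - 1.0), 0.1 + 1e-9)
  # phase filling the grid is flagged, empty phase errors
  solid <- binary_volume(array(TRUE, c(4, 4, 4)), 0.1)
  expect_warning(expect_true(is.na(local_thickness(solid, "foreground"))),
                 "unbounded")
  expect_error(local_thickness(solid, "background"), "empty")
})

test_that("thickness map equals the exhaustive sphere-search oracle", {
  for (seed in 1:3) {
    m <- random_mask(c(8, 8, 8), n_balls = 2, seed = seed)
    if (!any(m) || all(m)) next
    bv <- binary_volume(m, 1)
    got <- local_thickness(bv, "foreground", full_map = TRUE)
    expect_equal(got, brute_thickness_map(m), tolerance = 1e-12)
  }
})

test_that("Tb.N follows (BV/TV)/Tb.Th and matches plate counts", {
  expect_equal(trabecular_number(0.5, 0.5), 1.0)
  expect_equal(trabecular_number(0.25, 0.5), 0.5)
  expect_error(trabecular_number(0.5, 0), "positive")
  # 2 plates of 5 voxels in 40 layers at 0.1 mm: 2 plates / 4 mm = 0.5 /mm
  ph <- generate_phantom(phantom_spec(shape_voxels = c(16, 16, 40),
                                      voxel_size = 0.1,
                                      element_thickness = 0.5,
                                      target_bvtv = 0.25, noise_sd = 0))
  bvtv <- bone_volume_fraction(ph$mask)
  tb_th <- local_thickness(ph$mask, "foreground")
  expect_lt(abs(trabecular_number(bvtv, tb_th) - 0.5), 0.5 / 40 / 0.1)
})

test_that("Tb.Pf is positive for a ball, lower for a connected lattice", {
  r <- 5; n <- 17; ctr <- 9
  g <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  ball <- array((g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2 <= r^2,
                c(n, n, n))
  pf_ball <- trabecular_pattern_factor(binary_volume(ball, 1))
  expect_gt(pf_ball, 0)
  ph <- generate_phantom(phantom_spec(shape_voxels = c(17, 17, 17),
                                      voxel_size = 1, element_thickness = 5,
                                      target_bvtv = 0.3, noise_sd = 0))
  pf_plates <- trabecular_pattern_factor(ph$mask)
  expect_lt(pf_plates, pf_ball)
  expect_error(
    trabecular_pattern_factor(binary_volume(array(TRUE, c(3, 3, 3)), 1)),
    "fills")
})

test_that("Tb.Pf equals a from-scratch recount of S and V", {
  m <- random_mask(c(16, 16, 16), n_balls = 3, seed = 7)
  bv <- binary_volume(m, 1)
  got <- trabecular_pattern_factor(bv, smooth_sigma = 0)
  # independent recount: R marching tetrahedra + voxel counts, manual dilation
  d <- dim(m)
  m2 <- m
  for (sh in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))) {
    src <- function(a) pmin(pmax(seq_len(d[a]) - sh[a], 1L), d[a])
    nb <- m[src(1), src(2), src(3)]
    # do not wrap: voxels pulled from outside the grid are background
    if (sh[1] == 1) nb[1, , ] <- FALSE
    if (sh[1] == -1) nb[d[1], , ] <- FALSE
    if (sh[2] == 1) nb[, 1, ] <- FALSE
    if (sh[2] == -1) nb[, d[2], ] <- FALSE
    if (sh[3] == 1) nb[, , 1] <- FALSE
    if (sh[3] == -1) nb[, , d[3]] <- FALSE
    m2 <- m2 | nb
  }
  want <- (r_mt_area(m) - r_mt_area(m2)) / (sum(m) - sum(m2))
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("scale equivariance: doubling spacing rescales every parameter", {
  m <- random_mask(c(12, 12, 12), seed = 2)
  a <- binary_volume(m, 0.1)
  b <- binary_volume(m, 0.2)
  expect_equal(local_thickness(b, "foreground"),
               2 * local_thickness(a, "foreground"), tolerance = 1e-12)
  expect_equal(local_thickness(b, "background"),
               2 * local_thickness(a, "background"), tolerance = 1e-12)
  expect_equal(specific_surface(b)$bs_bv, specific_surface(a)$bs_bv / 2,
               tolerance = 1e-12)
  expect_equal(trabecular_pattern_factor(b),
               trabecular_pattern_factor(a) / 2, tolerance = 1e-12)
  bvtv <- bone_volume_fraction(a)
  expect_equal(trabecular_number(bvtv, local_thickness(b, "foreground")),
               trabecular_number(bvtv, local_thickness(a, "foreground")) / 2,
               tolerance = 1e-12)
})

test_that("BMD applies the linear calibration over the mask", {
  v <- image_volume(array(500, c(4, 4, 4)), 0.1)
  m <- binary_volume(array(TRUE, c(4, 4, 4)), 0.1)
  expect_equal(bmd_from_hu(v, m, bmd_calibration(1, 0)), 500)
  v2 <- image_volume(array(100, c(4, 4, 4)), 0.1)
  expect_equal(bmd_from_hu(v2, m, bmd_calibration(0.5, 10)), 60)
  # mixed HU under a partial mask equals the hand-computed mean
  set.seed(31)
  hu <- array(rnorm(64, 800, 200), c(4, 4, 4))
  sel <- array(runif(64) > 0.5, c(4, 4, 4))
  v3 <- image_volume(hu, 0.1)
  m3 <- binary_volume(sel, 0.1)
  cal <- bmd_calibration(0.7, -20)
  expect_equal(bmd_from_hu(v3, m3, cal), mean(0.7 * hu[sel] - 20),
               tolerance = 1e-12)
  expect_error(bmd_calibration(0), "non-zero")
})

test_that("Otsu threshold separates a bimodal phantom", {
  ph <- generate_phantom(phantom_spec(shape_voxels = c(16, 16, 16),
                                      noise_sd = 120, seed = 4))
  th <- otsu_threshold(ph$volume)
  expect_gt(th, 400)
  expect_lt(th, 1600)
  expect_error(otsu_threshold(image_volume(array(1, c(3, 3, 3)), 1)),
               "constant")
})

test_that("analyze_roi flags degenerate regions and labels metadata", {
  v <- image_volume(array(2000, c(8, 8, 8)), 0.1)
  row <- analyze_roi(v, roi("SA", c(0, 0, 0), c(8, 8, 8), level = "C4",
                            side = "right"), threshold = 1000)
  expect_equal(row$bvtv, 1)
  expect_true(is.na(row$tb_sp))
  expect_match(row$note, "Tb.Sp|unbounded|empty")
  expect_equal(row$level, "C4")
  expect_equal(row$side, "right")
})

test_that("four quadrant ROIs of a phantom give four labelled rows", {
  ph <- generate_phantom(phantom_spec(shape_voxels = c(24, 24, 24),
                                      noise_sd = 0))
  rois <- quadrant_rois(ph$volume, theta = c(SA = 40, SP = 45, IA = 50,
                                             IP = 55), level = "C5")
  tab <- analyze_morphometry(ph$volume, rois, threshold = 1000)
  expect_equal(nrow(tab), 4)
  expect_setequal(tab$label, c("SA", "SP", "IA", "IP"))
  expect_equal(tab$theta[tab$label == "IA"], 50)
  expect_true(all(tab$bvtv > 0 & tab$bvtv < 1))
})

test_that("plate phantom morphometry matches closed-form geometry", {
  ph <- generate_phantom(phantom_spec(shape_voxels = c(40, 40, 40),
                                      voxel_size = 0.1,
                                      element_thickness = 0.5,
                                      target_bvtv = 0.25, noise_sd = 0))
  row <- analyze_roi(ph$volume, roi("SA", c(0, 0, 0), c(40, 40, 40)),
                     threshold = 1000)
  expect_lt(abs(row$bvtv - 0.25), 5 / 40 + 1e-12)
  expect_lt(abs(row$tb_th - 0.5), 0.1 + 1e-9)
  # plates: BS/BV ~ 2/w plus side-wall contribution
  expect_lt(abs(row$bs_bv - 2 / 0.5) / (2 / 0.5), 0.30)
})
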
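make_bilinear <- function(E = 100, ey = 0.008, H = 0, n = 301,
                          emax = 0.03, noise = 0, seed = 1) {
  generate_curve(curve_spec(tissue_modulus = E, yield_strain = ey,
                            hardening_modulus = H, max_strain = emax,
                            n_points = n, noise_sd = noise, seed = seed))
}

test_that("elastic fit recovers an exact line over the whole record", {
  strain <- seq(0, 0.02, length.out = 50)
  cv <- as_ss_curve(tibble::tibble(strain = strain, stress = 50 * strain))
  fit <- fit_youngs_modulus(cv)
  expect_equal(fit$E, 50, tolerance = 1e-10)
  expect_equal(fit$window, range(strain))
})

test_that("elastic fit finds the pre-yield window of a bilinear curve", {
  cv <- make_bilinear(E = 100, ey = 0.008, H = 5)
  fit <- fit_youngs_modulus(cv)
  expect_equal(fit$E, 100, tolerance = 1e-9)
  expect_lte(fit$window[2], 0.008 + 1e-12)
  # manual window override
  fit2 <- fit_youngs_modulus(cv, window = c(0, 0.006))
  expect_equal(fit2$E, 100, tolerance = 1e-9)
})

test_that("elastic fit is accurate on noisy curves (simulation)", {
  # stress noise at 2% of the yield stress, 200 replicates
  est <- vapply(1:200, function(s) {
    cv <- make_bilinear(E = 100, ey = 0.008, H = 5, n = 200, noise = 0.016,
                        seed = s)
    fit_youngs_modulus(cv)$E
  }, numeric(1))
  expect_lt(abs(stats::median(est) - 100) / 100, 0.03)
})

test_that("offset yield matches the closed-form two-line intersection", {
  # flat post-yield branch: crossing at yield_strain + offset
  cv <- make_bilinear(E = 100, ey = 0.008, H = 0)
  y <- yield_offset(cv, E = 100)
  expect_equal(y$yield_stress, 0.8, tolerance = 1e-12)
  expect_equal(y$yield_strain, 0.010, tolerance = 1e-12)
  # hardening branch: closed-form e* = (sy - H ey + E off)/(E - H)
  H <- 10
  cv2 <- make_bilinear(E = 100, ey = 0.008, H = H)
  y2 <- yield_offset(cv2, E = 100)
  estar <- (0.8 - H * 0.008 + 100 * 0.002) / (100 - H)
  expect_equal(y2$yield_strain, estar, tolerance = 1e-12)
  expect_equal(y2$yield_stress, 100 * (estar - 0.002), tolerance = 1e-12)
  # a pure line never yields
  line <- as_ss_curve(tibble::tibble(strain = seq(0, 0.02, length.out = 20),
                                     stress = 100 * seq(0, 0.02, length.out = 20)))
  expect_equal(yield_offset(line, 100)$status, "no_yield")
  # offset 0 on a noiseless bilinear curve returns the true yield point
  y0 <- yield_offset(cv2, E = 100, offset = 0)
  expect_equal(y0$yield_strain, 0.008, tolerance = 1e-10)
  expect_equal(y0$yield_stress, 0.8, tolerance = 1e-10)
})

test_that("allowable stress follows the cosine rule", {
  expect_equal(allowable_stress(10, 0), 10)
  expect_equal(allowable_stress(10, 60), 20, tolerance = 1e-12)
  expect_equal(allowable_stress(7, 45), 7 * sqrt(2), tolerance = 1e-12)
  expect_error(allowable_stress(10, 90), "theta")
  expect_error(allowable_stress(10, -1), "theta")
  # strictly increasing in theta, equal to sigma_yield at 0
  th <- seq(0, 89, by = 1)
  a <- allowable_stress(5, th)
  expect_true(all(diff(a) > 0))
  expect_equal(a[1], 5)
})

test_that("curve maxima match an exhaustive scan", {
  cv <- make_bilinear()
  mx <- curve_maxima(cv, area = 25)
  expect_equal(mx$stress_max, max(cv$stress))
  expect_equal(mx$strain_max, 0.03)
  expect_equal(mx$force_max, max(cv$stress) * 25)
  # softening tail: interior maximum
  strain <- seq(0, 0.03, length.out = 60)
  stress <- 1 - (strain - 0.02)^2 * 1e3
  soft <- as_ss_curve(tibble::tibble(strain = strain, stress = stress))
  expect_equal(curve_maxima(soft)$stress_max, max(stress))
  expect_lt(which.max(stress), length(stress))
  # random curve vs scan oracle
  set.seed(8)
  rnd <- as_ss_curve(tibble::tibble(strain = sort(runif(40, 0, 0.03)),
                                    stress = abs(rnorm(40))))
  expect_equal(curve_maxima(rnd)$stress_max, max(rnd$stress))
  # force channel wins over area conversion
  wf <- tibble::tibble(strain = strain, stress = stress,
                       force = stress * 10)
  expect_equal(curve_maxima(as_ss_curve(wf))$force_max, max(wf$force))
  expect_true(is.na(curve_maxima(soft)$force_max))
})

test_that("bilinear fit recovers the generator parameters exactly", {
  cv <- make_bilinear(E = 100, ey = 0.008, H = 12, n = 200)
  fb <- fit_bilinear(cv)
  expect_true(fb$identifiable)
  expect_equal(fb$E, 100, tolerance = 1e-6)
  expect_equal(fb$H, 12, tolerance = 1e-5)
  expect_equal(fb$yield_strain, 0.008, tolerance = 1e-6)
  # a straight line leaves the breakpoint unidentifiable
  strain <- seq(0, 0.02, length.out = 30)
  line <- as_ss_curve(tibble::tibble(strain = strain, stress = 40 * strain))
  expect_false(fit_bilinear(line)$identifiable)
})

test_that("bilinear breakpoint is robust under noise (simulation)", {
  err <- vapply(1:200, function(s) {
    cv <- make_bilinear(E = 100, ey = 0.008, H = 10, n = 150, noise = 0.016,
                        seed = s + 1000)
    abs(fit_bilinear(cv)$yield_strain - 0.008) / 0.008
  }, numeric(1))
  expect_lt(stats::median(err), 0.10)
})

test_that("analyzing a noiseless record recovers every generator parameter", {
  res <- analyze_curve(make_bilinear(E = 100, ey = 0.008, H = 5), theta = 45,
                       area = 25)
  expect_equal(res$youngs_modulus, 100, tolerance = 1e-9)
  expect_lte(res$elastic_end, 0.008 + 1e-12)
  estar <- (0.8 - 5 * 0.008 + 0.2) / 95
  expect_equal(res$yield_strain, estar, tolerance = 1e-10)
  expect_equal(res$allowable_stress, res$yield_stress / cospi(45 / 180),
               tolerance = 1e-12)
  expect_equal(res$strain_max, 0.03)
  expect_equal(res$force_max, res$stress_max * 25)
  expect_equal(res$status, "yield")
})

test_that("curve container validates inputs and converts channels", {
  expect_error(as_ss_curve(tibble::tibble(strain = c(0, 1),
                                          stress = c(0, 1))), "3 points")
  expect_error(as_ss_curve(tibble::tibble(strain = c(0, 2, 1),
                                          stress = c(0, 1, 2))),
               "nondecreasing")
  expect_error(as_ss_curve(tibble::tibble(a = 1:5)), "strain")
  # force/displacement conversion
  fd <- tibble::tibble(displacement = seq(0, 0.5, length.out = 10),
                       force = seq(0, 50, length.out = 10))
  cv <- as_ss_curve(fd, area = 25, height = 5)
  expect_equal(cv$strain, fd$displacement / 5)
  expect_equal(cv$stress, fd$force / 25)
  expect_error(as_ss_curve(fd), "area")
})

test_that("curve CSV round trip and batch analysis preserve metadata", {
  dir <- withr::local_tempdir()
  cv <- make_bilinear(H = 5)
  f1 <- file.path(dir, "C4_right_SA_theta45.csv")
  readr::write_csv(cv, f1)
  back <- read_curve_csv(f1)
  expect_equal(back$stress, cv$stress, tolerance = 1e-12)
  tab <- analyze_curves(files = f1)
  expect_equal(tab$level, "C4")
  expect_equal(tab$side, "right")
  expect_equal(tab$region, "SA")
  expect_equal(tab$theta, 45)
  expect_equal(tab$youngs_modulus, 100, tolerance = 1e-9)
  # manifest interface
  mf <- tibble::tibble(file = f1, level = "C5", side = "left",
                       region = "IP", theta = 30)
  tab2 <- analyze_curves(manifest = mf)
  expect_equal(tab2$region, "IP")
  expect_equal(tab2$allowable_stress,
               tab2$yield_stress / cospi(30 / 180), tolerance = 1e-12)
})
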
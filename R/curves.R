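#' Stress-strain curve container
#'
#' A tibble subclass holding one compression record: columns `strain`
#' (dimensionless, nondecreasing, compressive magnitudes stored positive)
#' and `stress` (MPa), optionally `force` (N) and `displacement` (mm).
#' Specimen cross-section `area` (mm^2) and `height` (mm) can be attached as
#' attributes and are used to convert between the force and stress channels.
#'
#' @param x A data frame with at least `strain` and `stress`, or `force` and
#'   `displacement` together with `area` and `height`.
#' @param area Specimen cross-sectional area in mm^2 (optional).
#' @param height Specimen height in mm (optional).
#' @return An `ss_curve` tibble.
#' @export
as_ss_curve <- function(x, area = NULL, height = NULL) {
  x <- tibble::as_tibble(x)
  if (!all(c("strain", "stress") %in% names(x))) {
    if (all(c("force", "displacement") %in% names(x))) {
      if (is.null(area) || is.null(height)) {
        abort("force/displacement input needs `area` and `height`.")
      }
      x$strain <- x$displacement / height
      x$stress <- x$force / area
    } else {
      abort("curve needs `strain` + `stress` (or `force` + `displacement`).")
    }
  }
  if (nrow(x) < 3L) abort("a curve needs at least 3 points.")
  if (x$strain[1] < 0) abort("strain must start at or above 0.")
  if (is.unsorted(x$strain)) abort("`strain` must be nondecreasing.")
  structure(x, class = c("ss_curve", class(tibble::tibble())),
            area = area, height = height)
}

#' Read a stress-strain record from CSV
#'
#' Expects a header row with `strain,stress` columns (and optionally
#' `force,displacement`); force/displacement-only files are converted using
#' `area` and `height`.
#'
#' @param path CSV file path.
#' @inheritParams as_ss_curve
#' @return An `ss_curve` tibble.
#' @export
read_curve_csv <- function(path, area = NULL, height = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  as_ss_curve(df, area = area, height = height)
}

# rolling OLS slopes over `span`-point windows; slope i covers points
# i..(i + span - 1)
rolling_slopes <- function(strain, stress, span) {
  n <- length(strain)
  m <- n - span + 1L
  vapply(seq_len(m), function(i) {
    idx <- i:(i + span - 1L)
    x <- strain[idx]; y <- stress[idx]
    sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  }, numeric(1))
}

#' Fit Young's modulus over the elastic window
#'
#' Detects the linear (elastic) region of the curve and returns the
#' least-squares slope over it. Detection scans rolling OLS slopes at
#' increasing spans (2, 4, 8, ... points) for maximal windows in which
#' every local slope stays within `band` (default +/-5%) of the window
#' median; among admissible windows of at least `n/8` points the one with
#' the steepest median slope is chosen -- steepness, not length, so the
#' pre-yield branch wins even when the post-yield branch holds more
#' samples. Short spans resolve clean data exactly; noisier records only
#' produce long admissible windows at coarser spans (escalating the band
#' if necessary). Trailing points whose adjacent secant falls off the
#' window consensus (beyond the band or 3 robust sigma) are trimmed, which
#' pins the window end at the yield point on noise-free curves. A manual
#' window overrides detection.
#'
#' @param curve An `ss_curve` (see [as_ss_curve()]).
#' @param band Allowed relative slope deviation inside the window.
#' @param min_frac Minimum admissible window size as a fraction of the
#'   record length.
#' @param window Optional manual strain window `c(lo, hi)`; skips detection.
#' @return A list: `E` (MPa), `window` = `c(Es, Ee)` strain pair, `idx`
#'   point indices used, `span` and `band` finally applied.
#' @export
fit_youngs_modulus <- function(curve, band = 0.05, min_frac = 1 / 8,
                               window = NULL) {
  strain <- curve$strain; stress <- curve$stress
  n <- length(strain)
  ols_slope <- function(idx) {
    x <- strain[idx]; y <- stress[idx]
    sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  }
  if (!is.null(window)) {
    idx <- which(strain >= window[1] & strain <= window[2])
    if (length(idx) < 3L) abort("manual window holds fewer than 3 points.")
    return(list(E = ols_slope(idx), window = range(strain[idx]), idx = idx,
                span = NA_integer_, band = NA_real_))
  }
  if (n < 3L) abort("need at least 3 points.")
  find_runs <- function(sl, sp, b) {
    m <- length(sl); runs <- list(); a <- 1L
    while (a <= m) {
      z <- a
      repeat {
        if (z == m) break
        med <- stats::median(sl[a:(z + 1L)])
        if (all(abs(sl[a:(z + 1L)] - med) <= abs(med) * b)) z <- z + 1L
        else break
      }
      runs[[length(runs) + 1L]] <-
        list(a = a, z = z, npts = (z + sp - 1L) - a + 1L,
             med = stats::median(sl[a:z]))
      a <- z + 1L
    }
    runs
  }
  min_pts <- max(3L, floor(n * min_frac))
  best <- NULL; used_span <- NA_integer_; used_band <- NA_real_
  spans <- unique(pmin(c(2L, 4L, 8L, 16L, 32L), n - 1L))
  for (sp in spans) {
    sl <- rolling_slopes(strain, stress, sp)
    # fine spans are hopeless when slope scatter dwarfs the band; move on
    med_all <- stats::median(sl)
    if (sp != spans[length(spans)] &&
        stats::mad(sl) > 3 * band * abs(med_all)) {
      next
    }
    b <- band
    for (k in 1:5) {
      runs <- find_runs(sl, sp, b)
      ok <- Filter(function(r) r$npts >= min_pts, runs)
      if (length(ok)) {
        cand <- ok[[which.max(vapply(ok, function(r) r$med, numeric(1)))]]
        best <- cand$a:(cand$z + sp - 1L)
        used_span <- sp; used_band <- b
        break
      }
      b <- b * 1.5
    }
    if (!is.null(best)) break
  }
  if (is.null(best)) abort("no admissible elastic window found.")
  idx <- best
  repeat {  # trim post-yield stragglers off the window end
    if (length(idx) <= 3L) break
    s2 <- diff(stress[idx]) / diff(strain[idx])
    med <- stats::median(s2)
    tol <- max(abs(med) * band, 3 * stats::mad(s2))
    if (abs(s2[length(s2)] - med) > tol) idx <- idx[-length(idx)] else break
  }
  list(E = ols_slope(idx), window = range(strain[idx]), idx = idx,
       span = used_span, band = used_band)
}

#' 0.2% offset yield point
#'
#' Intersects the measured curve with the elastic line shifted by `offset`
#' strain, `sigma = E * (strain - offset)`, locating the crossing by linear
#' interpolation between the bracketing samples. A curve that never meets
#' the offset line before its last point has no yield (failed elastically).
#'
#' @param curve An `ss_curve`.
#' @param E Young's modulus (MPa), e.g. from [fit_youngs_modulus()].
#' @param offset Strain offset, default 0.002 (0.2%).
#' @return A list: `yield_stress` (MPa), `yield_strain`, `status`
#'   (`"yield"` or `"no_yield"`, the latter with `NA` values).
#' @export
yield_offset <- function(curve, E, offset = 0.002) {
  if (!is.numeric(E) || E <= 0) abort("`E` must be positive.")
  strain <- curve$strain; stress <- curve$stress
  g <- stress - E * (strain - offset)
  n <- length(g)
  # descending crossing of the offset line, including a tangent departure
  # (g identically 0 over the elastic branch when offset = 0)
  hit <- which((g[-n] >= 0 & g[-1] < 0) | (g[-n] > 0 & g[-1] <= 0))
  if (!length(hit)) {
    return(list(yield_stress = NA_real_, yield_strain = NA_real_,
                status = "no_yield"))
  }
  i <- hit[1]
  t <- g[i] / (g[i] - g[i + 1])
  list(yield_stress = stress[i] + t * (stress[i + 1] - stress[i]),
       yield_strain = strain[i] + t * (strain[i + 1] - strain[i]),
       status = "yield")
}

#' Facet-angle allowable stress
#'
#' The load on a facet region combines the vertical principal stress and a
#' shear component perpendicular to the facet plane; with `theta` the angle
#' between gravity and the shear force, the region's allowable stress is
#' `[sigma] = sigma_yield / cos(theta)`. Strictly increasing in `theta` and
#' equal to the yield stress at 0 degrees.
#'
#' @param yield_stress Yield stress in MPa.
#' @param theta Facet angle in degrees, `0 <= theta < 90`.
#' @return Allowable stress in MPa.
#' @examples
#' allowable_stress(10, 60)  # 20
#' @export
allowable_stress <- function(yield_stress, theta) {
  if (any(theta < 0 | theta >= 90)) {
    abort("`theta` must satisfy 0 <= theta < 90 degrees.")
  }
  yield_stress / cospi(theta / 180)
}

#' Curve maxima
#'
#' Componentwise maxima of the record: maximum stress, maximum strain and
#' maximum force (from the force channel if present, else `stress_max *
#' area`).
#'
#' @param curve An `ss_curve`.
#' @param area Cross-sectional area in mm^2; falls back to the curve
#'   attribute.
#' @return A list: `stress_max` (MPa), `strain_max`, `force_max` (N, `NA`
#'   if no force channel and no area).
#' @export
curve_maxima <- function(curve, area = NULL) {
  area <- area %||% attr(curve, "area")
  stress_max <- max(curve$stress)
  force_max <- if ("force" %in% names(curve)) {
    max(curve$force)
  } else if (!is.null(area)) {
    stress_max * area
  } else {
    NA_real_
  }
  list(stress_max = stress_max, strain_max = max(curve$strain),
       force_max = force_max)
}

#' Fit a bilinear (elastic-plastic) law to a curve
#'
#' Continuous two-segment piecewise-linear least squares with a free
#' breakpoint: for each candidate breakpoint the model `stress ~ strain +
#' (strain - b)_+` is linear and solved by OLS; the breakpoint is grid
#' searched over the interior samples and refined continuously between the
#' best grid neighbours. Collinear (single-line) data leave the breakpoint
#' unidentifiable, which is flagged rather than treated as an error.
#'
#' @param curve An `ss_curve` with at least 5 points.
#' @return A list: `E` (pre-break slope, MPa), `H` (post-break slope),
#'   `yield_strain` (breakpoint), `yield_stress` (stress of the fit at the
#'   breakpoint), `sse`, and `identifiable` (FALSE when a single line fits
#'   as well).
#' @export
fit_bilinear <- function(curve) {
  strain <- curve$strain; stress <- curve$stress
  n <- length(strain)
  if (n < 5L) abort("bilinear fit needs at least 5 points.")
  sse_at <- function(b) {
    X <- cbind(1, strain, pmax(strain - b, 0))
    fit <- stats::lm.fit(X, stress)
    sum(fit$residuals^2)
  }
  cand <- strain[3:(n - 2)]
  cand <- cand[cand > strain[1] & cand < strain[n]]
  sses <- vapply(cand, sse_at, numeric(1))
  k <- which.min(sses)
  lo <- cand[max(1L, k - 1L)]
  hi <- cand[min(length(cand), k + 1L)]
  b_opt <- if (lo < hi) {
    optimize(sse_at, c(lo, hi), tol = .Machine$double.eps^0.5)$minimum
  } else {
    cand[k]
  }
  if (sse_at(cand[k]) < sse_at(b_opt)) b_opt <- cand[k]
  X <- cbind(1, strain, pmax(strain - b_opt, 0))
  fit <- stats::lm.fit(X, stress)
  beta <- fit$coefficients
  sse <- sum(fit$residuals^2)
  line <- lm(stress ~ strain)
  sse_line <- sum(line$residuals^2)
  identifiable <- is.finite(beta[3]) &&
    (sse_line - sse) > 1e-9 * max(sse_line, .Machine$double.eps)
  E <- unname(beta[2]); H <- unname(beta[2] + beta[3])
  list(E = E, H = H, yield_strain = b_opt,
       yield_stress = unname(beta[1] + beta[2] * b_opt),
       sse = sse, identifiable = identifiable)
}

#' Reduce one stress-strain record to its mechanical parameters
#'
#' Chains [fit_youngs_modulus()], [yield_offset()], [curve_maxima()] and
#' [allowable_stress()] into one tidy row: Young's modulus with its elastic
#' window (Es, Ee), 0.2%-offset yield stress and strain, maxima, and the
#' facet-angle allowable stress when `theta` is given.
#'
#' @param curve An `ss_curve`.
#' @param theta Facet angle in degrees (optional; `NA` skips `[sigma]`).
#' @param offset Yield offset strain.
#' @param area Cross-sectional area in mm^2 for `force_max`.
#' @param ... Passed to [fit_youngs_modulus()].
#' @return A one-row tibble.
#' @examples
#' analyze_curve(generate_curve(curve_spec(noise_sd = 0)), theta = 45)
#' @export
analyze_curve <- function(curve, theta = NA_real_, offset = 0.002,
                          area = NULL, ...) {
  em <- fit_youngs_modulus(curve, ...)
  yld <- yield_offset(curve, em$E, offset)
  mx <- curve_maxima(curve, area)
  allow <- if (!is.na(theta) && yld$status == "yield") {
    allowable_stress(yld$yield_stress, theta)
  } else {
    NA_real_
  }
  tibble::tibble(
    youngs_modulus = em$E, elastic_start = em$window[1],
    elastic_end = em$window[2],
    yield_stress = yld$yield_stress, yield_strain = yld$yield_strain,
    stress_max = mx$stress_max, strain_max = mx$strain_max,
    force_max = mx$force_max, theta = theta, allowable_stress = allow,
    status = yld$status)
}

#' Batch curve analysis
#'
#' Analyzes a set of curve CSV files and binds one row per specimen.
#' Metadata comes either from a manifest tibble (columns `file`, `level`,
#' `side`, `region`, `theta`, optional `area`, `height`) or, failing that,
#' from file names of the form `<level>_<side>_<region>[_theta<deg>].csv`
#' (e.g. `C4_right_SA_theta45.csv`).
#'
#' @param files Character vector of CSV paths (ignored when `manifest`
#'   given).
#' @param manifest Optional tibble; see Description.
#' @param ... Passed to [analyze_curve()].
#' @return A tibble, one row per file, metadata columns first.
#' @export
analyze_curves <- function(files = NULL, manifest = NULL, ...) {
  if (is.null(manifest)) {
    if (is.null(files)) abort("give `files` or a `manifest`.")
    base <- sub("\\.csv$", "", basename(files))
    parts <- strsplit(base, "_")
    manifest <- purrr::map2_dfr(parts, files, function(p, f) {
      theta <- NA_real_
      th <- grep("^theta", p, value = TRUE)
      if (length(th)) theta <- as.numeric(sub("^theta", "", th[1]))
      tibble::tibble(file = f,
                     level = if (length(p) >= 1) p[1] else NA_character_,
                     side = if (length(p) >= 2) p[2] else NA_character_,
                     region = if (length(p) >= 3) p[3] else NA_character_,
                     theta = theta)
    })
  }
  grab <- function(row, col, default) {
    v <- if (col %in% names(manifest)) row[[col]] else NULL
    if (is.null(v) || (length(v) == 1L && is.na(v))) default else v
  }
  purrr::map_dfr(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    area <- grab(row, "area", NULL)
    curve <- read_curve_csv(row$file, area = area,
                            height = grab(row, "height", NULL))
    res <- analyze_curve(curve, theta = grab(row, "theta", NA_real_),
                         area = area, ...)
    dplyr::bind_cols(
      tibble::tibble(file = row$file,
                     level = grab(row, "level", NA_character_),
                     side = grab(row, "side", NA_character_),
                     region = grab(row, "region", NA_character_)),
      res)
  })
}
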
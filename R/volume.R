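#' Image volume container
#'
#' A 3-D grid of CT gray values (HU) with isotropic voxel spacing. Arrays are
#' indexed `[x, y, z]`; the z axis is the loading axis throughout the
#' package.
#'
#' @param voxels 3-D numeric array of gray values (HU).
#' @param spacing Isotropic voxel edge length in mm (a single positive
#'   number).
#' @return An object of class `image_volume`: a list with elements `voxels`
#'   and `spacing`.
#' @examples
#' v <- image_volume(array(1500, dim = c(8, 8, 8)), spacing = 0.078)
#' v
#' @export
image_volume <- function(voxels, spacing) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    abort("`voxels` must be a 3-D array.")
  }
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) ||
      spacing <= 0) {
    abort("`spacing` must be a single positive number (mm per voxel).")
  }
  storage.mode(voxels) <- "double"
  structure(list(voxels = voxels, spacing = as.numeric(spacing)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_volume> %d x %d x %d voxels @ %g mm (%.2f x %.2f x %.2f mm)\n",
              d[1], d[2], d[3], x$spacing,
              d[1] * x$spacing, d[2] * x$spacing, d[3] * x$spacing))
  cat(sprintf("  HU range: [%g, %g]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Binary (segmented) volume
#'
#' A boolean mask over the same grid as its source volume; `TRUE` marks bone.
#'
#' @param mask 3-D logical array (foreground = bone).
#' @param spacing Voxel edge length in mm.
#' @param threshold Optional HU threshold recorded as provenance.
#' @return An object of class `binary_volume`.
#' @export
binary_volume <- function(mask, spacing, threshold = NA_real_) {
  if (!is.array(mask) || length(dim(mask)) != 3L) {
    abort("`mask` must be a 3-D array.")
  }
  if (!is.logical(mask)) storage.mode(mask) <- "logical"
  if (anyNA(mask)) abort("`mask` must not contain NA.")
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0) {
    abort("`spacing` must be a single positive number (mm per voxel).")
  }
  structure(list(mask = mask, spacing = as.numeric(spacing),
                 threshold = as.numeric(threshold)),
            class = "binary_volume")
}

#' @export
print.binary_volume <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<binary_volume> %d x %d x %d voxels @ %g mm, BV/TV = %.3f",
              d[1], d[2], d[3], x$spacing, mean(x$mask)))
  if (!is.na(x$threshold)) cat(sprintf(" (threshold %g HU)", x$threshold))
  cat("\n")
  invisible(x)
}

#' Region of interest
#'
#' A labelled cube inside a parent volume, following the four-quadrant scheme
#' for an articular process: superior-anterior (SA), superior-posterior (SP),
#' inferior-anterior (IA) and inferior-posterior (IP). `theta` is the facet
#' angle in degrees between gravity and the shear force acting on the facet
#' plane; it enters the allowable-stress rule `[sigma] = sigma_yield /
#' cos(theta)`.
#'
#' Voxel coordinates are 0-based and the box is half-open:
#' `[origin, origin + size)`.
#'
#' @param label Region label, one of `"SA"`, `"SP"`, `"IA"`, `"IP"`.
#' @param origin Integer triple, 0-based voxel origin.
#' @param size Integer triple, extent in voxels.
#' @param theta Facet angle in degrees, `0 <= theta < 90`. Cervical facets
#'   sit at about 45 degrees, the default.
#' @param ... Further metadata carried through to result tables (for example
#'   `level = "C4"`, `side = "right"`).
#' @return An object of class `roi`.
#' @examples
#' roi("SA", origin = c(0, 0, 0), size = c(32, 32, 32), level = "C4",
#'     side = "right")
#' @export
roi <- function(label, origin, size, theta = 45, ...) {
  label <- match.arg(label, c("SA", "SP", "IA", "IP"))
  origin <- as.integer(origin)
  size <- as.integer(size)
  if (length(origin) != 3L || anyNA(origin) || any(origin < 0)) {
    abort("`origin` must be three non-negative integers (0-based voxels).")
  }
  if (length(size) != 3L || anyNA(size) || any(size < 1)) {
    abort("`size` must be three positive integers (voxels).")
  }
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0 || theta >= 90) {
    abort("`theta` must be an angle in degrees with 0 <= theta < 90.")
  }
  structure(c(list(label = label, origin = origin, size = size,
                   theta = as.numeric(theta)), list(...)),
            class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> %s  origin (%s)  size (%s)  theta %g deg\n", x$label,
              paste(x$origin, collapse = ","),
              paste(x$size, collapse = ","), x$theta))
  invisible(x)
}

#' Crop a volume to a region of interest
#'
#' @param volume An [image_volume()] (or [binary_volume()]).
#' @param roi An [roi()]; must lie inside the volume.
#' @return An object of the same class as `volume` covering only the ROI.
#' @export
crop_volume <- function(volume, roi) {
  arr <- if (inherits(volume, "image_volume")) volume$voxels else volume$mask
  d <- dim(arr)
  hi <- roi$origin + roi$size
  if (any(hi > d)) {
    abort(sprintf("ROI %s [origin %s, size %s] exceeds the %s-voxel volume.",
                  roi$label, paste(roi$origin, collapse = ","),
                  paste(roi$size, collapse = ","), paste(d, collapse = "x")))
  }
  ix <- (roi$origin[1] + 1L):hi[1]
  iy <- (roi$origin[2] + 1L):hi[2]
  iz <- (roi$origin[3] + 1L):hi[3]
  sub <- arr[ix, iy, iz, drop = FALSE]
  if (inherits(volume, "image_volume")) {
    image_volume(sub, volume$spacing)
  } else {
    binary_volume(sub, volume$spacing, volume$threshold)
  }
}

#' Split a volume into the four quadrant ROIs
#'
#' Convenience constructor of the SA/SP/IA/IP scheme: the volume is halved
#' along x (anterior/posterior) and z (superior/inferior). Superior is the
#' upper half in z, anterior the lower half in x.
#'
#' @param volume An [image_volume()].
#' @param theta Facet angle in degrees, recycled over the four regions or a
#'   named vector (`c(SA = 40, SP = 45, IA = 50, IP = 45)`).
#' @param ... Metadata passed to every [roi()] (e.g. `level`, `side`).
#' @return A list of four [roi()] objects named SA, SP, IA, IP.
#' @export
quadrant_rois <- function(volume, theta = 45, ...) {
  d <- dim(volume$voxels)
  hx <- d[1] %/% 2L
  hz <- d[3] %/% 2L
  labs <- c("SA", "SP", "IA", "IP")
  if (is.null(names(theta))) {
    theta <- setNames(rep_len(theta, 4L), labs)
  }
  out <- list(
    SA = roi("SA", c(0L, 0L, hz), c(hx, d[2], d[3] - hz), theta[["SA"]], ...),
    SP = roi("SP", c(hx, 0L, hz), c(d[1] - hx, d[2], d[3] - hz), theta[["SP"]], ...),
    IA = roi("IA", c(0L, 0L, 0L), c(hx, d[2], hz), theta[["IA"]], ...),
    IP = roi("IP", c(hx, 0L, 0L), c(d[1] - hx, d[2], hz), theta[["IP"]], ...)
  )
  out
}
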
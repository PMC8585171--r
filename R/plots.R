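#' Plot a stress-strain curve
#'
#' Draws the record and, when an [analyze_curve()] row is supplied, overlays
#' the detected elastic window, the offset line and the yield point.
#'
#' @param object An `ss_curve`.
#' @param analysis Optional one-row tibble from [analyze_curve()].
#' @param offset Offset strain of the overlay line.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.ss_curve <- function(object, analysis = NULL, offset = 0.002, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$strain, .data$stress)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "strain (-)", y = "stress (MPa)") +
    ggplot2::theme_minimal()
  if (!is.null(analysis)) {
    a <- analysis
    p <- p +
      ggplot2::annotate("rect", xmin = a$elastic_start, xmax = a$elastic_end,
                        ymin = -Inf, ymax = Inf, alpha = 0.12, fill = "steelblue")
    if (!is.na(a$yield_stress)) {
      xr <- range(object$strain)
      off <- tibble::tibble(strain = seq(offset, xr[2], length.out = 50))
      off$stress <- a$youngs_modulus * (off$strain - offset)
      off <- off[off$stress <= max(object$stress) * 1.05, ]
      p <- p +
        ggplot2::geom_line(data = off, linetype = "dashed", colour = "grey40") +
        ggplot2::annotate("point", x = a$yield_strain, y = a$yield_stress,
                          colour = "firebrick", size = 2)
    }
  }
  p
}

#' Plot a phantom mid-slice
#'
#' @param object A `phantom` from [generate_phantom()].
#' @param z Slice index (default mid-volume).
#' @param ... Ignored.
#' @return A ggplot raster of the HU slice.
#' @export
autoplot.phantom <- function(object, z = NULL, ...) {
  arr <- object$volume$voxels
  z <- z %||% (dim(arr)[3] %/% 2L)
  df <- expand.grid(x = seq_len(dim(arr)[1]), y = seq_len(dim(arr)[2]))
  df$hu <- as.vector(arr[, , z])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$hu)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("slice z = %d", z), fill = "HU") +
    ggplot2::theme_minimal()
}

#' Plot a micro-FE field
#'
#' `type = "histogram"` shows the element von Mises distribution with the
#' lower-quantile cut; `type = "slice"` maps the von Mises field on a
#' mid-height element layer.
#'
#' @param object An [fe_solution][solve_compression].
#' @param type `"histogram"` or `"slice"`.
#' @param quantile Quantile line of the histogram.
#' @param z Element layer (voxel z, 0-based) for the slice view.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.fe_solution <- function(object, type = c("histogram", "slice"),
                                 quantile = 0.75, z = NULL, ...) {
  type <- match.arg(type)
  if (type == "histogram") {
    df <- tibble::tibble(von_mises = object$von_mises)
    cut <- stats::quantile(df$von_mises, quantile, names = FALSE)
    return(
      ggplot2::ggplot(df, ggplot2::aes(.data$von_mises)) +
        ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = NA) +
        ggplot2::geom_vline(xintercept = cut, linetype = "dashed") +
        ggplot2::labs(x = "von Mises stress (MPa)", y = "elements") +
        ggplot2::theme_minimal())
  }
  d <- object$mesh$grid_dim
  v0 <- object$mesh$voxel_index - 1L
  vx <- v0 %% d[1]
  vy <- (v0 %/% d[1]) %% d[2]
  vz <- v0 %/% (d[1] * d[2])
  z <- z %||% as.integer(stats::median(vz))
  sel <- vz == z
  df <- tibble::tibble(x = vx[sel], y = vy[sel], vm = object$von_mises[sel])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$vm)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("von Mises, element layer z = %d", z),
                  fill = "MPa") +
    ggplot2::theme_minimal()
}

#' Plot a structure-mechanics regression
#'
#' @param object A [trab_regression][regress].
#' @param ... Ignored.
#' @return A ggplot scatter with the fitted line.
#' @export
autoplot.trab_regression <- function(object, ...) {
  df <- tibble::tibble(x = object$model$model$xv, y = object$model$model$yv)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "firebrick") +
    ggplot2::labs(x = object$x, y = object$y,
                  subtitle = sprintf("adj R2 = %.4f, p = %.3g",
                                     object$adj_r_squared, object$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot a morphometry parameter across the design
#'
#' Lines of one microstructure parameter by vertebral level, coloured by
#' region and facetted by side, mirroring the way regional trends are
#' usually displayed.
#'
#' @param data Tibble from [analyze_morphometry()] with `level`, `side` and
#'   `label` (region) columns.
#' @param parameter Column to plot (unquoted), e.g. `bvtv`.
#' @return A ggplot.
#' @export
plot_morphometry <- function(data, parameter) {
  psym <- rlang::ensym(parameter)
  p <- ggplot2::ggplot(data, ggplot2::aes(.data$level, !!psym,
                                          colour = .data$label,
                                          group = .data$label)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(colour = "region") +
    ggplot2::theme_minimal()
  if ("side" %in% names(data) && !all(is.na(data$side))) {
    p <- p + ggplot2::facet_wrap(~side)
  }
  p
}
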
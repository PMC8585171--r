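#' Read a 3-D image volume
#'
#' Supported inputs:
#' * NIfTI file (`.nii` / `.nii.gz`): voxel spacing from the header;
#' * multi-page TIFF file or a directory of per-slice TIFF files (sorted by
#'   name): gray values read as stored integers; spacing must be supplied
#'   because TIFF carries no reliable 3-D spacing metadata;
#' * DICOM series are not supported by this build (no reader available);
#'   convert to NIfTI first.
#'
#' @param path File or directory.
#' @param spacing Voxel spacing in mm; required for TIFF, overrides the
#'   header for NIfTI.
#' @param resample Permit anisotropic NIfTI spacing by nearest-neighbour
#'   resampling to the finest axis spacing; without it anisotropy is an
#'   error.
#' @return An [image_volume()].
#' @export
read_volume <- function(path, spacing = NULL, resample = FALSE) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                             ignore.case = TRUE))
    if (!length(files)) {
      if (length(list.files(path, pattern = "\\.dcm$", ignore.case = TRUE))) {
        abort(paste0("DICOM series are not supported by this build; ",
                     "convert to NIfTI (e.g. with dcm2niix) first."))
      }
      abort(sprintf("no TIFF slices found in %s.", path))
    }
    if (is.null(spacing)) {
      abort("TIFF stacks carry no spacing metadata: supply `spacing` (mm).")
    }
    slices <- lapply(files, function(f) {
      s <- tiff::readTIFF(f, as.is = TRUE)
      if (length(dim(s)) == 3L) s <- s[, , 1]
      t(s)  # readTIFF returns row = y; store x fastest
    })
    d <- dim(slices[[1]])
    arr <- array(unlist(slices, use.names = FALSE), dim = c(d, length(slices)))
    return(image_volume(arr, spacing))
  }
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    pix <- RNifti::pixdim(img)[1:3]
    if (is.null(spacing)) {
      if (diff(range(pix)) > 1e-6 * max(pix)) {
        if (!resample) {
          abort(sprintf(paste0("anisotropic spacing (%s mm): set `resample ",
                               "= TRUE` or supply `spacing`."),
                        paste(signif(pix, 4), collapse = " x ")))
        }
        target <- min(pix)
        d <- dim(img)
        newd <- as.integer(round(d * pix / target))
        idx <- lapply(1:3, function(a) {
          pmin(d[a], pmax(1L, as.integer(ceiling((seq_len(newd[a]) - 0.5) *
                                                   target / pix[a]))))
        })
        img <- array(img[idx[[1]], idx[[2]], idx[[3]]], dim = newd)
        pix <- rep(target, 3)
      }
      spacing <- pix[1]
    }
    arr <- array(as.numeric(img), dim = dim(img))
    return(image_volume(arr, spacing))
  }
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (is.null(spacing)) {
      abort("TIFF stacks carry no spacing metadata: supply `spacing` (mm).")
    }
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    slices <- lapply(pages, function(s) {
      if (length(dim(s)) == 3L) s <- s[, , 1]
      t(s)
    })
    d <- dim(slices[[1]])
    arr <- array(unlist(slices, use.names = FALSE), dim = c(d, length(slices)))
    return(image_volume(arr, spacing))
  }
  abort(sprintf("unrecognized volume format: %s", path))
}

#' Write a volume to NIfTI
#'
#' Stores the HU grid losslessly with the voxel spacing in the header.
#'
#' @param volume An [image_volume()] or [binary_volume()].
#' @param path Output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  arr <- if (inherits(volume, "image_volume")) volume$voxels else
    array(as.numeric(volume$mask), dim = dim(volume$mask))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(volume$spacing, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write an FE solution as a legacy VTK unstructured grid
#'
#' Plain-ASCII legacy VTK: hexahedral cells, nodal displacement vectors as
#' point data, and per-element modulus, density, von Mises, stress and
#' strain tensors as cell data. Readable by ParaView and VTK-based tools.
#'
#' @param sol An [fe_solution][solve_compression].
#' @param path Output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(sol, path) {
  stopifnot(inherits(sol, "fe_solution"))
  mesh <- sol$mesh
  np <- nrow(mesh$nodes)
  ne <- nrow(mesh$elems)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  num <- function(m) apply(format(m, trim = TRUE, digits = 9), 1, paste,
                           collapse = " ")
  wl("# vtk DataFile Version 3.0", "trabmech micro-FE solution", "ASCII",
     "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d double", np))
  wl(num(mesh$nodes))
  wl(sprintf("CELLS %d %d", ne, 9L * ne))
  wl(num(cbind(8L, mesh$elems - 1L)))
  wl(sprintf("CELL_TYPES %d", ne))
  wl(as.character(rep(12L, ne)))
  wl(sprintf("POINT_DATA %d", np), "VECTORS displacement double")
  wl(num(sol$displacements))
  wl(sprintf("CELL_DATA %d", ne))
  scalar <- function(name, x) {
    wl(sprintf("SCALARS %s double 1", name), "LOOKUP_TABLE default")
    wl(format(x, trim = TRUE, digits = 9))
  }
  scalar("von_mises", sol$von_mises)
  scalar("E", sol$material$E)
  if (!all(is.na(sol$material$density))) {
    scalar("density", sol$material$density)
  }
  tensor6 <- function(name, m) {
    wl(sprintf("FIELD %s 1", name), sprintf("%s_xx_yy_zz_xy_yz_zx 6 %d double",
                                            name, ne))
    wl(num(m))
  }
  tensor6("stress", sol$stress)
  tensor6("strain", sol$strain)
  invisible(path)
}

#' Pipeline configuration
#'
#' Validates a configuration list (or YAML file) for [run_pipeline()].
#' Recognized sections: `seed`, `output_dir` (optional; `run_pipeline()`
#' argument wins), `input` (either `phantom:` with [phantom_spec()] fields
#' or `volume: path` + `spacing`), `morphometry` (`threshold` required, or
#' `auto_threshold: true`; `bmd_slope`/`bmd_intercept`; `smooth_sigma`;
#' `theta` scalar or per-region map), `fe` (`enabled`, `strain`, `bc_mode`,
#' `solver`, `tol`, `roi` label to solve, `write_vtk`), `curves` (`specs`:
#' list of [curve_spec()] fields with a `name` each, or `files`), `stats`
#' (`paired` with [paired_spec()] fields, `regress: true`, `anova: true`).
#' Unknown keys are rejected.
#'
#' @param config A named list or a YAML file path.
#' @return A validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) abort("config must be a list or a YAML file path.")
  known <- c("seed", "output_dir", "input", "morphometry", "fe", "curves",
             "stats")
  extra <- setdiff(names(config), known)
  if (length(extra)) {
    abort(sprintf("unknown config key(s): %s", paste(extra, collapse = ", ")))
  }
  check_keys <- function(x, keys, where) {
    bad <- setdiff(names(x), keys)
    if (length(bad)) {
      abort(sprintf("unknown key(s) in `%s`: %s", where,
                    paste(bad, collapse = ", ")))
    }
  }
  if (is.null(config$input)) abort("config needs an `input` section.")
  check_keys(config$input, c("phantom", "volume", "spacing"), "input")
  if (is.null(config$input$phantom) && is.null(config$input$volume)) {
    abort("`input` needs `phantom` or `volume`.")
  }
  if (!is.null(config$input$phantom)) {
    check_keys(config$input$phantom,
               names(formals(phantom_spec)), "input$phantom")
  }
  if (!is.null(config$morphometry)) {
    check_keys(config$morphometry,
               c("threshold", "auto_threshold", "bmd_slope", "bmd_intercept",
                 "smooth_sigma", "theta", "tb_n_method"), "morphometry")
  }
  if (!is.null(config$fe)) {
    check_keys(config$fe, c("enabled", "strain", "bc_mode", "solver", "tol",
                            "roi", "write_vtk", "plasticity"), "fe")
  }
  if (!is.null(config$curves)) {
    check_keys(config$curves, c("specs", "files"), "curves")
    for (s in config$curves$specs) {
      check_keys(s, c("name", "theta", names(formals(curve_spec))),
                 "curves$specs[]")
    }
  }
  if (!is.null(config$stats)) {
    check_keys(config$stats, c("paired", "regress", "anova"), "stats")
    if (!is.null(config$stats$paired)) {
      check_keys(config$stats$paired, names(formals(paired_spec)),
                 "stats$paired")
    }
  }
  config$seed <- as.integer(config$seed %||% 1L)
  structure(config, class = c("pipeline_config", "list"))
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages on one configuration: input (generate a phantom
#' or read a volume), regional morphometry, micro-FE compression with field
#' summary (and optional VTK export), stress-strain curve analysis, and the
#' structure-mechanics statistics. Each stage logs its timing; outputs are
#' CSV files plus a JSON manifest holding the seed, config hash, package
#' version and per-file MD5 checksums, so a rerun with the same seed is
#' byte-reproducible and traceable.
#'
#' @param config A [pipeline_config()] (or list / YAML path coerced by it).
#' @param output_dir Output directory, created if missing.
#' @param quiet Suppress stage logging?
#' @return Invisibly, a list with the stage results and output paths.
#' @export
run_pipeline <- function(config, output_dir = NULL, quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  output_dir <- output_dir %||% config$output_dir %||%
    abort("no `output_dir` given.")
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    out <- tryCatch(expr, error = function(e) {
      abort(sprintf("stage `%s` failed: %s", name, conditionMessage(e)))
    })
    say("[%s] done in %.2f s", name, proc.time()[3] - t0)
    out
  }
  results <- list()
  outputs <- character()

  # -- input
  input <- stage("input", {
    if (!is.null(config$input$phantom)) {
      ph_args <- config$input$phantom
      ph_args$seed <- ph_args$seed %||% config$seed
      ph <- generate_phantom(do.call(phantom_spec, ph_args))
      list(volume = ph$volume, phantom = ph)
    } else {
      list(volume = read_volume(config$input$volume,
                                spacing = config$input$spacing),
           phantom = NULL)
    }
  })
  vol <- input$volume
  results$phantom <- input$phantom

  # -- morphometry
  mcfg <- config$morphometry %||% list()
  threshold <- mcfg$threshold %||% (
    if (isTRUE(mcfg$auto_threshold)) {
      otsu_threshold(vol)
    } else if (!is.null(results$phantom)) {
      with(results$phantom$spec, (bone_hu + marrow_hu) / 2)
    } else {
      abort("morphometry needs `threshold` (or `auto_threshold: true`).")
    })
  cal <- if (!is.null(mcfg$bmd_slope)) {
    bmd_calibration(mcfg$bmd_slope, mcfg$bmd_intercept %||% 0)
  }
  theta <- mcfg$theta %||% 45
  if (is.list(theta)) theta <- unlist(theta)
  rois <- quadrant_rois(vol, theta = theta)
  morpho <- stage("morphometry", {
    analyze_morphometry(vol, rois, threshold, cal = cal,
                        smooth_sigma = mcfg$smooth_sigma %||% 0.5,
                        tb_n_method = mcfg$tb_n_method %||% "thickness")
  })
  results$morphometry <- morpho
  p <- file.path(output_dir, "morphometry.csv")
  readr::write_csv(morpho, p)
  outputs <- c(outputs, p)

  # -- micro-FE
  fcfg <- config$fe %||% list()
  if (isTRUE(fcfg$enabled %||% TRUE)) {
    fe <- stage("fe", {
      lab <- fcfg$roi %||% "SA"
      sub <- crop_volume(vol, rois[[lab]])
      mask <- binarize(sub, threshold)
      mesh <- build_mesh(mask)
      mat <- map_materials(sub, mesh)
      sol <- solve_compression(mesh, mat, strain = fcfg$strain %||% 0.01,
                               bc_mode = fcfg$bc_mode %||% "platen",
                               solver = fcfg$solver %||% "auto",
                               tol = fcfg$tol %||% 1e-10,
                               plasticity = isTRUE(fcfg$plasticity))
      summ <- summarize_field(sol)
      summ$roi <- lab
      summ$apparent_modulus <- sol$apparent_modulus
      vp <- NULL
      if (isTRUE(fcfg$write_vtk)) {
        vp <- file.path(output_dir, sprintf("fe_%s.vtk", lab))
        write_vtk(sol, vp)
      }
      list(solution = sol, summary = summ, vtk = vp)
    })
    results$fe <- fe
    if (!is.null(fe$vtk)) outputs <- c(outputs, fe$vtk)
    p <- file.path(output_dir, "fe_summary.csv")
    readr::write_csv(fe$summary, p)
    outputs <- c(outputs, p)
  }

  # -- curves
  ccfg <- config$curves %||% list()
  curves_tbl <- stage("curves", {
    if (!is.null(ccfg$files)) {
      analyze_curves(files = ccfg$files)
    } else {
      specs <- ccfg$specs %||% list(list(name = "default"))
      purrr::map_dfr(specs, function(s) {
        nm <- s$name %||% "curve"
        th <- s$theta %||% 45
        s <- s[setdiff(names(s), c("name", "theta"))]
        s$seed <- s$seed %||% config$seed
        cv <- generate_curve(do.call(curve_spec, s))
        dplyr::bind_cols(tibble::tibble(name = nm),
                         analyze_curve(cv, theta = th))
      })
    }
  })
  results$curves <- curves_tbl
  p <- file.path(output_dir, "curves.csv")
  readr::write_csv(curves_tbl, p)
  outputs <- c(outputs, p)

  # -- stats
  scfg <- config$stats %||% list()
  if (!is.null(scfg$paired)) {
    stats_out <- stage("stats", {
      pr <- scfg$paired
      pr$seed <- pr$seed %||% config$seed
      d <- generate_paired_dataset(do.call(paired_spec, pr))
      out <- list()
      if (isTRUE(scfg$regress %||% TRUE)) {
        out$regression <- glance(regress(d, x, y))
      }
      if (isTRUE(scfg$anova %||% TRUE)) {
        out$anova <- tidy(factorial_anova(d, y))
      }
      out$data <- d
      out
    })
    results$stats <- stats_out
    if (!is.null(stats_out$regression)) {
      p <- file.path(output_dir, "stats_regression.csv")
      readr::write_csv(stats_out$regression, p)
      outputs <- c(outputs, p)
    }
    if (!is.null(stats_out$anova)) {
      p <- file.path(output_dir, "stats_anova.csv")
      readr::write_csv(stats_out$anova, p)
      outputs <- c(outputs, p)
    }
  }

  # -- manifest
  manifest <- list(
    package = "trabmech",
    version = as.character(utils::packageVersion("trabmech")),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    files = as.list(tools::md5sum(outputs)))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("[pipeline] wrote %d file(s) to %s", length(outputs) + 1L, output_dir)
  invisible(c(results, list(outputs = outputs, manifest = manifest)))
}
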
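#' Read a grayscale TIFF image or stack
#'
#' Reads single- or multi-page grayscale TIFF files into a list of
#' [raster_image()]s, widening integer data to floating point. RGB input is
#' rejected (it signals a wrong channel export).
#'
#' @param path TIFF file path.
#' @param pixel_size um/px; when `NULL`, taken from the TIFF resolution tags
#'   if present, else the 0.16 um/px default.
#' @return List of [raster_image()], one per page.
#' @export
read_stack <- function(path, pixel_size = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(pg) {
    if (length(dim(pg)) == 3L)
      stop("RGB TIFF input is unsupported: export a single grayscale channel")
    ps <- pixel_size
    if (is.null(ps)) {
      xres <- attr(pg, "x.resolution")
      unit <- attr(pg, "resolution.unit")
      if (!is.null(xres) && is.finite(xres) && xres > 0) {
        ps <- switch(as.character(unit %||% "inch"),
                     cm = 1e4 / xres, inch = 2.54e4 / xres, 1e4 / xres)
      } else ps <- 0.16
    }
    raster_image(matrix(as.numeric(pg), nrow(pg), ncol(pg)), pixel_size = ps)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write images as a grayscale TIFF stack
#'
#' Writes one or more images (or logical masks) as an 8- or 16-bit grayscale
#' TIFF. Integer-valued data within the bit range round-trips bit-identically
#' through [read_stack()].
#'
#' @param images a [raster_image()], matrix, or list of them.
#' @param path output file path.
#' @param bits 8 or 16 bits per sample.
#' @return `path`, invisibly.
#' @export
write_stack <- function(images, path, bits = 16L) {
  if (!is.list(images) || inherits(images, "raster_image")) images <- list(images)
  if (!bits %in% c(8L, 16L)) stop("bits must be 8 or 16")
  maxv <- 2^bits - 1
  pages <- lapply(images, function(im) {
    m <- if (inherits(im, "raster_image")) im$values else im * 1
    m <- round(pmin(pmax(m, 0), maxv))
    m / maxv
  })
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

#' Analysis configuration
#'
#' Validated bundle of every tunable pipeline parameter; each field is checked
#' against the preconditions of the module that consumes it.
#'
#' @param threshold_method method for [compute_threshold()].
#' @param histogram_bins bins for thresholding (>= 8).
#' @param min_area_px minimum cluster area (px).
#' @param grid spatial quadrat grid, integer pair.
#' @param rolling_ball_radius radius (px) for [rolling_ball()]; 0 disables.
#' @param frap_alpha F-test significance level.
#' @param actin_window_min half-time analysis window (min).
#' @param pixel_size um/px used when images carry no resolution tags.
#' @param seed integer seed controlling all pipeline randomness.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(threshold_method = "triangle",
                            histogram_bins = 256L, min_area_px = 4L,
                            grid = c(5L, 5L), rolling_ball_radius = 0L,
                            frap_alpha = 0.05, actin_window_min = 27,
                            pixel_size = 0.16, seed = 1L) {
  threshold_method <- match.arg(threshold_method,
                                c("triangle", "max_entropy", "sd_iterative"))
  if (histogram_bins < 8) stop("histogram_bins must be at least 8")
  if (min_area_px < 1) stop("min_area_px must be at least 1")
  if (length(grid) != 2 || any(grid < 1)) stop("grid must be two positive integers")
  if (rolling_ball_radius < 0) stop("rolling_ball_radius must be non-negative")
  if (frap_alpha <= 0 || frap_alpha >= 1) stop("frap_alpha must be in (0, 1)")
  if (actin_window_min <= 0) stop("actin_window_min must be positive")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  structure(list(threshold_method = threshold_method,
                 histogram_bins = as.integer(histogram_bins),
                 min_area_px = as.integer(min_area_px),
                 grid = as.integer(grid),
                 rolling_ball_radius = as.integer(rolling_ball_radius),
                 frap_alpha = frap_alpha, actin_window_min = actin_window_min,
                 pixel_size = pixel_size, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Load an analysis configuration from a YAML file
#'
#' Flat key-value YAML; unknown keys are rejected rather than silently
#' ignored.
#'
#' @param path YAML file.
#' @return An [analysis_config()].
#' @export
load_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  do.call(analysis_config, vals)
}

# Write a CSV plus a JSON sidecar describing columns and units.
write_csv_with_schema <- function(df, path, units) {
  utils::write.csv(df, path, row.names = FALSE)
  schema <- list(columns = as.list(units))
  jsonlite::write_json(schema, paste0(tools::file_path_sans_ext(path),
                                      ".schema.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Run the titration analysis pipeline over an image manifest
#'
#' Sequences correction, thresholding, segmentation and the order-parameter
#' metrics for each manifest entry, assembles the titration curve, estimates
#' the clustering concentration for both order parameters, and writes the
#' results (curve CSV with schema sidecar, per-image cluster CSVs, breakpoint
#' JSON, and a reproducibility log with the configuration hash). Entries that
#' fail are logged and skipped.
#'
#' @param manifest data frame with columns `concentration_nM` and
#'   `image_path`, sorted by concentration.
#' @param config an [analysis_config()].
#' @param background optional background image (TIFF path or
#'   [raster_image()]).
#' @param flatfield_reference optional homogeneous-bilayer reference (TIFF
#'   path or [raster_image()]) from which the correction field is computed.
#' @param out_dir output directory, created if needed.
#' @return A list with `curve`, `breakpoints` (per statistic), `n_failed`,
#'   `paths`. An empty manifest yields empty results with a warning.
#' @export
run_pipeline <- function(manifest, config = analysis_config(),
                         background = NULL, flatfield_reference = NULL,
                         out_dir = tempfile("puncta_run_")) {
  stopifnot(inherits(config, "analysis_config"))
  set.seed(config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_file <- tempfile(); saveRDS(config, cfg_file)
  cfg_hash <- unname(tools::md5sum(cfg_file)); unlink(cfg_file)
  log_path <- file.path(out_dir, "run.log")
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                               append = TRUE)
  logline("config_hash=%s seed=%d threshold=%s", cfg_hash, config$seed,
          config$threshold_method)
  if (nrow(manifest) == 0) {
    warning("empty manifest: nothing to analyze")
    return(list(curve = NULL, breakpoints = NULL, n_failed = 0L,
                paths = list(out_dir = out_dir, log = log_path)))
  }
  load_img <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.character(x)) read_stack(x, pixel_size = config$pixel_size)[[1]]
    else as_raster(x, config$pixel_size)
  }
  bg <- load_img(background)
  field <- if (!is.null(flatfield_reference)) {
    ref <- load_img(flatfield_reference)
    ref_c <- if (is.null(bg)) ref else correct_image(ref, bg)
    compute_flatfield(ref_c)
  } else NULL
  entries <- list()
  n_failed <- 0L
  for (i in seq_len(nrow(manifest))) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      img <- read_stack(manifest$image_path[i],
                        pixel_size = config$pixel_size)[[1]]
      img <- correct_image(img, bg, field)
      if (config$rolling_ball_radius > 0)
        img <- rolling_ball(img, config$rolling_ball_radius)
      thr <- tryCatch(compute_threshold(img, config$threshold_method,
                                        config$histogram_bins),
                      error = function(e) NA_real_)
      cl <- if (is.na(thr)) NULL
            else segment_clusters(img, thr, config$min_area_px)
      if (!is.null(cl))
        write_csv_with_schema(cl$clusters,
                              file.path(out_dir, sprintf("clusters_%03d.csv", i)),
                              c(id = "integer", area_px = "px",
                                area_um2 = "um^2",
                                integrated_intensity = "counts",
                                mean_intensity = "counts",
                                centroid_x = "px (0-based)",
                                centroid_y = "px (0-based)",
                                touches_image_edge = "logical"))
      list(concentration = manifest$concentration_nM[i], image = img)
    }, error = function(e) {
      logline("entry=%d status=failed error=%s", i, conditionMessage(e))
      NULL
    })
    if (is.null(res)) n_failed <- n_failed + 1L
    else {
      entries[[length(entries) + 1L]] <- res
      logline("entry=%d conc_nM=%g status=ok elapsed_s=%.2f", i,
              res$concentration, proc.time()[["elapsed"]] - t0)
    }
  }
  curve <- NULL; breakpoints <- NULL
  if (length(entries) >= 4) {
    curve <- titration_statistics(entries, method = config$threshold_method,
                                  bins = config$histogram_bins,
                                  min_area_px = config$min_area_px)
    curve_path <- file.path(out_dir, "titration_curve.csv")
    write_csv_with_schema(as.data.frame(curve), curve_path,
                          c(concentration = "nM",
                            fractional_intensity = "fraction [0,1]",
                            variance = "counts^2", cv2 = "dimensionless",
                            n_clusters = "count", n_tiles = "count",
                            sd_fractional_intensity = "fraction"))
    breakpoints <- list(
      fractional_intensity = clustering_concentration(curve,
                                                      "fractional_intensity"),
      variance = clustering_concentration(curve, "variance"))
    jsonlite::write_json(lapply(breakpoints, unclass),
                         file.path(out_dir, "breakpoints.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  logline("done n_ok=%d n_failed=%d", length(entries), n_failed)
  list(curve = curve, breakpoints = breakpoints, n_failed = n_failed,
       paths = list(out_dir = out_dir, log = log_path))
}
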
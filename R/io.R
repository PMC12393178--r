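# ---- raster I/O ------------------------------------------------------------

#' Read a grayscale raster as detector counts
#'
#' TIFF rasters are read with their native integer values (8/16-bit).
#' PNG rasters are rescaled from \[0, 1\] to 16-bit counts (the common
#' factor cancels in the log ratio, so the absolute count scale of PNG
#' inputs is immaterial as long as both channels share it).
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @return A numeric matrix of counts.
#' @export
read_counts_raster <- function(path) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path, as.is = TRUE),
    png = round(png::readPNG(path) * 65535),
    stop("unsupported raster format: ", ext))
  if (length(dim(img)) == 3) {
    if (dim(img)[3] > 1 && !all(img[, , 1] == img[, , 2]))
      stop("non-grayscale raster: ", path)
    img <- img[, , 1]
  }
  storage.mode(img) <- "double"
  img
}

#' Write a counts raster as 16-bit grayscale TIFF
#'
#' Counts are rounded and clamped to \[0, 65535\]. Reading the file back
#' with [read_counts_raster()] reproduces the rounded counts exactly.
#'
#' @param counts Numeric matrix.
#' @param path Output path.
#' @export
write_counts_tiff <- function(counts, path) {
  m <- pmin(pmax(round(counts), 0), 65535)
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Write an MPOD map to disk
#'
#' The density raster is affine-encoded to \[0, 1\] and stored as a
#' two-channel 32-bit float TIFF (channel 1: encoded density, channel 2:
#' validity mask), with the encoding range, scale model, reference
#' geometry and center recorded in a JSON sidecar. Values survive the
#' round trip to 32-bit float precision (about 1e-7 AU relative), and
#' further write/read cycles are stable at that quantization level.
#'
#' @param map An `mpod_map`.
#' @param path Output TIFF path; the sidecar is `<path>.json`.
#' @return Invisibly, `c(tiff = path, json = sidecar)`.
#' @export
write_mpod_map <- function(map, path) {
  stopifnot(inherits(map, "mpod_map"))
  v <- map$density[map$valid]
  lo <- if (length(v)) min(v) else 0
  hi <- if (length(v)) max(v) else 1
  if (hi <= lo) hi <- lo + 1
  enc <- (map$density - lo) / (hi - lo)
  enc[!map$valid] <- 0
  arr <- array(0, dim = c(nrow(enc), ncol(enc), 2))
  arr[, , 1] <- enc
  arr[, , 2] <- as.numeric(map$valid)
  tiff::writeTIFF(arr, path, bits.per.sample = 32L, compression = "none")
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(encoding = list(lo = lo, hi = hi),
         scale = list(um_per_px = map$scale$um_per_px,
                      um_per_deg = map$scale$um_per_deg),
         center = map$center,
         reference_eccentricity_deg = map$reference_eccentricity_deg,
         annulus_halfwidth_deg = map$annulus_halfwidth_deg,
         reference_offset = map$reference_offset),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(tiff = path, json = sidecar))
}

#' Read an MPOD map written by [write_mpod_map()]
#'
#' @param path Path to the map TIFF (sidecar `<path>.json` must exist).
#' @return An `mpod_map`.
#' @export
read_mpod_map <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(sidecar))
    stop("map or sidecar missing: ", path)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  # libtiff flags the validity channel as an ExtraSample; benign
  arr <- suppressWarnings(tiff::readTIFF(path))
  stopifnot(length(dim(arr)) == 3, dim(arr)[3] == 2)
  valid <- arr[, , 2] > 0.5
  density <- arr[, , 1] * (meta$encoding$hi - meta$encoding$lo) +
    meta$encoding$lo
  density[!valid] <- NA_real_
  structure(
    list(density = density, valid = valid,
         scale = scale_model(meta$scale$um_per_px, meta$scale$um_per_deg),
         center = as.numeric(meta$center),
         reference_eccentricity_deg = meta$reference_eccentricity_deg,
         annulus_halfwidth_deg = meta$annulus_halfwidth_deg,
         reference_offset = meta$reference_offset),
    class = "mpod_map")
}

# ---- tabular I/O -----------------------------------------------------------

#' Write a data frame as full-precision TSV
#'
#' UTF-8, tab-delimited, header row, '.' decimal. Numeric columns are
#' serialized with 17 significant digits so that re-parsing reproduces the
#' in-memory doubles exactly.
#'
#' @param df A data frame.
#' @param path Output path.
#' @export
write_tsv_report <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV written by [write_tsv_report()]
#'
#' @param path Path to the TSV.
#' @return A data frame (numeric columns restored).
#' @export
read_tsv_report <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

# ---- manifests and configuration ------------------------------------------

read_structured <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = jsonlite::read_json(path, simplifyVector = FALSE),
    yaml = , yml = yaml::read_yaml(path),
    stop("unsupported manifest/config format: ", ext))
}

#' Read a case manifest
#'
#' A manifest lists one record per eye: `eye_id`, `blue` and `green`
#' raster paths, optional `um_per_px`/`um_per_deg` overrides, optional
#' `anatomical_center` and `manual_center` (each `[x, y]`), optional
#' `laterality` ("OD"/"OS"). JSON manifests hold a top-level array (or an
#' object with a `cases` array); YAML a top-level sequence.
#'
#' @param path Manifest path (`.json`, `.yaml`, `.yml`).
#' @return List of validated manifest records.
#' @export
read_manifest <- function(path) {
  raw <- read_structured(path)
  if (!is.null(raw$cases)) raw <- raw$cases
  if (length(raw) == 0) stop("empty manifest")
  ids <- vapply(raw, function(r) as.character(r$eye_id %||% ""), "")
  if (any(ids == "")) stop("manifest record without eye_id")
  if (anyDuplicated(ids))
    stop("duplicate eye_id in manifest: ", ids[duplicated(ids)][1])
  lapply(raw, function(r) {
    for (f in c("blue", "green"))
      if (is.null(r[[f]])) stop("manifest record ", r$eye_id,
                                ": missing '", f, "' path")
    r
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load an image pair from a manifest record
#'
#' @param record One record from [read_manifest()].
#' @param base_dir Directory against which relative raster paths are
#'   resolved.
#' @param default_scale Fallback [scale_model] when the record carries no
#'   override.
#' @return An [af_image_pair].
#' @export
read_image_pair <- function(record, base_dir = ".",
                            default_scale = scale_model()) {
  resolve <- function(p) if (file.exists(p)) p else file.path(base_dir, p)
  blue <- tryCatch(read_counts_raster(resolve(record$blue)),
                   error = function(e) stop("eye ", record$eye_id, ": ",
                                            conditionMessage(e)))
  green <- tryCatch(read_counts_raster(resolve(record$green)),
                    error = function(e) stop("eye ", record$eye_id, ": ",
                                             conditionMessage(e)))
  if (!all(dim(blue) == dim(green)))
    stop("eye ", record$eye_id, ": dimension mismatch between blue (",
         paste(dim(blue), collapse = "x"), ") and green (",
         paste(dim(green), collapse = "x"), ")")
  sc <- scale_model(record$um_per_px %||% default_scale$um_per_px,
                    record$um_per_deg %||% default_scale$um_per_deg)
  af_image_pair(
    blue = blue, green = green, scale = sc,
    anatomical_center = if (!is.null(record$anatomical_center))
      as.numeric(unlist(record$anatomical_center)),
    manual_center = if (!is.null(record$manual_center))
      as.numeric(unlist(record$manual_center)),
    laterality = record$laterality %||% NA_character_,
    eye_id = as.character(record$eye_id),
    meta = list(blue_path = record$blue, green_path = record$green))
}

#' Run configuration
#'
#' Collects every tunable of the pipeline in one validated object.
#'
#' @param ref_ecc_deg Reference eccentricity (degrees).
#' @param annulus_halfwidth_deg Reference annulus half-width (degrees).
#' @param center_method Primary centration method used for the final map
#'   and profiles: one of `"hillclimb"`, `"contour"`, `"centroid"`,
#'   `"max"`, `"fovea"`.
#' @param methods Centration methods to evaluate.
#' @param search_radius_deg Central-region radius for MAX/CENTROID.
#' @param smooth_sigma_deg Smoothing sigma for MAX/CONTOUR.
#' @param window_radius_deg HILLCLIMB window radius.
#' @param tol_px,max_iter HILLCLIMB convergence controls.
#' @param bin_width_deg Profile bin width.
#' @param max_ecc_deg Profile outer limit.
#' @param classifier A [classifier_config()].
#' @param seed Integer seed for any stochastic step.
#' @return Object of class `run_config`.
#' @export
run_config <- function(ref_ecc_deg = 9.0, annulus_halfwidth_deg = 0.25,
                       center_method = "hillclimb",
                       methods = c("max", "centroid", "contour",
                                   "hillclimb"),
                       search_radius_deg = 2, smooth_sigma_deg = 0.1,
                       window_radius_deg = 2, tol_px = 0.5, max_iter = 100,
                       bin_width_deg = 0.1, max_ecc_deg = 9,
                       classifier = classifier_config(), seed = 1L) {
  stopifnot(ref_ecc_deg > 0, annulus_halfwidth_deg > 0,
            center_method %in% c("hillclimb", "contour", "centroid",
                                 "max", "fovea", "manual"),
            all(methods %in% c("max", "centroid", "contour", "hillclimb",
                               "fovea", "manual")),
            search_radius_deg > 0, smooth_sigma_deg >= 0,
            window_radius_deg > 0, tol_px > 0, max_iter >= 1,
            bin_width_deg > 0, max_ecc_deg > 0,
            inherits(classifier, "classifier_config"))
  structure(list(ref_ecc_deg = ref_ecc_deg,
                 annulus_halfwidth_deg = annulus_halfwidth_deg,
                 center_method = center_method, methods = methods,
                 search_radius_deg = search_radius_deg,
                 smooth_sigma_deg = smooth_sigma_deg,
                 window_radius_deg = window_radius_deg,
                 tol_px = tol_px, max_iter = as.integer(max_iter),
                 bin_width_deg = bin_width_deg, max_ecc_deg = max_ecc_deg,
                 classifier = classifier, seed = as.integer(seed)),
            class = "run_config")
}

#' Load / save a run configuration
#'
#' YAML or JSON; loading a dumped configuration reproduces it exactly.
#'
#' @param path File path (`.yaml`, `.yml`, `.json`).
#' @return `load_run_config()`: a [run_config()]. `save_run_config()`:
#'   the path, invisibly.
#' @export
load_run_config <- function(path) {
  raw <- read_structured(path)
  cls <- raw$classifier
  raw$classifier <- NULL
  if (!is.null(cls) && !is.null(cls$ring_crest_window_deg))
    cls$ring_crest_window_deg <- as.numeric(unlist(cls$ring_crest_window_deg))
  args <- lapply(raw, function(x) if (is.list(x)) unlist(x) else x)
  args$classifier <- do.call(classifier_config, cls %||% list())
  do.call(run_config, args)
}

#' @rdname load_run_config
#' @param config A [run_config()].
#' @export
save_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$classifier <- unclass(x$classifier)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}
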
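#' Registered blue/green autofluorescence image pair
#'
#' Container for a pair of registered fundus autofluorescence rasters:
#' blue-excited (488 nm; attenuated by macular pigment) and green-excited
#' (514 nm; outside the pigment absorption band). Rasters are matrices of
#' detector counts indexed `[y + 1, x + 1]` (0-based coordinates, x
#' rightward, y downward).
#'
#' @param blue,green Numeric matrices of identical dimensions, counts >= 0.
#' @param scale A [scale_model].
#' @param anatomical_center Optional `c(x, y)`: an externally determined
#'   anatomical foveal center (e.g. from the rise of the external limiting
#'   membrane on OCT).
#' @param manual_center Optional `c(x, y)`: a manually graded center.
#' @param laterality `"OD"`, `"OS"` or `NA`.
#' @param eye_id Identifier used in reports.
#' @param meta Free-form provenance list.
#' @return An object of class `af_image_pair`.
#' @export
af_image_pair <- function(blue, green, scale = scale_model(),
                          anatomical_center = NULL, manual_center = NULL,
                          laterality = NA_character_, eye_id = "eye",
                          meta = list()) {
  stopifnot(is.matrix(blue), is.matrix(green))
  if (!all(dim(blue) == dim(green)))
    stop("dimension mismatch between blue and green rasters")
  if (min(blue, na.rm = TRUE) < 0 || min(green, na.rm = TRUE) < 0)
    stop("counts must be non-negative")
  structure(
    list(blue = blue, green = green, scale = as_scale_model(scale),
         anatomical_center = anatomical_center,
         manual_center = manual_center,
         laterality = laterality, eye_id = eye_id, meta = meta),
    class = "af_image_pair")
}

#' @export
print.af_image_pair <- function(x, ...) {
  cat(sprintf("af_image_pair '%s': %d x %d px, laterality %s\n",
              x$eye_id, ncol(x$blue), nrow(x$blue), x$laterality))
  invisible(x)
}

#' Raw per-pixel log10 intensity ratio
#'
#' `raw(p) = log10(G(p) / B(p))` wherever both channels are strictly
#' positive; other pixels are marked invalid. This is the macular pigment
#' optical density before anchoring to the peripheral reference.
#'
#' @param pair An [af_image_pair].
#' @return List with `raw` (matrix, `NA` where invalid) and `valid`
#'   (logical matrix).
#' @export
compute_raw_logratio <- function(pair) {
  stopifnot(inherits(pair, "af_image_pair"))
  valid <- is.finite(pair$green) & is.finite(pair$blue) &
    pair$green > 0 & pair$blue > 0
  if (!any(valid)) stop("no measurable pixels")
  raw <- matrix(NA_real_, nrow(pair$blue), ncol(pair$blue))
  raw[valid] <- log10(pair$green[valid] / pair$blue[valid])
  list(raw = raw, valid = valid)
}

#' Anchor a raw log-ratio raster to the peripheral reference annulus
#'
#' Macular pigment is assumed absent at 9 degrees eccentricity, so the mean
#' raw log ratio over an annulus at the reference eccentricity is
#' subtracted from the whole raster. An annulus mean (rather than a single
#' point) is used for noise robustness.
#'
#' @param raw Raw log-ratio matrix (`NA` = invalid), e.g. from
#'   [compute_raw_logratio()].
#' @param valid Logical validity matrix.
#' @param center Center `c(x, y)` or [center_estimate] from which
#'   eccentricity is measured.
#' @param scale A [scale_model].
#' @param ref_ecc_deg Reference eccentricity (degrees), default 9.
#' @param annulus_halfwidth_deg Annulus half-width (degrees), default 0.25.
#' @return An object of class `mpod_map`: fields `density` (AU), `valid`,
#'   `scale`, `center` (the center used), `reference_eccentricity_deg`,
#'   `annulus_halfwidth_deg`, `reference_offset` (AU subtracted).
#' @export
normalize_to_reference <- function(raw, valid, center,
                                   scale = scale_model(),
                                   ref_ecc_deg = 9.0,
                                   annulus_halfwidth_deg = 0.25) {
  stopifnot(is.matrix(raw), is.matrix(valid), all(dim(raw) == dim(valid)))
  ecc <- eccentricity_map(dim(raw), center, scale)
  in_ann <- valid & ecc >= ref_ecc_deg - annulus_halfwidth_deg &
    ecc <= ref_ecc_deg + annulus_halfwidth_deg
  if (sum(in_ann) < 100)
    stop("reference annulus unavailable: fewer than 100 valid pixels at ",
         ref_ecc_deg, " degrees")
  offset <- mean(raw[in_ann])
  density <- raw - offset
  structure(
    list(density = density, valid = valid, scale = as_scale_model(scale),
         center = center_xy(center),
         reference_eccentricity_deg = ref_ecc_deg,
         annulus_halfwidth_deg = annulus_halfwidth_deg,
         reference_offset = offset),
    class = "mpod_map")
}

#' Compute a reference-anchored MPOD map from an image pair
#'
#' Convenience wrapper: raw log ratio, then reference normalization. When
#' no center is given the image center is used for a provisional map; the
#' usual workflow re-normalizes at the converged center (see
#' [renormalize_map()] and [process_eye()]).
#'
#' @param pair An [af_image_pair].
#' @param center Optional center; defaults to the image center.
#' @inheritParams normalize_to_reference
#' @return An `mpod_map`.
#' @export
compute_mpod <- function(pair, center = NULL, ref_ecc_deg = 9.0,
                         annulus_halfwidth_deg = 0.25) {
  lr <- compute_raw_logratio(pair)
  if (is.null(center)) center <- image_center(pair$blue)
  normalize_to_reference(lr$raw, lr$valid, center, pair$scale,
                         ref_ecc_deg, annulus_halfwidth_deg)
}

#' Re-anchor an existing map at a new center
#'
#' Restores the original raw raster (density + recorded offset) and
#' normalizes again with the annulus placed around `center`. Applying it
#' twice with the same center is a fixed point.
#'
#' @param map An `mpod_map`.
#' @param center The new center.
#' @return A new `mpod_map`.
#' @export
renormalize_map <- function(map, center) {
  stopifnot(inherits(map, "mpod_map"))
  raw <- map$density + map$reference_offset
  raw[!map$valid] <- NA_real_
  normalize_to_reference(raw, map$valid, center, map$scale,
                         map$reference_eccentricity_deg,
                         map$annulus_halfwidth_deg)
}

#' @export
print.mpod_map <- function(x, ...) {
  v <- x$density[x$valid]
  cat(sprintf(
    "mpod_map: %d x %d px, %.1f%% valid, range [%.3f, %.3f] AU\n",
    ncol(x$density), nrow(x$density), 100 * mean(x$valid),
    min(v), max(v)))
  cat(sprintf("  reference: %.2f deg +/- %.2f deg, offset %.6f AU\n",
              x$reference_eccentricity_deg, x$annulus_halfwidth_deg,
              x$reference_offset))
  invisible(x)
}

#' Pseudocolor rendering of an MPOD map
#'
#' Fixed monotone lookup from `[0, display_max]` AU into a 256-entry
#' blue-cyan-green-yellow-red ramp; values are clamped to the range and
#' invalid pixels are black.
#'
#' @param map An `mpod_map`.
#' @param display_max Upper end of the display range (AU), default 0.8.
#' @return A `height x width x 3` array of RGB values in \[0, 1\].
#' @export
render_pseudocolor <- function(map, display_max = 0.8) {
  stopifnot(inherits(map, "mpod_map"), display_max > 0)
  ramp <- grDevices::colorRamp(
    c("#00008B", "#0000FF", "#00FFFF", "#00FF00", "#FFFF00", "#FF0000"))
  idx <- pmin(pmax(map$density / display_max, 0), 1)
  idx[!map$valid] <- 0
  rgbv <- ramp(as.vector(idx)) / 255
  rgbv[as.vector(!map$valid), ] <- 0
  h <- nrow(map$density); w <- ncol(map$density)
  array(rgbv, dim = c(h, w, 3))
}
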
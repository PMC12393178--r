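#' Pixel/visual-angle scale model
#'
#' Converts between pixels, micrometers on the retina, and degrees of visual
#' angle. The defaults correspond to a 30-degree-field scanning laser
#' ophthalmoscope raster: 11.3 um per pixel on the retina and 288 um per
#' degree of visual angle, giving about 25.49 px per degree.
#'
#' @param um_per_px Micrometers per pixel (> 0).
#' @param um_per_deg Micrometers per degree of visual angle (> 0).
#' @return An object of class `scale_model` with fields `um_per_px`,
#'   `um_per_deg` and the derived `deg_per_px = um_per_px / um_per_deg`.
#' @examples
#' sc <- scale_model()
#' px_to_deg(25.486, sc)   # ~1 degree
#' px_to_um(5, sc)         # 56.5 um
#' @export
scale_model <- function(um_per_px = 11.3, um_per_deg = 288) {
  stopifnot(is.numeric(um_per_px), length(um_per_px) == 1L, um_per_px > 0,
            is.numeric(um_per_deg), length(um_per_deg) == 1L, um_per_deg > 0)
  structure(
    list(um_per_px = um_per_px,
         um_per_deg = um_per_deg,
         deg_per_px = um_per_px / um_per_deg),
    class = "scale_model")
}

as_scale_model <- function(x) {
  if (inherits(x, "scale_model")) return(x)
  if (is.list(x) && all(c("um_per_px", "um_per_deg") %in% names(x)))
    return(scale_model(x$um_per_px, x$um_per_deg))
  stop("cannot interpret 'scale' as a scale_model")
}

#' @rdname scale_model
#' @param px,deg,um Quantities to convert.
#' @param scale A `scale_model`.
#' @export
px_to_deg <- function(px, scale = scale_model()) px * scale$deg_per_px

#' @rdname scale_model
#' @export
deg_to_px <- function(deg, scale = scale_model()) deg / scale$deg_per_px

#' @rdname scale_model
#' @export
px_to_um <- function(px, scale = scale_model()) px * scale$um_per_px

#' @rdname scale_model
#' @export
um_to_px <- function(um, scale = scale_model()) um / scale$um_per_px

#' @export
print.scale_model <- function(x, ...) {
  cat(sprintf("scale_model: %.3f um/px, %.1f um/deg (%.5f deg/px)\n",
              x$um_per_px, x$um_per_deg, x$deg_per_px))
  invisible(x)
}

# Image-coordinate conventions used throughout the package:
# 0-based, pixel centers at integers, x rightward (columns), y downward
# (rows). A raster stored as an R matrix m has m[y + 1, x + 1].

#' Geometric center of a raster
#'
#' The subpixel point ((w-1)/2, (h-1)/2) in 0-based pixel coordinates.
#'
#' @param shape Integer vector `c(height, width)` or a matrix.
#' @return Numeric `c(x, y)`.
#' @export
image_center <- function(shape) {
  if (is.matrix(shape)) shape <- dim(shape)
  c(x = (shape[2] - 1) / 2, y = (shape[1] - 1) / 2)
}

#' Per-pixel eccentricity raster
#'
#' Distance of every pixel from a (subpixel) center, in degrees of visual
#' angle.
#'
#' @param shape `c(height, width)` or a matrix.
#' @param center Numeric `c(x, y)` in 0-based pixel coordinates, or a
#'   [center_estimate].
#' @param scale A [scale_model].
#' @return A `height x width` matrix of eccentricities (degrees).
#' @export
eccentricity_map <- function(shape, center, scale = scale_model()) {
  if (is.matrix(shape)) shape <- dim(shape)
  center <- center_xy(center)
  h <- shape[1]; w <- shape[2]
  if (center[1] < 0 || center[1] > w - 1 || center[2] < 0 || center[2] > h - 1)
    stop("center out of bounds")
  dx2 <- ((0:(w - 1)) - center[1])^2
  dy2 <- ((0:(h - 1)) - center[2])^2
  sqrt(outer(dy2, dx2, "+")) * scale$deg_per_px
}

# extract c(x, y) from a center_estimate or bare numeric
center_xy <- function(center) {
  if (inherits(center, "center_estimate")) return(c(center$x, center$y))
  stopifnot(is.numeric(center), length(center) == 2L)
  as.numeric(center)
}
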
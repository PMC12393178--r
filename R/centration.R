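#' Center estimate
#'
#' A subpixel foveal-center location together with the method that produced
#' it. Methods: `FOVEA` (externally supplied anatomical center), `MAX`
#' (smoothed maximum), `CENTROID` (weighted average), `CONTOUR`
#' (half-maximum iso-contour convex hull), `HILLCLIMB` (iterated windowed
#' centroid), `MANUAL` (human grading).
#'
#' @param x,y Subpixel 0-based coordinates.
#' @param method Method label.
#' @param iterations Iteration count (HILLCLIMB), else 0.
#' @param degenerate Logical: the method hit a degenerate input (e.g. zero
#'   weight) and fell back.
#' @return Object of class `center_estimate`.
#' @export
center_estimate <- function(x, y,
                            method = c("MANUAL", "FOVEA", "MAX", "CENTROID",
                                       "CONTOUR", "HILLCLIMB"),
                            iterations = 0L, degenerate = FALSE) {
  method <- match.arg(method)
  stopifnot(is.finite(x), is.finite(y), iterations >= 0)
  structure(list(x = as.numeric(x), y = as.numeric(y), method = method,
                 iterations = as.integer(iterations),
                 degenerate = isTRUE(degenerate)),
            class = "center_estimate")
}

#' @export
print.center_estimate <- function(x, ...) {
  cat(sprintf("center_estimate [%s]: (%.3f, %.3f)%s%s\n", x$method, x$x, x$y,
              if (x$iterations > 0) sprintf(", %d iterations", x$iterations)
              else "",
              if (x$degenerate) ", DEGENERATE" else ""))
  invisible(x)
}

check_in_bounds <- function(x, y, shape) {
  if (x < 0 || x > shape[2] - 1 || y < 0 || y > shape[1] - 1)
    stop("center out of bounds")
  invisible(TRUE)
}

#' FOVEA centration: pass through the anatomical center
#'
#' Uses the externally determined anatomical foveal center carried in the
#' image pair's manifest (typically the inward rise of the external
#' limiting membrane on OCT).
#'
#' @param pair An [af_image_pair].
#' @return A [center_estimate] with method `FOVEA`.
#' @export
center_fovea <- function(pair) {
  stopifnot(inherits(pair, "af_image_pair"))
  ac <- pair$anatomical_center
  if (is.null(ac)) stop("no anatomical center supplied")
  check_in_bounds(ac[1], ac[2], dim(pair$blue))
  center_estimate(ac[1], ac[2], "FOVEA")
}

# disc mask around a point, as index matrix restricted to a bbox crop;
# returns list(rows, cols, mask) with mask a logical matrix over the crop
disc_crop <- function(shape, center, radius_px) {
  cx <- center[1]; cy <- center[2]
  x0 <- max(0, floor(cx - radius_px)); x1 <- min(shape[2] - 1, ceiling(cx + radius_px))
  y0 <- max(0, floor(cy - radius_px)); y1 <- min(shape[1] - 1, ceiling(cy + radius_px))
  xs <- x0:x1; ys <- y0:y1
  m <- outer((ys - cy)^2, (xs - cx)^2, "+") <= radius_px^2
  list(xs = xs, ys = ys, rows = ys + 1L, cols = xs + 1L, mask = m)
}

#' MAX centration: maximum of the smoothed map in the central region
#'
#' Location of the maximum of a Gaussian-smoothed MPOD map within a disc
#' around the image center. Ties are broken by smallest y, then smallest x.
#'
#' @param map An `mpod_map`.
#' @param search_radius_deg Radius of the central search disc (degrees).
#' @param smooth_sigma_deg Gaussian smoothing sigma (degrees); 0 disables
#'   smoothing.
#' @param region_center Optional `c(x, y)` overriding the search-disc
#'   center (defaults to the image center).
#' @return A [center_estimate] with method `MAX`.
#' @export
center_max <- function(map, search_radius_deg = 2, smooth_sigma_deg = 0.1,
                       region_center = NULL) {
  stopifnot(inherits(map, "mpod_map"))
  if (is.null(region_center)) region_center <- image_center(map$density)
  r_px <- deg_to_px(search_radius_deg, map$scale)
  cr <- disc_crop(dim(map$density), region_center, r_px)
  # smooth a crop slightly larger than the disc so edge pixels see full mass
  sig_px <- deg_to_px(smooth_sigma_deg, map$scale)
  pad <- ceiling(4 * max(sig_px, 1))
  big <- disc_crop(dim(map$density), region_center, r_px + pad)
  s_big <- smooth_masked(map$density[big$rows, big$cols, drop = FALSE],
                         map$valid[big$rows, big$cols, drop = FALSE], sig_px)
  ri <- match(cr$rows, big$rows); ci <- match(cr$cols, big$cols)
  s <- s_big[ri, ci, drop = FALSE]
  s[!cr$mask] <- NA_real_
  if (all(is.na(s))) stop("no valid pixels in the search region")
  mx <- max(s, na.rm = TRUE)
  hit <- which(s == mx, arr.ind = TRUE)
  ys <- cr$ys[hit[, 1]]; xs <- cr$xs[hit[, 2]]
  ord <- order(ys, xs)[1]
  center_estimate(xs[ord], ys[ord], "MAX")
}

# baseline-subtracted non-negative weights used by CENTROID and HILLCLIMB
centroid_weights <- function(vals, baseline_quantile = 0.10) {
  baseline <- stats::quantile(vals, baseline_quantile, na.rm = TRUE,
                              names = FALSE)
  pmax(vals - baseline, 0)
}

#' CENTROID centration: weighted average in the central region
#'
#' Intensity-weighted mean position over a disc around the image center.
#' Weights are the map values minus the region's 10th percentile, floored
#' at zero, so they stay non-negative on noisy reference-anchored maps.
#'
#' @inheritParams center_max
#' @param baseline_quantile Quantile used as the weight baseline.
#' @return A [center_estimate] with method `CENTROID`; `degenerate` is set
#'   (and the region center returned) when total weight is zero.
#' @export
center_centroid <- function(map, search_radius_deg = 2, region_center = NULL,
                            baseline_quantile = 0.10) {
  stopifnot(inherits(map, "mpod_map"))
  if (is.null(region_center)) region_center <- image_center(map$density)
  r_px <- deg_to_px(search_radius_deg, map$scale)
  cr <- disc_crop(dim(map$density), region_center, r_px)
  v <- map$density[cr$rows, cr$cols, drop = FALSE]
  ok <- map$valid[cr$rows, cr$cols, drop = FALSE] & cr$mask
  if (!any(ok)) stop("no valid pixels in the search region")
  w <- matrix(0, nrow(v), ncol(v))
  w[ok] <- centroid_weights(v[ok], baseline_quantile)
  tot <- sum(w)
  if (tot <= 0)
    return(center_estimate(region_center[1], region_center[2], "CENTROID",
                           degenerate = TRUE))
  cx <- sum(w * matrix(cr$xs, nrow(v), ncol(v), byrow = TRUE)) / tot
  cy <- sum(w * matrix(cr$ys, nrow(v), ncol(v))) / tot
  center_estimate(cx, cy, "CENTROID")
}

# even-odd (crossing-number) point-in-polygon; vertices as x/y vectors
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if (((vy[i] > py) != (vy[j] > py)) &&
        (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]))
      inside <- !inside
    j <- i
  }
  inside
}

# vectorized membership test for a convex polygon (hull), vertices in
# counterclockwise order in the (x rightward, y downward) frame
in_convex_hull <- function(px, py, hx, hy) {
  # orient counterclockwise by signed area
  area <- sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy) / 2
  if (area < 0) { hx <- rev(hx); hy <- rev(hy) }
  inside <- rep(TRUE, length(px))
  n <- length(hx)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cross <- (hx[j] - hx[i]) * (py - hy[i]) - (hy[j] - hy[i]) * (px - hx[i])
    inside <- inside & cross >= -1e-9
  }
  inside
}

#' CONTOUR centration: half-maximum iso-contour convex hull
#'
#' Extracts the subpixel iso-contour of the smoothed map at the level
#' halfway between the reference baseline (zero after normalization) and
#' the smoothed maximum, keeps the closed contour component enclosing the
#' global maximum, takes the convex hull of its vertices, and returns the
#' intensity-weighted mean position of the valid pixels inside the hull.
#' The convex hull deliberately bridges the central hole of annular
#' (dip-type) distributions.
#'
#' @param map An `mpod_map`.
#' @param smooth_sigma_deg Gaussian smoothing sigma (degrees).
#' @param weighting `"intensity"` (map values floored at 0) or `"area"`
#'   (unweighted).
#' @param crop_radius_deg Radius of the region around the image center in
#'   which the maximum and its half-maximum contour are sought (the
#'   macular distribution; keeps the contour extraction cheap). `Inf`
#'   uses the whole raster.
#' @return A [center_estimate] with method `CONTOUR`.
#' @export
center_contour <- function(map, smooth_sigma_deg = 0.1,
                           weighting = c("intensity", "area"),
                           crop_radius_deg = 3.5) {
  stopifnot(inherits(map, "mpod_map"))
  weighting <- match.arg(weighting)
  sig_px <- deg_to_px(smooth_sigma_deg, map$scale)
  shape <- dim(map$density)
  r_px <- if (is.finite(crop_radius_deg))
    deg_to_px(crop_radius_deg, map$scale) else max(shape)
  cr <- disc_crop(shape, image_center(shape), r_px)
  dens <- map$density[cr$rows, cr$cols, drop = FALSE]
  vld <- map$valid[cr$rows, cr$cols, drop = FALSE]
  s <- smooth_masked(dens, vld, sig_px)
  # baseline: mean over the reference annulus (zero by construction)
  ecc <- eccentricity_map(shape, map$center, map$scale)
  ann <- map$valid & abs(ecc - map$reference_eccentricity_deg) <=
    map$annulus_halfwidth_deg
  baseline <- if (any(ann)) mean(map$density[ann], na.rm = TRUE) else 0
  smax <- max(s, na.rm = TRUE)
  if (!(smax > baseline + 1e-12) || smax - min(s, na.rm = TRUE) < 1e-12)
    stop("flat map: no half-maximum level")
  hit <- which(s == smax, arr.ind = TRUE)
  ord <- order(hit[, 1], hit[, 2])[1]
  mx_x <- cr$xs[hit[ord, 2]]; mx_y <- cr$ys[hit[ord, 1]]
  L <- baseline + 0.5 * (smax - baseline)
  z <- s
  z[is.na(z)] <- baseline
  h <- nrow(map$density); w <- ncol(map$density)
  # contourLines wants z[i, j] at x[i], y[j]
  cl <- grDevices::contourLines(x = cr$xs, y = cr$ys, z = t(z), levels = L)
  if (length(cl) == 0) stop("flat map: no half-maximum level")
  chosen <- NULL
  for (cc in cl) {
    closed <- abs(cc$x[1] - cc$x[length(cc$x)]) < 1e-8 &&
      abs(cc$y[1] - cc$y[length(cc$y)]) < 1e-8
    if (!closed) next
    if (point_in_polygon(mx_x, mx_y, cc$x, cc$y)) { chosen <- cc; break }
  }
  if (is.null(chosen)) stop("contour open at boundary")
  hull_idx <- grDevices::chull(chosen$x, chosen$y)
  hx <- chosen$x[hull_idx]; hy <- chosen$y[hull_idx]
  x0 <- max(0, floor(min(hx))); x1 <- min(w - 1, ceiling(max(hx)))
  y0 <- max(0, floor(min(hy))); y1 <- min(h - 1, ceiling(max(hy)))
  xs <- x0:x1; ys <- y0:y1
  gx <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  gy <- matrix(ys, length(ys), length(xs))
  inside <- in_convex_hull(as.vector(gx), as.vector(gy), hx, hy)
  ok <- inside & as.vector(map$valid[ys + 1, xs + 1, drop = FALSE])
  if (!any(ok)) stop("contour hull contains no valid pixels")
  wgt <- if (weighting == "intensity") {
    pmax(as.vector(map$density[ys + 1, xs + 1, drop = FALSE])[ok], 0)
  } else rep(1, sum(ok))
  if (sum(wgt) <= 0) wgt <- rep(1, sum(ok))
  center_estimate(sum(wgt * as.vector(gx)[ok]) / sum(wgt),
                  sum(wgt * as.vector(gy)[ok]) / sum(wgt), "CONTOUR")
}

#' HILLCLIMB centration: iterated windowed centroid
#'
#' Starting from an initial guess (the image center by default), repeatedly
#' replaces the current center by the intensity-weighted centroid of a disc
#' window around it (weights as in [center_centroid()]), until the step
#' falls below `tol_px` or `max_iter` is reached. A window with zero weight
#' stops the iteration with `degenerate = TRUE` and the center unchanged.
#'
#' The window must be large enough to enclose the whole parafoveal
#' distribution: a window whose radius is close to the crest radius of an
#' annular (ring/dip) distribution has spurious off-center fixed points.
#' The default of 2 degrees (the same central region used by
#' [center_max()] and [center_centroid()]) covers the annulus in all four
#' canonical patterns.
#'
#' @param map An `mpod_map`.
#' @param init Initial [center_estimate] or `c(x, y)`; default image
#'   center.
#' @param window_radius_deg Window radius (degrees), default 2.
#' @param tol_px Convergence tolerance on the step (pixels), default 0.5.
#' @param max_iter Maximum number of iterations, default 100.
#' @param baseline_quantile Quantile used as the weight baseline.
#' @return A [center_estimate] with method `HILLCLIMB` and the iteration
#'   count.
#' @export
center_hillclimb <- function(map, init = NULL, window_radius_deg = 2,
                             tol_px = 0.5, max_iter = 100,
                             baseline_quantile = 0.10) {
  stopifnot(inherits(map, "mpod_map"))
  if (is.null(init)) init <- image_center(map$density)
  cur <- center_xy(init)
  check_in_bounds(cur[1], cur[2], dim(map$density))
  r_px <- deg_to_px(window_radius_deg, map$scale)
  degenerate <- FALSE
  iter <- 0L
  shape <- dim(map$density)
  for (i in seq_len(max_iter)) {
    iter <- i
    cr <- disc_crop(shape, cur, r_px)
    v <- map$density[cr$rows, cr$cols, drop = FALSE]
    ok <- map$valid[cr$rows, cr$cols, drop = FALSE] & cr$mask
    if (!any(ok)) { degenerate <- TRUE; break }
    w <- matrix(0, nrow(v), ncol(v))
    w[ok] <- centroid_weights(v[ok], baseline_quantile)
    tot <- sum(w)
    if (tot <= 0) { degenerate <- TRUE; break }
    nx <- sum(w * matrix(cr$xs, nrow(v), ncol(v), byrow = TRUE)) / tot
    ny <- sum(w * matrix(cr$ys, nrow(v), ncol(v))) / tot
    step <- sqrt((nx - cur[1])^2 + (ny - cur[2])^2)
    cur <- c(min(max(nx, 0), shape[2] - 1), min(max(ny, 0), shape[1] - 1))
    if (step < tol_px) break
  }
  center_estimate(cur[1], cur[2], "HILLCLIMB", iterations = iter,
                  degenerate = degenerate)
}

#' 95 percent prediction ellipse of 2-D deviations
#'
#' Ellipse expected to contain a given fraction of deviations, from the
#' sample mean and covariance of `(dx, dy)` scaled by the chi-square
#' (2 df) quantile (5.991 at the 0.95 level).
#'
#' @param dx,dy Numeric deviation vectors (equal length >= 2).
#' @param level Coverage level, default 0.95.
#' @return List: `center`, `cov`, `semi_axes` (major, minor), `angle_deg`
#'   (major-axis angle from +x, counterclockwise in the x-right/y-down
#'   frame), `level`.
#' @export
prediction_ellipse <- function(dx, dy, level = 0.95) {
  stopifnot(length(dx) == length(dy), length(dx) >= 2)
  d <- cbind(dx, dy)
  S <- stats::cov(d)
  e <- eigen(S, symmetric = TRUE)
  q <- stats::qchisq(level, df = 2)
  list(center = colMeans(d), cov = S,
       semi_axes = sqrt(pmax(e$values, 0) * q),
       angle_deg = atan2(e$vectors[2, 1], e$vectors[1, 1]) * 180 / pi,
       level = level)
}

#' Membership in a prediction ellipse
#'
#' @param ellipse Result of [prediction_ellipse()].
#' @param dx,dy Points to test.
#' @return Logical vector.
#' @export
in_prediction_ellipse <- function(ellipse, dx, dy) {
  d <- cbind(dx, dy)
  md <- stats::mahalanobis(d, ellipse$center, ellipse$cov)
  md <= stats::qchisq(ellipse$level, df = 2)
}

#' Compare center estimates against a reference centration
#'
#' Computes, per method, the Euclidean distances from each eye's estimate
#' to its reference center (in px and um), summary statistics, and the
#' 95 percent prediction ellipse of the `(dx, dy)` deviations.
#'
#' @param estimates Data frame with columns `eye_id`, `method`, `x`, `y`
#'   (0-based px).
#' @param reference Data frame with columns `eye_id`, `x`, `y`: the
#'   reference center per eye.
#' @param scale A [scale_model] (used for the um conversion).
#' @return List of class `centration_report`: `per_eye` (adds `dx`, `dy`,
#'   `dist_px`, `dist_um`), `summary` (per method: n, min/mean/max/sd in px
#'   and um; `NA` SD when n = 1), `ellipses` (named list, `NULL` when
#'   n < 2).
#' @export
compare_centers <- function(estimates, reference, scale = scale_model()) {
  stopifnot(is.data.frame(estimates),
            all(c("eye_id", "method", "x", "y") %in% names(estimates)),
            is.data.frame(reference),
            all(c("eye_id", "x", "y") %in% names(reference)))
  if (nrow(estimates) < 1) stop("no estimates to compare")
  scale <- as_scale_model(scale)
  i <- match(estimates$eye_id, reference$eye_id)
  if (anyNA(i)) stop("reference center missing for some eye_id")
  per <- estimates
  per$dx <- per$x - reference$x[i]
  per$dy <- per$y - reference$y[i]
  per$dist_px <- sqrt(per$dx^2 + per$dy^2)
  per$dist_um <- px_to_um(per$dist_px, scale)
  methods <- unique(per$method)
  summ <- do.call(rbind, lapply(methods, function(m) {
    d <- per$dist_px[per$method == m]
    data.frame(method = m, n = length(d),
               min_px = min(d), mean_px = mean(d), max_px = max(d),
               sd_px = if (length(d) > 1) stats::sd(d) else NA_real_,
               min_um = px_to_um(min(d), scale),
               mean_um = px_to_um(mean(d), scale),
               max_um = px_to_um(max(d), scale),
               sd_um = if (length(d) > 1) px_to_um(stats::sd(d), scale)
                       else NA_real_)
  }))
  ell <- stats::setNames(lapply(methods, function(m) {
    sub <- per[per$method == m, ]
    if (nrow(sub) < 2) return(NULL)
    prediction_ellipse(sub$dx, sub$dy)
  }), methods)
  structure(list(per_eye = per, summary = summ, ellipses = ell,
                 scale = scale),
            class = "centration_report")
}

#' @export
print.centration_report <- function(x, ...) {
  cat("centration_report:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
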
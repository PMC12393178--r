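# Independent brute-force oracles and small fixture builders. Everything
# here is deliberately written as plain loops / direct formulas, separate
# from the package's vectorized implementations.

# build an mpod_map object directly (unit-test fixture; bypasses the
# reference-annulus machinery for small rasters)
make_map <- function(density, valid = NULL, deg_per_px = 0.1,
                     center = NULL, ref_ecc_deg = 9,
                     annulus_halfwidth_deg = 0.25, reference_offset = 0) {
  if (is.null(valid)) valid <- matrix(TRUE, nrow(density), ncol(density))
  density[!valid] <- NA_real_
  if (is.null(center)) center <- image_center(density)
  sc <- scale_model(um_per_px = deg_per_px * 288, um_per_deg = 288)
  structure(list(density = density, valid = valid, scale = sc,
                 center = as.numeric(center),
                 reference_eccentricity_deg = ref_ecc_deg,
                 annulus_halfwidth_deg = annulus_halfwidth_deg,
                 reference_offset = reference_offset),
            class = "mpod_map")
}

# random smooth-bump raster for the centration equivalence checks
random_bump_map <- function(seed, n = 64, deg_per_px = 0.1) {
  set.seed(seed)
  cx <- runif(1, n / 2 - 6, n / 2 + 6)
  cy <- runif(1, n / 2 - 6, n / 2 + 6)
  sig <- runif(1, 4, 8)
  amp <- runif(1, 0.3, 0.8)
  xs <- 0:(n - 1)
  d2 <- outer((xs - cy)^2, (xs - cx)^2, "+")
  dens <- amp * exp(-d2 / (2 * sig^2)) +
    matrix(rnorm(n * n, sd = 0.01), n, n)
  make_map(dens, deg_per_px = deg_per_px)
}

# --- brute-force centration ------------------------------------------------

# naive O(n^2 k^2) validity-normalized Gaussian convolution: per pixel,
# a direct weighted sum over its (2r+1)^2 neighborhood
bf_smooth <- function(density, valid, sigma_px) {
  if (sigma_px <= 0) {
    out <- density
    out[!valid] <- NA_real_
    return(out)
  }
  r <- max(1L, ceiling(4 * sigma_px))
  h <- nrow(density); w <- ncol(density)
  g <- exp(-((-r):r)^2 / (2 * sigma_px^2))
  out <- matrix(NA_real_, h, w)
  for (i in 1:h) for (j in 1:w) {
    iis <- max(1, i - r):min(h, i + r)
    jjs <- max(1, j - r):min(w, j + r)
    K <- outer(g[iis - i + r + 1], g[jjs - j + r + 1])
    vv <- valid[iis, jjs, drop = FALSE]
    den <- sum(K[vv])
    if (den > 1e-12)
      out[i, j] <- sum(K[vv] * density[iis, jjs, drop = FALSE][vv]) / den
  }
  out
}

bf_center_max <- function(map, search_radius_deg = 2,
                          smooth_sigma_deg = 0.1) {
  sig_px <- search_px <- NULL
  sig_px <- smooth_sigma_deg / map$scale$deg_per_px
  search_px <- search_radius_deg / map$scale$deg_per_px
  s <- bf_smooth(map$density, map$valid, sig_px)
  ctr <- image_center(map$density)
  best <- -Inf; bx <- NA; by <- NA
  h <- nrow(s); w <- ncol(s)
  for (y in 0:(h - 1)) for (x in 0:(w - 1)) {
    if ((x - ctr[1])^2 + (y - ctr[2])^2 > search_px^2) next
    v <- s[y + 1, x + 1]
    if (is.na(v)) next
    if (v > best) { best <- v; bx <- x; by <- y }
    # tie-break handled by scan order (y then x ascending)
  }
  c(bx, by)
}

bf_center_centroid <- function(map, search_radius_deg = 2) {
  search_px <- search_radius_deg / map$scale$deg_per_px
  ctr <- image_center(map$density)
  h <- nrow(map$density); w <- ncol(map$density)
  vals <- c()
  for (y in 0:(h - 1)) for (x in 0:(w - 1)) {
    if ((x - ctr[1])^2 + (y - ctr[2])^2 > search_px^2) next
    if (!map$valid[y + 1, x + 1]) next
    vals <- c(vals, map$density[y + 1, x + 1])
  }
  base <- stats::quantile(vals, 0.10, names = FALSE)
  sx <- 0; sy <- 0; sw <- 0
  for (y in 0:(h - 1)) for (x in 0:(w - 1)) {
    if ((x - ctr[1])^2 + (y - ctr[2])^2 > search_px^2) next
    if (!map$valid[y + 1, x + 1]) next
    wgt <- max(map$density[y + 1, x + 1] - base, 0)
    sx <- sx + wgt * x; sy <- sy + wgt * y; sw <- sw + wgt
  }
  if (sw <= 0) return(unname(ctr))
  c(sx / sw, sy / sw)
}

bf_center_hillclimb <- function(map, window_radius_deg = 2, tol_px = 0.5,
                                max_iter = 100) {
  r_px <- window_radius_deg / map$scale$deg_per_px
  cur <- unname(image_center(map$density))
  h <- nrow(map$density); w <- ncol(map$density)
  for (it in 1:max_iter) {
    vals <- c()
    for (y in 0:(h - 1)) for (x in 0:(w - 1)) {
      if ((x - cur[1])^2 + (y - cur[2])^2 > r_px^2) next
      if (!map$valid[y + 1, x + 1]) next
      vals <- c(vals, map$density[y + 1, x + 1])
    }
    if (length(vals) == 0) break
    base <- stats::quantile(vals, 0.10, names = FALSE)
    sx <- 0; sy <- 0; sw <- 0
    for (y in 0:(h - 1)) for (x in 0:(w - 1)) {
      if ((x - cur[1])^2 + (y - cur[2])^2 > r_px^2) next
      if (!map$valid[y + 1, x + 1]) next
      wgt <- max(map$density[y + 1, x + 1] - base, 0)
      sx <- sx + wgt * x; sy <- sy + wgt * y; sw <- sw + wgt
    }
    if (sw <= 0) break
    nx <- min(max(sx / sw, 0), w - 1); ny <- min(max(sy / sw, 0), h - 1)
    step <- sqrt((nx - cur[1])^2 + (ny - cur[2])^2)
    cur <- c(nx, ny)
    if (step < tol_px) break
  }
  cur
}

# CONTOUR oracle: same geometric definition (half-maximum contour around
# the global maximum, convex hull), but membership and weighting by a
# per-pixel even-odd point-in-polygon loop and direct summation.
bf_center_contour <- function(map, smooth_sigma_deg = 0.1) {
  sig_px <- smooth_sigma_deg / map$scale$deg_per_px
  s <- bf_smooth(map$density, map$valid, sig_px)
  ecc <- eccentricity_map(dim(map$density), map$center, map$scale)
  ann <- map$valid & abs(ecc - map$reference_eccentricity_deg) <=
    map$annulus_halfwidth_deg
  baseline <- if (any(ann)) mean(map$density[ann], na.rm = TRUE) else 0
  smax <- max(s, na.rm = TRUE)
  hit <- which(s == smax, arr.ind = TRUE)
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
  mx_x <- hit[1, 2] - 1; mx_y <- hit[1, 1] - 1
  L <- baseline + 0.5 * (smax - baseline)
  z <- s
  z[is.na(z)] <- baseline
  h <- nrow(z); w <- ncol(z)
  cl <- grDevices::contourLines(x = 0:(w - 1), y = 0:(h - 1), z = t(z),
                                levels = L)
  pip <- function(px, py, vx, vy) {
    n <- length(vx); j <- n; inside <- FALSE
    for (i in seq_len(n)) {
      if (((vy[i] > py) != (vy[j] > py)) &&
          (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]))
        inside <- !inside
      j <- i
    }
    inside
  }
  chosen <- NULL
  for (cc in cl) {
    if (abs(cc$x[1] - cc$x[length(cc$x)]) > 1e-8 ||
        abs(cc$y[1] - cc$y[length(cc$y)]) > 1e-8) next
    if (pip(mx_x, mx_y, cc$x, cc$y)) { chosen <- cc; break }
  }
  if (is.null(chosen)) stop("oracle: no closed contour")
  hidx <- grDevices::chull(chosen$x, chosen$y)
  hx <- chosen$x[hidx]; hy <- chosen$y[hidx]
  sx <- 0; sy <- 0; sw <- 0
  for (y in 0:(h - 1)) for (x in 0:(w - 1)) {
    if (!map$valid[y + 1, x + 1]) next
    if (!pip(x, y, hx, hy)) next
    wgt <- max(map$density[y + 1, x + 1], 0)
    sx <- sx + wgt * x; sy <- sy + wgt * y; sw <- sw + wgt
  }
  c(sx / sw, sy / sw)
}

# --- brute-force profile grouping ------------------------------------------

bf_circle_profile <- function(map, center, bin_width_deg, max_ecc_deg = 9) {
  h <- nrow(map$density); w <- ncol(map$density)
  nb <- ceiling(max_ecc_deg / bin_width_deg)
  groups <- vector("list", nb)
  for (y in 0:(h - 1)) for (x in 0:(w - 1)) {
    if (!map$valid[y + 1, x + 1]) next
    ecc <- sqrt((x - center[1])^2 + (y - center[2])^2) * map$scale$deg_per_px
    if (ecc >= max_ecc_deg) next
    b <- min(floor(ecc / bin_width_deg), nb - 1) + 1
    groups[[b]] <- c(groups[[b]], map$density[y + 1, x + 1])
  }
  data.frame(
    count = vapply(groups, length, 1L),
    mean = vapply(groups, function(g) if (length(g)) mean(g) else NA_real_, 1),
    sd = vapply(groups, function(g) if (length(g) > 1) sd(g)
                else if (length(g) == 1) 0 else NA_real_, 1),
    min = vapply(groups, function(g) if (length(g)) min(g) else NA_real_, 1),
    max = vapply(groups, function(g) if (length(g)) max(g) else NA_real_, 1))
}

# --- agreement oracles ------------------------------------------------------

# ICC(A,1) via base-R aov() mean squares
bf_icc_agreement <- function(a, b) {
  n <- length(a)
  df <- data.frame(y = c(a, b),
                   subj = factor(rep(seq_len(n), 2)),
                   rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ subj + rater, data = df))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  k <- 2
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# expected majority-vote outcome, written as an independent direct rule
bf_vote <- function(labels) {
  lv <- c("peak", "ring", "mixed", "dip")
  cnt <- sapply(lv, function(l) sum(labels == l))
  prec <- c(dip = 1, ring = 2, mixed = 3, peak = 4)
  top <- max(cnt)
  cand <- lv[cnt == top]
  cand <- cand[order(prec[cand])][1]
  list(overall = cand, confident = top >= 7)
}

# all 455 multisets of size 12 over 4 categories, as count vectors
all_vote_multisets <- function() {
  out <- list()
  for (a in 0:12) for (b in 0:(12 - a)) for (c in 0:(12 - a - b)) {
    d <- 12 - a - b - c
    out[[length(out) + 1]] <- c(peak = a, ring = b, mixed = c, dip = d)
  }
  out
}
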
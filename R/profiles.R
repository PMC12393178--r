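# Grouped per-bin statistics for a vector of values and integer bin ids in
# 1..nbins. rowsum gives C-speed mean/SD; min/max via a single ordered pass.
bin_stats <- function(values, bin, nbins) {
  cnt <- tabulate(bin, nbins)
  sums <- rowsum(values, bin)
  sqs <- rowsum(values^2, bin)
  mean <- rep(NA_real_, nbins); sd <- rep(NA_real_, nbins)
  mn <- rep(NA_real_, nbins); mx <- rep(NA_real_, nbins)
  present <- sort(unique(bin))
  mean[present] <- sums[, 1] / cnt[present]
  var <- pmax(sqs[, 1] / cnt[present] - (sums[, 1] / cnt[present])^2, 0)
  # unbiased SD where n > 1
  n <- cnt[present]
  sd[present] <- ifelse(n > 1, sqrt(var * n / (n - 1)), 0)
  o <- order(bin, values)
  vb <- bin[o]; vv <- values[o]
  first <- !duplicated(vb)
  last <- !duplicated(vb, fromLast = TRUE)
  mn[vb[first]] <- vv[first]
  mx[vb[last]] <- vv[last]
  data.frame(count = cnt, mean = mean, sd = sd, min = mn, max = mx)
}

#' Radial profile on concentric circles
#'
#' Bins valid map pixels into concentric annuli `[k*w, (k+1)*w)` around a
#' center and reports per-bin mean, SD, min, max and pixel count of MPOD.
#' Empty bins are reported with `count = 0` and `NA` statistics.
#'
#' @param map An `mpod_map`.
#' @param center Center `c(x, y)` or [center_estimate].
#' @param bin_width_deg Bin width (degrees), default 0.1.
#' @param max_ecc_deg Outer limit (degrees), default 9.
#' @return A data frame of class `radial_profile` with columns
#'   `bin_center`, `bin_lo`, `bin_hi`, `mean`, `sd`, `min`, `max`, `count`;
#'   attributes `geometry = "CIRCLES"`, `bin_width_deg`, `center`.
#' @export
radial_circle_profile <- function(map, center, bin_width_deg = 0.1,
                                  max_ecc_deg = 9) {
  stopifnot(inherits(map, "mpod_map"), bin_width_deg > 0)
  ecc <- eccentricity_map(dim(map$density), center, map$scale)
  ok <- map$valid & ecc < max_ecc_deg
  nbins <- ceiling(max_ecc_deg / bin_width_deg)
  bin <- pmin(floor(ecc[ok] / bin_width_deg), nbins - 1L) + 1L
  st <- bin_stats(map$density[ok], bin, nbins)
  out <- data.frame(
    bin_lo = (seq_len(nbins) - 1) * bin_width_deg,
    bin_hi = seq_len(nbins) * bin_width_deg)
  out$bin_center <- (out$bin_lo + out$bin_hi) / 2
  out <- cbind(out[c("bin_center", "bin_lo", "bin_hi")], st)
  structure(out, class = c("radial_profile", "data.frame"),
            geometry = "CIRCLES", bin_width_deg = bin_width_deg,
            center = center_xy(center))
}

#' Cumulative disc means
#'
#' For each radius `r` in `radii_deg`, the mean MPOD over all valid pixels
#' with eccentricity `< r` (each disc includes all interior pixels).
#'
#' @param map An `mpod_map`.
#' @param center Center `c(x, y)` or [center_estimate].
#' @param radii_deg Increasing vector of disc radii (degrees).
#' @return A data frame of class `radial_profile` with `geometry = "DISCS"`
#'   and columns `radius`, `mean`, `sd`, `min`, `max`, `count`.
#' @export
radial_disc_means <- function(map, center, radii_deg = seq(0.5, 9, by = 0.5)) {
  stopifnot(inherits(map, "mpod_map"), all(diff(radii_deg) > 0),
            all(radii_deg > 0))
  ecc <- eccentricity_map(dim(map$density), center, map$scale)
  rows <- lapply(radii_deg, function(r) {
    v <- map$density[map$valid & ecc < r]
    if (length(v) == 0)
      return(data.frame(radius = r, mean = NA_real_, sd = NA_real_,
                        min = NA_real_, max = NA_real_, count = 0L))
    data.frame(radius = r, mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else 0,
               min = min(v), max = max(v), count = length(v))
  })
  structure(do.call(rbind, rows),
            class = c("radial_profile", "data.frame"),
            geometry = "DISCS", center = center_xy(center))
}

#' Per-pixel clock-hour wedge index
#'
#' Assigns every pixel to one of 12 non-overlapping 30-degree sectors with
#' apex at the center. Wedge 12 spans \[-15, +15) degrees about the
#' 12-o'clock direction (up in image coordinates, i.e. -y); hours advance
#' clockwise as displayed for a right (OD) eye. For a left (OS) eye the
#' clock-hour labels are mirrored across the vertical meridian (12 and 6
#' unchanged, 3 and 9 swapped) so that hours retain their nasal/temporal
#' meaning; the pixel partition itself is identical.
#'
#' @param shape `c(height, width)` or a matrix.
#' @param center Center `c(x, y)` or [center_estimate].
#' @param laterality `"OD"` (default) or `"OS"`.
#' @return Integer matrix of wedge indices in 1..12.
#' @export
wedge_index_map <- function(shape, center, laterality = "OD") {
  if (is.matrix(shape)) shape <- dim(shape)
  center <- center_xy(center)
  h <- shape[1]; w <- shape[2]
  dx <- matrix((0:(w - 1)) - center[1], h, w, byrow = TRUE)
  dy <- matrix((0:(h - 1)) - center[2], h, w)
  # clockwise angle from "up" (-y): atan2(dx, -dy), in degrees
  ang <- atan2(dx, -dy) * 180 / pi
  idx <- floor((ang + 15) / 30) %% 12
  hour <- ifelse(idx == 0, 12, idx)
  if (identical(laterality, "OS")) {
    hour <- (12 - hour) %% 12
    hour[hour == 0] <- 12
  }
  matrix(as.integer(hour), h, w)
}

#' Radial profiles within 12 clock-hour wedges
#'
#' Partitions pixels by angle into 12 sectors (each pixel in exactly one
#' wedge) and computes the per-wedge radial circle profile. Over all
#' wedges the bin counts reproduce the full-circle profile exactly.
#'
#' @inheritParams radial_circle_profile
#' @param laterality `"OD"` or `"OS"` (clock-hour labeling only; see
#'   [wedge_index_map()]).
#' @return A list of class `wedge_profiles` of 12 `radial_profile` data
#'   frames, named `"1"` .. `"12"`, each with attribute `wedge`.
#' @export
wedge_profiles <- function(map, center, bin_width_deg = 0.1,
                           max_ecc_deg = 9, laterality = "OD") {
  stopifnot(inherits(map, "mpod_map"))
  ecc <- eccentricity_map(dim(map$density), center, map$scale)
  wix <- wedge_index_map(dim(map$density), center, laterality)
  ok <- map$valid & ecc < max_ecc_deg
  nbins <- ceiling(max_ecc_deg / bin_width_deg)
  bin <- pmin(floor(ecc[ok] / bin_width_deg), nbins - 1L) + 1L
  wk <- wix[ok]
  vals <- map$density[ok]
  out <- lapply(1:12, function(k) {
    sel <- wk == k
    st <- if (any(sel)) bin_stats(vals[sel], bin[sel], nbins) else
      data.frame(count = integer(nbins), mean = NA_real_, sd = NA_real_,
                 min = NA_real_, max = NA_real_)
    pr <- data.frame(
      bin_lo = (seq_len(nbins) - 1) * bin_width_deg,
      bin_hi = seq_len(nbins) * bin_width_deg)
    pr$bin_center <- (pr$bin_lo + pr$bin_hi) / 2
    pr <- cbind(pr[c("bin_center", "bin_lo", "bin_hi")], st)
    structure(pr, class = c("radial_profile", "data.frame"),
              geometry = "CIRCLES", bin_width_deg = bin_width_deg,
              center = center_xy(center), wedge = k)
  })
  structure(stats::setNames(out, as.character(1:12)),
            class = "wedge_profiles", laterality = laterality)
}

#' Long-format table of profile data
#'
#' @param profiles A `radial_profile` or `wedge_profiles` object.
#' @return A plain data frame in long format (one row per bin, with a
#'   `wedge` column for wedge profiles), suitable for CSV export and
#'   plotting.
#' @export
profile_table <- function(profiles) {
  if (inherits(profiles, "wedge_profiles")) {
    do.call(rbind, lapply(profiles, function(p) {
      cbind(wedge = attr(p, "wedge"), as.data.frame(p))
    }))
  } else {
    as.data.frame(profiles)
  }
}
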
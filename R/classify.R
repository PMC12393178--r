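#' Configuration of the spatial-pattern classifier
#'
#' All thresholds are relative (fractions of the profile's range over the
#' evaluation zone) so they transfer across overall pigment levels.
#'
#' @param eval_max_ecc_deg Evaluation zone outer limit (degrees), default
#'   3: the detailed central zone in which the four patterns are defined.
#' @param smooth_bins Moving-average window (bins) applied to the mean
#'   curve, default 3.
#' @param central_zone_deg Central zone (degrees), default 0.25.
#' @param ring_crest_window_deg Eccentricity window in which a parafoveal
#'   ring crest is sought, default `c(0.5, 1.5)`.
#' @param prominence_frac Minimum prominence of the ring crest, as a
#'   fraction of the range, default 0.05.
#' @param dip_depth_frac Minimum central depression (fraction of range)
#'   below the crest for a dip, default 0.05.
#' @param plateau_zone_deg Zone over which flatness is assessed for the
#'   mixed (plateau) pattern, default 0.6.
#' @param plateau_flat_frac Maximum variation (fraction of range) over the
#'   plateau zone, default 0.05.
#' @return Object of class `classifier_config`.
#' @export
classifier_config <- function(eval_max_ecc_deg = 3.0, smooth_bins = 3L,
                              central_zone_deg = 0.25,
                              ring_crest_window_deg = c(0.5, 1.5),
                              prominence_frac = 0.05,
                              dip_depth_frac = 0.05,
                              plateau_zone_deg = 0.6,
                              plateau_flat_frac = 0.05) {
  stopifnot(eval_max_ecc_deg > 0, smooth_bins >= 1,
            central_zone_deg > 0, central_zone_deg < eval_max_ecc_deg,
            length(ring_crest_window_deg) == 2,
            ring_crest_window_deg[1] < ring_crest_window_deg[2],
            ring_crest_window_deg[2] <= eval_max_ecc_deg,
            prominence_frac > 0, prominence_frac < 1,
            dip_depth_frac > 0, dip_depth_frac < 1,
            plateau_zone_deg > 0, plateau_zone_deg <= eval_max_ecc_deg,
            plateau_flat_frac > 0, plateau_flat_frac < 1)
  structure(list(eval_max_ecc_deg = eval_max_ecc_deg,
                 smooth_bins = as.integer(smooth_bins),
                 central_zone_deg = central_zone_deg,
                 ring_crest_window_deg = ring_crest_window_deg,
                 prominence_frac = prominence_frac,
                 dip_depth_frac = dip_depth_frac,
                 plateau_zone_deg = plateau_zone_deg,
                 plateau_flat_frac = plateau_flat_frac),
            class = "classifier_config")
}

# Count-weighted moving average over non-empty bins (window of w bins
# centered on each bin); bins with more pixels carry more weight.
smooth_profile_curve <- function(mean_vals, counts, w) {
  n <- length(mean_vals)
  half <- (w - 1L) %/% 2L
  out <- rep(NA_real_, n)
  cw <- as.numeric(counts)
  mv <- ifelse(cw > 0, mean_vals, 0)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    tot <- sum(cw[lo:hi])
    if (tot > 0) out[i] <- sum(mv[lo:hi] * cw[lo:hi]) / tot
  }
  out
}

# Interior-and-endpoint local maxima of a curve, with topographic
# prominence: for each peak, the drop to the highest saddle separating it
# from higher ground (or from the curve edge).
curve_local_maxima <- function(p) {
  n <- length(p)
  if (n < 2) return(data.frame(index = integer(), prominence = numeric()))
  is_max <- logical(n)
  for (i in seq_len(n)) {
    left_ok <- i == 1 || p[i] >= p[i - 1]
    right_ok <- i == n || p[i] >= p[i + 1]
    strict <- (i > 1 && p[i] > p[i - 1]) || (i < n && p[i] > p[i + 1]) ||
      (i == 1 && n > 1 && p[1] >= p[2]) || (i == n && n > 1 && p[n] >= p[n - 1])
    is_max[i] <- left_ok && right_ok && strict
  }
  # collapse flat-topped plateaus to their first index
  idx <- which(is_max)
  if (length(idx) == 0)
    return(data.frame(index = integer(), prominence = numeric()))
  keep <- if (length(idx) == 1) idx else
    idx[c(TRUE, diff(idx) > 1 | p[idx[-1]] != p[idx[-length(idx)]])]
  prom <- vapply(keep, function(i) {
    lmin <- p[i]
    j <- i
    while (j > 1 && p[j - 1] <= p[i]) { j <- j - 1; lmin <- min(lmin, p[j]) }
    left_drop <- if (j == 1 && p[1] <= p[i]) p[i] - min(p[1:i]) else p[i] - lmin
    rmin <- p[i]
    j <- i
    while (j < length(p) && p[j + 1] <= p[i]) { j <- j + 1; rmin <- min(rmin, p[j]) }
    right_drop <- if (j == length(p) && p[length(p)] <= p[i])
      p[i] - min(p[i:length(p)]) else p[i] - rmin
    min(left_drop, right_drop)
  }, numeric(1))
  data.frame(index = keep, prominence = prom)
}

#' Classify one radial profile into a spatial pattern
#'
#' Deterministic decision cascade on the smoothed mean MPOD curve `P(e)`
#' over the evaluation zone, with `R = max(P) - min(P)`:
#' \enumerate{
#'   \item \strong{dip} if the central-zone level lies more than
#'     `dip_depth_frac * R` below the maximum in the ring-crest window;
#'   \item else \strong{ring} if a local maximum exists in the central
#'     zone and a second local maximum with prominence at least
#'     `prominence_frac * R` exists in the ring-crest window;
#'   \item else \strong{mixed} if `P` varies by at most
#'     `plateau_flat_frac * R` over the plateau zone;
#'   \item else \strong{peak}.
#' }
#' The cascade tests dip first because a depressed center must not be
#' mistaken for a flat plateau. A perfectly flat profile (`R = 0`) is a
#' plateau, hence mixed.
#'
#' @param profile A `radial_profile` (or any data frame with `bin_center`,
#'   `mean`, `count`).
#' @param cfg A [classifier_config()].
#' @return Character label: `"peak"`, `"ring"`, `"mixed"` or `"dip"`.
#' @export
classify_wedge_profile <- function(profile, cfg = classifier_config()) {
  stopifnot(is.data.frame(profile),
            all(c("bin_center", "mean", "count") %in% names(profile)))
  pr <- profile[profile$bin_center <= cfg$eval_max_ecc_deg, ]
  nonempty <- pr$count > 0 & is.finite(pr$mean)
  if (sum(nonempty) < 10) stop("profile too sparse")
  P <- smooth_profile_curve(pr$mean, pr$count, cfg$smooth_bins)
  e <- pr$bin_center
  keep <- is.finite(P)
  P <- P[keep]; e <- e[keep]
  R <- max(P) - min(P)
  if (R <= 0) return("mixed")
  central <- e <= cfg$central_zone_deg
  crest_win <- e >= cfg$ring_crest_window_deg[1] &
    e <= cfg$ring_crest_window_deg[2]
  if (!any(central) || !any(crest_win)) stop("profile too sparse")
  central_level <- mean(P[central])
  crest_max <- max(P[crest_win])
  # (1) dip
  if (central_level < crest_max - cfg$dip_depth_frac * R) return("dip")
  # (2) ring
  lm <- curve_local_maxima(P)
  has_central_max <- any(central[lm$index])
  ring_peaks <- lm$index[crest_win[lm$index] &
                           lm$prominence >= cfg$prominence_frac * R]
  if (has_central_max && length(ring_peaks) > 0) return("ring")
  # (3) mixed
  plat <- e <= cfg$plateau_zone_deg
  if (max(P[plat]) - min(P[plat]) <= cfg$plateau_flat_frac * R)
    return("mixed")
  # (4) peak
  "peak"
}

pattern_levels <- c("peak", "ring", "mixed", "dip")
# tie-break precedence: dip > ring > mixed > peak
pattern_precedence <- c(dip = 1L, ring = 2L, mixed = 3L, peak = 4L)

#' Majority vote over 12 wedge labels
#'
#' Tallies the 12 per-wedge labels. A label reaching at least 7 of 12 wins
#' with `confident = TRUE`; otherwise the plurality label wins with
#' `confident = FALSE`, ties broken by the fixed precedence
#' dip > ring > mixed > peak.
#'
#' @param labels Character vector of exactly 12 labels in
#'   `c("peak", "ring", "mixed", "dip")`.
#' @return Object of class `pattern_result`: `wedge_labels`, `counts`
#'   (named, sums to 12), `overall`, `confident`, plus `NA` override
#'   fields (`wedge_overrides`, `overall_override`) that a reviewer may
#'   fill.
#' @export
vote_overall <- function(labels) {
  if (length(labels) != 12)
    stop("exactly 12 wedge labels are required")
  labels <- match.arg(tolower(labels), pattern_levels, several.ok = TRUE)
  counts <- table(factor(labels, levels = pattern_levels))
  counts <- stats::setNames(as.integer(counts), pattern_levels)
  top <- max(counts)
  cand <- names(counts)[counts == top]
  overall <- cand[which.min(pattern_precedence[cand])]
  structure(list(wedge_labels = labels, counts = counts,
                 overall = overall, confident = top >= 7,
                 wedge_overrides = rep(NA_character_, 12),
                 overall_override = NA_character_),
            class = "pattern_result")
}

#' @export
print.pattern_result <- function(x, ...) {
  cat(sprintf("pattern_result: %s (%svote %d/12)\n", x$overall,
              if (x$confident) "" else "NOT confident, ",
              max(x$counts)))
  cat("  counts:", paste(names(x$counts), x$counts, sep = "=",
                         collapse = " "), "\n")
  invisible(x)
}

#' Classify all 12 wedges of an eye and vote
#'
#' @param wedges A [wedge_profiles()] object.
#' @param cfg A [classifier_config()].
#' @return A `pattern_result`.
#' @export
classify_eye <- function(wedges, cfg = classifier_config()) {
  stopifnot(inherits(wedges, "wedge_profiles"))
  labels <- vapply(wedges, classify_wedge_profile, character(1), cfg = cfg)
  vote_overall(unname(labels))
}

#' Apply a manual override to a pattern result
#'
#' Mirrors the reviewer's ability to override individual wedge labels, the
#' overall pattern, or both; automatic assignments are retained alongside.
#'
#' @param result A `pattern_result`.
#' @param wedge Optional wedge index (1..12) to override.
#' @param label Replacement label for that wedge.
#' @param overall Optional replacement overall label.
#' @return The updated `pattern_result`.
#' @export
override_pattern <- function(result, wedge = NULL, label = NULL,
                             overall = NULL) {
  stopifnot(inherits(result, "pattern_result"))
  if (!is.null(wedge)) {
    stopifnot(wedge %in% 1:12, label %in% pattern_levels)
    result$wedge_overrides[wedge] <- label
  }
  if (!is.null(overall)) {
    stopifnot(overall %in% pattern_levels)
    result$overall_override <- overall
  }
  result
}
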
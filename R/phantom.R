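#' Synthetic two-wavelength autofluorescence phantom specification
#'
#' Describes a synthetic eye: a parametric macular pigment field (a central
#' Gaussian plus an optional annular Gaussian) attenuating a smooth
#' vignetted autofluorescence background. The four canonical spatial
#' patterns are expressed through the two Gaussian components:
#' \describe{
#'   \item{peak}{single central maximum, monotone radial decline
#'     (`A_r = 0`).}
#'   \item{ring}{central maximum plus a parafoveal annulus whose crest sits
#'     at 0.8--1.0 degrees eccentricity.}
#'   \item{mixed}{a central plateau: the radial section varies by at most
#'     5\% of its range over the central 0.5 degrees, with a single
#'     maximum.}
#'   \item{dip}{a depressed center: the value at the center lies at least
#'     10\% of the range below the global maximum, which falls between 0.5
#'     and 1.5 degrees.}
#' }
#' The declared `pattern` is validated against the rendered radial section
#' (dense 1-D scan); a contradictory specification is rejected.
#'
#' @param pattern One of `"peak"`, `"ring"`, `"mixed"`, `"dip"`.
#' @param width_px,height_px Raster size in pixels.
#' @param true_center Numeric `c(x, y)`, subpixel, 0-based. Default: the
#'   image center.
#' @param A_c Central Gaussian amplitude (AU, >= 0).
#' @param sigma_c Central Gaussian width (degrees, > 0).
#' @param A_r Annular Gaussian amplitude (AU, >= 0).
#' @param r0 Annulus crest eccentricity (degrees, >= 0).
#' @param sigma_r Annulus width (degrees, > 0).
#' @param base_intensity Background autofluorescence level (detector
#'   counts).
#' @param vignette_strength Fraction in \[0, 1): quadratic fall-off of the
#'   background toward the image corners, centered on the image (not the
#'   fovea).
#' @param noise_sigma Additive Gaussian noise SD as a fraction of
#'   `base_intensity`.
#' @param seed Integer seed making the rendered pair reproducible.
#' @param scale A [scale_model].
#' @return An object of class `phantom_spec`.
#' @seealso [default_phantom_spec()], [random_phantom_spec()],
#'   [render_pattern_field()], [simulate_pair()]
#' @export
phantom_spec <- function(pattern = c("peak", "ring", "mixed", "dip"),
                         width_px = 768L, height_px = 768L,
                         true_center = NULL,
                         A_c = 0.6, sigma_c = 0.5,
                         A_r = 0, r0 = 0.9, sigma_r = 0.2,
                         base_intensity = 20000,
                         vignette_strength = 0.15,
                         noise_sigma = 0,
                         seed = 1L,
                         scale = scale_model()) {
  pattern <- match.arg(pattern)
  if (is.null(true_center))
    true_center <- unname(image_center(c(height_px, width_px)))
  stopifnot(width_px >= 8, height_px >= 8,
            A_c >= 0, A_r >= 0, sigma_c > 0, sigma_r > 0, r0 >= 0,
            base_intensity > 0,
            vignette_strength >= 0, vignette_strength < 1,
            noise_sigma >= 0)
  spec <- structure(
    list(pattern = pattern,
         width_px = as.integer(width_px), height_px = as.integer(height_px),
         true_center = as.numeric(true_center),
         A_c = A_c, sigma_c = sigma_c,
         A_r = A_r, r0 = r0, sigma_r = sigma_r,
         base_intensity = base_intensity,
         vignette_strength = vignette_strength,
         noise_sigma = noise_sigma,
         seed = as.integer(seed),
         scale = scale),
    class = "phantom_spec")
  contract <- check_pattern_contract(spec)
  if (!contract$ok)
    stop(sprintf("parameters contradict declared pattern '%s': %s",
                 pattern, contract$reason))
  spec
}

#' Closed-form radial MPOD section of a phantom
#'
#' @param rho Eccentricities (degrees).
#' @param spec A `phantom_spec` (or any list with `A_c`, `sigma_c`, `A_r`,
#'   `r0`, `sigma_r`).
#' @return MPOD values (AU) at `rho`.
#' @export
radial_section <- function(rho, spec) {
  spec$A_c * exp(-rho^2 / (2 * spec$sigma_c^2)) +
    spec$A_r * exp(-(rho - spec$r0)^2 / (2 * spec$sigma_r^2))
}

# Local maxima of a sampled curve; index 1 counts when the curve starts
# non-increasing (the center of a radially symmetric field is a true
# stationary point).
section_local_maxima <- function(p) {
  n <- length(p)
  d <- diff(p)
  idx <- which(d[-(n - 1)] > 0 & d[-1] <= 0) + 1L
  if (p[1] >= p[2]) idx <- c(1L, idx)
  idx
}

# Validate the declared pattern against the dense 1-D radial section.
check_pattern_contract <- function(spec, step = 0.001, max_ecc = 3) {
  rho <- seq(0, max_ecc, by = step)
  p <- radial_section(rho, spec)
  rng <- diff(range(p))
  lm <- section_local_maxima(p)
  fail <- function(reason) list(ok = FALSE, reason = reason)
  switch(spec$pattern,
    peak = {
      if (spec$A_r != 0) return(fail("peak requires A_r = 0"))
      if (spec$A_c <= 0) return(fail("peak requires A_c > 0"))
      if (any(diff(p) >= 0)) return(fail("section not strictly decreasing"))
      list(ok = TRUE)
    },
    ring = {
      if (length(lm) < 2 || lm[1] != 1L)
        return(fail("needs maxima at the center and at the crest"))
      crest <- rho[lm[lm > 1L]]
      if (!any(crest >= 0.8 & crest <= 1.0))
        return(fail("second maximum not in [0.8, 1.0] degrees"))
      list(ok = TRUE)
    },
    mixed = {
      if (length(lm) > 1) return(fail("plateau must have a single maximum"))
      flat <- diff(range(p[rho <= 0.5]))
      if (rng > 0 && flat > 0.05 * rng)
        return(fail("central 0.5 degrees varies by more than 5% of range"))
      list(ok = TRUE)
    },
    dip = {
      imax <- which.max(p)
      if (rho[imax] < 0.5 || rho[imax] > 1.5)
        return(fail("global maximum not in [0.5, 1.5] degrees"))
      if (rng <= 0 || p[1] > max(p) - 0.10 * rng)
        return(fail("center not depressed by 10% of range"))
      list(ok = TRUE)
    })
}

#' Render the ground-truth MPOD field of a phantom
#'
#' Evaluates the two-Gaussian radial model at every pixel's eccentricity
#' from the phantom's true center.
#'
#' @param spec A [phantom_spec()].
#' @return A `height_px x width_px` matrix of MPOD values (AU).
#' @export
render_pattern_field <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  ecc <- eccentricity_map(c(spec$height_px, spec$width_px),
                          spec$true_center, spec$scale)
  radial_section(ecc, spec)
}

#' Simulate a registered blue/green autofluorescence image pair
#'
#' The generative inverse of the MPOD computation. A smooth background
#' `B0 = base_intensity * (1 - vignette_strength * (d/d_max)^2)` (d the
#' distance from the image center) fluoresces fully in the green channel;
#' the blue channel is attenuated by the pigment field:
#' `G = B0 + noise`, `B = B0 * 10^(-M) + noise`, with independent Gaussian
#' noise of SD `noise_sigma * base_intensity`, clipped below at 1 count so
#' log ratios stay finite.
#'
#' @param spec A [phantom_spec()].
#' @return A list with components `pair` (an [af_image_pair]) and `truth`
#'   (class `phantom_truth`: `true_center`, `pattern`, `mpod_field`,
#'   `spec`, `seed`).
#' @export
simulate_pair <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  M <- render_pattern_field(spec)
  h <- spec$height_px; w <- spec$width_px
  ctr <- image_center(c(h, w))
  dx2 <- ((0:(w - 1)) - ctr[1])^2
  dy2 <- ((0:(h - 1)) - ctr[2])^2
  d2 <- outer(dy2, dx2, "+")
  B0 <- spec$base_intensity * (1 - spec$vignette_strength * d2 / max(d2))
  noise_sd <- spec$noise_sigma * spec$base_intensity
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(spec$seed)
  G <- B0
  B <- B0 * 10^(-M)
  if (noise_sd > 0) {
    G <- G + matrix(stats::rnorm(h * w, sd = noise_sd), h, w)
    B <- B + matrix(stats::rnorm(h * w, sd = noise_sd), h, w)
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  G <- pmax(G, 1)
  B <- pmax(B, 1)
  pair <- af_image_pair(blue = B, green = G, scale = spec$scale,
                        anatomical_center = spec$true_center,
                        meta = list(source = "phantom",
                                    pattern = spec$pattern,
                                    seed = spec$seed))
  truth <- structure(
    list(true_center = spec$true_center, pattern = spec$pattern,
         mpod_field = M, spec = spec, seed = spec$seed),
    class = "phantom_truth")
  list(pair = pair, truth = truth)
}

#' Shipped default phantom parameterizations
#'
#' One canonical specification per spatial pattern, each satisfying its
#' pattern contract:
#' \itemize{
#'   \item peak: `A_c = 0.6`, `sigma_c = 0.5`;
#'   \item ring: `A_c = 0.5`, `sigma_c = 0.25`, `A_r = 0.2`, `r0 = 0.9`,
#'     `sigma_r = 0.2`;
#'   \item mixed: `A_c = 0.35`, `sigma_c = 0.55`, `A_r = 0.2`, `r0 = 0.78`,
#'     `sigma_r = 0.32`;
#'   \item dip: `A_c = 0.15`, `sigma_c = 0.3`, `A_r = 0.45`, `r0 = 1.0`,
#'     `sigma_r = 0.3`.
#' }
#'
#' @param pattern One of `"peak"`, `"ring"`, `"mixed"`, `"dip"`.
#' @param ... Overrides passed on to [phantom_spec()] (e.g. `noise_sigma`,
#'   `seed`, `true_center`).
#' @return A [phantom_spec()].
#' @export
default_phantom_spec <- function(pattern = c("peak", "ring", "mixed", "dip"),
                                 ...) {
  pattern <- match.arg(pattern)
  pars <- switch(pattern,
    peak  = list(A_c = 0.60, sigma_c = 0.50, A_r = 0.00),
    ring  = list(A_c = 0.50, sigma_c = 0.25, A_r = 0.20, r0 = 0.90,
                 sigma_r = 0.20),
    mixed = list(A_c = 0.35, sigma_c = 0.55, A_r = 0.20, r0 = 0.78,
                 sigma_r = 0.32),
    dip   = list(A_c = 0.15, sigma_c = 0.30, A_r = 0.45, r0 = 1.00,
                 sigma_r = 0.30))
  args <- utils::modifyList(c(list(pattern = pattern), pars), list(...))
  do.call(phantom_spec, args)
}

#' Draw a random phantom within a pattern's contract ranges
#'
#' Jitters the default parameterization within ranges that respect the
#' pattern contract, and jitters the true center by up to ~0.5 degrees so
#' centration is non-trivial. Draws are rejected and retried (up to 100
#' times) if the jittered parameters violate the contract.
#'
#' @param pattern Pattern name.
#' @param seed Integer seed; also stored in the spec for the noise draw.
#' @param noise_sigma Noise level passed through to the spec.
#' @param ... Further overrides for [phantom_spec()].
#' @return A [phantom_spec()].
#' @export
random_phantom_spec <- function(pattern = c("peak", "ring", "mixed", "dip"),
                                seed = 1L, noise_sigma = 0.02, ...) {
  pattern <- match.arg(pattern)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  ctr0 <- image_center(c(768, 768))
  for (try in 1:100) {
    shift <- stats::runif(2, -12, 12)  # up to ~0.5 deg off the image center
    pars <- switch(pattern,
      peak  = list(A_c = stats::runif(1, 0.40, 0.80),
                   sigma_c = stats::runif(1, 0.35, 0.60), A_r = 0),
      ring  = list(A_c = stats::runif(1, 0.40, 0.60),
                   sigma_c = stats::runif(1, 0.20, 0.28),
                   A_r = stats::runif(1, 0.15, 0.30),
                   r0 = stats::runif(1, 0.85, 0.95),
                   sigma_r = stats::runif(1, 0.16, 0.24)),
      mixed = list(A_c = 0.35 * stats::runif(1, 0.90, 1.10),
                   sigma_c = stats::runif(1, 0.53, 0.57),
                   A_r = 0.20 * stats::runif(1, 0.95, 1.05),
                   r0 = stats::runif(1, 0.76, 0.80), sigma_r = 0.32),
      dip   = list(A_c = stats::runif(1, 0.10, 0.20),
                   sigma_c = stats::runif(1, 0.25, 0.35),
                   A_r = stats::runif(1, 0.35, 0.55),
                   r0 = stats::runif(1, 0.80, 1.20),
                   sigma_r = stats::runif(1, 0.25, 0.40)))
    args <- c(list(pattern = pattern,
                   true_center = unname(ctr0) + shift,
                   noise_sigma = noise_sigma, seed = seed),
              pars)
    spec <- try(do.call(phantom_spec, utils::modifyList(args, list(...))),
                silent = TRUE)
    if (inherits(spec, "try-error")) next
    if (pattern == "mixed") {
      # a generated "mixed" eye must be a clean plateau: flat to within
      # 3.5% of range out to 0.65 deg, not only over the 0.5 deg contract
      # zone, so that borderline plateau/peak mixtures are excluded from
      # the study condition by construction
      rho <- seq(0, 3, by = 0.001)
      p <- radial_section(rho, spec)
      if (diff(range(p[rho <= 0.65])) > 0.035 * diff(range(p))) next
    }
    return(spec)
  }
  stop("could not draw a contract-satisfying spec in 100 tries")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("phantom_spec: %s, %dx%d px, center (%.2f, %.2f)\n",
              x$pattern, x$width_px, x$height_px,
              x$true_center[1], x$true_center[2]))
  cat(sprintf("  A_c=%.3f sigma_c=%.3f A_r=%.3f r0=%.3f sigma_r=%.3f\n",
              x$A_c, x$sigma_c, x$A_r, x$r0, x$sigma_r))
  cat(sprintf("  base=%.0f vignette=%.2f noise=%.3f seed=%d\n",
              x$base_intensity, x$vignette_strength, x$noise_sigma, x$seed))
  invisible(x)
}

#' Write a simulated pair to disk
#'
#' Two 16-bit grayscale TIFFs (counts scaled by 1/65535) plus a JSON truth
#' sidecar with the true center, pattern, full specification and seed.
#'
#' @param sim Result of [simulate_pair()].
#' @param dir Output directory (created if absent).
#' @param stem Filename stem; files are `<stem>_blue.tif`,
#'   `<stem>_green.tif`, `<stem>_truth.json`.
#' @return Invisibly, the paths written.
#' @export
write_phantom <- function(sim, dir, stem = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- sim$truth$spec
  paths <- c(blue  = file.path(dir, paste0(stem, "_blue.tif")),
             green = file.path(dir, paste0(stem, "_green.tif")),
             truth = file.path(dir, paste0(stem, "_truth.json")))
  write_counts_tiff(sim$pair$blue, paths["blue"])
  write_counts_tiff(sim$pair$green, paths["green"])
  meta <- list(true_center = spec$true_center, pattern = spec$pattern,
               seed = spec$seed,
               spec = spec[c("pattern", "width_px", "height_px",
                             "true_center", "A_c", "sigma_c", "A_r", "r0",
                             "sigma_r", "base_intensity",
                             "vignette_strength", "noise_sigma", "seed")],
               scale = list(um_per_px = spec$scale$um_per_px,
                            um_per_deg = spec$scale$um_per_deg))
  jsonlite::write_json(meta, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
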
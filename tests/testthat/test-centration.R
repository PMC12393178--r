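test_that("FOVEA passes the anatomical coordinate through and validates it", {
  b <- matrix(10, 32, 32)
  pair <- af_image_pair(b, b, anatomical_center = c(15.25, 16.5))
  ce <- center_fovea(pair)
  expect_equal(c(ce$x, ce$y), c(15.25, 16.5))
  expect_equal(ce$method, "FOVEA")
  expect_error(center_fovea(af_image_pair(b, b)), "no anatomical center")
  expect_error(center_fovea(af_image_pair(b, b,
                                          anatomical_center = c(99, 1))),
               "out of bounds")
})

test_that("MAX finds a hot pixel and breaks ties by smallest y then x", {
  dens <- matrix(0, 64, 64)
  dens[27, 23] <- 1  # (x=22, y=26), inside the 2-degree search disc
  m <- make_map(dens)
  ce <- center_max(m, smooth_sigma_deg = 0)
  expect_equal(c(ce$x, ce$y), c(22, 26))

  dens2 <- matrix(0, 64, 64)
  dens2[31, 26] <- 1  # (25, 30)
  dens2[41, 26] <- 1  # (25, 40): same x, larger y loses
  ce2 <- center_max(make_map(dens2), smooth_sigma_deg = 0)
  expect_equal(c(ce2$x, ce2$y), c(25, 30))
})

test_that("CENTROID matches direct weighted means", {
  # two point masses, baseline quantile 0 so weights are the raw values
  dens <- matrix(0, 64, 64)
  dens[33, 31] <- 1  # (30, 32), weight 1
  dens[33, 35] <- 3  # (34, 32), weight 3
  ce <- center_centroid(make_map(dens), baseline_quantile = 0)
  expect_equal(c(ce$x, ce$y), c(33, 32))  # (1*30 + 3*34)/4 = 33

  # radially symmetric bump: centroid = center of symmetry
  xs <- 0:63
  d2 <- outer((xs - 30)^2, (xs - 28)^2, "+")
  bump <- make_map(0.5 * exp(-d2 / 18))
  ce2 <- center_centroid(bump)
  expect_equal(c(ce2$x, ce2$y), c(28, 30), tolerance = 1e-3)
})

test_that("CENTROID flags a zero-weight region as degenerate", {
  ce <- center_centroid(make_map(matrix(0, 64, 64)))
  expect_true(ce$degenerate)
  expect_equal(c(ce$x, ce$y), unname(image_center(c(64, 64))))
})

test_that("CONTOUR recovers symmetric discs and errors on flat maps", {
  # uniform disc of density 1 on 0 background
  xs <- 0:63
  d2 <- outer((xs - 33)^2, (xs - 31)^2, "+")
  dens <- matrix(0, 64, 64)
  dens[d2 <= 100] <- 1
  ce <- center_contour(make_map(dens), smooth_sigma_deg = 0.05)
  expect_equal(c(ce$x, ce$y), c(31, 33), tolerance = 0.05)
  expect_error(center_contour(make_map(matrix(1, 64, 64))), "flat map")
})

test_that("CONTOUR bridges the central hole of an annular distribution", {
  spec <- default_phantom_spec("dip", noise_sigma = 0,
                               true_center = c(385.5, 381.5))
  map <- compute_mpod(simulate_pair(spec)$pair)
  ce <- center_contour(map)
  expect_lt(sqrt((ce$x - 385.5)^2 + (ce$y - 381.5)^2), 1)
})

test_that("HILLCLIMB converges immediately at a symmetric fixed point", {
  xs <- 0:63
  d2 <- outer((xs - 31.5)^2, (xs - 31.5)^2, "+")
  m <- make_map(0.5 * exp(-d2 / 60))
  ce <- center_hillclimb(m, init = c(31.5, 31.5))
  expect_equal(ce$iterations, 1L)
  expect_equal(c(ce$x, ce$y), c(31.5, 31.5), tolerance = 1e-6)
})

test_that("HILLCLIMB converges from a 2-degree offset on a peak phantom", {
  spec <- default_phantom_spec("peak", noise_sigma = 0)
  map <- compute_mpod(simulate_pair(spec)$pair)
  init <- spec$true_center + c(deg_to_px(2, spec$scale), 0)
  ce <- center_hillclimb(map, init = init, tol_px = 0.05)
  expect_lte(ce$iterations, 25)
  expect_lt(sqrt((ce$x - spec$true_center[1])^2 +
                 (ce$y - spec$true_center[2])^2), 0.5)
  expect_false(ce$degenerate)
})

test_that("HILLCLIMB flags a flat map and returns the init", {
  ce <- center_hillclimb(make_map(matrix(0, 64, 64)), init = c(20, 24))
  expect_true(ce$degenerate)
  expect_equal(c(ce$x, ce$y), c(20, 24))
})

test_that("methods agree with brute-force implementations on small rasters", {
  for (s in 1:6) {
    m <- random_bump_map(100 + s)
    ce <- center_max(m)
    expect_equal(c(ce$x, ce$y), bf_center_max(m), tolerance = 1e-6)
    ce <- center_centroid(m)
    expect_equal(c(ce$x, ce$y), bf_center_centroid(m), tolerance = 1e-6)
    ce <- center_contour(m)
    expect_equal(c(ce$x, ce$y), bf_center_contour(m), tolerance = 1e-6)
    ce <- center_hillclimb(m)
    expect_equal(c(ce$x, ce$y), bf_center_hillclimb(m), tolerance = 1e-6)
  }
})

test_that("translating the phantom translates every estimate with it", {
  delta <- c(7.25, -4.5)
  base <- default_phantom_spec("ring", noise_sigma = 0.01, seed = 5)
  shifted <- default_phantom_spec("ring", noise_sigma = 0.01, seed = 5,
                                  true_center = base$true_center + delta)
  m1 <- compute_mpod(simulate_pair(base)$pair)
  m2 <- compute_mpod(simulate_pair(shifted)$pair)
  for (f in list(center_max, center_centroid, center_contour,
                 center_hillclimb)) {
    c1 <- f(m1); c2 <- f(m2)
    # MAX lands on pixel centers, so allow up to a pixel of discretization
    expect_lt(max(abs(c(c2$x - c1$x, c2$y - c1$y) - delta)), 1)
  }
})

test_that("distance report converts px to um with the universal factor", {
  est <- data.frame(eye_id = "e1", method = "MAX", x = 3, y = 4)
  ref <- data.frame(eye_id = "e1", x = 0, y = 0)
  rep <- compare_centers(est, ref)
  expect_equal(rep$per_eye$dist_px, 5)
  expect_equal(rep$per_eye$dist_um, 56.5)
  expect_true(is.na(rep$summary$sd_px))   # single eye: SD undefined
  expect_null(rep$ellipses$MAX)
})

test_that("identical estimates give zero distances and a degenerate spread", {
  est <- data.frame(eye_id = c("a", "b"), method = "HILLCLIMB",
                    x = c(10, 20), y = c(5, 6))
  ref <- est[, c("eye_id", "x", "y")]
  rep <- compare_centers(est, ref)
  expect_equal(rep$summary$mean_px, 0)
  expect_equal(rep$summary$sd_px, 0)
  expect_equal(rep$ellipses$HILLCLIMB$semi_axes, c(0, 0))
})

test_that("the 95% prediction ellipse covers ~95% of isotropic deviations", {
  set.seed(77)
  dx <- rnorm(1000, sd = 2)
  dy <- rnorm(1000, sd = 2)
  ell <- prediction_ellipse(dx, dy)
  cover <- mean(in_prediction_ellipse(ell, dx, dy))
  expect_gt(cover, 0.93)
  expect_lt(cover, 0.97)
})
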
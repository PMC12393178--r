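test_that("raw log ratio handles identity, scaling, and invalid pixels", {
  g <- matrix(100, 8, 8)
  b <- matrix(100, 8, 8)
  pair <- af_image_pair(b, g)
  lr <- compute_raw_logratio(pair)
  expect_true(all(lr$valid))
  expect_equal(lr$raw, matrix(0, 8, 8))

  lr10 <- compute_raw_logratio(af_image_pair(b, 10 * g))
  expect_equal(lr10$raw, matrix(1, 8, 8))

  b2 <- b; b2[3, 5] <- 0
  lr2 <- compute_raw_logratio(af_image_pair(b2, g))
  expect_false(lr2$valid[3, 5])
  expect_true(is.na(lr2$raw[3, 5]))
  expect_equal(sum(!lr2$valid), 1L)
  expect_equal(lr2$raw[3, 4], 0)

  expect_error(compute_raw_logratio(af_image_pair(0 * b, g)),
               "no measurable pixels")
})

test_that("reference normalization zeroes the annulus and records the offset", {
  # uniform raw field: offset is the constant, map becomes zero
  raw <- matrix(1, 600, 600)
  valid <- matrix(TRUE, 600, 600)
  m <- normalize_to_reference(raw, valid, image_center(raw))
  expect_equal(m$reference_offset, 1)
  expect_true(all(m$density == 0))

  # annulus mean is zero to 1e-9 on a structured map
  sim <- simulate_pair(default_phantom_spec("ring", noise_sigma = 0.01,
                                            seed = 3))
  map <- compute_mpod(sim$pair)
  ecc <- eccentricity_map(dim(map$density), map$center, map$scale)
  ann <- map$valid & abs(ecc - 9) <= 0.25
  expect_lt(abs(mean(map$density[ann])), 1e-9)
})

test_that("annulus outside the frame raises an error", {
  raw <- matrix(1, 100, 100)
  valid <- matrix(TRUE, 100, 100)
  # at 11.3 um/px the 9-degree annulus needs ~229 px of radius
  expect_error(normalize_to_reference(raw, valid, image_center(raw)),
               "reference annulus unavailable")
})

test_that("normalization is idempotent and scale-invariant", {
  sim <- simulate_pair(default_phantom_spec("peak", noise_sigma = 0.02,
                                            seed = 9))
  map <- compute_mpod(sim$pair)
  map2 <- renormalize_map(map, map$center)
  expect_lt(max(abs(map2$density - map$density), na.rm = TRUE), 1e-9)

  scaled <- af_image_pair(2.5 * sim$pair$blue, 2.5 * sim$pair$green,
                          sim$pair$scale)
  map3 <- compute_mpod(scaled)
  expect_equal(map3$density, map$density, tolerance = 1e-12)
})

test_that("noise-free phantom round trip reproduces the generative field", {
  for (pat in c("peak", "dip")) {
    spec <- default_phantom_spec(pat, noise_sigma = 0)
    sim <- simulate_pair(spec)
    map <- compute_mpod(sim$pair, center = spec$true_center)
    # normalize the truth identically (subtract its own annulus mean)
    ecc <- eccentricity_map(dim(map$density), spec$true_center, spec$scale)
    ann <- abs(ecc - 9) <= 0.25
    truth <- sim$truth$mpod_field - mean(sim$truth$mpod_field[ann])
    expect_lt(max(abs(map$density - truth)), 1e-6)
  }
})

test_that("pseudocolor rendering is monotone with black invalid pixels", {
  dens <- matrix(seq(0, 0.8, length.out = 64), 8, 8)
  valid <- matrix(TRUE, 8, 8); valid[1, 1] <- FALSE
  m <- make_map(dens, valid)
  img <- render_pseudocolor(m, display_max = 0.8)
  expect_equal(dim(img), c(8, 8, 3))
  expect_equal(img[1, 1, ], c(0, 0, 0))      # invalid -> black
  # ramp endpoints: 0 AU -> first ramp color, display_max -> last (red)
  two <- make_map(matrix(c(0, 0.8), 1, 2))
  ends <- render_pseudocolor(two, display_max = 0.8)
  expect_equal(ends[1, 1, ], c(0, 0, 139 / 255))
  expect_equal(ends[1, 2, ], c(1, 0, 0))
  # equal densities map to equal colors; clamping above display_max
  over <- render_pseudocolor(make_map(matrix(c(0.8, 1.5), 1, 2)), 0.8)
  expect_equal(over[1, 1, ], over[1, 2, ])
  lo <- render_pseudocolor(make_map(matrix(0, 4, 4)), 0.8)
  expect_true(all(abs(lo[, , 1] - lo[1, 1, 1]) < 1e-12))  # uniform lowest color
})
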
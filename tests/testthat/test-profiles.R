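test_that("constant maps give constant profiles with zero spread", {
  m <- make_map(matrix(0.3, 64, 64))
  pr <- radial_circle_profile(m, image_center(c(64, 64)), 0.5, 3)
  nz <- pr$count > 0
  expect_equal(pr$mean[nz], rep(0.3, sum(nz)), tolerance = 1e-12)
  expect_lt(max(pr$sd[nz]), 1e-7)
  expect_true(all(pr$min[nz] == 0.3 & pr$max[nz] == 0.3))
  dm <- radial_disc_means(m, image_center(c(64, 64)), c(1, 2, 3))
  expect_true(all(dm$mean == 0.3))
})

test_that("circle and wedge binning equal brute-force per-pixel grouping", {
  m <- random_bump_map(55)
  ctr <- c(30.25, 33.5)
  pr <- radial_circle_profile(m, ctr, 0.3, 3)
  bf <- bf_circle_profile(m, ctr, 0.3, 3)
  expect_equal(pr$count, bf$count)
  expect_equal(pr$mean, bf$mean, tolerance = 1e-10)
  expect_equal(pr$sd, bf$sd, tolerance = 1e-8)
  expect_equal(pr$min, bf$min)
  expect_equal(pr$max, bf$max)
})

test_that("peak phantom profiles decline monotonically", {
  spec <- default_phantom_spec("peak", noise_sigma = 0)
  map <- compute_mpod(simulate_pair(spec)$pair)
  pr <- radial_circle_profile(map, spec$true_center, 0.25, 9)
  nz <- which(pr$count > 0)
  # strict decline where the field is measurable; never an increase beyond
  # floating-point noise in the far tail
  inner <- nz[pr$bin_center[nz] < 4]
  expect_true(all(diff(pr$mean[inner]) < 0))
  expect_true(all(diff(pr$mean[nz]) < 1e-12))
  dm <- radial_disc_means(map, spec$true_center, seq(0.5, 9, 0.5))
  expect_true(all(diff(dm$mean) < 0))
})

test_that("disc means are the count-weighted average of circle bins", {
  m <- random_bump_map(91)
  ctr <- image_center(c(64, 64))
  pr <- radial_circle_profile(m, ctr, 0.1, 3)
  dm <- radial_disc_means(m, ctr, 3)
  nz <- pr$count > 0
  expect_equal(dm$mean,
               sum(pr$mean[nz] * pr$count[nz]) / sum(pr$count[nz]))
  expect_equal(dm$count, sum(pr$count))
})

test_that("wedges tile the plane and reproduce full-circle counts", {
  m <- random_bump_map(12)
  ctr <- c(31, 30)
  wix <- wedge_index_map(c(64, 64), ctr)
  expect_true(all(wix %in% 1:12))
  wp <- wedge_profiles(m, ctr, 0.3, 3)
  pr <- radial_circle_profile(m, ctr, 0.3, 3)
  counts <- Reduce(`+`, lapply(wp, function(p) p$count))
  expect_equal(counts, pr$count)
})

test_that("wedge 12 points up and hours advance clockwise; OS mirrors", {
  ctr <- c(31.5, 31.5)
  wix <- wedge_index_map(c(64, 64), ctr)
  expect_equal(wix[2, 32], 12L)   # straight up (x = 31 < 31.5, near 12)
  expect_equal(wix[32, 60], 3L)   # right = 3 o'clock
  expect_equal(wix[60, 32], 6L)   # down = 6 o'clock
  expect_equal(wix[32, 2], 9L)    # left = 9 o'clock
  os <- wedge_index_map(c(64, 64), ctr, laterality = "OS")
  expect_equal(os[2, 32], 12L)
  expect_equal(os[32, 60], 9L)    # mirrored: right becomes 9
  expect_equal(os[60, 32], 6L)
})

test_that("a radially symmetric map yields 12 near-identical wedge profiles", {
  spec <- default_phantom_spec("ring", noise_sigma = 0)
  map <- compute_mpod(simulate_pair(spec)$pair)
  wp <- wedge_profiles(map, spec$true_center, 0.25, 3)
  means <- sapply(wp, function(p) p$mean)
  nz <- rowSums(is.na(means)) == 0
  spread <- apply(means[nz, ], 1, function(r) diff(range(r)))
  expect_lt(max(spread), 0.05)
})

test_that("an upper-half bright field separates upper from lower wedges", {
  dens <- matrix(0.1, 64, 64)
  dens[1:28, ] <- 0.5   # y < 28: upper half (above center y = 31.5)
  m <- make_map(dens)
  wp <- wedge_profiles(m, c(31.5, 31.5), 0.5, 2)
  at1deg <- sapply(wp, function(p) p$mean[p$bin_center == 1.25])
  expect_true(all(at1deg[c("11", "12", "1")] >
                    at1deg[c("5", "6", "7")]))
})

test_that("profile tables flatten to plot-ready long format", {
  m <- random_bump_map(3)
  wp <- wedge_profiles(m, c(31, 31), 0.5, 2)
  tab <- profile_table(wp)
  expect_equal(nrow(tab), 12 * 4)
  expect_true(all(c("wedge", "bin_center", "mean", "count") %in% names(tab)))
})
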
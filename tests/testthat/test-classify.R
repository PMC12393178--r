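# build a profile data frame from a closed-form radial section, with
# annulus-area-proportional pixel counts
section_profile <- function(f, bin_width = 0.1, max_ecc = 3) {
  centers <- seq(bin_width / 2, max_ecc - bin_width / 2, by = bin_width)
  data.frame(bin_center = centers, mean = f(centers),
             count = round(1000 * (2 * centers * bin_width)))
}

test_that("canonical curve shapes land in their categories", {
  cfg <- classifier_config()
  # strictly decreasing from a single central max -> peak
  peak <- section_profile(function(e) 0.6 * exp(-e^2 / 0.5))
  expect_equal(classify_wedge_profile(peak, cfg), "peak")
  # maxima at 0 and 0.9, center not depressed -> ring
  ring <- section_profile(function(e)
    0.5 * exp(-e^2 / (2 * 0.25^2)) + 0.2 * exp(-(e - 0.9)^2 / (2 * 0.2^2)))
  expect_equal(classify_wedge_profile(ring, cfg), "ring")
  # central plateau -> mixed
  mixed <- section_profile(function(e)
    0.35 * exp(-e^2 / (2 * 0.55^2)) + 0.2 * exp(-(e - 0.78)^2 / (2 * 0.32^2)))
  expect_equal(classify_wedge_profile(mixed, cfg), "mixed")
  # depressed center below a 1-degree crest -> dip
  dip <- section_profile(function(e)
    0.15 * exp(-e^2 / (2 * 0.3^2)) + 0.45 * exp(-(e - 1)^2 / (2 * 0.3^2)))
  expect_equal(classify_wedge_profile(dip, cfg), "dip")
})

test_that("hand-evaluated dip rule: 0.30 center vs 0.45 crest fires", {
  # P(0) = 0.30, crest 0.45 at 1.0 deg, range 0.45:
  # 0.30 < 0.45 - 0.05 * 0.45 = 0.4275
  f <- function(e) 0.30 + 0.15 * exp(-(e - 1)^2 / (2 * 0.25^2)) -
    0.30 * pmax(e - 1.5, 0) / 1.5
  pr <- section_profile(function(e) pmax(f(e), 0))
  expect_equal(classify_wedge_profile(pr), "dip")
})

test_that("degenerate profiles: constant -> mixed, sparse -> error", {
  flat <- section_profile(function(e) rep(0.2, length(e)))
  expect_equal(classify_wedge_profile(flat), "mixed")
  sparse <- data.frame(bin_center = seq(0.05, 0.85, 0.1),
                       mean = rnorm(9), count = rep(5, 9))
  expect_error(classify_wedge_profile(sparse), "too sparse")
})

test_that("every profile gets exactly one deterministic label", {
  set.seed(4)
  for (i in 1:25) {
    f <- function(e) 0.3 * exp(-e^2 / runif(1, 0.05, 1)) +
      runif(1, 0, 0.3) * exp(-(e - runif(1, 0.5, 1.5))^2 / 0.08)
    pr <- section_profile(f)
    l1 <- classify_wedge_profile(pr)
    l2 <- classify_wedge_profile(pr)
    expect_true(l1 %in% c("peak", "ring", "mixed", "dip"))
    expect_identical(l1, l2)
  }
})

test_that("tiny perturbations never flip a label away from thresholds", {
  cfg <- classifier_config()
  for (pat in c("peak", "ring", "mixed", "dip")) {
    spec <- default_phantom_spec(pat)
    pr <- section_profile(function(e) radial_section(e, spec))
    base <- classify_wedge_profile(pr, cfg)
    set.seed(8)
    for (k in 1:5) {
      pr2 <- pr
      pr2$mean <- pr2$mean + runif(nrow(pr2), -1, 1) * 1e-7
      expect_identical(classify_wedge_profile(pr2, cfg), base)
    }
  }
})

test_that("majority vote follows the 7-of-12 rule with fixed tie precedence", {
  v <- vote_overall(c(rep("peak", 7), rep("ring", 5)))
  expect_equal(v$overall, "peak")
  expect_true(v$confident)
  v2 <- vote_overall(rep("dip", 12))
  expect_equal(v2$overall, "dip")
  expect_true(v2$confident)
  v3 <- vote_overall(c(rep("ring", 6), rep("peak", 6)))
  expect_equal(v3$overall, "ring")   # precedence dip > ring > mixed > peak
  expect_false(v3$confident)
  expect_error(vote_overall(rep("peak", 11)), "12")
})

test_that("vote matches the enumeration oracle over all 455 multisets", {
  for (cnt in all_vote_multisets()) {
    labels <- rep(names(cnt), cnt)
    got <- vote_overall(labels)
    want <- bf_vote(labels)
    expect_identical(got$overall, want$overall)
    expect_identical(got$confident, want$confident)
    expect_equal(sum(got$counts), 12L)
  }
})

test_that("overrides are recorded without erasing automatic labels", {
  v <- vote_overall(c(rep("peak", 8), rep("ring", 4)))
  v <- override_pattern(v, wedge = 3, label = "mixed", overall = "ring")
  expect_equal(v$wedge_overrides[3], "mixed")
  expect_equal(v$overall_override, "ring")
  expect_equal(v$wedge_labels[3], "peak")
  expect_equal(v$overall, "peak")
})
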
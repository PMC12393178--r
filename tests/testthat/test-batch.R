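# small phantoms (512 px keeps the 9-degree reference annulus inside the
# frame at the default 11.3 um/px) so batch tests stay quick
batch_spec <- function(pattern, seed, center = NULL) {
  default_phantom_spec(pattern, width_px = 512, height_px = 512,
                       true_center = center, noise_sigma = 0.02,
                       seed = seed)
}

write_batch_fixture <- function(dir, patterns = c("peak", "ring", "dip")) {
  recs <- lapply(seq_along(patterns), function(i) {
    spec <- batch_spec(patterns[i], seed = 40 + i)
    sim <- simulate_pair(spec)
    write_phantom(sim, dir, paste0("eye", i))
    list(eye_id = paste0("eye", i),
         blue = paste0("eye", i, "_blue.tif"),
         green = paste0("eye", i, "_green.tif"),
         manual_center = spec$true_center,
         laterality = "OD")
  })
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(recs, mp, auto_unbox = TRUE, digits = NA)
  mp
}

test_that("process_eye runs the full two-pass pipeline on a phantom", {
  spec <- batch_spec("ring", seed = 19)
  res <- process_eye(simulate_pair(spec)$pair)
  expect_s3_class(res, "eye_result")
  expect_equal(res$pattern$overall, "ring")
  err <- sqrt((res$primary_center$x - spec$true_center[1])^2 +
              (res$primary_center$y - spec$true_center[2])^2)
  expect_lt(err, 1)
  # final map is anchored at the converged center
  expect_equal(res$map$center, c(res$primary_center$x, res$primary_center$y))
})

test_that("a batch of three phantoms yields the constructed frequency table", {
  d <- withr::local_tempdir()
  mp <- write_batch_fixture(d)
  out <- file.path(d, "out")
  br <- run_batch(mp, out_dir = out)
  expect_true(br$ok)
  freq <- structure(br$pattern_frequency$n, names = br$pattern_frequency$pattern)
  expect_equal(freq[["peak"]], 1L)
  expect_equal(freq[["ring"]], 1L)
  expect_equal(freq[["dip"]], 1L)
  expect_equal(freq[["mixed"]], 0L)
  # per-eye artifacts exist
  expect_true(file.exists(file.path(out, "eye1_mpod.tif")))
  expect_true(file.exists(file.path(out, "eye2_centers.tsv")))
  expect_true(file.exists(file.path(out, "eye3_pattern.tsv")))
  # centration comparison against the stored manual centers; MAX is
  # excluded: on an annular (dip) phantom its error is the crest radius
  expect_s3_class(br$centration, "centration_report")
  s <- br$centration$summary
  expect_true(all(s$mean_px[s$method %in% c("HILLCLIMB", "CONTOUR")] < 3))
})

test_that("one corrupt record does not abort the batch", {
  d <- withr::local_tempdir()
  mp <- write_batch_fixture(d, patterns = c("peak", "ring"))
  recs <- jsonlite::read_json(mp)
  recs[[2]]$green <- "missing.tif"
  jsonlite::write_json(recs, mp, auto_unbox = TRUE, digits = NA)
  expect_message(br <- run_batch(mp, out_dir = file.path(d, "out")),
                 "failed")
  expect_false(br$ok)
  expect_length(br$results, 1)
  expect_named(br$failures, "eye2")
  expect_equal(br$pattern_frequency$n[br$pattern_frequency$pattern == "peak"],
               1L)
  expect_error(run_batch(list()), "empty batch")
})

test_that("rerunning a batch writes byte-identical reports", {
  d <- withr::local_tempdir()
  mp <- write_batch_fixture(d, patterns = c("peak", "dip"))
  o1 <- file.path(d, "o1"); o2 <- file.path(d, "o2")
  run_batch(mp, out_dir = o1)
  run_batch(mp, out_dir = o2)
  for (f in list.files(o1)) {
    if (!grepl("\\.(tsv|csv|json)$", f)) next
    expect_identical(readLines(file.path(o1, f)),
                     readLines(file.path(o2, f)),
                     label = f)
  }
})
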
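#' Process a single eye end to end
#'
#' Two-pass pipeline: (1) raw log ratio normalized provisionally at the
#' image center; (2) the requested centration methods are run on the
#' provisional map; (3) the map is re-anchored at the primary center; (4)
#' radial, disc and wedge profiles are extracted at that center; (5) the
#' 12 wedge profiles are classified and voted into the eye's overall
#' pattern.
#'
#' @param pair An [af_image_pair].
#' @param config A [run_config()].
#' @return List of class `eye_result`: `eye_id`, `map` (final
#'   `mpod_map`), `centers` (named list of [center_estimate]s),
#'   `primary_center`, `circles`, `discs`, `wedges`, `pattern`
#'   (a `pattern_result`).
#' @export
process_eye <- function(pair, config = run_config()) {
  stopifnot(inherits(pair, "af_image_pair"),
            inherits(config, "run_config"))
  map0 <- compute_mpod(pair, ref_ecc_deg = config$ref_ecc_deg,
                       annulus_halfwidth_deg = config$annulus_halfwidth_deg)
  run_method <- function(m) switch(m,
    fovea = center_fovea(pair),
    max = center_max(map0, config$search_radius_deg,
                     config$smooth_sigma_deg),
    centroid = center_centroid(map0, config$search_radius_deg),
    contour = center_contour(map0, config$smooth_sigma_deg),
    hillclimb = center_hillclimb(map0,
                                 window_radius_deg = config$window_radius_deg,
                                 tol_px = config$tol_px,
                                 max_iter = config$max_iter),
    manual = {
      if (is.null(pair$manual_center)) stop("no manual center supplied")
      center_estimate(pair$manual_center[1], pair$manual_center[2],
                      "MANUAL")
    })
  methods <- unique(c(config$methods, config$center_method))
  centers <- stats::setNames(lapply(methods, run_method), methods)
  primary <- centers[[config$center_method]]
  map <- renormalize_map(map0, primary)
  lat <- if (identical(pair$laterality, "OS")) "OS" else "OD"
  circles <- radial_circle_profile(map, primary, config$bin_width_deg,
                                   config$max_ecc_deg)
  discs <- radial_disc_means(map, primary,
                             seq(0.5, config$max_ecc_deg, by = 0.5))
  wedges <- wedge_profiles(map, primary, config$bin_width_deg,
                           config$max_ecc_deg, laterality = lat)
  pattern <- classify_eye(wedges, config$classifier)
  structure(list(eye_id = pair$eye_id, map = map, centers = centers,
                 primary_center = primary, circles = circles,
                 discs = discs, wedges = wedges, pattern = pattern),
            class = "eye_result")
}

#' @export
print.eye_result <- function(x, ...) {
  cat(sprintf("eye_result '%s': pattern %s (%d/12), center (%.2f, %.2f) [%s]\n",
              x$eye_id, x$pattern$overall, max(x$pattern$counts),
              x$primary_center$x, x$primary_center$y,
              x$primary_center$method))
  invisible(x)
}

centers_table <- function(result) {
  do.call(rbind, lapply(result$centers, function(ce) {
    data.frame(eye_id = result$eye_id, method = ce$method,
               x_px = ce$x, y_px = ce$y, iterations = ce$iterations,
               degenerate = ce$degenerate)
  }))
}

pattern_row <- function(result) {
  p <- result$pattern
  df <- data.frame(eye_id = result$eye_id)
  for (k in 1:12) df[[paste0("wedge_", k)]] <- p$wedge_labels[k]
  for (lv in names(p$counts)) df[[paste0("n_", lv)]] <- p$counts[[lv]]
  df$overall <- p$overall
  df$confident <- p$confident
  for (k in 1:12)
    df[[paste0("override_", k)]] <- p$wedge_overrides[k]
  df$overall_override <- p$overall_override
  df
}

#' Batch-process a set of eyes
#'
#' Processes every manifest record independently; a failure in one eye is
#' logged and does not abort the batch. Per-eye outputs (MPOD map TIFF +
#' sidecar, centers TSV, profile CSVs, pattern TSV) and batch summaries
#' (pattern frequency table; centration comparison when a reference
#' center is available) are written under `out_dir`.
#'
#' @param manifest List of records from [read_manifest()], or a path to a
#'   manifest file.
#' @param config A [run_config()].
#' @param out_dir Output directory (created).
#' @param base_dir Base directory for relative raster paths (defaults to
#'   the manifest's directory when `manifest` is a path).
#' @param reference `"manual"` or `"fovea"`: which stored center to use
#'   as the reference for the centration comparison; skipped when absent.
#' @return List of class `batch_result`: `results` (per-eye
#'   `eye_result`s), `failures` (named character vector of error
#'   messages), `pattern_frequency` (data frame), `centration`
#'   (a `centration_report` or `NULL`), `ok` (logical: no failures).
#' @export
run_batch <- function(manifest, config = run_config(), out_dir = NULL,
                      base_dir = NULL, reference = "manual") {
  if (is.character(manifest) && length(manifest) == 1) {
    if (is.null(base_dir)) base_dir <- dirname(manifest)
    manifest <- read_manifest(manifest)
  }
  if (is.null(base_dir)) base_dir <- "."
  if (length(manifest) == 0) stop("empty batch")
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  failures <- character()
  for (rec in manifest) {
    id <- as.character(rec$eye_id)
    res <- tryCatch({
      pair <- read_image_pair(rec, base_dir)
      process_eye(pair, config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[id] <- conditionMessage(res)
      message("eye ", id, " failed: ", conditionMessage(res))
      next
    }
    results[[id]] <- res
    if (!is.null(out_dir)) {
      write_mpod_map(res$map, file.path(out_dir, paste0(id, "_mpod.tif")))
      write_tsv_report(centers_table(res),
                       file.path(out_dir, paste0(id, "_centers.tsv")))
      utils::write.csv(profile_table(res$circles),
                       file.path(out_dir, paste0(id, "_circles.csv")),
                       row.names = FALSE)
      utils::write.csv(profile_table(res$discs),
                       file.path(out_dir, paste0(id, "_discs.csv")),
                       row.names = FALSE)
      utils::write.csv(profile_table(res$wedges),
                       file.path(out_dir, paste0(id, "_wedges.csv")),
                       row.names = FALSE)
      write_tsv_report(pattern_row(res),
                       file.path(out_dir, paste0(id, "_pattern.tsv")))
    }
  }
  freq <- table(factor(vapply(results, function(r) r$pattern$overall, ""),
                       levels = pattern_levels))
  freq_df <- data.frame(pattern = names(freq), n = as.integer(freq),
                        fraction = if (length(results))
                          as.integer(freq) / length(results) else
                          rep(NA_real_, length(freq)))
  centration <- NULL
  refs <- do.call(rbind, lapply(manifest, function(rec) {
    ctr <- if (reference == "fovea") rec$anatomical_center else
      rec$manual_center
    if (is.null(ctr)) return(NULL)
    ctr <- as.numeric(unlist(ctr))
    data.frame(eye_id = as.character(rec$eye_id), x = ctr[1], y = ctr[2])
  }))
  if (!is.null(refs) && nrow(refs) > 0 && length(results) > 0) {
    est <- do.call(rbind, lapply(results, centers_table))
    est <- est[est$eye_id %in% refs$eye_id, ]
    names(est)[names(est) == "x_px"] <- "x"
    names(est)[names(est) == "y_px"] <- "y"
    if (nrow(est) > 0) {
      centration <- compare_centers(est[c("eye_id", "method", "x", "y")],
                                    refs, scale_model())
      if (!is.null(out_dir)) {
        write_tsv_report(centration$per_eye,
                         file.path(out_dir, "centration_per_eye.tsv"))
        write_tsv_report(centration$summary,
                         file.path(out_dir, "centration_summary.tsv"))
      }
    }
  }
  if (!is.null(out_dir))
    write_tsv_report(freq_df, file.path(out_dir, "pattern_frequency.tsv"))
  structure(list(results = results, failures = failures,
                 pattern_frequency = freq_df, centration = centration,
                 ok = length(failures) == 0),
            class = "batch_result")
}

#' @export
print.batch_result <- function(x, ...) {
  cat(sprintf("batch_result: %d processed, %d failed\n",
              length(x$results), length(x$failures)))
  print(x$pattern_frequency, row.names = FALSE)
  invisible(x)
}
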
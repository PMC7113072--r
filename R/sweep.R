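#' Configuration for an end-to-end compression sweep
#'
#' Bundles the scene generator settings, the train/test split, the JPEG2000
#' PSNR ladder, the classifier configuration and the evaluation options. The
#' default ladder is the figure ladder 18, 20, 22, 25, 30, 35, 40, 90 dB plus
#' the lossless endpoint (100). The default split keeps the 8:2
#' train:test ratio.
#'
#' @param task Scene task: `"nuclei"`, `"lymphocyte"` or `"region"`.
#' @param n_train,n_test Scene counts (>= 1 each).
#' @param scene A [scene_params()] template; its `task` and `seed` are
#'   overridden per generated scene.
#' @param ladder JPEG2000 target-PSNR levels in dB (100 = lossless; must be
#'   included — it anchors the stability matrix and relative metrics).
#' @param train A [train_config()].
#' @param pixel_threshold Probability threshold for binary masks.
#' @param detect_threshold,match_radius Detection threshold and matching
#'   radius (px); radius defaults to the scene nucleus radius.
#' @param min_area Minimum object area (px^2) when labelling predicted
#'   segmentations for feature extraction.
#' @param link_radius Subgraph linking radius; defaults to 3.5 x nucleus
#'   radius.
#' @param psnr_tol Codec attainment tolerance, dB.
#' @param seed Master seed: drives scene seeds, patch sampling and training.
#' @param out_dir Optional output directory for CSV/JSON/PNG artifacts.
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(task = c("nuclei", "lymphocyte", "region"),
                         n_train = 8L, n_test = 2L,
                         scene = scene_params(),
                         ladder = c(18, 20, 22, 25, 30, 35, 40, 90, 100),
                         train = train_config(),
                         pixel_threshold = 0.5,
                         detect_threshold = 0.5,
                         match_radius = NULL,
                         min_area = 9,
                         link_radius = NULL,
                         psnr_tol = 0.5,
                         seed = 1L,
                         out_dir = NULL) {
  task <- match.arg(task)
  if (n_train < 1L || n_test < 1L) abort_param("train/test counts must be >= 1.")
  if (!length(ladder)) abort_param("`ladder` must be non-empty.")
  if (!100 %in% ladder) abort_param("`ladder` must include the lossless level 100.")
  r <- scene$nucleus_radius_mean
  structure(list(task = task, n_train = as.integer(n_train),
                 n_test = as.integer(n_test), scene = scene,
                 ladder = sort(unique(ladder)), train = train,
                 pixel_threshold = pixel_threshold,
                 detect_threshold = detect_threshold,
                 match_radius = match_radius %||% r,
                 min_area = min_area,
                 link_radius = link_radius %||% (3.5 * r),
                 psnr_tol = psnr_tol,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "sweep_config")
}

scene_with <- function(template, task, seed) {
  scene_params(width = template$width, height = template$height, task = task,
               cell_density = template$cell_density,
               nucleus_radius_mean = template$nucleus_radius_mean,
               nucleus_radius_sd = template$nucleus_radius_sd,
               eccentricity_range = template$eccentricity_range,
               stain_fg = template$stain_fg, stain_bg = template$stain_bg,
               stain_distractor = template$stain_distractor,
               stain_clutter = template$stain_clutter,
               clutter_density = template$clutter_density,
               illumination_sd = template$illumination_sd,
               texture_sd = template$texture_sd, noise_sd = template$noise_sd,
               region_fraction = template$region_fraction,
               distractor_ratio = template$distractor_ratio, seed = seed)
}

evaluate_map <- function(config, scene, map) {
  task <- scene$params$task
  if (task == "lymphocyte") {
    det <- detect_centers(map, config$detect_threshold,
                          min_distance = scene$params$nucleus_radius_mean)
    gt <- scene$centers[scene$centers$class == "target", ]
    m <- match_detections(det, gt, radius = config$match_radius)
    return(tibble(metric = "detection_f1", value = detection_f1(m)))
  }
  truth <- scene_truth_mask(scene)
  f1 <- pixel_f1(binarize_map(map, config$pixel_threshold), truth)
  auc <- tryCatch(pixel_auc(map, truth),
                  histocompress_undefined_metric_error = function(e) NA_real_)
  tibble(metric = c("pixel_f1", "pixel_auc"), value = c(f1, auc))
}

#' Run the full compression-robustness experiment
#'
#' Generates seeded synthetic scenes, trains the patch classifier on the
#' uncompressed training scenes only (train-on-clean protocol), then subjects
#' every test scene to the JPEG2000 PSNR ladder, re-runs inference on each
#' decoded image and records metrics per (image, level). For the nuclei task
#' the 77 nuclear-architecture features are additionally extracted from each
#' predicted segmentation and folded into a stability matrix against the
#' lossless level. Fully deterministic given `config$seed`.
#'
#' Ladder levels the codec cannot realise within tolerance (e.g. very high
#' PSNR targets on small images) are kept best-effort with `converged =
#' FALSE`; downstream plots use the achieved PSNR, not the target.
#'
#' @param config A [sweep_config()].
#' @return An object of class `sweep_result`: `results` (long metric tibble),
#'   `features`, `stability` (nuclei task), `curves`, `model`, `manifest`,
#'   `config`.
#' @export
run_sweep <- function(config) {
  if (!inherits(config, "sweep_config")) abort_param("`config` must be a sweep_config().")
  n_all <- config$n_train + config$n_test
  seeds <- with_seed(config$seed, sample.int(1e6, n_all))
  scenes <- lapply(seq_len(n_all), function(i) {
    generate_scene(scene_with(config$scene, config$task, seeds[i]))
  })
  train_scenes <- scenes[seq_len(config$n_train)]
  test_scenes <- scenes[config$n_train + seq_len(config$n_test)]

  tcfg <- config$train
  tcfg$seed <- config$seed
  patches <- combine_patch_sets(lapply(train_scenes, extract_patches, config = tcfg))
  model <- train_classifier(patches, tcfg)

  manifest <- list(
    task = config$task, master_seed = config$seed, ladder = config$ladder,
    training = lapply(seq_along(train_scenes), function(i) {
      list(id = paste0("train", i), seed = seeds[i], codec = "none")
    }),
    testing = lapply(seq_len(config$n_test), function(i) {
      list(id = paste0("test", i), seed = seeds[config$n_train + i],
           codec = "jpeg2000", levels = config$ladder)
    }))

  res_rows <- list()
  feat_rows <- list()
  for (i in seq_len(config$n_test)) {
    sc <- test_scenes[[i]]
    image_id <- paste0("test", i)
    ladder_res <- compress_psnr_ladder(sc$image, config$ladder,
                                       tol = config$psnr_tol, best_effort = TRUE)
    for (li in seq_along(config$ladder)) {
      lvl <- config$ladder[li]
      enc <- ladder_res[[li]]
      map <- predict_probability_map(model, enc$decoded)
      met <- evaluate_map(config, sc, map)
      res_rows[[length(res_rows) + 1L]] <- mutate(
        met, image = image_id, codec = "jpeg2000", target_psnr = lvl,
        achieved_psnr = enc$record$achieved_psnr,
        ratio = enc$record$ratio,
        compressed_bytes = enc$record$compressed_bytes,
        converged = enc$record$converged)
      if (config$task == "nuclei") {
        seg <- label_objects(binarize_map(map, config$pixel_threshold),
                             min_area = config$min_area)
        ft <- compute_features(seg$labels, link_radius = config$link_radius)
        ft$level <- lvl
        ft$image <- image_id
        ft$achieved_psnr <- enc$record$achieved_psnr
        feat_rows[[length(feat_rows) + 1L]] <- ft
      }
    }
  }
  results <- select(bind_rows(res_rows), "image", "codec", "target_psnr",
                    "achieved_psnr", "ratio", "compressed_bytes", "converged",
                    "metric", "value")
  features <- if (length(feat_rows)) bind_rows(feat_rows) else NULL
  stability <- if (!is.null(features)) stability_matrix(features, 100) else NULL

  out <- structure(list(results = results, features = features,
                        stability = stability, model = model,
                        manifest = manifest, config = config),
                   class = "sweep_result")
  out$curves <- summarize_curves(out)
  if (!is.null(config$out_dir)) write_sweep_outputs(out, config$out_dir)
  out
}

#' Per-level summary curves of a sweep
#'
#' Mean and sd of each metric per ladder level, with mean achieved PSNR and
#' compression ratio, plus the Spearman correlation between achieved PSNR and
#' ratio over all (image, level) rows.
#'
#' @param result A [run_sweep()] result.
#' @return Tibble with one row per (metric, level); the Spearman correlation
#'   is attached as attribute `spearman_psnr_ratio`.
#' @export
summarize_curves <- function(result) {
  r <- result$results
  if (length(unique(r$target_psnr)) < 2L) {
    abort_param("at least 2 ladder levels are needed to summarise curves.")
  }
  curves <- summarise(group_by(r, .data$metric, .data$target_psnr),
                      mean_value = mean(.data$value, na.rm = TRUE),
                      sd_value = sd_pop(.data$value),
                      mean_achieved_psnr = mean(.data$achieved_psnr),
                      mean_ratio = mean(.data$ratio),
                      .groups = "drop")
  one <- r[r$metric == r$metric[1], ]
  attr(curves, "spearman_psnr_ratio") <-
    stats::cor(one$achieved_psnr, one$ratio, method = "spearman")
  curves
}

write_sweep_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$results, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(result$curves), file.path(out_dir, "curves.csv"),
                   row.names = FALSE)
  if (!is.null(result$features)) {
    utils::write.csv(result$features, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    stab <- tidy.stability_matrix(result$stability)
    utils::write.csv(stab, file.path(out_dir, "stability.csv"), row.names = FALSE)
    grDevices::png(file.path(out_dir, "stability_heatmap.png"),
                   width = 1200, height = 500, res = 120)
    print(autoplot.stability_matrix(result$stability))
    grDevices::dev.off()
  }
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Audit a sweep manifest for protocol fidelity
#'
#' Confirms that no lossy-compressed image entered training: every training
#' entry must carry `codec == "none"`.
#'
#' @param manifest A `sweep_result$manifest`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
audit_clean_training <- function(manifest) {
  codecs <- vapply(manifest$training, `[[`, "", "codec")
  if (any(codecs != "none")) {
    abort("protocol violation: compressed images present in the training set.",
          class = "histocompress_protocol_error")
  }
  invisible(TRUE)
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> task = %s, %d test images x %d levels, seed %d\n",
              x$config$task, x$config$n_test, length(x$config$ladder),
              x$config$seed))
  print(x$curves)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot

#' Tidy the per-(image, level) metric rows of a sweep
#' @param x A `sweep_result`.
#' @param ... Unused.
#' @return The long results tibble.
#' @export
tidy.sweep_result <- function(x, ...) x$results

#' One-row summary of a sweep
#'
#' Reports the clean (lossless) and the most-compressed mean value of each
#' metric and the Spearman correlation between achieved PSNR and ratio.
#'
#' @param x A `sweep_result`.
#' @param ... Unused.
#' @return A one-row tibble per metric.
#' @export
glance.sweep_result <- function(x, ...) {
  cv <- x$curves
  lowest <- min(cv$target_psnr)
  out <- summarise(group_by(cv, .data$metric),
                   clean_value = .data$mean_value[.data$target_psnr == 100],
                   most_compressed_value = .data$mean_value[.data$target_psnr == lowest],
                   .groups = "drop")
  out$spearman_psnr_ratio <- attr(cv, "spearman_psnr_ratio")
  out$task <- x$config$task
  out
}

#' Degradation curves of a sweep
#'
#' Metric means against achieved PSNR (or compression ratio), the standard
#' degradation read-out of the experiment.
#'
#' @param object A `sweep_result`.
#' @param x_axis `"psnr"` or `"ratio"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sweep_result <- function(object, x_axis = c("psnr", "ratio"), ...) {
  x_axis <- match.arg(x_axis)
  cv <- object$curves
  xv <- if (x_axis == "psnr") cv$mean_achieved_psnr else cv$mean_ratio
  df <- mutate(cv, x = xv)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$mean_value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_value - .data$sd_value,
                                        ymax = .data$mean_value + .data$sd_value),
                           width = 0) +
    ggplot2::labs(x = if (x_axis == "psnr") "achieved PSNR (dB)" else
      "compression ratio (compressed / raw bytes)",
      y = "metric value") +
    ggplot2::theme_minimal()
}
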
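tiny_sweep_config <- function(task = "nuclei", seed = 1L, out_dir = NULL) {
  sweep_config(task = task, n_train = 2L, n_test = 1L,
               scene = scene_params(width = 96, height = 96),
               ladder = c(25, 100),
               train = train_config(patch_size = 16L, epochs = 2L,
                                    patches_per_scene = 80L),
               seed = seed, out_dir = out_dir)
}

test_that("a sweep yields one row per image, level and metric", {
  res <- fixture("tiny_sweep", function() run_sweep(tiny_sweep_config()))
  expect_s3_class(res, "sweep_result")
  expect_equal(nrow(res$results), 1 * 2 * 2)  # 1 image x 2 levels x 2 metrics
  expect_true(all(c("pixel_f1", "pixel_auc") %in% res$results$metric))
  expect_true(all(res$results$ratio > 0 & res$results$ratio <= 1))
  expect_equal(nrow(res$features), 2 * 77)
  expect_s3_class(res$stability, "stability_matrix")
  expect_true(all(res$stability$rel_diff[res$stability$levels == 100, ] == 0))
})

test_that("the lossless ladder level reproduces the clean-test metric exactly", {
  res <- fixture("tiny_sweep", function() run_sweep(tiny_sweep_config()))
  seeds <- histocompress:::with_seed(1L, sample.int(1e6, 3))
  sc <- generate_scene(histocompress:::scene_with(res$config$scene, "nuclei",
                                                  seeds[3]))
  map <- predict_probability_map(res$model, sc$image)
  clean_f1 <- pixel_f1(binarize_map(map, 0.5), scene_truth_mask(sc))
  got <- res$results$value[res$results$metric == "pixel_f1" &
                             res$results$target_psnr == 100]
  expect_equal(got, clean_f1)
})

test_that("sweeps are reproducible and auditable end to end", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- run_sweep(tiny_sweep_config(seed = 4L, out_dir = d1))
  r2 <- run_sweep(tiny_sweep_config(seed = 4L, out_dir = d2))
  expect_identical(readLines(file.path(d1, "metrics.csv")),
                   readLines(file.path(d2, "metrics.csv")))
  expect_identical(readLines(file.path(d1, "features.csv")),
                   readLines(file.path(d2, "features.csv")))
  expect_identical(readLines(file.path(d1, "stability.csv")),
                   readLines(file.path(d2, "stability.csv")))
  expect_true(file.exists(file.path(d1, "manifest.json")))
  expect_true(file.exists(file.path(d1, "stability_heatmap.png")))
  expect_true(audit_clean_training(r1$manifest))
  bad <- r1$manifest
  bad$training[[1]]$codec <- "jpeg2000"
  expect_error(audit_clean_training(bad), class = "histocompress_protocol_error")
})

test_that("summaries, tidiers and plots expose the sweep results", {
  res <- fixture("tiny_sweep", function() run_sweep(tiny_sweep_config()))
  cv <- res$curves
  expect_true(all(c("metric", "target_psnr", "mean_value", "mean_ratio") %in%
                    names(cv)))
  expect_lt(cv$mean_ratio[cv$target_psnr == 100][1], 1)
  expect_equal(tidy(res), res$results)
  g <- glance(res)
  expect_equal(nrow(g), 2)
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(autoplot(res$stability), "ggplot")
  expect_s3_class(tidy(res$stability), "tbl_df")
})

test_that("detection sweeps run the lymphocyte pipeline", {
  res <- fixture("tiny_lymph_sweep", function() {
    run_sweep(tiny_sweep_config(task = "lymphocyte", seed = 2L))
  })
  expect_equal(unique(res$results$metric), "detection_f1")
  expect_true(all(res$results$value >= 0 & res$results$value <= 1))
  expect_null(res$stability)
})
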
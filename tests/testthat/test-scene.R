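test_that("scene generation is deterministic and label bookkeeping is consistent", {
  p <- small_params(seed = 11)
  a <- generate_scene(p)
  b <- generate_scene(p)
  expect_identical(a$image, b$image)
  expect_identical(a$label_mask, b$label_mask)
  expect_identical(a$centers, b$centers)

  K <- max(a$label_mask)
  expect_gt(K, 0)
  expect_identical(sort(unique(as.vector(a$label_mask[a$label_mask > 0]))),
                   seq_len(K))
  # nuclei task: one centre per label id, centre = centroid of its pixels
  targets <- a$centers[a$centers$class == "target", ]
  expect_equal(nrow(targets), K)
  H <- nrow(a$label_mask)
  for (k in sample(K, min(K, 5))) {
    px <- which(a$label_mask == k)
    expect_equal(targets$row[k], mean((px - 1) %% H + 1))
    expect_equal(targets$col[k], mean((px - 1) %/% H + 1))
  }
  expect_true(all(a$centers$row >= 1 & a$centers$row <= p$height))
  expect_true(all(a$centers$col >= 1 & a$centers$col <= p$width))
  expect_true(max(a$image) <= 255 && min(a$image) >= 0)
})

test_that("zero density gives an empty scene; overcrowding is rejected", {
  sc <- generate_scene(small_params(seed = 1, cell_density = 0, clutter_density = 0))
  expect_equal(max(sc$label_mask), 0)
  expect_equal(nrow(sc$centers), 0)
  expect_error(
    generate_scene(scene_params(width = 64, height = 64, cell_density = 60,
                                nucleus_radius_mean = 10, seed = 1)),
    class = "histocompress_overcrowding_error")
})

test_that("object count follows the Poisson law of the density parameter", {
  # 256 x 256 at density 8 -> mean 8 * 256^2 / 1e4 = 52.4; check the
  # mean over 100 seeds against the Poisson standard error.
  lambda <- 8 * 256^2 / 1e4
  counts <- vapply(1:100, function(s) {
    sc <- generate_scene(scene_params(width = 256, height = 256,
                                      cell_density = 8, clutter_density = 0,
                                      texture_sd = 0, noise_sd = 0,
                                      illumination_sd = 0, seed = s))
    max(sc$label_mask)
  }, numeric(1))
  se <- sqrt(lambda / 100)
  expect_lt(abs(mean(counts) - lambda), 3 * se)
})

test_that("rendered area matches the generating ellipse area for isolated nuclei", {
  # sd 0 and eccentricity 0 make every ellipse a disk of the mean radius, so
  # pixel area should be within 15% of pi * r^2
  sc <- generate_scene(scene_params(width = 128, height = 128, cell_density = 3,
                                    nucleus_radius_mean = 8,
                                    nucleus_radius_sd = 0,
                                    eccentricity_range = c(0, 0),
                                    clutter_density = 0, seed = 5))
  K <- max(sc$label_mask)
  expect_gt(K, 0)
  areas <- tabulate(sc$label_mask[sc$label_mask > 0], nbins = K)
  overlap_free <- function(k) {
    ct <- sc$centers[k, ]
    others <- sc$centers[-k, ]
    nrow(others) == 0 ||
      min(sqrt((others$row - ct$row)^2 + (others$col - ct$col)^2)) > 16
  }
  for (k in seq_len(K)) {
    if (overlap_free(k)) {
      expect_lt(abs(areas[k] - pi * 64) / (pi * 64), 0.15)
    }
  }
})

test_that("region task produces a connected region near the requested fraction", {
  p <- scene_params(width = 128, height = 128, task = "region",
                    region_fraction = 0.3, seed = 21)
  sc <- generate_scene(p)
  frac <- mean(sc$region_mask)
  expect_lt(abs(frac - 0.3) / 0.3, 0.2)
  lab <- histocompress:::label_connected(sc$region_mask)
  expect_equal(max(lab), 1)  # single connected component
})

test_that("lymphocyte task annotates both target and distractor centres", {
  sc <- generate_scene(small_params(seed = 31, task = "lymphocyte"))
  expect_setequal(unique(sc$centers$class), c("target", "distractor"))
  # labelled objects are exactly the targets
  expect_equal(max(sc$label_mask),
               sum(sc$centers$class == "target"))
})

test_that("invalid scene parameters are rejected", {
  expect_error(scene_params(width = 32), class = "histocompress_parameter_error")
  expect_error(scene_params(eccentricity_range = c(0, 1)),
               class = "histocompress_parameter_error")
  expect_error(scene_params(region_fraction = 1.2),
               class = "histocompress_parameter_error")
  expect_error(scene_params(stain_fg = c(300, 0, 0)),
               class = "histocompress_parameter_error")
})
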
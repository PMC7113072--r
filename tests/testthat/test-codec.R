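test_that("PSNR follows its closed form, is symmetric, and caps at 100", {
  img <- flat_image()
  expect_equal(compute_psnr(img, img), 100)
  a <- array(0L, c(8, 8, 3)); b <- array(255L, c(8, 8, 3))
  expect_equal(compute_psnr(a, b), 0)
  # single differing value of 10 in one pixel/channel of a 1x1 image:
  # MSE over the 3 channels is 100/3 -> hand evaluation on a pure 1-channel
  # equivalent: constructed so MSE = 100 exactly
  r <- array(100L, c(1, 1, 3)); dg <- array(c(110L, 90L, 110L), c(1, 1, 3))
  expect_equal(compute_psnr(r, dg), 10 * log10(65025 / 100))
  x <- generate_scene(small_params(seed = 2))$image
  y <- encode_jpeg(x, 40L)$decoded
  expect_equal(compute_psnr(x, y), compute_psnr(y, x))
  expect_error(compute_psnr(x, flat_image()), class = "histocompress_dimension_error")
})

test_that("JPEG quality controls fidelity and size monotonically", {
  img <- generate_scene(small_params(seed = 3))$image
  hi <- encode_jpeg(img, 100L)
  lo <- encode_jpeg(img, 1L)
  expect_gt(hi$record$achieved_psnr, lo$record$achieved_psnr)
  qs <- c(1L, seq(5L, 100L, by = 5L))
  bytes <- vapply(qs, function(q) encode_jpeg(img, q)$record$compressed_bytes,
                  numeric(1))
  # non-decreasing up to 2% codec noise
  expect_true(all(diff(bytes) >= -0.02 * bytes[-length(bytes)]))
  flat <- encode_jpeg(flat_image(200L), 50L)
  expect_gte(flat$record$achieved_psnr, 45)
  expect_error(encode_jpeg(img, 0L), class = "histocompress_parameter_error")
})

test_that("lossless JPEG2000 is bit-exact and compresses", {
  img <- generate_scene(small_params(seed = 4))$image
  res <- encode_jpeg2000_lossless(img)
  expect_identical(res$decoded, img)
  expect_equal(res$record$achieved_psnr, 100)
  expect_lt(res$record$ratio, 1)
  flat <- encode_jpeg2000_lossless(flat_image(180L, 96L, 96L))
  expect_lt(flat$record$ratio, 0.05)
})

test_that("PSNR targeting attains the figure ladder within tolerance", {
  img <- generate_scene(scene_params(width = 128, height = 128, seed = 5))$image
  lad <- compress_psnr_ladder(img, c(20, 25, 40), tol = 0.5)
  for (r in lad) {
    expect_lte(abs(r$record$achieved_psnr - r$record$control), 0.5)
    expect_lte(r$iterations, 30)
  }
  # rate-distortion ordering
  expect_lt(lad[["psnr25"]]$record$ratio, lad[["psnr40"]]$record$ratio)
  # lossless boundary delegates
  full <- compress_to_target_psnr(img, 100)
  expect_identical(full$decoded, img)
  expect_error(compress_to_target_psnr(img, 10), class = "histocompress_parameter_error")
  # an unreachable target errors unless best_effort
  expect_error(compress_to_target_psnr(flat_image(100L, 96L, 96L), 18),
               class = "histocompress_convergence_error")
})

test_that("byte-budget compression respects the ratio bound", {
  img <- generate_scene(scene_params(width = 128, height = 128, seed = 6))$image
  res <- compress_to_target_ratio(img, 0.15)
  expect_lte(res$record$ratio, 0.15)
  expect_gt(res$record$ratio, 0.01)  # uses most of the budget
})

test_that("compressed bytes increase with achieved PSNR on a fixed image", {
  img <- generate_scene(scene_params(width = 128, height = 128, seed = 7))$image
  lad <- compress_psnr_ladder(img, c(20, 25, 30, 35, 40, 100), best_effort = TRUE)
  recs <- dplyr::bind_rows(lapply(lad, function(x) x$record))
  recs <- recs[order(recs$achieved_psnr), ]
  expect_true(all(diff(recs$compressed_bytes) >= 0))
})
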
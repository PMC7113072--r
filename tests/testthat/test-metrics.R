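test_that("pixel F1 matches hand-counted fixtures", {
  gt <- matrix(FALSE, 4, 5)
  gt[1:2, 1:5] <- TRUE        # 10 positive pixels
  pred <- matrix(FALSE, 4, 5)
  pred[1:2, 1:4] <- TRUE      # 8 TP, 2 FN so far
  pred[3, 1:2] <- TRUE        # 2 FP
  expect_equal(pixel_f1(pred, gt), 16 / 20)
  expect_equal(pixel_f1(gt, gt), 1)
  expect_equal(pixel_f1(matrix(FALSE, 4, 5), gt), 0)
  expect_warning(v <- pixel_f1(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)))
  expect_equal(v, 1)
  expect_error(pixel_f1(gt, matrix(TRUE, 2, 2)),
               class = "histocompress_dimension_error")
})

test_that("pixel AUC equals exhaustive pair counting", {
  # worked example: labels (1,1,0,0), scores (.9,.4,.6,.2) -> 3/4
  m <- matrix(c(0.9, 0.4, 0.6, 0.2), 1, 4)
  g <- matrix(c(TRUE, TRUE, FALSE, FALSE), 1, 4)
  expect_equal(pixel_auc(m, g), 0.75)
  expect_equal(pixel_auc(matrix(c(1, 0.9, 0.5, 0.2), 2, 2),
                         matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)), 1)
  expect_equal(pixel_auc(matrix(0.5, 2, 3),
                         matrix(c(TRUE, FALSE), 2, 3)), 0.5)
  expect_error(pixel_auc(matrix(0.5, 2, 2), matrix(TRUE, 2, 2)),
               class = "histocompress_undefined_metric_error")
  # 100 random instances, n <= 50 pixels, ties included
  set.seed(101)
  for (i in 1:100) {
    n <- sample(4:50, 1)
    labels <- sample(c(0, 1), n, replace = TRUE)
    if (all(labels == 0)) labels[1] <- 1
    if (all(labels == 1)) labels[1] <- 0
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # frequent ties
    expect_equal(pixel_auc(matrix(scores, 1, n), matrix(labels > 0, 1, n)),
                 pairwise_auc(scores, labels))
  }
})

test_that("detection matching equals brute-force assignment enumeration", {
  pts <- function(n, lim = 30) tibble::tibble(row = runif(n, 1, lim),
                                              col = runif(n, 1, lim))
  # worked example: 2 gt, 1 pred within radius of both -> matches the nearer
  pred <- tibble::tibble(row = 10, col = 10)
  gt <- tibble::tibble(row = c(10, 10), col = c(12, 16))
  m <- match_detections(pred, gt, radius = 8)
  expect_equal(m$tp, 1); expect_equal(m$fn, 1); expect_equal(m$fp, 0)
  expect_equal(m$pairs$gt_index, 1)
  # radius cutoff
  m2 <- match_detections(tibble::tibble(row = 1, col = 1),
                         tibble::tibble(row = 1, col = 7), radius = 5)
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(0, 1, 1))
  # identity
  m3 <- match_detections(gt, gt, radius = 2)
  expect_equal(c(m3$tp, m3$fp, m3$fn), c(2, 0, 0))
  # 200 random instances vs the oracle (cardinality and total distance)
  set.seed(202)
  for (i in 1:200) {
    np <- sample(0:7, 1); ng <- sample(0:7, 1)
    pred <- pts(np); gt <- pts(ng)
    radius <- runif(1, 3, 15)
    got <- match_detections(pred, gt, radius)
    oracle <- brute_force_match(pred, gt, radius)
    expect_equal(got$tp, oracle$tp)
    expect_equal(sum(got$pairs$distance), oracle$dist, tolerance = 1e-9)
    expect_true(all(got$pairs$distance <= radius))
    expect_equal(got$tp + got$fp, np)
    expect_equal(got$tp + got$fn, ng)
  }
})

test_that("matching is invariant to point ordering", {
  set.seed(9)
  pred <- tibble::tibble(row = runif(6, 1, 20), col = runif(6, 1, 20))
  gt <- tibble::tibble(row = runif(5, 1, 20), col = runif(5, 1, 20))
  a <- match_detections(pred, gt, 6)
  b <- match_detections(pred[sample(6), ], gt[sample(5), ], 6)
  expect_equal(a$tp, b$tp)
  expect_equal(sum(a$pairs$distance), sum(b$pairs$distance))
})

test_that("detection F1 follows its formula including empty edge cases", {
  mk <- function(tp, fp, fn) structure(list(tp = tp, fp = fp, fn = fn,
                                            pairs = NULL),
                                       class = "detection_match")
  expect_equal(detection_f1(mk(1, 0, 1)), 2 / 3)
  expect_equal(detection_f1(mk(0, 2, 3)), 0)
  expect_equal(detection_f1(mk(10, 0, 0)), 1)
  expect_equal(detection_f1(mk(0, 0, 0)), 1)
})
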
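test_that("object labelling is 8-connected with area filtering", {
  m <- matrix(0, 8, 8)
  m[1:2, 1:2] <- 1
  m[3:4, 3:4] <- 1           # touches the first square only diagonally
  lo <- label_objects(m > 0)
  expect_equal(max(lo$labels), 1)  # one object under 8-connectivity
  m2 <- matrix(0, 9, 9)
  m2[1:3, 1:3] <- 1; m2[6:8, 6:8] <- 1
  lo2 <- label_objects(m2 > 0)
  expect_equal(max(lo2$labels), 2)
  expect_equal(lo2$centroids$row, c(2, 7))
  expect_equal(lo2$centroids$col, c(2, 7))
  expect_equal(max(label_objects(m2 > 0, min_area = 10)$labels), 0)
  expect_equal(nrow(label_objects(matrix(FALSE, 4, 4))$centroids), 0)
})

test_that("Voronoi areas are exact on a unit lattice and scale quadratically", {
  pts <- expand.grid(row = 1:6 + 10, col = 1:6 + 10)
  gm <- graph_measures(tibble::as_tibble(pts), bounds = c(40, 40))
  # interior cells of a unit lattice are unit squares; with the window far
  # away, cells 8..28 (interior) have area exactly 1
  interior <- with(pts, row > 11 & row < 16 & col > 11 & col < 16)
  expect_true(all(abs(gm$voronoi$area[interior] - 1) < 1e-9))
  # MST has n - 1 edges
  expect_equal(length(gm$mst$edge_length), nrow(pts) - 1)
  # doubling coordinates doubles MST mean edge and quadruples Voronoi area
  pts2 <- pts * 2
  gm2 <- graph_measures(tibble::as_tibble(pts2), bounds = c(80, 80))
  expect_equal(mean(gm2$mst$edge_length), 2 * mean(gm$mst$edge_length))
  expect_equal(mean(gm2$voronoi$area[interior]),
               4 * mean(gm$voronoi$area[interior]))
})

test_that("collinear centroids keep the MST but skip the tessellation families", {
  pts <- tibble::tibble(row = c(5, 5, 5), col = c(0, 1, 3) + 5)
  expect_warning(gm <- graph_measures(pts, bounds = c(10, 12)),
                 class = "histocompress_degenerate_geometry_warning")
  expect_equal(sort(gm$mst$edge_length), c(1, 2))
  expect_equal(mean(gm$mst$edge_length), 1.5)
  expect_length(gm$voronoi$area, 0)
  expect_error(graph_measures(pts[1, ], bounds = c(10, 10)),
               class = "histocompress_degenerate_geometry_error")
})

test_that("nuclear morphology distinguishes disks from elongated objects", {
  mk_ellipse <- function(a, b, H = 41) {
    m <- matrix(0L, H, H)
    c0 <- (H + 1) / 2
    for (r in 1:H) for (cc in 1:H) {
      if (((r - c0) / a)^2 + ((cc - c0) / b)^2 <= 1) m[r, cc] <- 1L
    }
    m
  }
  disk <- mk_ellipse(12, 12)
  lo <- label_objects(disk > 0)
  nm <- nuclear_measures(lo$labels, lo$centroids)
  expect_lt(nm$eccentricity[1], 0.15)
  expect_gt(nm$compactness[1], 0.85)
  expect_lt(nm$compactness[1], 1.15)
  # 10x2 is more eccentric than 5x4
  long <- nuclear_measures(label_objects(mk_ellipse(10, 2))$labels,
                           label_objects(mk_ellipse(10, 2))$centroids)
  squat <- nuclear_measures(label_objects(mk_ellipse(5, 4))$labels,
                            label_objects(mk_ellipse(5, 4))$centroids)
  expect_gt(long$eccentricity[1], squat$eccentricity[1])
  # two objects: 1-NN distances are mutual and equal
  two <- matrix(0L, 20, 20); two[5, 5] <- 1L; two[15, 15] <- 1L
  lo2 <- label_objects(two > 0)
  nm2 <- nuclear_measures(lo2$labels, lo2$centroids)
  expect_equal(nm2$knn1[1], nm2$knn1[2])
  expect_null(nm2$knn3)
  expect_equal(nm2$count, 2)
})

test_that("subgraph clustering follows the link radius", {
  # 4 nodes on a 10 px square, link 15 -> one complete-graph cluster
  sq <- tibble::tibble(row = c(0, 0, 10, 10), col = c(0, 10, 0, 10))
  sm <- subgraph_measures(sq, link_radius = 15)
  expect_equal(sm$cluster_count, 1)
  expect_equal(sm$edges, 6)
  expect_equal(sm$degree, 3)
  expect_equal(sm$clustered_fraction, 1)
  # two tight triads 100 px apart
  triad <- function(oy, ox) tibble::tibble(row = oy + c(0, 8, 0),
                                           col = ox + c(0, 0, 8))
  two <- dplyr::bind_rows(triad(0, 0), triad(100, 100))
  sm2 <- subgraph_measures(two, link_radius = 20)
  expect_equal(sm2$cluster_count, 2)
  expect_equal(sm2$nodes, c(3, 3))
  expect_equal(length(sm2$intercluster_dist), 2)
  # all points farther than the link radius -> no clusters
  sparse <- tibble::tibble(row = c(0, 50, 100), col = c(0, 50, 100))
  expect_equal(subgraph_measures(sparse, link_radius = 10)$cluster_count, 0)
})

test_that("summary statistics follow their closed forms", {
  s <- summarize_measures(c(2, 2, 2))
  expect_equal(unname(s["sd"]), 0)
  expect_equal(unname(s["disorder"]), 0)
  expect_equal(unname(s["minmax"]), 1)
  s2 <- summarize_measures(c(1, 3))
  expect_equal(unname(s2["mean"]), 2)
  expect_equal(unname(s2["sd"]), 1)               # population sd
  expect_equal(unname(s2["disorder"]), 1 / 3)
  set.seed(3)
  v <- runif(20)
  expect_equal(summarize_measures(v)["mean"], summarize_measures(sample(v))["mean"])
  expect_true(all(is.na(summarize_measures(numeric(0)))))
})

test_that("the feature ledger has exactly 77 statistics partitioned 12/8/4/27/26", {
  led <- feature_families()
  expect_equal(nrow(led), 77)
  expect_equal(as.vector(table(led$family)[c("voronoi", "delaunay", "mst",
                                             "nuclear", "subgraph")]),
               c(12, 8, 4, 27, 26))
  expect_false(any(duplicated(led$name)))
  sc <- generate_scene(small_params(seed = 13))
  ft <- compute_features(sc$label_mask)
  expect_equal(nrow(ft), 77)
  expect_identical(ft$name, led$name)
})

test_that("stability matrices normalise per feature and zero the lossless row", {
  mk_tab <- function(level, image, values) {
    led <- feature_families()
    tibble::tibble(level = level, image = image, name = led$name,
                   family = led$family, value = values)
  }
  led_n <- 77
  base <- rnorm(led_n)
  tabs <- dplyr::bind_rows(
    mk_tab(100, "a", base), mk_tab(30, "a", base), mk_tab(20, "a", base))
  st <- stability_matrix(tabs, 100)
  expect_true(all(st$rel_diff == 0))             # identical tables
  # single feature with raw diffs {0, 1, 2} over levels -> rel {0, 0.5, 1}
  tabs2 <- dplyr::bind_rows(
    mk_tab(100, "a", base),
    mk_tab(30, "a", base + c(1, rep(0, 76))),
    mk_tab(20, "a", base + c(2, rep(0, 76))))
  st2 <- stability_matrix(tabs2, 100)
  expect_equal(unname(st2$raw_diff[, 1]), c(2, 1, 0)[order(c(20, 30, 100))])
  expect_equal(unname(st2$rel_diff[st2$levels == 20, 1]), 1)
  expect_equal(unname(st2$rel_diff[st2$levels == 30, 1]), 0.5)
  expect_true(all(st2$rel_diff[st2$levels == 100, ] == 0))
  # random property: every nonzero column attains max exactly 1
  set.seed(11)
  tabs3 <- dplyr::bind_rows(lapply(c(100, 40, 25, 18), function(L) {
    dplyr::bind_rows(mk_tab(L, "a", rnorm(77)), mk_tab(L, "b", rnorm(77)))
  }))
  st3 <- stability_matrix(tabs3, 100)
  cm <- apply(st3$rel_diff, 2, max)
  expect_true(all(abs(cm - 1) < 1e-12 | cm == 0))
  expect_true(all(st3$rel_diff >= 0 & st3$rel_diff <= 1))
  # vanished features read as maximal instability
  vals_na <- base; vals_na[2] <- NA
  st4 <- stability_matrix(dplyr::bind_rows(mk_tab(100, "a", base),
                                           mk_tab(20, "a", vals_na)), 100)
  expect_equal(unname(st4$rel_diff[st4$levels == 20, 2]), 1)
  expect_error(stability_matrix(tabs[tabs$level != 100, ], 100),
               class = "histocompress_schema_error")
})
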
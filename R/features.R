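#' Label connected objects in a binary mask
#'
#' 8-connected component labelling; components smaller than `min_area` px^2
#' are removed and the rest renumbered 1..K in raster order. Centroids are
#' area centroids.
#'
#' @param mask Logical/binary matrix.
#' @param min_area Minimum component area in px^2 (>= 1).
#' @return List with `labels` (integer matrix) and `centroids` (tibble
#'   `label`, `row`, `col`, `area`).
#' @export
label_objects <- function(mask, min_area = 1) {
  if (min_area < 1) abort_param("`min_area` must be >= 1.")
  lab <- label_connected(mask)
  K <- max(lab)
  if (K == 0L) {
    return(list(labels = lab,
                centroids = tibble(label = integer(0), row = numeric(0),
                                   col = numeric(0), area = numeric(0))))
  }
  sizes <- tabulate(lab[lab > 0L], nbins = K)
  keep <- which(sizes >= min_area)
  relabel <- integer(K)
  relabel[keep] <- seq_along(keep)
  lab[lab > 0L] <- relabel[lab[lab > 0L]]
  if (!length(keep)) {
    return(list(labels = lab,
                centroids = tibble(label = integer(0), row = numeric(0),
                                   col = numeric(0), area = numeric(0))))
  }
  idx <- which(lab > 0L)
  lv <- lab[idx]
  H <- nrow(mask)
  rr <- (idx - 1L) %% H + 1L
  cc <- (idx - 1L) %/% H + 1L
  cent <- tibble(label = sort(unique(lv)),
                 row = as.numeric(tapply(rr, lv, mean)),
                 col = as.numeric(tapply(cc, lv, mean)),
                 area = as.numeric(tabulate(lv)))
  list(labels = lab, centroids = cent)
}

#' Voronoi, Delaunay and MST measures over cell centroids
#'
#' Voronoi cells are clipped to the image bounds; per cell the area, perimeter
#' and chord (maximum vertex-to-vertex distance) are recorded. Delaunay
#' triangles contribute side lengths and areas. The Euclidean minimum spanning
#' tree over the centroids (a subgraph of the Delaunay graph) contributes edge
#' lengths.
#'
#' @param centroids Tibble/data frame with `row`, `col`.
#' @param bounds `c(H, W)` image bounds used as the Voronoi clipping window.
#' @return List of measure vectors: `voronoi` (`area`, `perimeter`, `chord`),
#'   `delaunay` (`side_length`, `triangle_area`), `mst` (`edge_length`).
#' @export
graph_measures <- function(centroids, bounds) {
  n <- nrow(centroids)
  x <- centroids$col
  y <- centroids$row
  out <- list(voronoi = list(area = numeric(0), perimeter = numeric(0),
                             chord = numeric(0)),
              delaunay = list(side_length = numeric(0), triangle_area = numeric(0)),
              mst = list(edge_length = numeric(0)))
  if (n < 2L) {
    abort("at least 2 centroids are needed for any graph family (mst).",
          class = "histocompress_degenerate_geometry_error")
  }
  # MST on the full Euclidean graph == MST restricted to Delaunay edges,
  # and it also covers collinear configurations where Delaunay fails.
  dmat <- as.matrix(stats::dist(cbind(y, x)))
  adj <- tryCatch(unclass(ape::mst(stats::dist(cbind(y, x)))),
                  error = function(e) NULL)
  if (is.null(adj)) {
    abort("MST computation failed on degenerate input.",
          class = "histocompress_degenerate_geometry_error")
  }
  out$mst$edge_length <- dmat[which(upper.tri(adj) & adj == 1)]

  dd <- NULL
  if (n >= 4L) {
    dd <- tryCatch(
      deldir::deldir(x, y, rw = c(0, bounds[2], 0, bounds[1]),
                     suppressMsge = TRUE),
      error = function(e) NULL)
  }
  if (is.null(dd)) {
    # collinear or too-few points: tessellation undefined, MST still valid
    warn("fewer than 4 non-degenerate centroids; families skipped: voronoi, delaunay.",
         class = "histocompress_degenerate_geometry_warning")
    return(out)
  }
  tl <- deldir::tile.list(dd)
  out$voronoi$area <- vapply(tl, function(t) shoelace_area(t$x, t$y), numeric(1))
  out$voronoi$perimeter <- vapply(tl, function(t) polygon_perimeter(t$x, t$y), numeric(1))
  out$voronoi$chord <- vapply(tl, function(t) max_pairwise_dist(t$x, t$y), numeric(1))
  tr <- deldir::triang.list(dd)
  if (length(tr)) {
    sides <- unlist(lapply(tr, function(t) {
      xs <- t$x; ys <- t$y
      c(sqrt((xs[1] - xs[2])^2 + (ys[1] - ys[2])^2),
        sqrt((xs[2] - xs[3])^2 + (ys[2] - ys[3])^2),
        sqrt((xs[3] - xs[1])^2 + (ys[3] - ys[1])^2))
    }))
    areas <- vapply(tr, function(t) shoelace_area(t$x, t$y), numeric(1))
    out$delaunay$side_length <- sides
    out$delaunay$triangle_area <- areas
  }
  out
}

# Staircase boundary length of one object's pixel set, corrected by pi/4 so a
# digital disk recovers ~2*pi*r (digital staircase perimeter of a convex set
# is 2*(width+height)).
object_perimeter <- function(rows, cols) {
  r0 <- min(rows) - 1L; c0 <- min(cols) - 1L
  h <- max(rows) - r0 + 1L; w <- max(cols) - c0 + 1L
  m <- matrix(FALSE, h + 2L, w + 2L)
  m[cbind(rows - r0 + 1L, cols - c0 + 1L)] <- TRUE
  core <- m[2:(h + 1L), 2:(w + 1L)]
  edges <- sum(core & !m[1:h, 2:(w + 1L)]) + sum(core & !m[3:(h + 2L), 2:(w + 1L)]) +
    sum(core & !m[2:(h + 1L), 1:w]) + sum(core & !m[2:(h + 1L), 3:(w + 2L)])
  edges * pi / 4
}

#' Nuclear morphology and neighbourhood measures
#'
#' Per object: pixel area, eccentricity from second central moments
#' (`sqrt(1 - lambda2/lambda1)`), and compactness `4*pi*A/P^2` with a
#' staircase-corrected perimeter. Per centroid: distance to the k-nearest
#' neighbours for k in {1, 3, 5, 7} (recorded as missing when fewer objects
#' exist). Scalars: objects per 10^4 px^2, object count, fraction of image
#' area occupied.
#'
#' @param labels Integer label matrix (0 background).
#' @param centroids Centroid tibble from [label_objects()].
#' @return List of measure vectors and scalars.
#' @export
nuclear_measures <- function(labels, centroids) {
  K <- max(labels)
  if (K < 1L) {
    abort("at least one object is required.",
          class = "histocompress_degenerate_geometry_error")
  }
  H <- nrow(labels); W <- ncol(labels)
  idx <- which(labels > 0L)
  lv <- labels[idx]
  rr <- (idx - 1L) %% H + 1L
  cc <- (idx - 1L) %/% H + 1L
  area <- ecc <- comp <- numeric(K)
  for (k in seq_len(K)) {
    sel <- lv == k
    r <- rr[sel]; cl <- cc[sel]
    area[k] <- length(r)
    mu20 <- mean((r - mean(r))^2) + 1 / 12  # pixel extent regularisation
    mu02 <- mean((cl - mean(cl))^2) + 1 / 12
    mu11 <- mean((r - mean(r)) * (cl - mean(cl)))
    tr2 <- (mu20 + mu02) / 2
    det_sqrt <- sqrt(max(((mu20 - mu02) / 2)^2 + mu11^2, 0))
    l1 <- tr2 + det_sqrt; l2 <- max(tr2 - det_sqrt, 0)
    ecc[k] <- if (l1 > 0) sqrt(max(1 - l2 / l1, 0)) else 0
    P <- object_perimeter(r, cl)
    comp[k] <- if (P > 0) 4 * pi * area[k] / P^2 else NA_real_
  }
  coords <- as.matrix(centroids[, c("row", "col")])
  knn <- list(knn1 = NULL, knn3 = NULL, knn5 = NULL, knn7 = NULL)
  kmax <- min(7L, K - 1L)
  if (kmax >= 1L) {
    nn <- FNN::get.knn(coords, k = kmax)$nn.dist
    for (k in c(1L, 3L, 5L, 7L)) {
      knn[[paste0("knn", k)]] <- if (k <= kmax) nn[, k] else NULL
    }
  }
  list(area = area, eccentricity = ecc, compactness = comp,
       knn1 = knn$knn1, knn3 = knn$knn3, knn5 = knn$knn5, knn7 = knn$knn7,
       density = K / (H * W) * 1e4, count = K,
       area_fraction = length(idx) / (H * W))
}

#' Cell-cluster subgraph measures
#'
#' Links centroid pairs within `link_radius` px; connected components with at
#' least 3 nodes are cell clusters. Per cluster: node count, edge count,
#' average degree, graph-hop diameter, convex-hull area, and distance to the
#' nearest other cluster (point-to-point). Scalars: cluster count and the
#' fraction of cells belonging to a cluster.
#'
#' @param centroids Centroid tibble (`row`, `col`).
#' @param link_radius Linking distance in px (> 0).
#' @return List of measure vectors and scalars.
#' @export
subgraph_measures <- function(centroids, link_radius) {
  if (link_radius <= 0) abort_param("`link_radius` must be > 0.")
  n <- nrow(centroids)
  empty <- list(nodes = numeric(0), edges = numeric(0), degree = numeric(0),
                diameter = numeric(0), hull_area = numeric(0),
                intercluster_dist = numeric(0), cluster_count = 0,
                clustered_fraction = if (n > 0) 0 else NA_real_)
  if (n < 3L) return(empty)
  coords <- as.matrix(centroids[, c("row", "col")])
  dmat <- as.matrix(stats::dist(coords))
  adj <- dmat <= link_radius
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  clusters <- which(comp$csize >= 3L)
  if (!length(clusters)) return(empty)
  members <- lapply(clusters, function(ci) which(comp$membership == ci))
  nodes <- vapply(members, length, integer(1))
  edges <- degree <- diam <- hull <- numeric(length(clusters))
  for (i in seq_along(clusters)) {
    sub <- igraph::induced_subgraph(g, members[[i]])
    edges[i] <- igraph::gsize(sub)
    degree[i] <- 2 * edges[i] / nodes[i]
    diam[i] <- igraph::diameter(sub, unconnected = FALSE)
    pts <- coords[members[[i]], , drop = FALSE]
    hp <- grDevices::chull(pts[, 2], pts[, 1])
    hull[i] <- shoelace_area(pts[hp, 2], pts[hp, 1])
  }
  interd <- numeric(0)
  if (length(clusters) >= 2L) {
    interd <- vapply(seq_along(clusters), function(i) {
      others <- unlist(members[-i])
      min(dmat[members[[i]], others])
    }, numeric(1))
  }
  list(nodes = as.numeric(nodes), edges = edges, degree = degree,
       diameter = diam, hull_area = hull, intercluster_dist = interd,
       cluster_count = length(clusters),
       clustered_fraction = sum(nodes) / n)
}

#' First-order summary statistics of a measure list
#'
#' The designated subset of mean, population standard deviation, min/max
#' ratio, and disorder `1 - 1/(1 + sd/mean)` (a bounded coefficient-of-
#' variation transform). Undefined combinations (empty input; `max == 0` for
#' min/max; `mean == 0` for disorder) are recorded as missing, not errors.
#'
#' @param values Numeric vector of raw measures.
#' @param stats Character subset of `c("mean", "sd", "minmax", "disorder")`.
#' @return Named numeric vector.
#' @export
summarize_measures <- function(values, stats = c("mean", "sd", "minmax", "disorder")) {
  values <- values[!is.na(values)]
  out <- stats::setNames(rep(NA_real_, length(stats)), stats)
  if (!length(values)) return(out)
  mu <- mean(values)
  sdv <- sd_pop(values)
  for (s in stats) {
    out[s] <- switch(s,
      mean = mu,
      sd = sdv,
      minmax = if (max(values) == 0) NA_real_ else min(values) / max(values),
      disorder = if (mu == 0) NA_real_ else 1 - 1 / (1 + sdv / mu))
  }
  out
}

# The fixed 77-statistic ledger: family / measure / statistic triples.
feature_ledger <- function() {
  four <- c("mean", "sd", "minmax", "disorder")
  rows <- list()
  add <- function(family, measure, stats) {
    rows[[length(rows) + 1L]] <<- tibble(family = family, measure = measure,
                                         statistic = stats)
  }
  for (m in c("area", "perimeter", "chord")) add("voronoi", m, four)
  for (m in c("side_length", "triangle_area")) add("delaunay", m, four)
  add("mst", "edge_length", four)
  for (m in c("area", "eccentricity", "compactness")) add("nuclear", m, four)
  for (m in c("knn1", "knn3", "knn5", "knn7")) {
    add("nuclear", m, c("mean", "sd", "disorder"))
  }
  for (m in c("density", "count", "area_fraction")) add("nuclear", m, "value")
  for (m in c("nodes", "edges", "degree", "diameter", "hull_area",
              "intercluster_dist")) add("subgraph", m, four)
  for (m in c("cluster_count", "clustered_fraction")) add("subgraph", m, "value")
  ledger <- bind_rows(rows)
  ledger$name <- paste(ledger$family, ledger$measure, ledger$statistic, sep = "_")
  ledger
}

#' The 77 nuclear-architecture feature names and families
#'
#' Fixed ledger partitioned 12/8/4/27/26 over the voronoi / delaunay / mst /
#' nuclear / subgraph families.
#'
#' @return Tibble with `name`, `family`, `measure`, `statistic`.
#' @export
feature_families <- function() {
  feature_ledger()[, c("name", "family", "measure", "statistic")]
}

#' Compute the 77-statistic feature vector for a nuclear segmentation
#'
#' Runs [graph_measures()], [nuclear_measures()] and [subgraph_measures()] on
#' a label mask and summarises each raw measure with its designated
#' first-order statistics. Families whose geometry is degenerate (too few
#' objects) yield missing values rather than errors, so feature tables keep a
#' stable schema across compression levels.
#'
#' @param labels Integer label matrix (e.g. from [label_objects()] on a
#'   thresholded probability map, or a scene's ground-truth `label_mask`).
#' @param link_radius Subgraph linking radius, px. Default 3.5 times a
#'   7 px nucleus radius (just under the percolation point at default density).
#' @return Tibble with `name`, `family`, `value` (77 rows, fixed order).
#' @export
compute_features <- function(labels, link_radius = 3.5 * 7) {
  lo <- label_objects(labels > 0L, min_area = 1)
  cent <- lo$centroids
  bounds <- dim(labels)
  ledger <- feature_ledger()
  gm <- tryCatch(graph_measures(cent, bounds),
                 histocompress_degenerate_geometry_error = function(e) NULL)
  nm <- tryCatch(nuclear_measures(lo$labels, cent),
                 histocompress_degenerate_geometry_error = function(e) NULL)
  sm <- subgraph_measures(cent, link_radius)
  pool <- list(
    voronoi = if (is.null(gm)) list() else gm$voronoi,
    delaunay = if (is.null(gm)) list() else gm$delaunay,
    mst = if (is.null(gm)) list() else gm$mst,
    nuclear = if (is.null(nm)) list() else nm,
    subgraph = list(nodes = sm$nodes, edges = sm$edges, degree = sm$degree,
                    diameter = sm$diameter, hull_area = sm$hull_area,
                    intercluster_dist = sm$intercluster_dist,
                    cluster_count = sm$cluster_count,
                    clustered_fraction = sm$clustered_fraction))
  values <- numeric(nrow(ledger))
  for (i in seq_len(nrow(ledger))) {
    fam <- ledger$family[i]; msr <- ledger$measure[i]; st <- ledger$statistic[i]
    raw <- pool[[fam]][[msr]]
    values[i] <- if (is.null(raw)) {
      NA_real_
    } else if (st == "value") {
      if (length(raw) == 1L) as.numeric(raw) else NA_real_
    } else {
      summarize_measures(raw, st)[[st]]
    }
  }
  tibble(name = ledger$name, family = ledger$family, value = values)
}

#' Stability of features across compression levels
#'
#' For each feature j and level l, the raw difference is
#' `mean over images |f(l, image, j) - f(lossless, image, j)|`; the relative
#' difference normalises each feature column by its maximum raw difference
#' over levels (0/0 defined as 0), so every column lies in `[0, 1]` and the
#' lossless row is identically zero.
#'
#' A feature can exist at the lossless level but vanish under compression
#' (e.g. cell clusters destroyed when the segmentation degrades) or vice
#' versa. Such one-sided missingness is structural, not random: when at least
#' half of the image pairs at a level have the feature on exactly one side,
#' the relative difference for that (level, feature) is set to the maximal
#' instability 1. Pairs missing on both sides carry no information and are
#' dropped.
#'
#' @param tables Tibble with columns `level` (achieved or target PSNR, dB),
#'   `image` (identifier), `name`, `family`, `value` — stacked
#'   [compute_features()] outputs.
#' @param lossless_level The `level` value to difference against (default 100).
#' @return Object of class `stability_matrix`: list with `levels`, `names`,
#'   `families`, `raw_diff` and `rel_diff` (levels x features matrices).
#' @export
stability_matrix <- function(tables, lossless_level = 100) {
  needed <- c("level", "image", "name", "value")
  if (!all(needed %in% names(tables))) {
    abort("`tables` must have columns level, image, name, value.",
          class = "histocompress_schema_error")
  }
  ledger <- feature_ledger()
  if (!all(tables$name %in% ledger$name)) {
    abort("feature names inconsistent with the 77-feature ledger.",
          class = "histocompress_schema_error")
  }
  levels <- sort(unique(tables$level))
  if (!lossless_level %in% levels) {
    abort("lossless level absent from `tables`.",
          class = "histocompress_schema_error")
  }
  nms <- ledger$name
  base <- tables[tables$level == lossless_level, ]
  raw <- matrix(NA_real_, length(levels), length(nms),
                dimnames = list(NULL, nms))
  vanish <- matrix(0, length(levels), length(nms), dimnames = list(NULL, nms))
  for (li in seq_along(levels)) {
    lv <- tables[tables$level == levels[li], ]
    m <- merge(as.data.frame(lv[, c("image", "name", "value")]),
               as.data.frame(base[, c("image", "name", "value")]),
               by = c("image", "name"), suffixes = c("", "_0"))
    m$adiff <- abs(m$value - m$value_0)
    m$one_sided <- xor(is.na(m$value), is.na(m$value_0))
    agg <- tapply(m$adiff, m$name, function(v) {
      v <- v[!is.na(v)]
      if (length(v)) mean(v) else NA_real_
    })
    raw[li, names(agg)] <- as.numeric(agg)
    vfrac <- tapply(m$one_sided, m$name, mean)
    vanish[li, names(vfrac)] <- as.numeric(vfrac)
  }
  raw[levels == lossless_level, ] <- 0
  colmax <- apply(raw, 2, function(v) max(v, na.rm = TRUE))
  colmax[!is.finite(colmax)] <- 0
  rel <- sweep(raw, 2, ifelse(colmax > 0, colmax, 1), "/")
  rel[is.na(rel)] <- 0
  rel[raw == 0 & !is.na(raw)] <- 0
  rel[vanish >= 0.5] <- 1  # structure destroyed (or created) by compression
  rel[levels == lossless_level, ] <- 0
  structure(list(levels = levels, names = nms,
                 families = ledger$family, raw_diff = raw, rel_diff = rel),
            class = "stability_matrix")
}

#' @export
print.stability_matrix <- function(x, ...) {
  cat(sprintf("<stability_matrix> %d levels x %d features (families: %s)\n",
              length(x$levels), length(x$names),
              paste(unique(x$families), collapse = ", ")))
  invisible(x)
}

#' Tidy a stability matrix into long format
#'
#' @param x A [stability_matrix()] result.
#' @param ... Unused.
#' @return Tibble with `level`, `name`, `family`, `raw_diff`, `rel_diff`.
#' @export
tidy.stability_matrix <- function(x, ...) {
  tibble(level = rep(x$levels, times = length(x$names)),
         name = rep(x$names, each = length(x$levels)),
         family = rep(x$families, each = length(x$levels)),
         raw_diff = as.vector(x$raw_diff),
         rel_diff = as.vector(x$rel_diff))
}

#' Heat map of feature stability across compression levels
#'
#' ggplot2 analogue of the stability heat map: features on the x-axis grouped
#' by family, compression levels on the y-axis, fill = relative difference.
#'
#' @param object A `stability_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stability_matrix <- function(object, ...) {
  df <- tidy.stability_matrix(object)
  df$name <- factor(df$name, levels = object$names)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$name, y = factor(.data$level),
                                   fill = .data$rel_diff)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(. ~ family, scales = "free_x", space = "free_x") +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "relative\ndifference") +
    ggplot2::labs(x = NULL, y = "PSNR level (dB)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
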
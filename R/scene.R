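#' Parameters for a synthetic histology-like scene
#'
#' Bundles everything that determines a generated scene. Defaults emulate an
#' H&E-stained field of view at roughly 10x-20x: purple (hematoxylin-like)
#' nuclei on a pink (eosin-like) background, mild chromatin texture inside
#' nuclei and mild sensor noise everywhere.
#'
#' @param width,height Image size in pixels (>= 64).
#' @param task One of `"nuclei"`, `"lymphocyte"`, `"region"`.
#' @param cell_density Expected cells per 10^4 px^2 (Poisson mean scale).
#' @param nucleus_radius_mean,nucleus_radius_sd Equivalent-circle radius of a
#'   nucleus, in pixels (the ellipse axes preserve `pi * r^2` area).
#' @param eccentricity_range Interval in `[0, 1)` the per-nucleus eccentricity
#'   is drawn from uniformly.
#' @param stain_fg,stain_bg,stain_distractor RGB triples (0-255): nuclear
#'   stain, background, and the paler stain used for distractor cells
#'   (lymphocyte task) / out-of-region cells (region task).
#' @param stain_clutter RGB triple for unlabelled stromal/cytoplasmic clutter
#'   structures (pale elongated ellipses rendered beneath the cells).
#' @param clutter_density Expected clutter structures per 10^4 px^2.
#' @param illumination_sd Amplitude (intensity units) of the low-frequency
#'   additive illumination/stain-unevenness field.
#' @param texture_sd Within-nucleus intensity texture (Gaussian sd, shared
#'   across channels, intensity units).
#' @param noise_sd Additive background pixel noise sd, per channel.
#' @param region_fraction Target area fraction of the tumour-like region
#'   (region task only), in `(0, 1)`.
#' @param distractor_ratio Expected distractor-to-target cell count ratio
#'   (lymphocyte task only).
#' @param seed Integer seed; the scene is fully determined by it.
#'
#' @return An object of class `scene_params` (a named list).
#' @export
scene_params <- function(width = 256, height = 256,
                         task = c("nuclei", "lymphocyte", "region"),
                         cell_density = 14,
                         nucleus_radius_mean = 7,
                         nucleus_radius_sd = 1.2,
                         eccentricity_range = c(0, 0.7),
                         stain_fg = c(90, 60, 140),
                         stain_bg = c(230, 180, 200),
                         stain_distractor = c(170, 120, 170),
                         stain_clutter = c(185, 135, 175),
                         clutter_density = 6,
                         illumination_sd = 8,
                         texture_sd = 12,
                         noise_sd = 3,
                         region_fraction = 0.3,
                         distractor_ratio = 1.5,
                         seed = 1L) {
  task <- match.arg(task)
  p <- list(width = as.integer(width), height = as.integer(height), task = task,
            cell_density = cell_density,
            nucleus_radius_mean = nucleus_radius_mean,
            nucleus_radius_sd = nucleus_radius_sd,
            eccentricity_range = as.numeric(eccentricity_range),
            stain_fg = as.numeric(stain_fg), stain_bg = as.numeric(stain_bg),
            stain_distractor = as.numeric(stain_distractor),
            stain_clutter = as.numeric(stain_clutter),
            clutter_density = clutter_density,
            illumination_sd = illumination_sd,
            texture_sd = texture_sd, noise_sd = noise_sd,
            region_fraction = region_fraction,
            distractor_ratio = distractor_ratio,
            seed = as.integer(seed))
  class(p) <- "scene_params"
  validate_scene_params(p)
  p
}

validate_scene_params <- function(p) {
  if (p$width < 64L || p$height < 64L) {
    abort_param("`width` and `height` must both be >= 64 px.")
  }
  if (p$cell_density < 0) abort_param("`cell_density` must be >= 0.")
  if (p$nucleus_radius_mean <= 0 || p$nucleus_radius_sd < 0) {
    abort_param("nucleus radii must be positive.")
  }
  er <- p$eccentricity_range
  if (length(er) != 2L || er[1] < 0 || er[2] >= 1 || er[1] > er[2]) {
    abort_param("`eccentricity_range` must be an interval inside [0, 1).")
  }
  if (p$clutter_density < 0) abort_param("`clutter_density` must be >= 0.")
  if (p$illumination_sd < 0) abort_param("`illumination_sd` must be >= 0.")
  for (nm in c("stain_fg", "stain_bg", "stain_distractor", "stain_clutter")) {
    v <- p[[nm]]
    if (length(v) != 3L || any(v < 0) || any(v > 255)) {
      abort_param(sprintf("`%s` must be an RGB triple in [0, 255].", nm))
    }
  }
  if (p$region_fraction < 0 || p$region_fraction >= 1) {
    abort_param("`region_fraction` must be in [0, 1).")
  }
  if (p$task == "region" && p$region_fraction <= 0) {
    abort_param("`region_fraction` must be > 0 for the region task.")
  }
  if (p$distractor_ratio < 0) abort_param("`distractor_ratio` must be >= 0.")
  invisible(p)
}

# Pixels of a rotated filled ellipse centred at (cy, cx) with semi-axes a
# (along theta) and b, clipped to the H x W raster. Returns linear indices.
ellipse_pixels <- function(cy, cx, a, b, theta, H, W) {
  rmax <- max(a, b)
  r0 <- max(1L, floor(cy - rmax)); r1 <- min(H, ceiling(cy + rmax))
  c0 <- max(1L, floor(cx - rmax)); c1 <- min(W, ceiling(cx + rmax))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rr <- r0:r1
  cc <- c0:c1
  dy <- rep(rr - cy, times = length(cc))
  dx <- rep(cc - cx, each = length(rr))
  ct <- cos(theta); st <- sin(theta)
  u <- (dx * ct + dy * st) / a
  v <- (-dx * st + dy * ct) / b
  inside <- u * u + v * v <= 1
  rows <- rep(rr, times = length(cc))[inside]
  cols <- rep(cc, each = length(rr))[inside]
  rows + (cols - 1L) * H
}

# Sequential uniform placement with rejection: a candidate closer than
# `min_sep` to an accepted centre is redrawn, up to 50 times, after which it
# is accepted anyway (so the object count stays exactly the Poisson draw).
place_centers <- function(n, H, W, margin, min_sep) {
  pts <- matrix(numeric(0), 0, 2)
  lo_r <- min(margin, H / 2); lo_c <- min(margin, W / 2)
  for (i in seq_len(n)) {
    for (try in seq_len(50L)) {
      cand <- c(stats::runif(1, lo_r, H - lo_r), stats::runif(1, lo_c, W - lo_c))
      if (nrow(pts) == 0L) break
      d2 <- (pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2
      if (min(d2) >= min_sep^2) break
    }
    pts <- rbind(pts, cand)
  }
  pts
}

# Smoothed connected region mask with area fraction within +/-20% of target:
# threshold a bilinearly upsampled coarse Gaussian field, keep the largest
# 8-connected component, and scan candidate mask fractions for the best fit.
make_region_mask <- function(H, W, target_frac) {
  for (attempt in seq_len(10L)) {
    field <- upsample_bilinear(matrix(stats::rnorm(64), 8, 8), H, W)
    qs <- seq(target_frac, min(0.97, target_frac * 2.5 + 0.05), length.out = 25)
    best <- NULL
    for (f in qs) {
      thr <- stats::quantile(field, 1 - f, names = FALSE)
      lab <- label_connected(field >= thr)
      if (max(lab) == 0L) next
      sizes <- tabulate(lab[lab > 0L])
      frac <- max(sizes) / (H * W)
      if (is.null(best) || abs(frac - target_frac) < abs(best$frac - target_frac)) {
        best <- list(frac = frac, mask = lab == which.max(sizes))
      }
    }
    if (!is.null(best) && abs(best$frac - target_frac) <= 0.2 * target_frac) {
      return(best$mask)
    }
  }
  abort_param(sprintf(
    "could not realise a connected region with area fraction %.2f (+/-20%%).",
    target_frac))
}

#' Generate a synthetic histology-like scene
#'
#' Renders elliptical textured nuclei over a noisy stained background, with
#' exact ground truth. The three tasks emulate nuclei segmentation (label
#' mask per nucleus), lymphocyte detection (small dark round targets among
#' larger pale distractors, annotated centres), and tumour-region
#' segmentation (a spatially coherent binary region whose cells differ in
#' appearance from those outside).
#'
#' The object count is a Poisson draw with mean
#' `cell_density * height * width / 1e4`; placement is uniform with rejection
#' to limit overlap. Overlaps are resolved later-object-wins so the label
#' mask is a partition. Everything is determined by `params$seed`.
#'
#' @param params A [scene_params()] object.
#' @return An object of class `scene`: a list with `image` (H x W x 3 integer
#'   array, 0-255), `label_mask` (integer matrix, 0 = background, ids
#'   contiguous 1..K), `region_mask` (logical matrix or `NULL`), `centers`
#'   (tibble with `row`, `col`, `class`), and `params`.
#' @export
#' @examples
#' sc <- generate_scene(scene_params(width = 96, height = 96, seed = 7))
#' max(sc$label_mask)  # number of rendered nuclei
generate_scene <- function(params) {
  if (!inherits(params, "scene_params")) {
    abort_param("`params` must be created with scene_params().")
  }
  validate_scene_params(params)
  H <- params$height; W <- params$width
  r_mean <- params$nucleus_radius_mean
  lambda <- params$cell_density * H * W / 1e4
  if (lambda > 0.25 * H * W / (pi * r_mean^2)) {
    abort("expected object count exceeds the overcrowding bound 0.25*H*W/(pi*r^2).",
          class = "histocompress_overcrowding_error")
  }

  with_seed(params$seed, {
    img <- array(0, dim = c(H, W, 3))
    for (ch in 1:3) {
      img[, , ch] <- params$stain_bg[ch] + stats::rnorm(H * W, 0, params$noise_sd)
    }
    if (params$illumination_sd > 0) {
      # low-frequency stain/illumination unevenness, shared across channels
      illum <- upsample_bilinear(matrix(stats::rnorm(36, 0, params$illumination_sd), 6, 6),
                                 H, W)
      for (ch in 1:3) img[, , ch] <- img[, , ch] + illum
    }
    region_mask <- NULL
    if (params$task == "region") {
      region_mask <- make_region_mask(H, W, params$region_fraction)
    }

    draw_objects <- function(n, radius_scale, ecc_range, base_cols, label_from) {
      # base_cols: function(center) -> RGB base colour for that object
      info <- list()
      if (n == 0L) return(info)
      centers <- place_centers(n, H, W, margin = ceiling(r_mean) + 1,
                               min_sep = 1.8 * r_mean)
      for (i in seq_len(n)) {
        r <- max(1.5, stats::rnorm(1, r_mean * radius_scale,
                                   params$nucleus_radius_sd * radius_scale))
        e <- stats::runif(1, ecc_range[1], ecc_range[2])
        th <- stats::runif(1, 0, pi)
        s <- (1 - e^2)^(1 / 4)
        col <- base_cols(centers[i, ]) + stats::rnorm(3, 0, 8)
        info[[i]] <- list(center = centers[i, ], a = r / s, b = r * s,
                          theta = th, col = col)
      }
      info
    }

    lab <- matrix(0L, H, W)
    # stromal/cytoplasmic clutter: pale, strongly elongated, unlabelled,
    # rendered beneath every cell
    n_cl <- stats::rpois(1, params$clutter_density * H * W / 1e4)
    clutter <- draw_objects(n_cl, 1.6, c(0.85, 0.97),
                            function(ct) params$stain_clutter, FALSE)
    plan <- lapply(clutter, function(o) c(o, list(labelled = FALSE, class = "clutter")))
    if (params$task == "nuclei") {
      n <- stats::rpois(1, lambda)
      objs <- draw_objects(n, 1, params$eccentricity_range,
                           function(ct) params$stain_fg, TRUE)
      plan <- c(plan, lapply(objs, function(o) c(o, list(labelled = TRUE, class = "target"))))
    } else if (params$task == "lymphocyte") {
      n_t <- stats::rpois(1, lambda)
      n_d <- stats::rpois(1, lambda * params$distractor_ratio)
      # distractors first so targets render on top
      dis <- draw_objects(n_d, 1.4, params$eccentricity_range,
                          function(ct) params$stain_distractor, FALSE)
      tar <- draw_objects(n_t, 0.6, c(0, min(0.3, params$eccentricity_range[2])),
                          function(ct) params$stain_fg * 0.6, TRUE)
      plan <- c(plan,
                lapply(dis, function(o) c(o, list(labelled = FALSE, class = "distractor"))),
                lapply(tar, function(o) c(o, list(labelled = TRUE, class = "target"))))
    } else { # region
      n <- stats::rpois(1, lambda)
      objs <- draw_objects(n, 1, params$eccentricity_range, function(ct) {
        inside <- region_mask[round(ct[1]), round(ct[2])]
        if (inside) params$stain_fg else params$stain_distractor
      }, TRUE)
      plan <- c(plan, lapply(objs, function(o) {
        inside <- region_mask[round(o$center[1]), round(o$center[2])]
        c(o, list(labelled = TRUE, class = if (inside) "target" else "distractor"))
      }))
    }

    next_id <- 0L
    class_by_id <- character(0)        # class of the labelled object with id i
    distractor_centers <- matrix(numeric(0), 0, 2)
    for (o in plan) {
      px <- ellipse_pixels(o$center[1], o$center[2], o$a, o$b, o$theta, H, W)
      tex <- stats::rnorm(length(px), 0, params$texture_sd)
      if (length(px)) {
        for (ch in 1:3) img[px + (ch - 1L) * H * W] <- o$col[ch] + tex
      }
      if (o$labelled) {
        if (length(px)) {
          next_id <- next_id + 1L
          lab[px] <- next_id
          class_by_id <- c(class_by_id, o$class)
        }
      } else if (o$class == "distractor") {
        distractor_centers <- rbind(distractor_centers, o$center)
      }
    }
    img <- array(as.integer(pmin(pmax(round(img), 0), 255)), dim = c(H, W, 3))

    # Later objects may fully erase earlier labels; relabel contiguously and
    # take centres as the centroids of surviving labelled pixels.
    ids <- sort(unique(lab[lab > 0L]))
    if (length(ids)) {
      relabel <- integer(max(ids))
      relabel[ids] <- seq_along(ids)
      lab[lab > 0L] <- relabel[lab[lab > 0L]]
    }

    centers <- tibble(row = numeric(0), col = numeric(0), class = character(0))
    if (length(ids)) {
      pix <- which(lab > 0L)
      lv <- lab[pix]
      rr <- (pix - 1L) %% H + 1L
      cc <- (pix - 1L) %/% H + 1L
      centers <- tibble(row = as.numeric(tapply(rr, lv, mean)),
                        col = as.numeric(tapply(cc, lv, mean)),
                        class = class_by_id[ids])
    }
    if (nrow(distractor_centers)) {
      # lymphocyte distractor centres are annotation-only (no mask id)
      centers <- bind_rows(centers,
                           tibble(row = distractor_centers[, 1],
                                  col = distractor_centers[, 2],
                                  class = "distractor"))
    }

    structure(list(image = img, label_mask = lab, region_mask = region_mask,
                   centers = centers, params = params),
              class = "scene")
  })
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> %dx%d, task = %s, %d labelled objects, %d centres\n",
              x$params$height, x$params$width, x$params$task,
              max(x$label_mask), nrow(x$centers)))
  invisible(x)
}

#' Ground-truth positive mask for a scene's task
#'
#' Nuclei and lymphocyte tasks use the label mask; the region task uses the
#' region mask.
#' @param scene A [generate_scene()] result.
#' @return Logical matrix.
#' @export
scene_truth_mask <- function(scene) {
  if (scene$params$task == "region") scene$region_mask else scene$label_mask > 0L
}
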
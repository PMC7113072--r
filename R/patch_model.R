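#' Training configuration for the patch classifier
#'
#' A compact AlexNet-style network (two 5x5 conv + ReLU + 2x2 maxpool blocks,
#' one hidden dense layer, softmax; about 17k parameters at the defaults) that
#' trains in minutes on one CPU. Patch labels come from the ground truth at
#' the patch centre; training patches are sampled with a configurable
#' positive:negative balance and augmented with the 8 dihedral transforms.
#'
#' @param patch_size Patch side in px (must fit the architecture: 16, 20, 24,
#'   28, 32, ...). Default 32.
#' @param stride Inference grid stride in px; probabilities are scored on a
#'   strided grid and linearly interpolated to full resolution. Default 4.
#' @param epochs Training epochs (>= 1).
#' @param batch_size Mini-batch size.
#' @param learning_rate SGD learning rate (momentum 0.9).
#' @param balance Positive:negative sampling ratio (1 = balanced).
#' @param patches_per_scene Patches sampled from each training scene.
#' @param conv1_filters,conv2_filters,hidden Layer widths.
#' @param seed Seed driving sampling, augmentation and weight init.
#' @return An object of class `train_config`.
#' @export
train_config <- function(patch_size = 32L, stride = 4L, epochs = 4L,
                         batch_size = 64L, learning_rate = 0.05,
                         balance = 1, patches_per_scene = 128L,
                         conv1_filters = 8L, conv2_filters = 16L,
                         hidden = 32L, seed = 1L) {
  if (epochs < 1L) abort_param("`epochs` must be >= 1.")
  if (patch_size %% 2L != 0L) abort_param("`patch_size` must be even.")
  if (balance <= 0) abort_param("`balance` must be > 0.")
  dims <- cnn_dims(patch_size, conv1_filters, conv2_filters, hidden)
  structure(list(patch_size = as.integer(patch_size), stride = as.integer(stride),
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, balance = balance,
                 patches_per_scene = as.integer(patches_per_scene),
                 conv1_filters = as.integer(conv1_filters),
                 conv2_filters = as.integer(conv2_filters),
                 hidden = as.integer(hidden),
                 seed = as.integer(seed), dims = dims),
            class = "train_config")
}

mirror_index <- function(n, pad) {
  c(rev(seq_len(pad)), seq_len(n), n + 1L - seq_len(pad))
}

pad_image_sym <- function(image, pad) {
  ri <- mirror_index(dim(image)[1], pad)
  ci <- mirror_index(dim(image)[2], pad)
  image[ri, ci, , drop = FALSE]
}

# Gather patches centred at (rows, cols) from a symmetric-padded image.
# Returns (P, P, 3, n) array of raw 0-255 values.
gather_patches <- function(image, rows, cols, patch_size) {
  pad <- patch_size %/% 2L
  padded <- pad_image_sym(image, pad)
  n <- length(rows)
  out <- array(0, c(patch_size, patch_size, 3L, n))
  for (i in seq_len(n)) {
    r0 <- rows[i]  # centre (r, c) maps to padded rows r .. r+P-1
    c0 <- cols[i]
    out[, , , i] <- padded[r0:(r0 + patch_size - 1L),
                           c0:(c0 + patch_size - 1L), , drop = FALSE]
  }
  out
}

# Per-pixel positive mask defining patch labels for a scene's task.
positive_label_mask <- function(scene) {
  p <- scene$params
  if (p$task == "region") return(scene$region_mask)
  if (p$task == "nuclei") return(scene$label_mask > 0L)
  # lymphocyte: pixels within 0.6 * nucleus_radius_mean of a target centre
  H <- p$height; W <- p$width
  tc <- scene$centers[scene$centers$class == "target", , drop = FALSE]
  mask <- matrix(FALSE, H, W)
  if (!nrow(tc)) return(mask)
  r <- 0.6 * p$nucleus_radius_mean
  grid <- cbind(rep(seq_len(H), times = W), rep(seq_len(W), each = H))
  nn <- FNN::get.knnx(as.matrix(tc[, c("row", "col")]), grid, k = 1L)
  mask[] <- nn$nn.dist[, 1L] <= r
  mask
}

#' Extract labelled training patches from a scene
#'
#' The patch label is the ground-truth class at the patch centre (mask value
#' for nuclei/region; proximity to a target centre for lymphocytes). Sampling
#' draws `patches_per_scene` centres at the configured positive:negative
#' balance, without replacement where possible. Deterministic given
#' `config$seed` and the scene.
#'
#' @param scene A [generate_scene()] result (or [read_scene()]).
#' @param config A [train_config()].
#' @return An object of class `patch_set`: list with `x` (P x P x 3 x N array,
#'   0-255), `y` (integer 0/1), and `centers` (tibble of sampled positions).
#' @export
extract_patches <- function(scene, config) {
  if (!inherits(config, "train_config")) abort_param("`config` must be a train_config().")
  pos_mask <- positive_label_mask(scene)
  pos_idx <- which(pos_mask)
  neg_idx <- which(!pos_mask)
  if (!length(pos_idx)) {
    abort("scene has no positive pixels for its task; cannot label patches.",
          class = "histocompress_empty_class_error")
  }
  n <- config$patches_per_scene
  npos <- round(n * config$balance / (1 + config$balance))
  nneg <- n - npos
  H <- dim(scene$image)[1]
  with_seed(config$seed + scene$params$seed, {
    sample_px <- function(idx, k) {
      if (!length(idx)) return(integer(0))
      idx[sample.int(length(idx), k, replace = length(idx) < k)]
    }
    pos_sel <- sample_px(pos_idx, npos)
    neg_sel <- sample_px(neg_idx, nneg)
    sel <- c(pos_sel, neg_sel)
    y <- c(rep(1L, length(pos_sel)), rep(0L, length(neg_sel)))
    rows <- (sel - 1L) %% H + 1L
    cols <- (sel - 1L) %/% H + 1L
    x <- gather_patches(scene$image, rows, cols, config$patch_size)
    structure(list(x = x, y = y,
                   centers = tibble(row = rows, col = cols, label = y)),
              class = "patch_set")
  })
}

#' Combine patch sets from several scenes
#' @param sets List of `patch_set` objects.
#' @return A single `patch_set`.
#' @export
combine_patch_sets <- function(sets) {
  xs <- lapply(sets, `[[`, "x")
  n <- sum(vapply(xs, function(a) dim(a)[4], integer(1)))
  d <- dim(xs[[1]])
  x <- array(0, c(d[1:3], n))
  at <- 0L
  for (a in xs) {
    k <- dim(a)[4]
    if (k) x[, , , (at + 1L):(at + k)] <- a
    at <- at + k
  }
  structure(list(x = x, y = unlist(lapply(sets, `[[`, "y")),
                 centers = bind_rows(lapply(sets, `[[`, "centers"))),
            class = "patch_set")
}

#' Apply a dihedral transform to a square patch
#'
#' @param patch P x P x C array.
#' @param rotation Number of 90-degree rotations (0-3).
#' @param mirror Mirror (flip columns) before rotating?
#' @return Transformed patch; the pixel multiset is unchanged.
#' @export
dihedral_transform <- function(patch, rotation = 0L, mirror = FALSE) {
  if (length(dim(patch)) != 3L) abort_dim("`patch` must be a P x P x C array.")
  apply_dihedral(patch, rotation, mirror)
}

#' Randomly augment a patch with one of the 8 dihedral transforms
#'
#' Random rotation by 0/90/180/270 degrees combined with random mirroring,
#' each of the 8 variants drawn uniformly.
#'
#' @param patch P x P x C array (square spatial dims).
#' @param seed Seed for the draw.
#' @return Transformed patch.
#' @export
augment_patch <- function(patch, seed = 1L) {
  if (length(dim(patch)) != 3L || dim(patch)[1] != dim(patch)[2]) {
    abort_dim("`patch` must be square (P x P x C).")
  }
  with_seed(seed, {
    t <- sample.int(8L, 1L)
    apply_dihedral(patch, rotation = (t - 1L) %% 4L, mirror = t > 4L)
  })
}

#' Train the patch classifier
#'
#' Trains the compact CNN on labelled patches (train-on-clean protocol: the
#' caller supplies patches from uncompressed scenes only). Inputs are scaled
#' to `[-0.5, 0.5]`; each epoch re-augments every patch with a random
#' dihedral transform. Deterministic given `config$seed`.
#'
#' @param patches A `patch_set` (see [extract_patches()],
#'   [combine_patch_sets()]).
#' @param config A [train_config()].
#' @return An object of class `patch_model` with `weights`, `dims`, `config`
#'   and `loss_history` (mean cross-entropy per epoch).
#' @export
train_classifier <- function(patches, config) {
  if (!inherits(patches, "patch_set")) abort_param("`patches` must be a patch_set.")
  if (length(unique(patches$y)) < 2L) {
    abort("training patches contain a single class.",
          class = "histocompress_training_error")
  }
  x <- patches$x / 255 - 0.5
  fit <- cnn_train(x, patches$y, config$dims, epochs = config$epochs,
                   batch_size = config$batch_size,
                   learning_rate = config$learning_rate,
                   seed = config$seed)
  structure(list(weights = fit$weights, dims = config$dims, config = config,
                 loss_history = fit$loss_history),
            class = "patch_model")
}

#' @export
print.patch_model <- function(x, ...) {
  np <- sum(vapply(x$weights, length, integer(1)))
  cat(sprintf("<patch_model> patch %d, %d parameters, %d epochs, final loss %.4f\n",
              x$dims$patch, np, length(x$loss_history),
              x$loss_history[length(x$loss_history)]))
  invisible(x)
}

predict_patch_probs <- function(model, x_raw, chunk = 256L) {
  n <- dim(x_raw)[4]
  probs <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    sel <- start:min(start + chunk - 1L, n)
    xb <- x_raw[, , , sel, drop = FALSE] / 255 - 0.5
    probs[sel] <- cnn_forward(model$weights, model$dims, xb)$probs[, 2L]
  }
  probs
}

#' Dense per-pixel probability map for an image
#'
#' Scores patches centred on a strided grid (stride from the model's config;
#' image borders handled by symmetric padding) and linearly interpolates the
#' grid probabilities to every pixel.
#'
#' @param model A [train_classifier()] result.
#' @param image H x W x 3 integer array, 0-255; both dims must be at least the
#'   patch size.
#' @return An object of class `probability_map`: list with `values` (H x W
#'   matrix in `[0, 1]`) and `task`.
#' @export
predict_probability_map <- function(model, image) {
  check_uint8_image(image)
  P <- model$dims$patch
  H <- dim(image)[1]; W <- dim(image)[2]
  if (H < P || W < P) abort_dim("image is smaller than the patch size.")
  s <- model$config$stride
  rs <- unique(c(seq(1L, H, by = s), H))
  cs <- unique(c(seq(1L, W, by = s), W))
  grid_r <- rep(rs, times = length(cs))
  grid_c <- rep(cs, each = length(rs))
  vals <- matrix(0, length(rs), length(cs))
  chunk <- 512L
  for (start in seq(1L, length(grid_r), by = chunk)) {
    sel <- start:min(start + chunk - 1L, length(grid_r))
    xr <- gather_patches(image, grid_r[sel], grid_c[sel], P)
    vals[sel] <- predict_patch_probs(model, xr)
  }
  full <- interp_grid(rs, cs, vals, H, W)
  full <- pmin(pmax(full, 0), 1)
  structure(list(values = full, task = model$config$task %||% NA_character_),
            class = "probability_map")
}

#' Threshold a probability map into a binary mask
#'
#' @param map A `probability_map` (or plain numeric matrix in `[0, 1]`).
#' @param threshold Threshold; mask is `values >= threshold`.
#' @return Logical matrix.
#' @export
binarize_map <- function(map, threshold = 0.5) {
  v <- if (inherits(map, "probability_map")) map$values else map
  v >= threshold
}

#' Detect cell centres as suppressed local maxima of a probability map
#'
#' Local maxima (8-neighbourhood) above `threshold` are collected in order of
#' descending score and greedily suppressed so that no two returned centres
#' are closer than `min_distance`.
#'
#' @param map A `probability_map` or numeric matrix.
#' @param threshold Detection threshold in (0, 1).
#' @param min_distance Minimum separation between returned centres, px.
#' @return Tibble with `row`, `col`, `score`, sorted by descending score.
#' @export
detect_centers <- function(map, threshold = 0.5, min_distance = 7) {
  v <- if (inherits(map, "probability_map")) map$values else map
  if (threshold <= 0 || threshold >= 1) abort_param("`threshold` must be in (0, 1).")
  H <- nrow(v); W <- ncol(v)
  padded <- matrix(-Inf, H + 2L, W + 2L)
  padded[2:(H + 1L), 2:(W + 1L)] <- v
  is_max <- v > threshold
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    is_max <- is_max & v >= padded[(2:(H + 1L)) + dr, (2:(W + 1L)) + dc]
  }
  idx <- which(is_max)
  if (!length(idx)) return(tibble(row = integer(0), col = integer(0), score = numeric(0)))
  rows <- (idx - 1L) %% H + 1L
  cols <- (idx - 1L) %/% H + 1L
  score <- v[idx]
  ord <- order(-score, rows, cols)
  rows <- rows[ord]; cols <- cols[ord]; score <- score[ord]
  keep <- logical(length(ord))
  for (i in seq_along(ord)) {
    if (i == 1L) { keep[1L] <- TRUE; next }
    prev <- which(keep[seq_len(i - 1L)])
    d2 <- (rows[prev] - rows[i])^2 + (cols[prev] - cols[i])^2
    keep[i] <- all(d2 >= min_distance^2)
  }
  tibble(row = rows[keep], col = cols[keep], score = score[keep])
}
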
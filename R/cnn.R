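# Compact convolutional network for patch classification, implemented with
# im2col + BLAS matrix products. Two conv(5x5)+ReLU+maxpool(2) blocks, one
# hidden dense layer, softmax output. Gradients are exact (verified against
# finite differences in the test suite); optimiser is mini-batch SGD with
# momentum. Everything is deterministic given the seed.

cnn_dims <- function(patch_size, conv1_filters = 8L, conv2_filters = 16L,
                     hidden = 32L, kernel = 5L) {
  c1 <- patch_size - kernel + 1L
  if (c1 <= 0L || c1 %% 2L != 0L) {
    abort_param(sprintf("patch_size %d incompatible with the architecture (conv1 output %d must be even).",
                        patch_size, c1))
  }
  p1 <- c1 %/% 2L
  c2 <- p1 - kernel + 1L
  if (c2 <= 0L || c2 %% 2L != 0L) {
    abort_param(sprintf("patch_size %d incompatible with the architecture (conv2 output %d must be positive and even).",
                        patch_size, c2))
  }
  p2 <- c2 %/% 2L
  list(patch = patch_size, k = kernel, f1 = conv1_filters, f2 = conv2_filters,
       hidden = hidden, c1 = c1, p1 = p1, c2 = c2, p2 = p2,
       flat = p2 * p2 * conv2_filters)
}

cnn_init <- function(dims) {
  he <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nr)), nr, nc)
  k2 <- dims$k^2
  list(W1 = he(k2 * 3, dims$f1), b1 = numeric(dims$f1),
       W2 = he(k2 * dims$f1, dims$f2), b2 = numeric(dims$f2),
       W3 = he(dims$flat, dims$hidden), b3 = numeric(dims$hidden),
       W4 = he(dims$hidden, 2L), b4 = numeric(2L))
}

# Within-image gather indices for im2col: (Hout*Wout) x (k*k*Cin) matrix of
# linear indices into an Hin x Win x Cin array.
im2col_index <- function(Hin, Win, Cin, k) {
  Hout <- Hin - k + 1L
  Wout <- Win - k + 1L
  i <- rep(seq_len(Hout), times = Wout)
  j <- rep(seq_len(Wout), each = Hout)
  pos0 <- (i - 1L) + (j - 1L) * Hin
  u <- rep(seq_len(k), times = k * Cin)
  v <- rep(rep(seq_len(k), each = k), times = Cin)
  ch <- rep(seq_len(Cin), each = k * k)
  off <- (u - 1L) + (v - 1L) * Hin + (ch - 1L) * Hin * Win
  outer(pos0, off, "+") + 1L
}

im2col <- function(x, idx) {
  d <- dim(x)               # Hin, Win, Cin, B
  B <- d[4]
  xf <- matrix(x, ncol = B)
  hw <- nrow(idx)
  out <- matrix(0, hw * B, ncol(idx))
  for (b in seq_len(B)) {
    out[((b - 1L) * hw + 1L):(b * hw), ] <- matrix(xf[idx, b], hw, ncol(idx))
  }
  out
}

col2im <- function(dcol, idx, Hin, Win, Cin, B) {
  hw <- nrow(idx)
  dxf <- matrix(0, Hin * Win * Cin, B)
  iv <- as.vector(idx)
  for (b in seq_len(B)) {
    v <- as.vector(dcol[((b - 1L) * hw + 1L):(b * hw), ])
    rs <- rowsum(v, iv)
    dxf[as.integer(rownames(rs)), b] <- rs[, 1L]
  }
  array(dxf, c(Hin, Win, Cin, B))
}

col_to_maps <- function(zcol, Hout, Wout, Fout, B) {
  aperm(array(zcol, c(Hout, Wout, B, Fout)), c(1L, 2L, 4L, 3L))
}

maps_to_col <- function(z) {
  d <- dim(z)               # Hout, Wout, F, B
  matrix(aperm(z, c(1L, 2L, 4L, 3L)), d[1] * d[2] * d[4], d[3])
}

maxpool2 <- function(x) {
  d <- dim(x)
  ro <- seq(1L, d[1], 2L); co <- seq(1L, d[2], 2L)
  a1 <- x[ro, co, , , drop = FALSE]
  a2 <- x[ro + 1L, co, , , drop = FALSE]
  a3 <- x[ro, co + 1L, , , drop = FALSE]
  a4 <- x[ro + 1L, co + 1L, , , drop = FALSE]
  out <- pmax(a1, a2, a3, a4)
  which4 <- ifelse(a1 == out, 1L, ifelse(a2 == out, 2L, ifelse(a3 == out, 3L, 4L)))
  list(out = out, which = which4, in_dim = d)
}

maxpool2_backward <- function(dout, pool) {
  d <- pool$in_dim
  Hp <- d[1] %/% 2L; Wp <- d[2] %/% 2L; Fo <- d[3]; B <- d[4]
  n <- Hp * Wp * Fo * B
  ig <- rep_len(seq_len(Hp), n)
  jg <- rep(rep(seq_len(Wp), each = Hp), times = Fo * B)
  fg <- rep(rep(seq_len(Fo), each = Hp * Wp), times = B)
  bg <- rep(seq_len(B), each = Hp * Wp * Fo)
  k <- as.vector(pool$which)
  r <- 2L * ig - 1L + as.integer(k == 2L | k == 4L)
  cc <- 2L * jg - 1L + as.integer(k >= 3L)
  li <- r + (cc - 1L) * d[1] + (fg - 1L) * d[1] * d[2] + (bg - 1L) * d[1] * d[2] * d[3]
  dx <- array(0, d)
  dx[li] <- as.vector(dout)
  dx
}

# Forward pass. x: (P, P, 3, B) array of centred inputs. Returns class
# probabilities and, if keep_cache, intermediates for the backward pass.
cnn_forward <- function(weights, dims, x, keep_cache = FALSE) {
  B <- dim(x)[4]
  idx1 <- im2col_index(dims$patch, dims$patch, 3L, dims$k)
  col1 <- im2col(x, idx1)
  z1col <- sweep(col1 %*% weights$W1, 2L, weights$b1, "+")
  z1 <- col_to_maps(z1col, dims$c1, dims$c1, dims$f1, B)
  a1 <- pmax(z1, 0)
  pool1 <- maxpool2(a1)

  idx2 <- im2col_index(dims$p1, dims$p1, dims$f1, dims$k)
  col2 <- im2col(pool1$out, idx2)
  z2col <- sweep(col2 %*% weights$W2, 2L, weights$b2, "+")
  z2 <- col_to_maps(z2col, dims$c2, dims$c2, dims$f2, B)
  a2 <- pmax(z2, 0)
  pool2 <- maxpool2(a2)

  xflat <- t(matrix(pool2$out, dims$flat, B))
  z3 <- sweep(xflat %*% weights$W3, 2L, weights$b3, "+")
  a3 <- pmax(z3, 0)
  z4 <- sweep(a3 %*% weights$W4, 2L, weights$b4, "+")
  zs <- z4 - apply(z4, 1L, max)
  ez <- exp(zs)
  probs <- ez / rowSums(ez)
  if (!keep_cache) return(list(probs = probs))
  list(probs = probs, col1 = col1, z1 = z1, pool1 = pool1, idx2 = idx2,
       col2 = col2, z2 = z2, pool2 = pool2, xflat = xflat, z3 = z3, a3 = a3,
       B = B)
}

# Backward pass for mean cross-entropy; y is an integer vector of 0/1 labels.
cnn_backward <- function(weights, dims, cache, y) {
  B <- cache$B
  onehot <- matrix(0, B, 2L)
  onehot[cbind(seq_len(B), y + 1L)] <- 1
  dz4 <- (cache$probs - onehot) / B
  gW4 <- t(cache$a3) %*% dz4
  gb4 <- colSums(dz4)
  dz3 <- (dz4 %*% t(weights$W4)) * (cache$z3 > 0)
  gW3 <- t(cache$xflat) %*% dz3
  gb3 <- colSums(dz3)
  dxflat <- dz3 %*% t(weights$W3)
  dpool2 <- array(t(dxflat), c(dims$p2, dims$p2, dims$f2, B))
  da2 <- maxpool2_backward(dpool2, cache$pool2)
  dz2 <- da2 * (cache$z2 > 0)
  dz2col <- maps_to_col(dz2)
  gW2 <- t(cache$col2) %*% dz2col
  gb2 <- colSums(dz2col)
  dcol2 <- dz2col %*% t(weights$W2)
  dpool1 <- col2im(dcol2, cache$idx2, dims$p1, dims$p1, dims$f1, B)
  da1 <- maxpool2_backward(dpool1, cache$pool1)
  dz1 <- da1 * (cache$z1 > 0)
  dz1col <- maps_to_col(dz1)
  gW1 <- t(cache$col1) %*% dz1col
  gb1 <- colSums(dz1col)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
       W3 = gW3, b3 = gb3, W4 = gW4, b4 = gb4)
}

cnn_loss <- function(probs, y) {
  -mean(log(pmax(probs[cbind(seq_along(y), y + 1L)], 1e-12)))
}

# One of the 8 dihedral (rotation/mirror) transforms applied to the spatial
# dims of a (P, P, C) or (P, P, C, N) array.
apply_dihedral <- function(x, rotation = 0L, mirror = FALSE) {
  added_dim <- length(dim(x)) == 3L
  if (added_dim) dim(x) <- c(dim(x), 1L)
  P <- dim(x)[1]
  if (dim(x)[2] != P) abort_dim("dihedral transforms require square patches.")
  if (mirror) x <- x[, P:1, , , drop = FALSE]
  r <- as.integer(rotation) %% 4L
  for (i in seq_len(r)) {  # 90 degrees counter-clockwise per step
    x <- aperm(x, c(2L, 1L, 3L, 4L))[P:1, , , , drop = FALSE]
  }
  if (added_dim) dim(x) <- dim(x)[1:3]
  x
}

# Per-epoch dihedral augmentation: one uniformly drawn transform per patch,
# applied group-wise so each of the 8 variants is a single vectorised op.
augment_batch <- function(x) {
  N <- dim(x)[4]
  tf <- sample.int(8L, N, replace = TRUE)
  for (t in seq_len(8L)) {
    sel <- which(tf == t)
    if (!length(sel)) next
    x[, , , sel] <- apply_dihedral(x[, , , sel, drop = FALSE],
                                   rotation = (t - 1L) %% 4L,
                                   mirror = t > 4L)
  }
  x
}

cnn_train <- function(x, y, dims, epochs, batch_size, learning_rate,
                      momentum = 0.9, seed = 1L, augment = TRUE) {
  N <- dim(x)[4]
  with_seed(seed, {
    weights <- cnn_init(dims)
    velocity <- lapply(weights, function(w) w * 0)
    loss_history <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      xe <- if (augment) augment_batch(x) else x
      ord <- sample.int(N)
      losses <- numeric(0)
      for (start in seq(1L, N, by = batch_size)) {
        sel <- ord[start:min(start + batch_size - 1L, N)]
        xb <- xe[, , , sel, drop = FALSE]
        yb <- y[sel]
        cache <- cnn_forward(weights, dims, xb, keep_cache = TRUE)
        losses <- c(losses, cnn_loss(cache$probs, yb))
        grads <- cnn_backward(weights, dims, cache, yb)
        for (nm in names(weights)) {
          velocity[[nm]] <- momentum * velocity[[nm]] - learning_rate * grads[[nm]]
          weights[[nm]] <- weights[[nm]] + velocity[[nm]]
        }
      }
      loss_history[ep] <- mean(losses)
    }
    list(weights = weights, loss_history = loss_history)
  })
}
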
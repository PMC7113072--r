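#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup bind_rows left_join n
#' @importFrom purrr map map_dbl map2 imap pmap
#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a fixed RNG state, restoring the caller's state after.
# All stochastic steps in the package route through this so that a scene /
# training run / sweep is fully determined by its seed.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single non-missing number.", class = "histocompress_parameter_error")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

abort_param <- function(msg) abort(msg, class = "histocompress_parameter_error")
abort_dim <- function(msg) abort(msg, class = "histocompress_dimension_error")
abort_format <- function(msg) abort(msg, class = "histocompress_format_error")

is_uint8_image <- function(x) {
  is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L &&
    !anyNA(x) && min(x) >= 0 && max(x) <= 255 && all(x == round(x))
}

check_uint8_image <- function(x, arg = "image") {
  if (!is_uint8_image(x)) {
    abort_format(sprintf(
      "`%s` must be an H x W x 3 array of integers in [0, 255].", arg))
  }
  invisible(x)
}

# Bilinear upsampling of a coarse matrix onto an H x W pixel grid. Used for the
# smooth random field behind the synthetic tumour-region mask and nowhere else
# (probability maps interpolate from a non-uniform grid, see interp_grid()).
upsample_bilinear <- function(m, H, W) {
  hs <- seq(1, nrow(m), length.out = H)
  ws <- seq(1, ncol(m), length.out = W)
  r0 <- pmin(floor(hs), nrow(m) - 1L)
  c0 <- pmin(floor(ws), ncol(m) - 1L)
  fr <- hs - r0
  fc <- ws - c0
  a <- m[r0, c0, drop = FALSE]
  b <- m[r0 + 1L, c0, drop = FALSE]
  cc <- m[r0, c0 + 1L, drop = FALSE]
  d <- m[r0 + 1L, c0 + 1L, drop = FALSE]
  a * outer(1 - fr, 1 - fc) + b * outer(fr, 1 - fc) +
    cc * outer(1 - fr, fc) + d * outer(fr, fc)
}

# Separable linear interpolation of values known on an irregular grid
# (rows `rs`, cols `cs`) onto the full 1..H x 1..W pixel grid.
interp_grid <- function(rs, cs, vals, H, W) {
  stopifnot(nrow(vals) == length(rs), ncol(vals) == length(cs))
  if (length(rs) == 1L) {
    tmp <- matrix(vals, nrow = H, ncol = length(cs), byrow = TRUE)
  } else {
    tmp <- apply(vals, 2, function(col) stats::approx(rs, col, xout = seq_len(H), rule = 2)$y)
  }
  if (length(cs) == 1L) {
    out <- matrix(tmp, nrow = H, ncol = W)
  } else {
    out <- t(apply(tmp, 1, function(row) stats::approx(cs, row, xout = seq_len(W), rule = 2)$y))
  }
  out
}

# 8-connected component labelling of a binary/positive mask. Returns an
# integer matrix with components numbered 1..K in raster-scan order of their
# first pixel. igraph does the union-find; edge construction is vectorised.
label_connected <- function(mask) {
  H <- nrow(mask)
  W <- ncol(mask)
  idx <- which(mask > 0)
  out <- matrix(0L, H, W)
  if (length(idx) == 0L) return(out)
  node <- integer(H * W)
  node[idx] <- seq_along(idx)
  r <- (idx - 1L) %% H + 1L
  cl <- (idx - 1L) %/% H + 1L
  edges <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    dr <- off[1]; dc <- off[2]
    ok <- r + dr >= 1L & r + dr <= H & cl + dc >= 1L & cl + dc <= W
    nb <- idx[ok] + dr + dc * H
    keep <- node[nb] > 0L
    if (any(keep)) {
      edges <- c(edges, rbind(node[idx[ok]][keep], node[nb][keep]))
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  memb <- igraph::components(g)$membership
  # renumber components by first appearance in column-major raster order
  first <- !duplicated(memb)
  relabel <- integer(max(memb))
  relabel[memb[first]] <- seq_len(sum(first))
  out[idx] <- relabel[memb]
  out
}

# Population standard deviation (divides by n, not n - 1).
sd_pop <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

shoelace_area <- function(x, y) {
  n <- length(x)
  if (n < 3L) return(0)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

polygon_perimeter <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  j <- c(seq_len(n)[-1], 1L)
  sum(sqrt((x[j] - x)^2 + (y[j] - y)^2))
}

max_pairwise_dist <- function(x, y) {
  if (length(x) < 2L) return(NA_real_)
  max(stats::dist(cbind(x, y)))
}
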
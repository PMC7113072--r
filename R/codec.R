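PSNR_CAP <- 100

#' Peak signal-to-noise ratio between two 8-bit RGB images
#'
#' `10 * log10(255^2 / MSE)` with the mean squared error taken over all pixels
#' and channels. Identical images (MSE = 0) return the cap value 100 dB, the
#' conventional "lossless" endpoint of the quality scale.
#'
#' @param reference,degraded H x W x 3 integer arrays in 0-255.
#' @return PSNR in decibels.
#' @export
#' @examples
#' a <- array(100L, c(4, 4, 3)); b <- a; b[1, 1, 1] <- 110L
#' compute_psnr(a, b)
compute_psnr <- function(reference, degraded) {
  check_uint8_image(reference, "reference")
  check_uint8_image(degraded, "degraded")
  if (!identical(dim(reference), dim(degraded))) {
    abort_dim("`reference` and `degraded` must have identical dimensions.")
  }
  mse <- mean((as.numeric(reference) - as.numeric(degraded))^2)
  if (mse == 0) return(PSNR_CAP)
  min(10 * log10(255^2 / mse), PSNR_CAP)
}

compression_record <- function(codec, control, achieved_psnr, compressed_bytes,
                               raw_bytes, converged = TRUE) {
  tibble(codec = codec, control = control,
         achieved_psnr = achieved_psnr,
         compressed_bytes = as.numeric(compressed_bytes),
         raw_bytes = as.numeric(raw_bytes),
         ratio = as.numeric(compressed_bytes) / as.numeric(raw_bytes),
         converged = converged)
}

#' Encode an image as JPEG at a given quality score
#'
#' @param image H x W x 3 integer array in 0-255.
#' @param quality Integer quality score in 1-100.
#' @return A list with `bytes` (raw vector), `decoded` (the round-tripped
#'   image) and `record` (a one-row tibble: codec, control, achieved PSNR,
#'   byte counts, ratio against the raw bitmap size `H*W*3`).
#' @export
encode_jpeg <- function(image, quality) {
  check_uint8_image(image)
  if (length(quality) != 1L || is.na(quality) || quality != round(quality) ||
      quality < 1 || quality > 100) {
    abort_param("`quality` must be an integer in [1, 100].")
  }
  bytes <- suppressWarnings(jpeg::writeJPEG(image / 255, raw(), quality = quality / 100))
  # libjpeg warns about coarse quantisation tables at extreme qualities;
  # that caution is inherent to the setting being studied
  decoded <- suppressWarnings(
    array(as.integer(round(jpeg::readJPEG(bytes) * 255)), dim = dim(image)))
  rec <- compression_record("jpeg", quality, compute_psnr(image, decoded),
                            length(bytes), prod(dim(image)))
  list(bytes = bytes, decoded = decoded, record = rec)
}

python_binary <- function() {
  bin <- getOption("histocompress.python", Sys.which("python"))
  if (!nzchar(bin)) {
    abort("no `python` binary found on PATH (needed for JPEG2000 codec calls); set options(histocompress.python=...).",
          class = "histocompress_codec_error")
  }
  bin
}

jp2_helper <- function() {
  path <- system.file("python", "jp2_codec.py", package = "histocompress")
  if (!nzchar(path)) abort("jp2_codec.py helper not found in the installed package.",
                           class = "histocompress_codec_error")
  path
}

run_jp2 <- function(args) {
  out <- suppressWarnings(system2(python_binary(), c(shQuote(jp2_helper()), args),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  if (status != 0L) {
    abort(paste0("JPEG2000 codec call failed: ", paste(out, collapse = "\n")),
          class = "histocompress_codec_error")
  }
  # last stdout line is the JSON payload
  jsonlite::fromJSON(out[length(out)], simplifyDataFrame = FALSE)
}

write_temp_png <- function(image, dir) {
  f <- tempfile("img", tmpdir = dir, fileext = ".png")
  png::writePNG(image / 255, f)
  f
}

read_decoded_png <- function(path, dims) {
  x <- png::readPNG(path)
  array(as.integer(round(x * 255)), dim = dims)
}

#' Losslessly encode an image with JPEG2000
#'
#' Reversible 5/3 wavelet, no truncation: the decoded image equals the input
#' bit-exactly and the achieved PSNR is the 100 dB cap.
#'
#' @inheritParams encode_jpeg
#' @return As [encode_jpeg()]: `bytes` is the compressed size in bytes (the
#'   codestream itself stays on disk only transiently), plus `decoded` and
#'   `record`.
#' @export
encode_jpeg2000_lossless <- function(image) {
  check_uint8_image(image)
  tmp <- tempfile("jp2work"); dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  src <- write_temp_png(image, tmp)
  jp2 <- file.path(tmp, "out.jp2")
  dec_png <- file.path(tmp, "out.png")
  res <- run_jp2(c("lossless", shQuote(src), shQuote(jp2),
                   "--decode-to", shQuote(dec_png)))
  decoded <- read_decoded_png(dec_png, dim(image))
  if (!isTRUE(res$exact) || !identical(decoded, image)) {
    abort("lossless JPEG2000 round-trip was not exact.",
          class = "histocompress_codec_error")
  }
  rec <- compression_record("jpeg2000-lossless", NA_real_, PSNR_CAP,
                            res$bytes, prod(dim(image)))
  list(bytes = res$bytes, decoded = decoded, record = rec)
}

#' JPEG2000 compression to a target PSNR
#'
#' Bisects the codec's compression-ratio parameter (on a log2 axis spanning
#' ratios 2^-10..1) with round-trip PSNR measurement until the achieved PSNR
#' is within `tol` of `target`. A target of 100 dB delegates to
#' [encode_jpeg2000_lossless()]. The achieved PSNR reported by the codec
#' helper is re-verified in R with [compute_psnr()].
#'
#' @inheritParams encode_jpeg
#' @param target Target PSNR in dB, in `[18, 100]`.
#' @param tol Attainment tolerance in dB (default 0.5).
#' @param max_iter Bisection iteration budget (default 30).
#' @param best_effort If `TRUE`, return the closest achievable encoding
#'   instead of erroring when the target cannot be met within `tol` (the
#'   record carries `converged = FALSE`). Sweeps use this so that ladder
#'   levels the codec cannot realise are kept with their achieved PSNR.
#' @return As [encode_jpeg()], with `record$control` the target PSNR.
#' @export
compress_to_target_psnr <- function(image, target, tol = 0.5, max_iter = 30L,
                                    best_effort = FALSE) {
  check_uint8_image(image)
  if (length(target) != 1L || is.na(target) || target < 18 || target > 100) {
    abort_param("`target` must be a PSNR in [18, 100] dB.")
  }
  if (tol <= 0) abort_param("`tol` must be > 0.")
  if (target >= PSNR_CAP) {
    out <- encode_jpeg2000_lossless(image)
    out$record$codec <- "jpeg2000"
    out$record$control <- target
    return(out)
  }
  res <- compress_psnr_ladder(image, target, tol = tol, max_iter = max_iter,
                              best_effort = best_effort)[[1]]
  res
}

#' JPEG2000 compression at several target PSNR levels in one call
#'
#' Runs the bisection of [compress_to_target_psnr()] for each target against
#' a single loaded image (one codec subprocess for the whole ladder).
#'
#' @inheritParams compress_to_target_psnr
#' @param targets Numeric vector of target PSNRs in dB (100 = lossless).
#' @return A named list (one element per target) of [encode_jpeg2000_lossless()]-style
#'   results.
#' @export
compress_psnr_ladder <- function(image, targets, tol = 0.5, max_iter = 30L,
                                 best_effort = FALSE) {
  check_uint8_image(image)
  if (!length(targets) || any(is.na(targets)) || any(targets < 18 | targets > 100)) {
    abort_param("`targets` must be PSNR values in [18, 100] dB.")
  }
  tmp <- tempfile("jp2work"); dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  src <- write_temp_png(image, tmp)
  prefix <- file.path(tmp, "lvl")
  res <- run_jp2(c("target", shQuote(src), shQuote(prefix),
                   "--targets", paste(targets, collapse = ","),
                   "--tol", format(tol), "--max-iter", max_iter))
  out <- lapply(res, function(r) {
    decoded <- read_decoded_png(r$png, dim(image))
    achieved <- compute_psnr(image, decoded)
    converged <- abs(achieved - r$target) <= tol || r$target >= PSNR_CAP
    if (!converged && !best_effort) {
      abort(sprintf(
        "PSNR target %.1f dB not attainable within %.2f dB in %d iterations (best achieved %.2f dB).",
        r$target, tol, max_iter, achieved),
        class = "histocompress_convergence_error")
    }
    rec <- compression_record("jpeg2000", r$target, achieved, r$bytes,
                              prod(dim(image)), converged = converged)
    list(bytes = r$bytes, decoded = decoded, record = rec,
         iterations = r$iterations, rate = r$rate)
  })
  names(out) <- paste0("psnr", targets)
  out
}

#' JPEG2000 compression to a byte budget
#'
#' Finds the largest reversible-wavelet encoding whose compressed size is at
#' most `max_ratio` times the raw bitmap size `H*W*3`, by bisection on the
#' rate axis.
#'
#' @inheritParams encode_jpeg
#' @param max_ratio Maximum allowed `compressed_bytes / raw_bytes`.
#' @param max_iter Bisection iteration budget.
#' @return As [encode_jpeg()].
#' @export
compress_to_target_ratio <- function(image, max_ratio, max_iter = 30L) {
  check_uint8_image(image)
  if (length(max_ratio) != 1L || is.na(max_ratio) || max_ratio <= 0 || max_ratio > 1) {
    abort_param("`max_ratio` must be in (0, 1].")
  }
  tmp <- tempfile("jp2work"); dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  src <- write_temp_png(image, tmp)
  prefix <- file.path(tmp, "budget")
  res <- run_jp2(c("ratio", shQuote(src), shQuote(prefix),
                   "--max-ratio", format(max_ratio), "--max-iter", max_iter))
  if (!is.null(res$error)) {
    abort(sprintf("byte budget %.3f unreachable (best %d bytes).",
                  max_ratio, res$bytes),
          class = "histocompress_convergence_error")
  }
  decoded <- read_decoded_png(res$png, dim(image))
  rec <- compression_record("jpeg2000", NA_real_, compute_psnr(image, decoded),
                            res$bytes, prod(dim(image)))
  list(bytes = res$bytes, decoded = decoded, record = rec,
       iterations = res$iterations)
}

#' JPEG encoding matched to a reference PSNR
#'
#' Searches the integer JPEG quality scale (bisection, PSNR is monotone in
#' quality up to codec noise) for the quality whose achieved PSNR is closest
#' to `target_psnr`. Used to compare JPEG and JPEG2000 compression ratios at
#' matched fidelity.
#'
#' @inheritParams encode_jpeg
#' @param target_psnr PSNR to match, in dB.
#' @return As [encode_jpeg()] for the best-matching quality.
#' @export
match_jpeg_to_psnr <- function(image, target_psnr) {
  check_uint8_image(image)
  lo <- 1L; hi <- 100L
  best <- NULL
  while (hi - lo > 1L) {
    q <- as.integer((lo + hi) %/% 2)
    enc <- encode_jpeg(image, q)
    if (is.null(best) ||
        abs(enc$record$achieved_psnr - target_psnr) <
        abs(best$record$achieved_psnr - target_psnr)) best <- enc
    if (enc$record$achieved_psnr < target_psnr) lo <- q else hi <- q
  }
  for (q in unique(c(lo, hi))) {
    enc <- encode_jpeg(image, q)
    if (abs(enc$record$achieved_psnr - target_psnr) <
        abs(best$record$achieved_psnr - target_psnr)) best <- enc
  }
  best
}
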
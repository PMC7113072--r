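#' Write a scene to a directory
#'
#' Layout: `image.png` (8-bit lossless), `label_mask.tiff` (16-bit lossless),
#' `region_mask.png` (region task), `centers.csv` (`row`, `col`, `class`) and
#' `manifest.json` holding the generation parameters and the file list.
#' Reading back with [read_scene()] reproduces every field exactly.
#'
#' @param scene A [generate_scene()] result.
#' @param directory Output directory (created if absent).
#' @return The manifest path, invisibly.
#' @export
write_scene <- function(scene, directory) {
  if (!inherits(scene, "scene")) abort_param("`scene` must be a scene object.")
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (max(scene$label_mask) > 65535L) {
    abort_format("label mask has more than 65535 objects; 16-bit storage overflows.")
  }
  files <- list(image = "image.png", label_mask = "label_mask.tiff",
                centers = "centers.csv")
  png::writePNG(scene$image / 255, file.path(directory, files$image))
  tiff::writeTIFF(scene$label_mask / 65535,
                  file.path(directory, files$label_mask),
                  bits.per.sample = 16L, compression = "deflate")
  if (!is.null(scene$region_mask)) {
    files$region_mask <- "region_mask.png"
    png::writePNG(scene$region_mask * 1.0, file.path(directory, files$region_mask))
  }
  utils::write.csv(scene$centers, file.path(directory, files$centers),
                   row.names = FALSE)
  manifest <- list(format_version = 1L, params = unclass(scene$params),
                   files = files)
  manifest_path <- file.path(directory, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest_path)
}

read_component <- function(directory, fname, what) {
  path <- file.path(directory, fname)
  if (!file.exists(path)) {
    abort_format(sprintf("scene component `%s` (%s) is missing from %s.",
                         what, fname, directory))
  }
  path
}

#' Read a scene written by [write_scene()]
#'
#' @param directory Directory containing `manifest.json` and components.
#' @return A `scene` object.
#' @export
read_scene <- function(directory) {
  manifest_path <- file.path(directory, "manifest.json")
  if (!file.exists(manifest_path)) {
    abort_format(sprintf("no manifest.json in %s.", directory))
  }
  manifest <- jsonlite::fromJSON(manifest_path)
  p <- manifest$params
  params <- scene_params(width = p$width, height = p$height, task = p$task,
                         cell_density = p$cell_density,
                         nucleus_radius_mean = p$nucleus_radius_mean,
                         nucleus_radius_sd = p$nucleus_radius_sd,
                         eccentricity_range = p$eccentricity_range,
                         stain_fg = p$stain_fg, stain_bg = p$stain_bg,
                         stain_distractor = p$stain_distractor,
                         stain_clutter = p$stain_clutter,
                         clutter_density = p$clutter_density,
                         illumination_sd = p$illumination_sd,
                         texture_sd = p$texture_sd, noise_sd = p$noise_sd,
                         region_fraction = p$region_fraction,
                         distractor_ratio = p$distractor_ratio, seed = p$seed)
  img_raw <- png::readPNG(read_component(directory, manifest$files$image, "image"))
  H <- dim(img_raw)[1]; W <- dim(img_raw)[2]
  image <- array(as.integer(round(img_raw * 255)), dim = c(H, W, 3))
  lab_raw <- tiff::readTIFF(read_component(directory, manifest$files$label_mask,
                                           "label_mask"))
  label_mask <- matrix(as.integer(round(lab_raw * 65535)), nrow(lab_raw), ncol(lab_raw))
  region_mask <- NULL
  if (!is.null(manifest$files$region_mask)) {
    rm_raw <- png::readPNG(read_component(directory, manifest$files$region_mask,
                                          "region_mask"))
    region_mask <- matrix(rm_raw > 0.5, nrow(rm_raw), ncol(rm_raw))
  }
  centers_path <- read_component(directory, manifest$files$centers, "centers")
  centers <- utils::read.csv(centers_path, stringsAsFactors = FALSE)
  if (!all(c("row", "col", "class") %in% names(centers))) {
    abort_format(sprintf("centers file %s lacks row/col/class columns.", centers_path))
  }
  centers <- as_tibble(centers)
  if (nrow(centers)) {
    bad <- centers$row < 1 | centers$row > H | centers$col < 1 | centers$col > W
    if (any(bad)) abort_format("centers file contains out-of-bounds coordinates.")
  } else {
    centers <- tibble(row = numeric(0), col = numeric(0), class = character(0))
  }
  structure(list(image = image, label_mask = label_mask,
                 region_mask = region_mask, centers = centers, params = params),
            class = "scene")
}
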
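# Image and report I/O: PNG/TIFF in, PNG masks and CSV/JSON/Newick out.

#' Read an RGB image from PNG or TIFF
#'
#' @param path file path; format chosen by extension.
#' @return numeric array `height x width x 3` with values in 0..255.
#' @export
read_image_rgb <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "': ", path))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  round(img * 255)
}

#' Write an RGB image (0..255 array) as PNG
#' @param img `height x width x 3` array, values 0..255.
#' @param path output path.
#' @export
write_image_png <- function(img, path) {
  png::writePNG(img / 255, path)
  invisible(path)
}

#' Write a binary mask as single-channel PNG (0/255)
#' @param mask 0/1 matrix.
#' @param path output path.
#' @export
write_mask_png <- function(mask, path) {
  check_mask(mask)
  png::writePNG(mask + 0.0, path)  # 1 -> 255 in the 8-bit file
  invisible(path)
}

#' Read a single-channel PNG mask back to 0/1
#' @param path PNG path.
#' @return 0/1 integer matrix.
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(m > 0.5), nrow(m), ncol(m))
}

#' QC overlay of segmentation boundaries
#'
#' Renders the input with villous boundaries in white and capillary
#' boundaries in green, the conventional segmentation QC view.
#'
#' @param img RGB array.
#' @param villi binary villous mask.
#' @param capillaries binary capillary mask.
#' @return RGB array with boundary pixels recolored.
#' @export
overlay_qc <- function(img, villi, capillaries) {
  vb <- boundary_pixels(villi == 1L, 8L)
  cb <- boundary_pixels(capillaries == 1L, 8L)
  out <- img
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[vb] <- 255
    plane[cb] <- if (ch == 2) 255 else 0
    out[, , ch] <- plane
  }
  out
}

#' Write a synthetic scene bundle to disk
#'
#' Image and ground-truth masks as PNG, truth records as CSV, scene
#' parameters as JSON — everything needed to reload or audit a scene.
#'
#' @param scene a [generate_image()] result.
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "synthetic_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_image_png(scene$image, file.path(dir, "image.png"))
  write_mask_png(scene$villi_mask, file.path(dir, "villi_mask.png"))
  write_mask_png(scene$capillary_mask, file.path(dir, "capillary_mask.png"))
  write_mask_png(scene$blood_mask, file.path(dir, "blood_mask.png"))
  utils::write.csv(scene$villous_records,
                   file.path(dir, "villous_records.csv"), row.names = FALSE)
  utils::write.csv(scene$capillary_records,
                   file.path(dir, "capillary_records.csv"), row.names = FALSE)
  p <- scene$params
  class(p) <- NULL
  jsonlite::write_json(p, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
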
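#' Convert an RGB micrograph to grayscale
#'
#' Luminance conversion by the standard ITU-R BT.601 weighted sum
#' `0.2989 * R + 0.5870 * G + 0.1140 * B`, rounded half-away-from-zero to the
#' nearest integer and clamped to `[0, 255]`.
#'
#' @param img RGB image: numeric array of dimension `height x width x 3` with
#'   integer channel values in `[0, 255]`.
#' @return Integer matrix (`height x width`) of gray levels in `[0, 255]`.
#' @examples
#' px <- array(c(255, 0, 0), dim = c(1, 1, 3))
#' rgb_to_gray(px)  # 76
#' @export
rgb_to_gray <- function(img) {
  stopifnot(is.array(img), length(dim(img)) == 3L, dim(img)[3] == 3L)
  if (min(img) < 0 || max(img) > 255)
    stop("RGB channel values must lie in [0, 255]")
  g <- 0.2989 * img[, , 1] + 0.5870 * img[, , 2] + 0.1140 * img[, , 3]
  # round half away from zero; values are non-negative here
  g <- trunc(g + 0.5)
  g[g < 0] <- 0; g[g > 255] <- 255
  storage.mode(g) <- "integer"
  matrix(g, dim(img)[1], dim(img)[2])
}

#' Median-filter a grayscale image
#'
#' Each output pixel is the median of the `window x window` neighborhood of
#' the input; the image border is handled by edge replication, so corner and
#' edge pixels see a full (replicated) window.
#'
#' @param img integer matrix of gray levels.
#' @param window odd window side length, at least 3. Default 3.
#' @return filtered integer matrix of the same dimension.
#' @export
median_filter <- function(img, window = 3L) {
  stopifnot(is.matrix(img))
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("median filter window must be an odd integer >= 3")
  h <- nrow(img); w <- ncol(img)
  half <- window %/% 2L
  k <- window * window
  stack <- matrix(0L, h * w, k)
  col_i <- 0L
  for (dy in -half:half) {
    ri <- pmin.int(pmax.int(seq_len(h) + dy, 1L), h)  # replicate edges
    for (dx in -half:half) {
      ci <- pmin.int(pmax.int(seq_len(w) + dx, 1L), w)
      col_i <- col_i + 1L
      stack[, col_i] <- img[ri, ci]
    }
  }
  med <- row_median(stack)
  out <- matrix(as.integer(med), h, w)
  out
}

# Row-wise median of a matrix with an odd number of columns.  The 9-column
# case (3x3 window) uses a fixed comparison network so the whole image is
# processed with vectorized pmin/pmax; other widths fall back to apply().
row_median <- function(m) {
  k <- ncol(m)
  if (k == 9L) {
    s <- function(i, j) {
      lo <- pmin.int(m[, i], m[, j]); hi <- pmax.int(m[, i], m[, j])
      m[, i] <<- lo; m[, j] <<- hi
    }
    # median-of-9 selection network (Paeth's opt_med9)
    s(2,3); s(5,6); s(8,9); s(1,2); s(4,5); s(7,8)
    s(2,3); s(5,6); s(8,9); s(1,4); s(6,9); s(5,8)
    s(4,7); s(2,5); s(3,6); s(5,8); s(5,3); s(7,5); s(5,3)
    m[, 5]
  } else {
    apply(m, 1L, stats::median)
  }
}

#' Global histogram equalization
#'
#' Standard cumulative-histogram remapping of an 8-bit grayscale image: level
#' `v` maps to `round(255 * cdf(v))` where `cdf` is the empirical cumulative
#' distribution of gray levels. The mapping is monotone non-decreasing, so
#' intensity ordering is preserved.
#'
#' @param img integer matrix of gray levels in `[0, 255]`.
#' @return equalized integer matrix.
#' @export
equalize_histogram <- function(img) {
  stopifnot(is.matrix(img))
  v <- as.integer(img)
  if (min(v) < 0 || max(v) > 255) stop("gray levels must lie in [0, 255]")
  counts <- tabulate(v + 1L, nbins = 256L)
  if (sum(counts > 0L) == 1L) return(img)  # constant image: leave untouched
  cdf <- cumsum(counts) / length(v)
  map <- as.integer(round(255 * cdf))
  matrix(map[v + 1L], nrow(img), ncol(img))
}

#' Preprocess an RGB micrograph for segmentation
#'
#' Grayscale conversion, median denoising and global contrast enhancement in
#' one call. The filter/equalization order is configurable because the two
#' operations do not commute; median-first is the default (denoise before
#' stretching contrast amplifies noise).
#'
#' @param img RGB array (`height x width x 3`, values in 0..255).
#' @param window median filter window (odd, >= 3).
#' @param equalize_first if `TRUE`, equalize the histogram before median
#'   filtering instead of after.
#' @return integer grayscale matrix ready for thresholding.
#' @export
preprocess_image <- function(img, window = 3L, equalize_first = FALSE) {
  g <- rgb_to_gray(img)
  if (equalize_first) median_filter(equalize_histogram(g), window)
  else equalize_histogram(median_filter(g, window))
}
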
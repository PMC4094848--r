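#' Otsu threshold of a grayscale image
#'
#' Exhaustive search over the 256-bin gray-level histogram for the threshold
#' maximizing the between-class variance
#' \eqn{\sigma_B^2(t) = \omega_0(t)\,\omega_1(t)\,(\mu_0(t)-\mu_1(t))^2},
#' where class 0 holds levels `<= t` and class 1 levels `> t`. For an H&E
#' section the gray histogram is bimodal (bright background, darker villous
#' tissue) and the maximizer sits in the valley between the modes. Ties are
#' broken toward the smallest level so the result is deterministic.
#'
#' @param img integer matrix of gray levels in `[0, 255]`.
#' @return integer threshold `t` in `[0, 254]`.
#' @export
otsu_threshold <- function(img) {
  v <- as.integer(img)
  if (min(v) < 0 || max(v) > 255) stop("gray levels must lie in [0, 255]")
  counts <- tabulate(v + 1L, nbins = 256L)
  if (sum(counts > 0L) < 2L)
    stop("degenerate input: image has fewer than 2 distinct gray levels")
  n <- length(v)
  p <- counts / n
  levels <- 0:255
  omega0 <- cumsum(p)                 # P(level <= t)
  mu_cum <- cumsum(p * levels)        # E[level * 1(level <= t)]
  mu_T <- mu_cum[256L]
  omega1 <- 1 - omega0
  # between-class variance; undefined where a class is empty
  num <- (mu_T * omega0 - mu_cum)^2
  den <- omega0 * omega1
  sigma_b <- ifelse(den > 0, num / den, -Inf)
  sigma_b <- sigma_b[1:255]           # t = 255 leaves class 1 empty
  t <- which.max(sigma_b) - 1L        # which.max takes the first (smallest) max
  t
}

#' Binarize a grayscale image into a tissue mask
#'
#' Marks the tissue class of an Otsu-thresholded image with 1s. H&E tissue is
#' darker than the glass background in grayscale, so under `"auto"` polarity
#' the class with the lower mean input intensity is taken as tissue;
#' `"dark-tissue"` and `"bright-tissue"` force the choice.
#'
#' @param img integer matrix of gray levels.
#' @param t threshold in `[0, 255]`; pixels `<= t` form the dark class.
#' @param polarity one of `"auto"`, `"dark-tissue"`, `"bright-tissue"`.
#' @return binary integer matrix (0/1) with tissue = 1.
#' @export
binarize_villi <- function(img, t, polarity = c("auto", "dark-tissue", "bright-tissue")) {
  polarity <- match.arg(polarity)
  stopifnot(is.matrix(img), t >= 0, t <= 255)
  dark <- img <= t
  if (polarity == "auto") {
    mean_dark <- if (any(dark)) mean(img[dark]) else Inf
    mean_bright <- if (any(!dark)) mean(img[!dark]) else Inf
    polarity <- if (mean_dark <= mean_bright) "dark-tissue" else "bright-tissue"
  }
  mask <- if (polarity == "dark-tissue") dark else !dark
  matrix(as.integer(mask), nrow(img), ncol(img))
}

#' Remove small islands and fill small holes in a binary mask
#'
#' Foreground connected components smaller than `min_area` pixels are
#' deleted; background holes (background components not touching the image
#' border) smaller than `hole_area_cap` are filled. In villous masks the
#' filled holes are mostly capillary lumina, which belong to the villous
#' region for area accounting.
#'
#' @param mask binary integer matrix (0/1).
#' @param min_area minimum foreground component area kept, in pixels.
#' @param hole_area_cap holes strictly smaller than this are filled; `0`
#'   disables hole filling.
#' @param connectivity foreground connectivity, 4 or 8 (holes use the dual).
#' @return cleaned binary integer matrix.
#' @export
remove_islands <- function(mask, min_area = 64L, hole_area_cap = 0L,
                           connectivity = 8L) {
  check_mask(mask)
  out <- mask
  if (any(out == 1L) && min_area > 0L) {
    lab <- label_regions(out, connectivity)
    if (lab$n_regions > 0L) {
      sizes <- tabulate(lab$labels[lab$labels > 0L], nbins = lab$n_regions)
      drop <- which(sizes < min_area)
      if (length(drop)) out[lab$labels %in% drop] <- 0L
    }
  }
  if (hole_area_cap > 0L) {
    # holes: background components under the dual connectivity that do not
    # touch the image border
    dual <- if (connectivity == 8L) 4L else 8L
    comp <- label_regions(1L - out, dual)
    if (comp$n_regions > 0L) {
      border_labels <- unique(c(comp$labels[1, ], comp$labels[nrow(out), ],
                                comp$labels[, 1], comp$labels[, ncol(out)]))
      sizes <- tabulate(comp$labels[comp$labels > 0L], nbins = comp$n_regions)
      fill <- setdiff(which(sizes < hole_area_cap), border_labels)
      if (length(fill)) out[comp$labels %in% fill] <- 1L
    }
  }
  out
}

#' Label connected components of a binary mask
#'
#' Maximal connected components under 4- or 8-connectivity, labeled
#' `1..K` in raster-scan order of each component's first pixel
#' (deterministic).
#'
#' @param mask binary integer matrix (0/1).
#' @param connectivity 4 (edge-adjacent) or 8 (edge- or corner-adjacent).
#' @return list with `labels` (integer matrix, 0 = background) and
#'   `n_regions` (K).
#' @export
label_regions <- function(mask, connectivity = 8L) {
  check_mask(mask)
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  h <- nrow(mask); w <- ncol(mask)
  fg <- which(mask == 1L)            # column-major linear indices
  labels <- matrix(0L, h, w)
  if (!length(fg)) return(list(labels = labels, n_regions = 0L))
  node <- integer(h * w)
  node[fg] <- seq_along(fg)
  row_of <- ((fg - 1L) %% h) + 1L
  col_of <- ((fg - 1L) %/% h) + 1L
  offs <- list(c(1L, 0L), c(0L, 1L))                 # down, right
  if (connectivity == 8L)
    offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))     # the two diagonals
  edges <- integer(0)
  for (o in offs) {
    nr <- row_of + o[1]; nc <- col_of + o[2]
    ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
    nb <- (nc[ok] - 1L) * h + nr[ok]
    keep <- node[nb] > 0L
    if (any(keep))
      edges <- c(edges, rbind(node[fg[ok]][keep], node[nb][keep]))
  }
  memb <- if (length(edges)) {
    g <- igraph::make_graph(edges, n = length(fg), directed = FALSE)
    igraph::components(g)$membership
  } else {
    seq_along(fg)
  }
  # relabel components 1..K by raster order of first appearance
  first <- !duplicated(memb)
  relabel <- integer(max(memb))
  relabel[memb[first]] <- seq_len(sum(first))
  labels[fg] <- relabel[memb]
  list(labels = labels, n_regions = max(relabel))
}

#' Morphological capillary segmentation inside villi
#'
#' Detects the pale capillary lumina that appear as small bright structures
#' inside the darker villous tissue. The grayscale image restricted to the
#' villous mask is morphologically opened with a 3 x 3 square structuring
#' element applied `iterations` times; the opening erases bright structures
#' up to about `2 * iterations + 1` pixels across, so the residue
#' (image minus opening) is large exactly at the lumina. The residue is
#' thresholded and the result intersected with the villous mask, of which it
#' is therefore always a subset.
#'
#' @param img integer grayscale matrix (use the unequalized or preprocessed
#'   image consistently across a study).
#' @param villi binary villous mask aligned with `img`.
#' @param iterations number of 3 x 3 opening passes; bounds the detectable
#'   lumen diameter.
#' @param resid_threshold minimum residue (gray levels) for a capillary pixel.
#' @param min_area small detections below this area are discarded.
#' @return binary capillary mask, subset of `villi`.
#' @export
morph_capillaries <- function(img, villi, iterations = 8L,
                              resid_threshold = 40L, min_area = 4L) {
  stopifnot(is.matrix(img))
  check_mask(villi)
  stopifnot(all(dim(img) == dim(villi)))
  if (!any(villi == 1L)) return(matrix(0L, nrow(img), ncol(img)))
  g <- img
  g[villi == 0L] <- 0L                       # outside villi: flat zero
  gn <- g / 255                              # EBImage works on [0,1]
  brush <- EBImage::makeBrush(3L, shape = "box")
  op <- gn
  for (i in seq_len(iterations)) op <- EBImage::erode(op, brush)
  for (i in seq_len(iterations)) op <- EBImage::dilate(op, brush)
  resid <- (gn - op) * 255
  # the residue also rings around dark structures (nuclear rims, blood);
  # a lumen must additionally be brighter than the villous stroma level
  floor_level <- stats::median(img[villi == 1L]) + resid_threshold
  mask <- matrix(as.integer(resid >= resid_threshold &
                              img >= floor_level & villi == 1L),
                 nrow(img), ncol(img))
  remove_islands(mask, min_area = min_area, hole_area_cap = 0L)
}

# Published standard H&E optical-density stain vectors (hematoxylin, eosin)
# with the residual channel completed as their normalized cross product.
#' Default H&E stain matrix for color deconvolution
#'
#' Columns are unit optical-density direction vectors for hematoxylin,
#' eosin, and a residual channel orthogonal to both.
#'
#' @return 3 x 3 numeric matrix with unit-norm columns.
#' @export
he_stain_matrix <- function() {
  h <- c(0.650, 0.704, 0.286)
  e <- c(0.072, 0.990, 0.105)
  r <- c(h[2] * e[3] - h[3] * e[2],
         h[3] * e[1] - h[1] * e[3],
         h[1] * e[2] - h[2] * e[1])
  m <- cbind(hematoxylin = h / sqrt(sum(h^2)),
             eosin       = e / sqrt(sum(e^2)),
             residual    = r / sqrt(sum(r^2)))
  rownames(m) <- c("R", "G", "B")
  m
}

#' Color deconvolution of an H&E image
#'
#' Unmixes per-pixel stain contributions via the Beer-Lambert law: optical
#' density `OD = -log10((I + 1) / 256)` per channel (so a saturated-white
#' pixel has exactly zero density), projected onto the stain directions by
#' the inverse stain matrix. Densities are clamped at zero (negative
#' densities are unphysical unmixing residue).
#'
#' @param img RGB array (`height x width x 3`, 0..255).
#' @param stains 3 x 3 stain matrix, columns = unit OD vectors
#'   (default [he_stain_matrix()]).
#' @return array `height x width x 3` of stain densities, channels named
#'   after the stain matrix columns.
#' @export
color_deconvolve <- function(img, stains = he_stain_matrix()) {
  stopifnot(is.array(img), length(dim(img)) == 3L, dim(img)[3] == 3L)
  if (abs(det(stains)) < 1e-8) stop("singular stain matrix")
  od <- -log10((img + 1) / 256)              # h x w x 3; white -> OD 0
  h <- dim(img)[1]; w <- dim(img)[2]
  odm <- matrix(od, ncol = 3L)               # pixels x channels
  dens <- odm %*% t(solve(stains))
  dens[dens < 0] <- 0
  out <- array(dens, dim = c(h, w, 3L))
  dimnames(out) <- list(NULL, NULL, colnames(stains))
  out
}

#' Reconstruct an RGB image from stain densities
#'
#' Forward Beer-Lambert model, the inverse of [color_deconvolve()]; used for
#' round-trip checks and QC renders.
#'
#' @param dens density array from [color_deconvolve()].
#' @param stains the stain matrix used for deconvolution.
#' @return RGB array with values in `[0, 255]` (not rounded).
#' @export
stain_render <- function(dens, stains = he_stain_matrix()) {
  h <- dim(dens)[1]; w <- dim(dens)[2]
  od <- matrix(dens, ncol = 3L) %*% t(stains)
  rgb <- 256 * 10^(-od) - 1                  # invert OD = -log10((I+1)/256)
  rgb[rgb < 0] <- 0; rgb[rgb > 255] <- 255
  array(rgb, dim = c(h, w, 3L))
}

#' Convert an RGB image to CIELAB
#'
#' Standard sRGB to CIELAB conversion under the D65 white point. The b*
#' channel spans blue (negative) to yellow/red (positive), which separates
#' blood (strongly positive b*) from hematoxylin/eosin hues (negative b*).
#'
#' @param img RGB array (`height x width x 3`, 0..255).
#' @return array `height x width x 3` with channels L*, a*, b*.
#' @export
rgb_to_lab <- function(img) {
  stopifnot(is.array(img), length(dim(img)) == 3L, dim(img)[3] == 3L)
  h <- dim(img)[1]; w <- dim(img)[2]
  srgb <- matrix(img, ncol = 3L) / 255
  lab <- grDevices::convertColor(srgb, from = "sRGB", to = "Lab")
  out <- array(lab, dim = c(h, w, 3L))
  dimnames(out) <- list(NULL, NULL, c("L", "a", "b"))
  out
}

#' Blood-filled capillary segmentation
#'
#' Marks pixels inside villi whose color is blood-like: eosin/residual
#' optical density above `density_threshold` (blood absorbs outside the
#' hematoxylin direction) and CIELAB b* above `b_threshold` (red/yellow hue;
#' H&E stains themselves sit at negative b*). The result is a subset of the
#' villous mask by construction.
#'
#' @param img RGB array.
#' @param villi binary villous mask.
#' @param stains stain matrix for deconvolution.
#' @param b_threshold minimum b* for a blood pixel.
#' @param density_threshold minimum eosin+residual optical density.
#' @param min_area detections below this area are discarded.
#' @return binary mask of blood-filled capillary pixels.
#' @export
blood_capillary_mask <- function(img, villi, stains = he_stain_matrix(),
                                 b_threshold = 10, density_threshold = 0.15,
                                 min_area = 4L) {
  check_mask(villi)
  dens <- color_deconvolve(img, stains)
  lab <- rgb_to_lab(img)
  non_h <- dens[, , 2] + dens[, , 3]
  mask <- matrix(as.integer(lab[, , 3] >= b_threshold &
                              non_h >= density_threshold &
                              villi == 1L),
                 nrow(villi), ncol(villi))
  remove_islands(mask, min_area = min_area, hole_area_cap = 0L)
}

#' Combine morphological and blood capillary masks
#'
#' Pixelwise union of the lumen-based and blood-based capillary detections,
#' restricted to the villous mask, cleaned with [remove_islands()], and
#' labeled. Overlapping detections of the same vessel merge into a single
#' component.
#'
#' @param morph capillary mask from [morph_capillaries()].
#' @param blood capillary mask from [blood_capillary_mask()].
#' @param villi villous mask.
#' @param connectivity component connectivity for labeling.
#' @param min_area island-removal floor applied to the union.
#' @return `label_regions()`-style list (`labels`, `n_regions`).
#' @export
combine_capillaries <- function(morph, blood, villi, connectivity = 8L,
                                min_area = 4L) {
  check_mask(morph); check_mask(blood); check_mask(villi)
  stopifnot(all(dim(morph) == dim(blood)), all(dim(morph) == dim(villi)))
  u <- matrix(as.integer((morph == 1L | blood == 1L) & villi == 1L),
              nrow(villi), ncol(villi))
  u <- remove_islands(u, min_area = min_area, hole_area_cap = 0L,
                      connectivity = connectivity)
  label_regions(u, connectivity)
}

#' Segment villi from a preprocessed grayscale image
#'
#' Otsu threshold, polarity resolution, island removal and hole filling in
#' one call: the standard villous-mask path.
#'
#' @param gray preprocessed grayscale matrix.
#' @param polarity passed to [binarize_villi()].
#' @param min_area minimum villous component area (px).
#' @param hole_area_cap holes below this area (capillary lumina) are filled.
#' @return binary villous mask.
#' @export
segment_villi <- function(gray, polarity = "auto", min_area = 64L,
                          hole_area_cap = 400L) {
  t <- otsu_threshold(gray)
  mask <- binarize_villi(gray, t, polarity)
  remove_islands(mask, min_area = min_area, hole_area_cap = hole_area_cap)
}

#' Dice overlap coefficient between two binary masks
#'
#' @param a,b binary matrices of equal dimension.
#' @return `2|A n B| / (|A| + |B|)`; 1 when both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  sa <- sum(a == 1L); sb <- sum(b == 1L)
  if (sa + sb == 0L) return(1)
  2 * sum(a == 1L & b == 1L) / (sa + sb)
}

check_mask <- function(mask) {
  if (!is.matrix(mask) || !all(mask %in% c(0L, 1L)))
    stop("mask must be a 0/1 matrix")
  invisible(TRUE)
}
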
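#' Area of a labeled region
#'
#' Area in the pixel-counting sense: the number of pixels carrying the
#' region's label, \eqn{\mathrm{Area} = \sum_x \sum_y f(x,y)} for the
#' region's indicator image f.
#'
#' @param labeled a `label_regions()` result (or plain label matrix).
#' @param label region id.
#' @return integer pixel count.
#' @export
region_area <- function(labeled, label) {
  lm <- label_matrix(labeled)
  a <- sum(lm == label)
  if (a == 0L) stop("unknown label: ", label)
  a
}

#' Perimeter of a labeled region
#'
#' The number of boundary pixels of the region: region pixels with at least
#' one background (or other-region) neighbor under the chosen neighborhood.
#' Pixels on the image border count as boundary (out-of-image is background).
#'
#' @param labeled a `label_regions()` result (or plain label matrix).
#' @param label region id.
#' @param connectivity neighborhood used for the background-adjacency test,
#'   4 (default, the literal "boundary pixel" definition) or 8.
#' @return integer boundary-pixel count.
#' @export
region_perimeter <- function(labeled, label, connectivity = 4L) {
  lm <- label_matrix(labeled)
  reg <- lm == label
  if (!any(reg)) stop("unknown label: ", label)
  sum(boundary_pixels(reg, connectivity))
}

# logical matrix of region pixels adjacent to background (padded with bg)
boundary_pixels <- function(reg, connectivity = 4L) {
  h <- nrow(reg); w <- ncol(reg)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- reg
  offs <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (connectivity == 8L)
    offs <- c(offs, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
  any_bg <- matrix(FALSE, h, w)
  for (o in offs) {
    nb <- pad[(2:(h + 1L)) + o[1], (2:(w + 1L)) + o[2], drop = FALSE]
    any_bg <- any_bg | !nb
  }
  reg & any_bg
}

#' Equivalent-circle diameter
#'
#' Diameter of the circle with the same area as the region,
#' \eqn{\sqrt{4 \cdot \mathrm{Area} / \pi}}.
#'
#' @param area region area (px or um^2); vectorized.
#' @return diameter in the corresponding length unit.
#' @export
equivalent_diameter <- function(area) {
  if (any(area < 0)) stop("area must be non-negative")
  sqrt(4 * area / pi)
}

#' Capillarization index
#'
#' `CI = total capillary area / total villous area * 100`, the percentage of
#' villous tissue occupied by capillaries.
#'
#' @param total_cap_area summed capillary area.
#' @param total_villous_area summed villous area; must be positive.
#' @return CI in percent.
#' @export
capillarization_index <- function(total_cap_area, total_villous_area) {
  if (any(total_villous_area <= 0)) stop("villous area must be positive")
  100 * total_cap_area / total_villous_area
}

#' Per-villous capillarization index
#'
#' For one villous: the summed area of the capillaries it contains over its
#' own area, times 100. A villous without capillaries scores 0. Subjects are
#' summarized by the unweighted mean over their villi (see
#' [subject_features()]).
#'
#' @param cap_area_in_villous summed capillary area inside the parent
#'   villous; vectorized over villi.
#' @param parent_villous_area the parent villous area(s); must be positive.
#' @return per-villous CI in percent.
#' @export
capillarization_index_per_villous <- function(cap_area_in_villous,
                                              parent_villous_area) {
  if (any(parent_villous_area <= 0)) stop("parent villous area must be positive")
  100 * cap_area_in_villous / parent_villous_area
}

#' Per-region feature table of a labeled mask
#'
#' Area, perimeter and equivalent diameter for every region, in pixels and
#' in physical units via the pixel size.
#'
#' @param labeled a `label_regions()` result.
#' @param pixel_size pixel edge length in micrometers (default 0.63).
#' @param connectivity perimeter boundary test neighborhood.
#' @return data.frame with columns `label`, `area_px`, `perimeter_px`,
#'   `diameter_px`, `area_um2`, `perimeter_um`, `diameter_um`.
#' @export
region_features <- function(labeled, pixel_size = 0.63, connectivity = 4L) {
  lm <- label_matrix(labeled)
  k <- max(lm)
  if (k == 0L) {
    return(data.frame(label = integer(), area_px = integer(),
                      perimeter_px = integer(), diameter_px = numeric(),
                      area_um2 = numeric(), perimeter_um = numeric(),
                      diameter_um = numeric()))
  }
  areas <- tabulate(lm[lm > 0L], nbins = k)
  per <- integer(k)
  for (i in seq_len(k)) per[i] <- sum(boundary_pixels(lm == i, connectivity))
  data.frame(
    label = seq_len(k),
    area_px = areas,
    perimeter_px = per,
    diameter_px = equivalent_diameter(areas),
    area_um2 = areas * pixel_size^2,
    perimeter_um = per * pixel_size,
    diameter_um = equivalent_diameter(areas) * pixel_size
  )
}

#' Assign capillaries to parent villi
#'
#' Each capillary component is assigned to the villous component holding the
#' majority of its pixels (ties toward the smaller villous label).
#'
#' @param capillaries labeled capillary mask.
#' @param villi labeled villous mask.
#' @return integer vector, entry i = villous label of capillary i (0 when a
#'   capillary has no overlap with any villous).
#' @export
assign_capillaries <- function(capillaries, villi) {
  cm <- label_matrix(capillaries); vm <- label_matrix(villi)
  kc <- max(cm)
  if (kc == 0L) return(integer())
  out <- integer(kc)
  idx <- which(cm > 0L)
  if (!length(idx)) return(out)
  tab <- table(cap = cm[idx], villous = vm[idx])
  for (i in seq_len(kc)) {
    row <- tab[as.character(i), , drop = TRUE]
    vlabs <- as.integer(colnames(tab))
    keep <- vlabs > 0L
    if (!any(keep) || all(row[keep] == 0)) { out[i] <- 0L; next }
    out[i] <- vlabs[keep][which.max(row[keep])]
  }
  out
}

#' The ten morphometric features of a subject
#'
#' Aggregates labeled villous and capillary masks over all of a subject's
#' images into one feature vector:
#' counts are summed over images; area, perimeter and equivalent diameter
#' are per-region means over all regions of the subject; the
#' capillarization index (CI) is computed from summed areas; the per-villous
#' CI is the unweighted mean over all villi (villi without capillaries
#' contribute 0). Lengths/areas are reported in pixels, with micrometer
#' counterparts via `pixel_size`.
#'
#' @param villi list of labeled villous masks, one per image.
#' @param capillaries list of labeled capillary masks, parallel to `villi`.
#' @param pixel_size pixel edge length in micrometers.
#' @param connectivity perimeter neighborhood.
#' @return one-row data.frame with the ten features (`villous_count`,
#'   `villous_area`, `villous_perimeter`, `villous_diameter`,
#'   `capillary_count`, `capillary_area`, `capillary_perimeter`,
#'   `capillary_diameter`, `capillarization_index`,
#'   `capillarization_index_per_villous`; px units) plus `*_um` /
#'   `*_um2` columns and summed totals.
#' @export
subject_features <- function(villi, capillaries, pixel_size = 0.63,
                             connectivity = 4L) {
  if (!length(villi)) stop("empty image list")
  stopifnot(length(villi) == length(capillaries))
  vfeat <- list(); cfeat <- list(); ci_villous <- numeric()
  for (i in seq_along(villi)) {
    vf <- region_features(villi[[i]], pixel_size, connectivity)
    cf <- region_features(capillaries[[i]], pixel_size, connectivity)
    parent <- assign_capillaries(capillaries[[i]], villi[[i]])
    cap_in_villous <- rep(0, nrow(vf))
    if (length(parent)) {
      agg <- tapply(cf$area_px, parent, sum)
      hit <- as.integer(names(agg))
      ok <- hit > 0L
      cap_in_villous[hit[ok]] <- agg[ok]
    }
    if (nrow(vf))
      ci_villous <- c(ci_villous,
                      capillarization_index_per_villous(cap_in_villous, vf$area_px))
    vfeat[[i]] <- vf; cfeat[[i]] <- cf
  }
  vf <- do.call(rbind, vfeat); cf <- do.call(rbind, cfeat)
  tot_v_area <- sum(vf$area_px); tot_c_area <- sum(cf$area_px)
  mean0 <- function(x) if (length(x)) mean(x) else 0
  data.frame(
    villous_count = nrow(vf),
    villous_area = mean0(vf$area_px),
    villous_perimeter = mean0(vf$perimeter_px),
    villous_diameter = mean0(vf$diameter_px),
    capillary_count = nrow(cf),
    capillary_area = mean0(cf$area_px),
    capillary_perimeter = mean0(cf$perimeter_px),
    capillary_diameter = mean0(cf$diameter_px),
    capillarization_index =
      if (tot_v_area > 0) capillarization_index(tot_c_area, tot_v_area) else 0,
    capillarization_index_per_villous = mean0(ci_villous),
    villous_area_um2 = mean0(vf$area_um2),
    villous_perimeter_um = mean0(vf$perimeter_um),
    villous_diameter_um = mean0(vf$diameter_um),
    capillary_area_um2 = mean0(cf$area_um2),
    capillary_perimeter_um = mean0(cf$perimeter_um),
    capillary_diameter_um = mean0(cf$diameter_um),
    total_villous_area_px = tot_v_area,
    total_capillary_area_px = tot_c_area
  )
}

#' Canonical feature column names
#'
#' The ten morphometric features in their conventional reporting order.
#' @return character vector of length 10.
#' @export
feature_names <- function() {
  c("villous_count", "villous_area", "villous_perimeter", "villous_diameter",
    "capillary_count", "capillary_area", "capillary_perimeter",
    "capillary_diameter", "capillarization_index",
    "capillarization_index_per_villous")
}

label_matrix <- function(labeled) {
  if (is.list(labeled)) labeled$labels else labeled
}
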
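# Synthetic H&E scenes and synthetic cohorts.
#
# No public image archive accompanies the study design this package
# implements, so every downstream stage is exercised against synthetic data:
# (a) rendered H&E-like scenes with ground-truth masks, for the image
# pipeline, and (b) per-subject feature tables drawn from published group
# means/SDs, for the statistics. Scene-level parameters (pixels) are
# deliberately decoupled from cohort-table parameters: per-image geometry
# cannot be inverted from per-subject summary statistics.

#' Scene parameters for the synthetic H&E renderer
#'
#' Defaults mirror the nominal acquisition geometry (1388 x 1040 px at
#' 0.63 um/px under a 10x objective) and plausible villous/capillary sizes at
#' that magnification: villous equivalent radii around 60 px (~75 um
#' diameter), a handful of capillaries of radius ~6 px per villous, half of
#' them blood-filled.
#'
#' @param width,height image size in pixels.
#' @param pixel_size pixel edge in micrometers.
#' @param n_villi number of villi to place (non-overlapping).
#' @param villous_radius_mean,villous_radius_sd,villous_radius_range normal
#'   draw (clamped) for the villous equivalent radius, px.
#' @param boundary_amplitude total amplitude of the low-order radial Fourier
#'   perturbation of the villous outline (0 = smooth ellipse).
#' @param axis_ratio_max maximum ellipse axis ratio (drawn uniformly in
#'   `[1, axis_ratio_max]`).
#' @param capillary_lambda Poisson mean of capillaries per villous.
#' @param capillary_count if non-`NULL`, a fixed capillary count per villous
#'   overriding the Poisson draw (useful for controlled renders).
#' @param capillary_radius_mean,capillary_radius_sd,capillary_radius_range
#'   normal draw (clamped) for capillary radii, px.
#' @param blood_fraction probability that a capillary is blood-filled.
#' @param colors named list of RGB reference triplets (0..255):
#'   `background`, `stroma`, `nuclear`, `lumen`, `blood`.
#' @param noise_sd sd of additive Gaussian pixel noise per channel.
#' @param seed RNG seed; every stochastic choice in the renderer derives
#'   from it.
#' @param max_attempts placement attempts per villous before the scene is
#'   declared over-dense.
#' @return list of class `scene_params`.
#' @export
scene_params <- function(width = 1388L, height = 1040L, pixel_size = 0.63,
                         n_villi = 12L,
                         villous_radius_mean = 60, villous_radius_sd = 10,
                         villous_radius_range = c(35, 90),
                         boundary_amplitude = 0.12, axis_ratio_max = 1.3,
                         capillary_lambda = 4, capillary_count = NULL,
                         capillary_radius_mean = 6, capillary_radius_sd = 1.5,
                         capillary_radius_range = c(3, 10),
                         blood_fraction = 0.5,
                         colors = list(background = c(244, 244, 244),
                                       stroma = c(220, 140, 180),
                                       nuclear = c(90, 60, 130),
                                       lumen = c(242, 240, 243),
                                       blood = c(150, 40, 50)),
                         noise_sd = 3, seed = 1L, max_attempts = 200L) {
  p <- list(width = as.integer(width), height = as.integer(height),
            pixel_size = pixel_size, n_villi = as.integer(n_villi),
            villous_radius_mean = villous_radius_mean,
            villous_radius_sd = villous_radius_sd,
            villous_radius_range = villous_radius_range,
            boundary_amplitude = boundary_amplitude,
            axis_ratio_max = axis_ratio_max,
            capillary_lambda = capillary_lambda,
            capillary_count = if (is.null(capillary_count)) NULL
                              else as.integer(capillary_count),
            capillary_radius_mean = capillary_radius_mean,
            capillary_radius_sd = capillary_radius_sd,
            capillary_radius_range = capillary_radius_range,
            blood_fraction = blood_fraction, colors = colors,
            noise_sd = noise_sd, seed = as.integer(seed),
            max_attempts = as.integer(max_attempts))
  stopifnot(p$width > 0, p$height > 0, p$pixel_size > 0, p$n_villi >= 0,
            p$villous_radius_mean > 0, all(p$villous_radius_range > 0),
            p$capillary_lambda >= 0, p$capillary_radius_mean > 0,
            p$blood_fraction >= 0, p$blood_fraction <= 1, p$noise_sd >= 0)
  class(p) <- "scene_params"
  p
}

#' Render a synthetic H&E scene with ground truth
#'
#' Places `n_villi` non-overlapping villi (ellipses perturbed by low-order
#' radial Fourier noise, eosin-pink stroma with a dark hematoxylin rim),
#' drops capillaries inside each villous (pale lumina or blood-red discs),
#' paints the scene over a near-white background and adds Gaussian pixel
#' noise. Ground-truth masks are returned alongside, and the per-region truth
#' records are computed from those masks (never from the renderer's
#' intentions), so truth areas always equal mask pixel counts.
#'
#' @param params a [scene_params()] list.
#' @return object of class `synthetic_scene`: `image` (h x w x 3, 0..255),
#'   `villi_mask`, `capillary_mask`, `blood_mask` (0/1 matrices with
#'   capillaries a subset of villi), `villous_records` and
#'   `capillary_records` (per-region feature data.frames), and `params`.
#' @export
generate_image <- function(params = scene_params()) {
  stopifnot(inherits(params, "scene_params"))
  local_seed(params$seed)
  h <- params$height; w <- params$width
  villi <- matrix(0L, h, w); caps <- matrix(0L, h, w); blood <- matrix(0L, h, w)
  rim <- matrix(FALSE, h, w)

  placed <- list()  # cx, cy, rmax per accepted villous
  shapes <- list()
  for (v in seq_len(params$n_villi)) {
    ok <- FALSE
    for (att in seq_len(params$max_attempts)) {
      r0 <- clamp(stats::rnorm(1, params$villous_radius_mean,
                               params$villous_radius_sd),
                  params$villous_radius_range[1], params$villous_radius_range[2])
      ar <- stats::runif(1, 1, params$axis_ratio_max)
      phi <- stats::runif(1, 0, pi)
      amp <- params$boundary_amplitude
      ak <- amp * c(stats::runif(1, 0.2, 0.5), stats::runif(1, 0.2, 0.5),
                    stats::runif(1, 0.1, 0.3))
      ak <- ak / sum(ak) * amp
      psi <- stats::runif(3, 0, 2 * pi)
      rmax <- r0 * sqrt(ar) * (1 + amp)
      cx <- stats::runif(1, rmax + 3, w - rmax - 2)
      cy <- stats::runif(1, rmax + 3, h - rmax - 2)
      clash <- FALSE
      for (q in placed)
        if ((cx - q$cx)^2 + (cy - q$cy)^2 < (rmax + q$rmax + 4)^2) {
          clash <- TRUE; break
        }
      if (clash) next
      placed[[length(placed) + 1L]] <- list(cx = cx, cy = cy, rmax = rmax)
      shapes[[length(shapes) + 1L]] <-
        list(cx = cx, cy = cy, r0 = r0, ar = ar, phi = phi, ak = ak,
             psi = psi, rmax = rmax)
      ok <- TRUE
      break
    }
    if (!ok)
      stop("over-dense scene: could not place ", params$n_villi,
           " non-overlapping villi in ", w, "x", h, " after ",
           params$max_attempts, " attempts each")
  }

  brush5 <- EBImage::makeBrush(5L, shape = "disc")
  villus_pixels <- vector("list", length(shapes))
  for (i in seq_along(shapes)) {
    s <- shapes[[i]]
    m <- rasterize_villus(s, h, w)
    villus_pixels[[i]] <- which(m)
    villi[m] <- 1L
    er <- EBImage::erode(matrix(as.numeric(m), h, w), brush5) > 0.5
    rim <- rim | (m & !er)
  }

  # capillaries: discs strictly inside a villous, non-overlapping
  for (i in seq_along(shapes)) {
    vp <- villus_pixels[[i]]
    vm <- matrix(0, h, w); vm[vp] <- 1
    dm <- EBImage::distmap(vm)
    n_cap <- if (!is.null(params$capillary_count)) params$capillary_count
             else stats::rpois(1, params$capillary_lambda)
    placed_caps <- list()
    for (k in seq_len(n_cap)) {
      r <- clamp(stats::rnorm(1, params$capillary_radius_mean,
                              params$capillary_radius_sd),
                 params$capillary_radius_range[1],
                 params$capillary_radius_range[2])
      elig <- which(dm > r + 2.5)
      if (length(placed_caps)) {
        ey <- ((elig - 1L) %% h) + 1L; ex <- ((elig - 1L) %/% h) + 1L
        for (q in placed_caps) {
          keep <- (ex - q$cx)^2 + (ey - q$cy)^2 > (r + q$r + 2)^2
          elig <- elig[keep]; ey <- ey[keep]; ex <- ex[keep]
          if (!length(elig)) break
        }
      }
      if (!length(elig)) next  # villous full; capillary skipped
      pick <- elig[sample.int(length(elig), 1L)]
      cy <- ((pick - 1L) %% h) + 1L; cx <- ((pick - 1L) %/% h) + 1L
      disc <- disc_pixels(cx, cy, r, h, w)
      caps[disc] <- 1L
      if (stats::runif(1) < params$blood_fraction) blood[disc] <- 1L
      placed_caps[[length(placed_caps) + 1L]] <- list(cx = cx, cy = cy, r = r)
    }
  }

  img <- array(0, dim = c(h, w, 3L))
  for (ch in 1:3) {
    plane <- matrix(params$colors$background[ch], h, w)
    plane[villi == 1L] <- params$colors$stroma[ch]
    plane[rim] <- params$colors$nuclear[ch]
    plane[caps == 1L] <- params$colors$lumen[ch]
    plane[blood == 1L] <- params$colors$blood[ch]
    img[, , ch] <- plane
  }
  if (params$noise_sd > 0)
    img <- img + stats::rnorm(length(img), 0, params$noise_sd)
  img <- round(img)
  img[img < 0] <- 0; img[img > 255] <- 255

  vlab <- label_regions(villi, 8L)
  clab <- label_regions(caps, 8L)
  scene <- list(image = img,
                villi_mask = villi, capillary_mask = caps, blood_mask = blood,
                villous_records = region_features(vlab, params$pixel_size),
                capillary_records = region_features(clab, params$pixel_size),
                params = params)
  class(scene) <- "synthetic_scene"
  scene
}

# pixel set of one perturbed ellipse, as logical matrix
rasterize_villus <- function(s, h, w) {
  x0 <- max(1L, floor(s$cx - s$rmax - 1)); x1 <- min(w, ceiling(s$cx + s$rmax + 1))
  y0 <- max(1L, floor(s$cy - s$rmax - 1)); y1 <- min(h, ceiling(s$cy + s$rmax + 1))
  xs <- x0:x1; ys <- y0:y1
  u <- outer(rep(1, length(ys)), xs - s$cx)
  v <- outer(ys - s$cy, rep(1, length(xs)))
  # rotate into ellipse frame, normalize axes
  ur <- (cos(s$phi) * u + sin(s$phi) * v) / (s$r0 * sqrt(s$ar))
  vr <- (-sin(s$phi) * u + cos(s$phi) * v) / (s$r0 / sqrt(s$ar))
  theta <- atan2(vr, ur)
  rho <- 1
  for (k in 1:3) rho <- rho + s$ak[k] * cos((k + 1) * theta + s$psi[k])
  inside <- (ur^2 + vr^2) <= rho^2
  m <- matrix(FALSE, h, w)
  m[cbind(rep(ys, times = length(xs))[as.vector(inside)],
          rep(xs, each = length(ys))[as.vector(inside)])] <- TRUE
  m
}

disc_pixels <- function(cx, cy, r, h, w) {
  x0 <- max(1L, floor(cx - r)); x1 <- min(w, ceiling(cx + r))
  y0 <- max(1L, floor(cy - r)); y1 <- min(h, ceiling(cy + r))
  xs <- x0:x1; ys <- y0:y1
  u <- outer(rep(1, length(ys)), xs - cx)
  v <- outer(ys - cy, rep(1, length(xs)))
  inside <- (u^2 + v^2) <= r^2
  idx <- cbind(rep(ys, times = length(xs))[as.vector(inside)],
               rep(xs, each = length(ys))[as.vector(inside)])
  (idx[, 2] - 1L) * h + idx[, 1]
}

#' Group-level feature distribution parameters
#'
#' `(mean, sd)` per feature plus group label and size; the sampling model of
#' [generate_cohort_features()].
#'
#' @param label group label string (e.g. `"PE"`, `"control"`).
#' @param n group size (>= 2).
#' @param means,sds named numeric vectors over [feature_names()].
#' @return list of class `group_params`.
#' @export
group_params <- function(label, n, means, sds) {
  fn <- feature_names()
  stopifnot(n >= 2, all(fn %in% names(means)), all(fn %in% names(sds)))
  if (any(sds[fn] <= 0)) stop("all feature sds must be positive")
  structure(list(label = label, n = as.integer(n),
                 means = means[fn], sds = sds[fn]),
            class = "group_params")
}

#' Published group parameters for the two cohort presets
#'
#' Transcribed mean/SD/n per feature for the preeclampsia (PE) and
#' normotensive control groups: the full cohort (n = 40 vs 35) and the
#' gestational-age-matched (35-36 weeks) subgroup (n = 10 vs 8).
#'
#' @param preset `"full-cohort"` or `"gestation-matched"`.
#' @return list with elements `pe` and `ctrl`, each a [group_params()].
#' @export
default_group_params <- function(preset = c("full-cohort", "gestation-matched")) {
  preset <- match.arg(preset)
  fn <- feature_names()
  if (preset == "full-cohort") {
    pe_m <- c(188.5, 4018.7, 267.5, 127.625, 665.8, 155.8, 34.9, 16.8, 15.7, 2.91)
    pe_s <- c(16.9, 25.7, 12.1, 7.5, 28.1, 13.6, 3.7, 1.9, 0.8, 0.14)
    ct_m <- c(128.8, 3028, 187.1, 107.6, 509.2, 132.6, 35.1, 16.2, 13.1, 2.69)
    ct_s <- c(9.2, 34.7, 7.9, 3.1, 16.6, 15.1, 3.8, 1.7, 2.1, 0.07)
    n_pe <- 40L; n_ct <- 35L
  } else {
    pe_m <- c(190.2, 4025.4, 268.4, 129.78, 670.8, 162.3, 34.9, 16.7, 16.4, 2.94)
    pe_s <- c(12.3, 21.3, 10.9, 8.5, 22.5, 11.3, 1.8, 1.4, 0.3, 0.08)
    ct_m <- c(150.6, 3050.8, 185.3, 105.9, 513.6, 134.2, 35.3, 16.5, 11.9, 2.65)
    ct_s <- c(14.5, 22.9, 6.7, 4.1, 13.4, 9.2, 2.7, 1.1, 1.8, 0.03)
    n_pe <- 10L; n_ct <- 8L
  }
  names(pe_m) <- names(pe_s) <- names(ct_m) <- names(ct_s) <- fn
  list(pe = group_params("PE", n_pe, pe_m, pe_s),
       ctrl = group_params("control", n_ct, ct_m, ct_s))
}

#' Draw a synthetic cohort feature table
#'
#' One row per subject, ten feature columns plus a group label. Each feature
#' is drawn independently per subject from a normal distribution with the
#' group's mean and SD (only marginal summaries are published, so no
#' between-feature correlation is modeled beyond what the group mean shift
#' induces). Negative draws are truncated to a small positive floor; at the
#' published effect sizes this is vanishingly rare.
#'
#' @param pe,ctrl [group_params()] for the two groups.
#' @param seed RNG seed.
#' @return data.frame with columns `subject`, `group` (factor, PE first) and
#'   the ten features.
#' @export
generate_cohort_features <- function(pe = default_group_params()$pe,
                                     ctrl = default_group_params()$ctrl,
                                     seed = 1L) {
  stopifnot(inherits(pe, "group_params"), inherits(ctrl, "group_params"))
  if (pe$n < 2L || ctrl$n < 2L) stop("each group needs at least 2 subjects")
  local_seed(seed)
  fn <- feature_names()
  draw <- function(gp) {
    m <- sapply(fn, function(f) stats::rnorm(gp$n, gp$means[f], gp$sds[f]))
    m <- pmax(m, 1e-6)
    as.data.frame(m)
  }
  d_pe <- draw(pe); d_ct <- draw(ctrl)
  out <- rbind(
    cbind(data.frame(subject = sprintf("%s_%02d", pe$label, seq_len(pe$n)),
                     group = pe$label), d_pe),
    cbind(data.frame(subject = sprintf("%s_%02d", ctrl$label, seq_len(ctrl$n)),
                     group = ctrl$label), d_ct))
  out$group <- factor(out$group, levels = c(pe$label, ctrl$label))
  rownames(out) <- NULL
  out
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# seed the RNG for the calling function's scope, restoring the caller's
# stream when that function exits
local_seed <- function(seed, envir = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  expr <- if (is.null(old))
    quote(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  else
    bquote(assign(".Random.seed", .(old), globalenv()))
  do.call(on.exit, list(expr, add = TRUE), envir = envir)
  set.seed(seed)
  invisible(seed)
}
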
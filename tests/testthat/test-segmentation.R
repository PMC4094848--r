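test_that("Otsu threshold equals the brute-force within-class-variance scan", {
  set.seed(101)
  for (rep in 1:30) {
    img <- matrix(sample(0:255, 120, replace = TRUE,
                         prob = stats::runif(256)), 12, 10)
    if (length(unique(as.vector(img))) < 2) next
    expect_identical(otsu_threshold(img), otsu_oracle(img))
  }
})

test_that("Otsu separates well-defined populations and rejects constants", {
  two <- matrix(c(rep(10L, 50), rep(200L, 50)), 10, 10)
  t <- otsu_threshold(two)
  expect_identical(t, otsu_oracle(two))
  expect_true(t >= 10 && t < 200)

  # two well-separated Gaussian modes: the threshold lands in the valley and
  # splits the populations exactly (the between-class variance is flat over
  # the empty gap, so the tie-break returns its smallest level)
  set.seed(5)
  lo_px <- as.integer(pmin(pmax(round(rnorm(500, 60, 10)), 0), 255))
  hi_px <- as.integer(pmin(pmax(round(rnorm(500, 180, 10)), 0), 255))
  mix <- matrix(c(lo_px, hi_px), 50, 20)
  tm <- otsu_threshold(mix)
  expect_identical(tm, otsu_oracle(mix))
  expect_true(all(lo_px <= tm) && all(hi_px > tm))

  expect_error(otsu_threshold(matrix(128L, 4, 4)), "degenerate")
})

test_that("binarization polarity marks the tissue class", {
  img <- matrix(c(rep(40L, 30), rep(220L, 70)), 10, 10)
  dark <- binarize_villi(img, 100L, "dark-tissue")
  expect_equal(sum(dark), 30)
  expect_true(all(dark[img <= 100] == 1L))
  bright <- binarize_villi(img, 100L, "bright-tissue")
  expect_equal(dark + bright, matrix(1L, 10, 10))
  # auto picks the darker class as tissue
  expect_identical(binarize_villi(img, 100L, "auto"), dark)
  low <- matrix(10L, 5, 5)
  expect_equal(sum(binarize_villi(low, 100L, "dark-tissue")), 25)
  expect_equal(sum(binarize_villi(low, 5L, "dark-tissue")), 0)
})

test_that("island removal deletes small components and fills small holes", {
  m <- matrix(0L, 150, 150)
  m[20:119, 20:119] <- 1L            # 10,000 px blob
  m[140, 140] <- 1L; m[140, 141] <- 1L; m[141, 140:142] <- 1L  # 5 px speck
  out <- remove_islands(m, min_area = 50L)
  expect_equal(sum(out), 10000)
  expect_equal(out[140, 140], 0L)

  blob <- matrix(0L, 40, 40); blob[5:35, 5:35] <- 1L
  blob[15:18, 15:19] <- 0L           # 20 px hole
  filled <- remove_islands(blob, min_area = 0L, hole_area_cap = 100L)
  expect_equal(sum(filled), 31 * 31)
  kept <- remove_islands(blob, min_area = 0L, hole_area_cap = 10L)
  expect_equal(sum(kept), 31 * 31 - 20)

  empty <- matrix(0L, 10, 10)
  expect_identical(remove_islands(empty, 50L), empty)
})

test_that("component labeling respects connectivity and raster order", {
  m <- matrix(0L, 12, 12)
  m[2:4, 2:4] <- 1L; m[8:10, 8:10] <- 1L
  expect_equal(label_regions(m, 8L)$n_regions, 2L)
  expect_equal(label_regions(m, 4L)$n_regions, 2L)

  corner <- matrix(0L, 6, 6)
  corner[2:3, 2:3] <- 1L; corner[4:5, 4:5] <- 1L  # touch at one corner
  expect_equal(label_regions(corner, 8L)$n_regions, 1L)
  expect_equal(label_regions(corner, 4L)$n_regions, 2L)

  expect_equal(label_regions(matrix(0L, 5, 5))$n_regions, 0L)

  lab <- label_regions(m, 8L)$labels
  expect_equal(sort(unique(as.vector(lab))), c(0L, 1L, 2L))
  expect_equal(lab[2, 2], 1L)  # first in raster order gets label 1
})

test_that("labeling agrees with EBImage's 4-connectivity labeler on random masks", {
  set.seed(77)
  for (rep in 1:10) {
    m <- matrix(as.integer(stats::runif(600) < 0.4), 20, 30)
    ours <- label_regions(m, 4L)
    ref <- EBImage::bwlabel(m)
    expect_equal(ours$n_regions, max(ref))
    # identical partitions: one-to-one label correspondence
    expect_equal(ours$n_regions,
                 nrow(unique(cbind(as.vector(ours$labels), as.vector(ref))[
                   as.vector(m) == 1L, , drop = FALSE])))
  }
})

test_that("color deconvolution inverts the Beer-Lambert forward model", {
  white <- array(255, dim = c(1, 1, 3))
  expect_true(all(color_deconvolve(white) < 1e-6))

  stains <- he_stain_matrix()
  # render a patch of pure hematoxylin density 0.8 and unmix it
  dens_true <- array(0, dim = c(2, 2, 3)); dens_true[, , 1] <- 0.8
  img <- round(stain_render(dens_true, stains))
  d <- color_deconvolve(img, stains)
  expect_equal(mean(d[, , 1]), 0.8, tolerance = 0.02)
  expect_lt(max(d[, , 2:3]), 0.05)

  # round trip on random densities reconstructs within 1 intensity level
  set.seed(3)
  dens <- array(stats::runif(3 * 4 * 3, 0, 0.7), dim = c(3, 4, 3))
  img2 <- stain_render(dens, stains)            # unquantized
  back <- stain_render(color_deconvolve(round(img2), stains), stains)
  expect_lt(max(abs(back - img2)), 1)

  expect_error(color_deconvolve(white, matrix(1, 3, 3)), "singular")
})

test_that("CIELAB conversion hits the D65 reference points", {
  lab_of <- function(r, g, b) rgb_to_lab(array(c(r, g, b), dim = c(1, 1, 3)))[1, 1, ]
  white <- lab_of(255, 255, 255)
  expect_equal(unname(white[1]), 100, tolerance = 0.1)
  expect_lt(max(abs(white[2:3])), 0.1)
  gray <- lab_of(128, 128, 128)
  expect_lt(max(abs(gray[2:3])), 0.1)
  expect_lt(lab_of(0, 0, 255)["b"], 0)     # blue: negative b*
  expect_gt(lab_of(255, 200, 0)["b"], 0)   # yellow-red: positive b*
})

test_that("morphological capillary detection finds lumina inside villi only", {
  img <- matrix(200L, 20, 20)
  none <- morph_capillaries(img, matrix(0L, 20, 20))
  expect_equal(sum(none), 0)

  # noise-free render with exactly 3 pale lumina per villous
  sc <- generate_image(small_scene_params(13, capillary_count = 3L,
                                          blood_fraction = 0,
                                          noise_sd = 0))
  gray <- median_filter(rgb_to_gray(sc$image), 3L)
  villi <- segment_villi(gray)
  cap <- morph_capillaries(gray, villi)
  expect_true(all(villi[cap == 1L] == 1L))        # subset contract
  clab <- label_regions(cap, 8L)
  expect_equal(clab$n_regions, 3L * 6L)
  vlab <- label_regions(villi, 8L)
  per_villous <- table(vlab$labels[clab$labels > 0L])
  expect_equal(length(per_villous), 6L)           # 3 per villous
  expect_true(all(tapply(clab$labels[clab$labels > 0L],
                         vlab$labels[clab$labels > 0L],
                         function(x) length(unique(x))) == 3L))
})

test_that("blood capillary mask matches the rendered blood truth", {
  sc0 <- generate_image(small_scene_params(21, blood_fraction = 0))
  b0 <- blood_capillary_mask(sc0$image, sc0$villi_mask)
  expect_equal(sum(b0), 0)

  sc <- generate_image(small_scene_params(22, blood_fraction = 1))
  b <- blood_capillary_mask(sc$image, sc$villi_mask)
  expect_true(all(sc$villi_mask[b == 1L] == 1L))
  expect_gte(dice_coefficient(b, sc$blood_mask), 0.9)
})

test_that("combining capillary masks unions, cleans and labels", {
  villi <- matrix(0L, 20, 30); villi[2:19, 2:29] <- 1L
  morph <- matrix(0L, 20, 30); morph[5:8, 5:8] <- 1L
  blood <- matrix(0L, 20, 30)

  only_morph <- combine_capillaries(morph, blood, villi)
  expect_equal(only_morph$n_regions, 1L)
  expect_equal(sum(only_morph$labels > 0L), 16)

  blood[7:10, 7:10] <- 1L                       # overlaps the morph blob
  merged <- combine_capillaries(morph, blood, villi)
  expect_equal(merged$n_regions, 1L)

  blood2 <- matrix(0L, 20, 30); blood2[14:17, 20:23] <- 1L
  disjoint <- combine_capillaries(morph, blood2, villi)
  expect_equal(disjoint$n_regions, 2L)

  # intersection with villi is enforced
  outside <- matrix(0L, 20, 30); outside[1, 1] <- 1L
  res <- combine_capillaries(outside, blood2, villi, min_area = 0L)
  expect_true(all(villi[res$labels > 0L] == 1L))
})

test_that("thresholding the denoised image beats thresholding the equalized one", {
  # when a narrow-band background dominates the frame, equalization spreads
  # the background mode over the dynamic range and Otsu splits background
  # noise instead of tissue from background
  sc <- generate_image(small_scene_params(35))
  den <- segment_image(sc$image, pipeline_config(threshold_on = "denoised"))
  eq <- segment_image(sc$image, pipeline_config(threshold_on = "equalized"))
  d_den <- dice_coefficient(den$villi_mask, sc$villi_mask)
  d_eq <- dice_coefficient(eq$villi_mask, sc$villi_mask)
  expect_gte(d_den, 0.99)
  expect_gt(d_den, d_eq)
  expect_equal(den$villi$n_regions, nrow(sc$villous_records))
})

test_that("full segmentation recovers villi and capillaries on rendered scenes", {
  cfg <- pipeline_config()
  for (s in 31:33) {
    sc <- generate_image(small_scene_params(s))
    seg <- segment_image(sc$image, cfg)
    expect_equal(seg$villi$n_regions, label_regions(sc$villi_mask, 8L)$n_regions)
    expect_gte(dice_coefficient(seg$villi_mask, sc$villi_mask), 0.9)
    expect_gte(dice_coefficient(seg$capillary_mask, sc$capillary_mask), 0.85)
    # every capillary component lies inside exactly one villous component
    vl <- seg$villi$labels; cl <- seg$capillaries$labels
    inside <- vl[cl > 0L]
    expect_true(all(inside > 0L))
    expect_true(all(tapply(inside, cl[cl > 0L],
                           function(x) length(unique(x))) == 1L))
  }
})
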
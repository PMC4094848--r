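# Reduced-scale scene parameters shared across test files: 320 x 240 px,
# 6 villi of equivalent radius ~30 px, capillaries of radius ~4 px.  Same
# renderer and defaults otherwise; small enough that a scene generates and
# segments in under a second.
small_scene_params <- function(seed, n_villi = 6L, width = 320L,
                               height = 240L, ...) {
  scene_params(width = width, height = height, n_villi = n_villi,
               villous_radius_mean = 30, villous_radius_sd = 5,
               villous_radius_range = c(18, 40),
               capillary_radius_mean = 4, capillary_radius_sd = 1,
               capillary_radius_range = c(2, 6),
               seed = seed, ...)
}

# independent Otsu oracle: brute-force scan over all 255 candidate splits,
# minimizing the weighted within-class variance computed from the raw pixel
# vector (population variances); ties to the smallest level
otsu_oracle <- function(img) {
  v <- as.integer(img)
  best_t <- NA_integer_; best_w <- Inf
  popvar <- function(x) if (length(x) < 2) 0 else mean((x - mean(x))^2)
  for (t in 0:254) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    wcv <- length(lo) * popvar(lo) + length(hi) * popvar(hi)
    if (wcv < best_w - 1e-9) { best_w <- wcv; best_t <- t }
  }
  best_t
}

# nearest-(left-out)-group-mean leave-one-out classifier: the 1-D oracle for
# single-feature FLDA with a midpoint threshold
loo_nearest_mean <- function(x, g) {
  correct <- logical(length(x))
  for (i in seq_along(x)) {
    m1 <- mean(x[-i][g[-i] == 1L]); m2 <- mean(x[-i][g[-i] == 2L])
    pred <- if (abs(x[i] - m1) <= abs(x[i] - m2)) 1L else 2L
    correct[i] <- pred == g[i]
  }
  100 * mean(correct)
}
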
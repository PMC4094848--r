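test_that("two-sample t behaves on textbook cases", {
  a <- c(1, 2, 3)
  expect_equal(two_sample_t(a, a)$t, 0)
  expect_equal(two_sample_t(a, a)$p, 1)
  r <- two_sample_t(a, a + 10)
  expect_lt(r$p, 0.01)
  expect_equal(r$df, 4)
  sw <- two_sample_t(a + 10, a)
  expect_equal(sw$t, -r$t)
  expect_equal(sw$p, r$p)
  expect_error(two_sample_t(c(1, 1), c(1, 1)), "zero variance")
  expect_error(two_sample_t(1, a), ">= 2")
})

test_that("FLDA weights solve the pooled-scatter system on hand-worked cases", {
  # 1-D: A = {1,2,3}, B = {7,8,9}; pooled variance 1, w = mean gap = -6
  m <- flda_fit(matrix(1:3), matrix(7:9))
  expect_equal(unname(m$s_pooled[1, 1]), 1)
  expect_equal(unname(m$w), -6)
  expect_equal(m$threshold, -6 * 5)             # midpoint of projected means
  expect_equal(flda_classify(m, 4), 1L)
  expect_equal(flda_classify(m, 10), 2L)
  expect_equal(flda_classify(m, 5), 1L)         # exact threshold -> group 1

  # 2-D with isotropic pooled scatter: w is proportional to the mean gap
  base <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  m2 <- flda_fit(sweep(base, 2, c(1, 0), "+"), base)
  expect_equal(unname(m2$w / m2$w[1]), c(1, 0))

  expect_error(flda_fit(base, base), "identical group means")
  collinear <- cbind(1:4, 2 * (1:4))
  expect_error(flda_fit(collinear, collinear + 1), "singular")
})

test_that("the fitted discriminant maximizes Fisher's criterion", {
  set.seed(202)
  for (d in 2:5) {
    x1 <- matrix(stats::rnorm(12 * d), 12) %*% diag(stats::runif(d, 0.5, 2)) + 1
    x2 <- matrix(stats::rnorm(10 * d), 10)
    m <- flda_fit(x1, x2)
    j_fit <- fisher_criterion(m$w, x1, x2)
    for (i in 1:100) {
      v <- stats::rnorm(d); v <- v / sqrt(sum(v^2))
      expect_lte(fisher_criterion(v, x1, x2), j_fit + 1e-10)
    }
  }
})

test_that("the FLDA direction matches the reference LDA implementation", {
  set.seed(33)
  x1 <- matrix(stats::rnorm(40, 1), 20, 2)
  x2 <- matrix(stats::rnorm(40), 20, 2)
  m <- flda_fit(x1, x2)
  df <- data.frame(g = rep(1:2, each = 20), rbind(x1, x2))
  ref <- MASS::lda(g ~ X1 + X2, df)$scaling[, 1]
  cosine <- sum(m$w * ref) / sqrt(sum(m$w^2) * sum(ref^2))
  expect_equal(abs(cosine), 1, tolerance = 1e-8)
})

test_that("leave-one-out accuracy matches the nearest-mean oracle in 1-D", {
  # perfectly separated groups
  co <- data.frame(group = factor(rep(c("A", "B"), each = 5)),
                   f = c(1:5, 101:105))
  expect_equal(loo_accuracy(co, "f"), 100)

  # 3 + 3 toy cohort, enumerated by hand: only the held-out 4 crosses over
  toy <- data.frame(group = factor(rep(c("A", "B"), each = 3), c("A", "B")),
                    f = c(1, 2, 3, 4, 8, 9))
  expect_equal(loo_accuracy(toy, "f"), 100 * 5 / 6)
  expect_equal(loo_accuracy(toy, "f"),
               loo_nearest_mean(toy$f, as.integer(toy$group)))

  # random 1-D cohorts agree with the oracle fold by fold
  set.seed(55)
  for (rep in 1:5) {
    x <- c(stats::rnorm(12, 1.5), stats::rnorm(9))
    g <- rep(1:2, c(12, 9))
    co2 <- data.frame(group = factor(g), f = x)
    expect_equal(loo_accuracy(co2, "f"), loo_nearest_mean(x, g))
  }
})

test_that("accuracy is near chance for exchangeable groups and scale invariant", {
  # exchangeable groups carry no signal: resubstitution sits at chance per
  # draw; leave-one-out is pessimistically biased (excluding a subject moves
  # its own group mean away from it) and noisy, so only its mean over draws
  # is banded
  loo <- numeric(10)
  for (s in 1:10) {
    set.seed(600 + s)
    co <- data.frame(group = factor(rep(c("A", "B"), each = 100)),
                     f = stats::rnorm(200))
    resub <- loo_accuracy(co, "f", scheme = "resubstitution")
    expect_gte(resub, 40); expect_lte(resub, 60)
    loo[s] <- loo_accuracy(co, "f")
  }
  expect_gte(mean(loo), 35); expect_lte(mean(loo), 65)

  gp <- default_group_params()
  cohort <- generate_cohort_features(gp$pe, gp$ctrl, seed = 2)
  a1 <- loo_accuracy(cohort, c("villous_count", "capillarization_index"))
  cohort$villous_count <- cohort$villous_count * 1000
  expect_equal(loo_accuracy(cohort, c("villous_count", "capillarization_index")), a1)
})

test_that("feature ranking orders by single-feature accuracy, deterministically", {
  set.seed(77)
  co <- data.frame(group = factor(rep(c("A", "B"), each = 20)),
                   sep = c(stats::rnorm(20, 10), stats::rnorm(20)),
                   noise = stats::rnorm(40))
  rk <- rank_features(co, c("sep", "noise"))
  expect_equal(rk$feature, c("sep", "noise"))
  expect_equal(rk$rank, 1:2)
  expect_equal(rk$accuracy[1], 100)

  gp <- default_group_params()
  cohort <- generate_cohort_features(gp$pe, gp$ctrl, seed = 3)
  expect_identical(rank_features(cohort), rank_features(cohort))
  expect_true(all(diff(rank_features(cohort)$accuracy) <= 0))
})

test_that("hierarchical clustering merges tight pairs first with sane heights", {
  co <- data.frame(subject = paste0("s", 1:4),
                   group = factor(c("A", "A", "B", "B")),
                   x = c(0, 0.1, 10, 10.1), y = c(0, 0.05, 5, 5.1))
  cl <- hca(co, c("x", "y"))
  first_two <- cl$hclust$merge[1:2, ]
  expect_true(all(first_two < 0))                 # leaf-leaf merges
  expect_setequal(as.vector(abs(first_two)), 1:4)
  expect_equal(unname(cl$clusters), c(1, 1, 2, 2))
  expect_true(all(diff(cl$merges$height) >= 0))   # Ward heights monotone
  expect_match(cl$newick, "^\\(.*\\);$")

  two <- data.frame(group = factor(c("A", "B")), x = c(0, 1), y = c(0, 1))
  expect_equal(nrow(hca(two, c("x", "y"))$merges), 1L)
})

test_that("PCA explained variances are a valid, correctly ordered spectrum", {
  line <- data.frame(x = 1:10, y = 2 * (1:10) + 3)
  pc <- pca_features(line, c("x", "y"))
  expect_equal(pc$explained[1], 100)
  expect_equal(sum(pc$explained), 100)

  set.seed(88)
  iso <- data.frame(x = stats::rnorm(10000), y = stats::rnorm(10000))
  pci <- pca_features(iso, c("x", "y"))
  expect_equal(pci$explained[1], 50, tolerance = 0.06)
  expect_true(all(diff(pci$explained) <= 0))
  expect_true(all(pci$explained >= 0))
  expect_equal(pci$cumulative[2], 100)

  cst <- data.frame(x = rep(1, 5), y = 1:5)
  expect_error(pca_features(cst, c("x", "y")), "constant feature")
})

test_that("group comparison reproduces group means, SDs and the t-test", {
  gp <- default_group_params()
  co <- generate_cohort_features(gp$pe, gp$ctrl, seed = 5)
  cmp <- group_comparison(co)
  expect_equal(nrow(cmp), 10L)
  row <- cmp[cmp$feature == "villous_count", ]
  pe <- co[co$group == "PE", "villous_count"]
  ct <- co[co$group == "control", "villous_count"]
  expect_equal(row$mean_PE, mean(pe))
  expect_equal(row$sd_control, stats::sd(ct))
  expect_equal(row$p, stats::t.test(pe, ct, var.equal = TRUE)$p.value)
  # group-mean recovery within 4 SE of the generating parameters
  expect_lt(abs(row$mean_PE - 188.5), 4 * 16.9 / sqrt(40))
})

test_that("the Rand index scores partition agreement", {
  expect_equal(rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), 1 / 3)
  expect_equal(rand_index(1:4, c(1, 1, 1, 1)), 0)
})
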
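# Statistical battery over cohort feature tables: two-sample t-tests,
# Fisher's linear discriminant analysis with leave-one-out feature ranking,
# agglomerative hierarchical clustering, and correlation-matrix PCA.

#' Two-sample t-test
#'
#' Two-sided Student's t-test between two groups of values; the pooled
#' (equal-variance) variant is the default, Welch is available.
#'
#' @param a,b numeric vectors, each with at least 2 values and nonzero
#'   variance.
#' @param variant `"pooled"` or `"welch"`.
#' @return list with `t`, `df`, `p`.
#' @export
two_sample_t <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("degenerate input: both groups have zero variance")
  ht <- stats::t.test(a, b, var.equal = variant == "pooled")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Fit Fisher's linear discriminant between two groups
#'
#' Computes the weight vector \eqn{w = S_{pooled}^{-1}(\bar{x}_1 - \bar{x}_2)}
#' that maximizes Fisher's criterion \eqn{J(w) = (w^T S_B w)/(w^T S_W w)},
#' the ratio of between- to within-group variance of the projection
#' \eqn{y = w^T x}. `S_pooled` is the bias-corrected pooled covariance
#' (divisor `n1 + n2 - 2`). The decision threshold is placed at the midpoint
#' of the projected group means (equal priors).
#'
#' @param x1,x2 numeric matrices (rows = subjects, columns = features) for
#'   groups 1 and 2; vectors are treated as single-feature matrices.
#' @return object of class `flda_model`: `w`, `means` (list), `s_pooled`,
#'   `threshold`, projected means `y1`, `y2`, group sizes.
#' @export
flda_fit <- function(x1, x2) {
  x1 <- as.matrix(x1); x2 <- as.matrix(x2)
  if (ncol(x1) != ncol(x2)) stop("groups must share the feature space")
  n1 <- nrow(x1); n2 <- nrow(x2)
  if (n1 < 2 || n2 < 2) stop("each group needs >= 2 rows")
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  if (all(abs(m1 - m2) < .Machine$double.eps^0.5))
    stop("degenerate model: identical group means give w = 0")
  s_pooled <- ((n1 - 1) * stats::cov(x1) + (n2 - 1) * stats::cov(x2)) /
    (n1 + n2 - 2)
  w <- tryCatch(solve(s_pooled, m1 - m2),
                error = function(e) stop("singular pooled scatter: ",
                                         "collinear features", call. = FALSE))
  y1 <- sum(w * m1); y2 <- sum(w * m2)
  structure(list(w = w, means = list(m1, m2), s_pooled = s_pooled,
                 threshold = (y1 + y2) / 2, y1 = y1, y2 = y2,
                 n = c(n1, n2)),
            class = "flda_model")
}

#' Classify a sample with a fitted Fisher discriminant
#'
#' Projects `x` onto the discriminant (`y = w^T x`) and assigns the group
#' whose projected mean is nearer; a sample exactly at the threshold goes to
#' group 1.
#'
#' @param model a [flda_fit()] model.
#' @param x numeric vector (one sample) or matrix (rows = samples).
#' @return integer vector of group assignments (1 or 2).
#' @export
flda_classify <- function(model, x) {
  stopifnot(inherits(model, "flda_model"))
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  y <- as.vector(x %*% model$w)
  if (model$y1 >= model$y2) ifelse(y >= model$threshold, 1L, 2L)
  else ifelse(y <= model$threshold, 1L, 2L)
}

#' Fisher criterion of a direction
#'
#' Evaluates \eqn{J(w) = (w^T S_B w)/(w^T S_W w)} for an arbitrary direction
#' on a two-group sample; used to verify that the fitted discriminant is the
#' maximizer.
#'
#' @param w direction vector.
#' @param x1,x2 group sample matrices.
#' @return scalar criterion value.
#' @export
fisher_criterion <- function(w, x1, x2) {
  x1 <- as.matrix(x1); x2 <- as.matrix(x2)
  d <- colMeans(x1) - colMeans(x2)
  sb <- outer(d, d)
  n1 <- nrow(x1); n2 <- nrow(x2)
  sw <- (n1 - 1) * stats::cov(x1) + (n2 - 1) * stats::cov(x2)
  as.numeric((t(w) %*% sb %*% w) / (t(w) %*% sw %*% w))
}

#' Leave-one-out classification accuracy of FLDA
#'
#' For each subject: refit the discriminant on all other subjects and
#' classify the held-out one; accuracy is the percentage classified into
#' their true group. A resubstitution variant (fit once on everything) is
#' available for comparison; it is optimistic and not the default.
#'
#' @param cohort cohort data.frame with a `group` factor and feature columns.
#' @param features character vector of feature columns to use.
#' @param scheme `"loo"` (default) or `"resubstitution"`.
#' @return overall accuracy in percent.
#' @export
loo_accuracy <- function(cohort, features, scheme = c("loo", "resubstitution")) {
  scheme <- match.arg(scheme)
  stopifnot(all(features %in% names(cohort)), "group" %in% names(cohort))
  g <- as.integer(factor(cohort$group, levels = unique(cohort$group)))
  if (any(tabulate(g, 2) < 3)) stop("each group needs >= 3 subjects")
  x <- as.matrix(cohort[, features, drop = FALSE])
  n <- nrow(x)
  if (scheme == "resubstitution") {
    model <- flda_fit(x[g == 1L, , drop = FALSE], x[g == 2L, , drop = FALSE])
    pred <- flda_classify(model, x)
    return(100 * mean(pred == g))
  }
  correct <- logical(n)
  for (i in seq_len(n)) {
    gi <- g[-i]; xi <- x[-i, , drop = FALSE]
    model <- flda_fit(xi[gi == 1L, , drop = FALSE],
                      xi[gi == 2L, , drop = FALSE])
    correct[i] <- flda_classify(model, x[i, ]) == g[i]
  }
  100 * mean(correct)
}

#' Rank features by single-feature discrimination accuracy
#'
#' Computes the leave-one-out FLDA accuracy of each feature used alone and
#' ranks features by descending accuracy; ties keep the conventional feature
#' listing order.
#'
#' @param cohort cohort data.frame.
#' @param features features to rank (default: all ten, [feature_names()]).
#' @param scheme accuracy scheme, see [loo_accuracy()].
#' @return data.frame `feature`, `accuracy` (%), `rank`, sorted by rank.
#' @export
rank_features <- function(cohort, features = feature_names(),
                          scheme = "loo") {
  acc <- vapply(features, function(f) loo_accuracy(cohort, f, scheme),
                numeric(1))
  ord <- order(-acc, seq_along(features))
  data.frame(feature = features[ord], accuracy = unname(acc[ord]),
             rank = seq_along(features), row.names = NULL)
}

#' Hierarchical cluster analysis of a cohort
#'
#' Agglomerative clustering of subjects on z-scored features under the
#' Euclidean distance. Ward linkage (`ward.D2`) is the default: it produces
#' the compact two-cluster structure expected when two groups are well
#' separated; average linkage is available. Returns the merge history, a
#' flat cut, and the dendrogram in Newick form.
#'
#' @param cohort cohort data.frame.
#' @param features feature columns to cluster on.
#' @param linkage `"ward"` or `"average"`.
#' @param k number of flat clusters to cut (default 2).
#' @return list with `hclust` (the [stats::hclust] object), `merges`
#'   (data.frame of merge pairs and heights), `clusters` (flat assignment),
#'   `newick` (character).
#' @export
hca <- function(cohort, features, linkage = c("ward", "average"), k = 2L) {
  linkage <- match.arg(linkage)
  x <- scale(as.matrix(cohort[, features, drop = FALSE]))
  if (nrow(x) < 2) stop("need >= 2 subjects")
  rownames(x) <- if ("subject" %in% names(cohort)) cohort$subject
                 else paste0("s", seq_len(nrow(x)))
  hc <- stats::hclust(stats::dist(x),
                      method = if (linkage == "ward") "ward.D2" else "average")
  phy <- ape::as.phylo(hc)
  list(hclust = hc,
       merges = data.frame(left = hc$merge[, 1], right = hc$merge[, 2],
                           height = hc$height),
       clusters = stats::cutree(hc, k = k),
       newick = ape::write.tree(phy))
}

#' Principal component analysis of cohort features
#'
#' Eigendecomposition of the correlation matrix of the selected features
#' (i.e. PCA of z-scored data): the features carry incommensurate units
#' (counts, areas, percentages), so the covariance matrix would be dominated
#' by whichever feature has the largest raw scale.
#'
#' @param cohort cohort data.frame.
#' @param features feature columns.
#' @return list of class `pca_result`: `loadings` (columns = components),
#'   `eigenvalues`, `explained` (% per component, non-increasing, summing to
#'   100), `cumulative`, `scores` (z-scored data projected on the loadings).
#' @export
pca_features <- function(cohort, features) {
  x <- as.matrix(cohort[, features, drop = FALSE])
  if (nrow(x) < 2) stop("need >= 2 subjects")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) stop("constant feature: ", features[which(sds == 0)[1]])
  r <- stats::cor(x)
  eig <- eigen(r, symmetric = TRUE)
  explained <- 100 * eig$values / sum(eig$values)
  z <- scale(x)
  structure(list(loadings = eig$vectors, eigenvalues = eig$values,
                 explained = explained, cumulative = cumsum(explained),
                 scores = z %*% eig$vectors),
            class = "pca_result")
}

#' Group-comparison table
#'
#' Per-feature group means, SDs, and two-sample t-test, matching the
#' mean +/- SD reporting convention of clinical morphometry tables.
#'
#' @param cohort cohort data.frame with a two-level `group`.
#' @param features feature columns (default all ten).
#' @param variant t-test variant.
#' @return data.frame: feature, per-group mean and sd, t, df, p.
#' @export
group_comparison <- function(cohort, features = feature_names(),
                             variant = "pooled") {
  lv <- levels(factor(cohort$group, levels = unique(cohort$group)))
  stopifnot(length(lv) == 2L)
  rows <- lapply(features, function(f) {
    a <- cohort[cohort$group == lv[1], f]; b <- cohort[cohort$group == lv[2], f]
    ht <- two_sample_t(a, b, variant)
    data.frame(feature = f,
               mean_1 = mean(a), sd_1 = stats::sd(a),
               mean_2 = mean(b), sd_2 = stats::sd(b),
               t = ht$t, df = ht$df, p = ht$p)
  })
  out <- do.call(rbind, rows)
  names(out)[2:5] <- c(paste0("mean_", lv[1]), paste0("sd_", lv[1]),
                       paste0("mean_", lv[2]), paste0("sd_", lv[2]))
  out
}

#' Rand index between two partitions
#'
#' Fraction of subject pairs on which two partitions agree (same cluster in
#' both, or different in both).
#'
#' @param a,b integer/factor vectors of equal length.
#' @return Rand index in `[0, 1]`.
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 2) return(1)
  pa <- outer(a, a, "=="); pb <- outer(b, b, "==")
  ut <- upper.tri(pa)
  mean(pa[ut] == pb[ut])
}
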
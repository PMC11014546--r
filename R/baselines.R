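two_group_result <- function(method, statistic, p_value, detected) {
  structure(
    list(method = method, statistic = statistic, p_value = p_value,
         detected = detected),
    class = "two_group_result"
  )
}

#' @export
print.two_group_result <- function(x, ...) {
  cat(sprintf("<two_group_result: %s> statistic = %.4g%s, detected = %s\n",
              x$method, x$statistic,
              if (is.na(x$p_value)) "" else sprintf(", p = %.4g", x$p_value),
              x$detected))
  invisible(x)
}

check_two_groups <- function(group_a, group_b) {
  group_a <- as.matrix(group_a)
  group_b <- as.matrix(group_b)
  if (ncol(group_a) != ncol(group_b)) stop("feature dimension mismatch")
  if (nrow(group_a) < 1 || nrow(group_b) < 1) stop("each group must be nonempty")
  list(a = group_a, b = group_b)
}

# Mahalanobis distance between group centroids of variance-weighted PCA
# scores, with pooled within-group covariance and a small ridge for rank
# deficiency. `labels` is logical (TRUE = group a).
mahalanobis_weighted_pca <- function(scores, labels) {
  ma <- colMeans(scores[labels, , drop = FALSE])
  mb <- colMeans(scores[!labels, , drop = FALSE])
  na <- sum(labels)
  nb <- sum(!labels)
  pool <- matrix(0, ncol(scores), ncol(scores))
  dof <- 0
  if (na >= 2) {
    pool <- pool + (na - 1) * stats::cov(scores[labels, , drop = FALSE])
    dof <- dof + na - 1
  }
  if (nb >= 2) {
    pool <- pool + (nb - 1) * stats::cov(scores[!labels, , drop = FALSE])
    dof <- dof + nb - 1
  }
  if (dof == 0) stop("degenerate pooled covariance: both groups are singletons")
  pool <- pool / dof
  lambda <- 1e-6 * sum(diag(pool)) / ncol(scores)
  if (lambda <= 0) lambda <- 1e-12
  pool <- pool + diag(lambda, ncol(scores))
  delta <- ma - mb
  sqrt(drop(delta %*% solve(pool, delta)))
}

#' Multidimensional perturbation value (mp-value)
#'
#' A PCA/Mahalanobis two-sample statistic: the pooled profiles are projected
#' onto their principal components (all components up to the pooled-sample
#' rank), component scores are weighted by their explained-variance
#' fraction, and the statistic is the Mahalanobis distance between the two
#' group centroids under the ridge-regularized pooled within-group
#' covariance of the weighted scores. Significance comes from reshuffling
#' the group labels; since the PCA is fit on the pooled sample it does not
#' depend on the labels and is fit once.
#'
#' @param group_a,group_b Numeric matrices (rows = profiles) with equal
#'   column count.
#' @param n_perm Number of label permutations.
#' @param seed Optional seed.
#' @return A `two_group_result` with the Mahalanobis statistic, add-one
#'   smoothed permutation p-value, and `detected = p < alpha`.
#' @param alpha Detection threshold on the permutation p-value.
#' @export
mp_value <- function(group_a, group_b, n_perm = 1000, seed = NULL,
                     alpha = 0.05) {
  g <- check_two_groups(group_a, group_b)
  n <- nrow(g$a) + nrow(g$b)
  if (n < 3) stop("combined sample size must be at least 3")
  run <- function() {
    pooled <- rbind(g$a, g$b)
    pca <- stats::prcomp(pooled, center = TRUE, scale. = FALSE)
    keep <- pca$sdev > 1e-12
    if (!any(keep)) stop("degenerate pooled covariance: all profiles identical")
    evf <- pca$sdev[keep]^2 / sum(pca$sdev[keep]^2)
    scores <- sweep(pca$x[, keep, drop = FALSE], 2, evf, "*")
    labels <- c(rep(TRUE, nrow(g$a)), rep(FALSE, nrow(g$b)))
    observed <- mahalanobis_weighted_pca(scores, labels)
    balanced <- sum(labels) == sum(!labels)
    perm <- vapply(seq_len(n_perm), function(i) {
      # the observed labeling itself is accounted for by the add-one term;
      # redrawing its partition would double-count it
      repeat {
        labs <- sample(labels)
        if (!all(labs == labels) && !(balanced && all(labs != labels))) break
      }
      mahalanobis_weighted_pca(scores, labs)
    }, double(1))
    p <- (1 + sum(perm >= observed - 1e-12)) / (1 + n_perm)
    two_group_result("mp_value", observed, p, p < alpha)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Maximum mean discrepancy two-sample test
#'
#' Unbiased MMD^2 estimate with a radial basis function kernel
#' `exp(-||x - y||^2 / (2 sigma^2))`, the bandwidth `sigma` set by the median
#' heuristic (median pairwise Euclidean distance over the pooled sample).
#' Significance by label permutation on the precomputed kernel matrix; the
#' bandwidth is fixed from the pooled sample and is label-free.
#'
#' @inheritParams mp_value
#' @return A `two_group_result` with the unbiased MMD^2 statistic,
#'   add-one smoothed permutation p-value, and `detected = p < alpha`.
#' @export
mmd_test <- function(group_a, group_b, n_perm = 1000, seed = NULL,
                     alpha = 0.05) {
  g <- check_two_groups(group_a, group_b)
  na <- nrow(g$a)
  nb <- nrow(g$b)
  if (na < 2 || nb < 2) stop("each group needs at least 2 profiles")
  pooled <- rbind(g$a, g$b)
  d <- as.matrix(stats::dist(pooled))
  sigma <- stats::median(d[upper.tri(d)])
  if (sigma == 0) stop("zero bandwidth: all pooled profiles are identical")
  k <- exp(-d^2 / (2 * sigma^2))
  mmd2 <- function(ia) {
    ib <- setdiff(seq_len(na + nb), ia)
    kaa <- k[ia, ia]
    kbb <- k[ib, ib]
    kab <- k[ia, ib]
    # equal sizes: the U-statistic form also excludes the paired cross
    # terms, so identical point sets give exactly zero
    cross <- if (na == nb) {
      2 * (sum(kab) - sum(diag(kab))) / (na * (na - 1))
    } else {
      2 * mean(kab)
    }
    (sum(kaa) - sum(diag(kaa))) / (na * (na - 1)) +
      (sum(kbb) - sum(diag(kbb))) / (nb * (nb - 1)) - cross
  }
  run <- function() {
    observed <- mmd2(seq_len(na))
    orig <- seq_len(na)
    comp <- na + seq_len(nb)
    perm <- vapply(seq_len(n_perm), function(i) {
      # skip draws that recreate the observed partition (see mp_value)
      repeat {
        ia <- sort.int(sample.int(na + nb, na))
        if (!identical(ia, orig) &&
            !(na == nb && identical(ia, comp))) break
      }
      mmd2(ia)
    }, double(1))
    p <- (1 + sum(perm >= observed - 1e-12)) / (1 + n_perm)
    two_group_result("mmd", observed, p, p < alpha)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' k-means separation of two profile groups
#'
#' Clusters the pooled profiles with k-means (k = 2, 10 random restarts,
#' lowest within-cluster sum of squares kept) and declares the groups
#' separated when the 2-cluster partition exactly reproduces the group
#' partition, up to cluster label swap. No p-value is attached.
#'
#' @inheritParams mp_value
#' @param n_restarts Number of random k-means restarts.
#' @return A `two_group_result` with `statistic` 1/0 (separated or not),
#'   `p_value = NA`, and `detected` equal to the separation indicator.
#' @export
kmeans_separation <- function(group_a, group_b, n_restarts = 10,
                              seed = NULL) {
  g <- check_two_groups(group_a, group_b)
  pooled <- rbind(g$a, g$b)
  if (nrow(pooled) < 2) stop("fewer points than clusters")
  run <- function() {
    km <- suppressWarnings(
      stats::kmeans(pooled, centers = 2, nstart = n_restarts)
    )
    truth <- c(rep(1L, nrow(g$a)), rep(2L, nrow(g$b)))
    match_direct <- all(km$cluster == truth)
    match_swapped <- all(km$cluster == (3L - truth))
    detected <- match_direct || match_swapped
    two_group_result("kmeans", as.numeric(detected), NA_real_, detected)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
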
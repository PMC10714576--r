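# Internal cluster-validity indices (silhouette, Calinski-Harabasz,
# Davies-Bouldin) and the clustering comparison table used to choose the
# algorithm and number of groups.

.check_labels <- function(X, labels) {
  if (length(labels) != nrow(X)) stop("labels must match rows of X")
  labs <- sort(unique(labels))
  if (length(labs) < 2L) stop("at least 2 clusters are required")
  labs
}

#' Mean silhouette coefficient
#'
#' For sample i with mean intra-cluster distance a(i) (excluding itself)
#' and b(i) the smallest mean distance to another cluster,
#' s(i) = (b(i) - a(i)) / max(a(i), b(i)); the index is the mean of s(i)
#' over all samples (Euclidean metric). Members of singleton clusters get
#' s(i) = 0, the standard convention where the definition is undefined.
#' Distances are computed in row blocks so large cohorts never materialize
#' a full n x n distance matrix.
#'
#' @param X Numeric matrix (n x d).
#' @param labels Cluster assignment per row.
#' @param block Rows per distance block (default 512).
#' @return Scalar in [-1, 1].
#' @export
silhouette_index <- function(X, labels, block = 512L) {
  X <- as.matrix(X)
  labs <- .check_labels(X, labels)
  n <- nrow(X)
  K <- length(labs)
  li <- match(labels, labs)
  sizes <- tabulate(li, nbins = K)
  s <- numeric(n)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    # accumulate squared differences per feature: same precision as dist()
    d2 <- matrix(0, length(idx), n)
    for (f in seq_len(ncol(X))) {
      d2 <- d2 + outer(X[idx, f], X[, f], `-`)^2
    }
    d <- sqrt(d2)
    # mean distance from each block row to every cluster
    sums <- sapply(seq_len(K), function(k) {
      rowSums(d[, li == k, drop = FALSE])
    })
    sums <- matrix(sums, nrow = length(idx))
    for (j in seq_along(idx)) {
      i <- idx[j]
      k <- li[i]
      if (sizes[k] == 1L) { s[i] <- 0; next }
      a <- sums[j, k] / (sizes[k] - 1L)  # exclude self (distance 0)
      b <- min(sums[j, -k] / sizes[-k])
      s[i] <- (b - a) / max(a, b)
    }
  }
  mean(s)
}

#' Calinski-Harabasz index
#'
#' CH = (B_k / W_k) * (N - k) / (k - 1), with B_k the trace of the
#' between-cluster scatter (size-weighted squared distances of centroids
#' to the global mean) and W_k the trace of the pooled within-cluster
#' scatter. When every cluster is collapsed to a point (W_k = 0) the
#' index is unbounded and `Inf` is returned as the documented sentinel.
#'
#' @inheritParams silhouette_index
#' @return Non-negative scalar (possibly `Inf`).
#' @export
calinski_harabasz_index <- function(X, labels) {
  X <- as.matrix(X)
  labs <- .check_labels(X, labels)
  n <- nrow(X)
  k <- length(labs)
  if (k >= n) stop("need k < N")
  g <- colMeans(X)
  B <- 0; W <- 0
  for (lab in labs) {
    Xi <- X[labels == lab, , drop = FALSE]
    ci <- colMeans(Xi)
    B <- B + nrow(Xi) * sum((ci - g)^2)
    W <- W + sum(sweep(Xi, 2L, ci)^2)
  }
  if (W == 0) return(Inf)
  (B / W) * (n - k) / (k - 1)
}

#' Davies-Bouldin index
#'
#' DB = (1/k) * sum_i max_{j != i} (s_i + s_j) / d(c_i, c_j), where s_i is
#' the mean Euclidean distance of cluster members to their centroid and
#' d(c_i, c_j) the distance between centroids. Lower is better.
#'
#' @inheritParams silhouette_index
#' @return Non-negative scalar.
#' @export
davies_bouldin_index <- function(X, labels) {
  X <- as.matrix(X)
  labs <- .check_labels(X, labels)
  k <- length(labs)
  cent <- t(sapply(labs, function(lab) colMeans(X[labels == lab, , drop = FALSE])))
  cent <- matrix(cent, nrow = k)
  sc <- vapply(seq_len(k), function(i) {
    Xi <- X[labels == labs[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(Xi, 2L, cent[i, ])^2)))
  }, numeric(1))
  val <- 0
  for (i in seq_len(k)) {
    Rij <- vapply(setdiff(seq_len(k), i), function(j) {
      dij <- sqrt(sum((cent[i, ] - cent[j, ])^2))
      if (dij == 0) stop("coincident cluster centroids; index undefined")
      (sc[i] + sc[j]) / dij
    }, numeric(1))
    val <- val + max(Rij)
  }
  val / k
}

#' Compare clustering algorithms and cluster counts
#'
#' Fits the EM Gaussian mixture (hard labels = argmax responsibilities)
#' and/or Lloyd k-means for each K in `K_range` and tabulates the three
#' validity indices. The recommended configuration is the one with the
#' best combined rank of silhouette (higher better) and Davies-Bouldin
#' (lower better); ties go to the higher silhouette.
#'
#' @param X Numeric matrix (n x d), typically the normalized cohort.
#' @param algorithms Subset of `c("em_gmm", "kmeans")`.
#' @param K_range Integer vector of cluster counts (>= 2).
#' @param seed Integer seed.
#' @param restarts,max_iter,tol,ridge Passed to [fit_em_gmm()]; `restarts`
#'   is also used as the k-means `nstart`.
#' @return Data frame with one row per (algorithm, K): the three indices
#'   and a logical `recommended` column.
#' @export
select_clustering <- function(X, algorithms = c("em_gmm", "kmeans"),
                              K_range = 2:4, seed = 1L, restarts = 5L,
                              max_iter = 100L, tol = 1e-6, ridge = 1e-6) {
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  if (any(K_range < 2L)) stop("K_range must contain values >= 2")
  rows <- list()
  for (alg in algorithms) {
    for (K in K_range) {
      if (alg == "em_gmm") {
        fit <- fit_em_gmm(X, K, seed = derive_seed(seed, K),
                          max_iter = max_iter, tol = tol,
                          restarts = restarts, ridge = ridge)
        labels <- hard_labels(fit)
      } else {
        set.seed(derive_seed(seed, 100L + K))
        labels <- stats::kmeans(X, centers = K, iter.max = max_iter,
                                nstart = restarts,
                                algorithm = "Lloyd")$cluster
      }
      rows[[length(rows) + 1L]] <- data.frame(
        algorithm = alg, K = K,
        silhouette = silhouette_index(X, labels),
        calinski_harabasz = calinski_harabasz_index(X, labels),
        davies_bouldin = davies_bouldin_index(X, labels),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rk <- rank(-out$silhouette) + rank(out$davies_bouldin)
  best <- which(rk == min(rk))
  if (length(best) > 1L) best <- best[which.max(out$silhouette[best])]
  out$recommended <- seq_len(nrow(out)) == best
  out
}
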
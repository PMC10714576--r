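# Gaussian mixture model fitted by expectation-maximization, with
# responsibilities, a log-likelihood trace, and semantic cluster ordering.

# Log-density of rows of X under N(mean, Sigma), via the Cholesky factor.
dmvnorm_log <- function(X, mean, Sigma) {
  R <- tryCatch(chol(Sigma), error = function(e) {
    stop("covariance matrix numerically singular; increase the ridge", call. = FALSE)
  })
  d <- ncol(X)
  z <- backsolve(R, t(X) - mean, transpose = TRUE)  # R^T z = (x - mu)
  -0.5 * colSums(z^2) - sum(log(diag(R))) - 0.5 * d * log(2 * pi)
}

rowlogsumexp <- function(M) {
  m <- apply(M, 1L, max)
  m + log(rowSums(exp(M - m)))
}

# Mixture log-density matrix (n x K) of log(pi_k) + log N(x | mu_k, Sigma_k).
gmm_logdens <- function(X, pi, means, covariances) {
  K <- length(pi)
  ld <- matrix(NA_real_, nrow(X), K)
  for (k in seq_len(K)) {
    ld[, k] <- log(pi[k]) + dmvnorm_log(X, means[k, ], covariances[[k]])
  }
  ld
}

# Total log-likelihood of data under mixture parameters; used by tests to
# verify permutation invariance and by the E-step.
gmm_loglik <- function(X, pi, means, covariances) {
  sum(rowlogsumexp(gmm_logdens(X, pi, means, covariances)))
}

# k-means++-style seeding: first center uniform, subsequent centers drawn
# with probability proportional to squared distance to the nearest chosen
# center.
kmeanspp_centers <- function(X, K) {
  n <- nrow(X)
  idx <- integer(K)
  idx[1] <- sample.int(n, 1L)
  d2 <- rowSums((X - matrix(X[idx[1], ], n, ncol(X), byrow = TRUE))^2)
  for (k in seq_len(K - 1L) + 1L) {
    p <- d2 / sum(d2)
    idx[k] <- sample.int(n, 1L, prob = p)
    nd2 <- rowSums((X - matrix(X[idx[k], ], n, ncol(X), byrow = TRUE))^2)
    d2 <- pmin(d2, nd2)
  }
  X[idx, , drop = FALSE]
}

#' Fit a Gaussian mixture model by expectation-maximization
#'
#' The E-step computes posterior component memberships
#' (responsibilities) from the current parameters; the M-step updates each
#' component mean as the responsibility-weighted average, each covariance
#' as the responsibility-weighted scatter (maximum-likelihood, 1/N_k
#' denominator, plus a diagonal ridge), and each mixture weight as
#' N_k / N. Iterations stop when the relative change in log-likelihood
#' falls below `tol` or after `max_iter` iterations. Several restarts with
#' k-means++-seeded means are run and the fit with the highest final
#' log-likelihood is returned.
#'
#' @param X Numeric matrix (n x d), n > K.
#' @param K Number of mixture components.
#' @param seed Integer seed driving initialization (one stream per restart).
#' @param max_iter Maximum EM iterations (default 100).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-6).
#' @param restarts Number of random initializations (default 5).
#' @param ridge Diagonal regularization added to every covariance update
#'   (default 1e-6).
#' @return An `em_gmm` object: list with `K`, `pi`, `means` (K x d),
#'   `covariances` (list of d x d), `gamma` (n x K responsibilities),
#'   `loglik_trace`, `n_iter`, `converged`, `seed`, `ridge`.
#' @export
fit_em_gmm <- function(X, K, seed = 1L, max_iter = 100L, tol = 1e-6,
                       restarts = 5L, ridge = 1e-6) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (n <= K) stop("need more observations than mixture components")
  best <- NULL
  for (r in seq_len(restarts)) {
    set.seed(derive_seed(seed, r))
    fit <- .em_gmm_once(X, K, max_iter, tol, ridge)
    if (is.null(best) ||
        fit$loglik_trace[length(fit$loglik_trace)] >
          best$loglik_trace[length(best$loglik_trace)]) {
      best <- fit
    }
  }
  best$seed <- seed
  best$ridge <- ridge
  class(best) <- "em_gmm"
  best
}

.em_gmm_once <- function(X, K, max_iter, tol, ridge) {
  n <- nrow(X); d <- ncol(X)
  means <- kmeanspp_centers(X, K)
  pooled <- stats::cov(X) * (n - 1) / n + diag(ridge, d)
  covariances <- replicate(K, pooled, simplify = FALSE)
  pi <- rep(1 / K, K)
  trace <- numeric(0)
  converged <- FALSE
  gamma <- NULL
  # Each iteration runs E then M, so the returned parameters are always the
  # M-step image of the returned responsibilities (in particular
  # pi = colMeans(gamma) exactly). The trace records the log-likelihood of
  # the parameters entering each E-step.
  for (it in seq_len(max_iter)) {
    ld <- gmm_logdens(X, pi, means, covariances)
    lse <- rowlogsumexp(ld)
    ll <- sum(lse)
    trace <- c(trace, ll)
    gamma <- exp(ld - lse)
    gamma <- gamma / rowSums(gamma)  # exact row normalization
    Nk <- colSums(gamma)
    pi <- Nk / n
    means <- t(gamma) %*% X / Nk
    for (k in seq_len(K)) {
      Xc <- X - matrix(means[k, ], n, d, byrow = TRUE)
      S <- crossprod(Xc * sqrt(gamma[, k])) / Nk[k]
      covariances[[k]] <- (S + t(S)) / 2 + diag(ridge, d)
    }
    if (it > 1L && abs(ll - trace[it - 1L]) <= tol * abs(trace[it - 1L])) {
      converged <- TRUE
      break
    }
  }
  list(K = K, pi = pi, means = means, covariances = covariances,
       gamma = gamma, loglik_trace = trace, n_iter = length(trace),
       converged = converged)
}

#' @export
print.em_gmm <- function(x, ...) {
  cat(sprintf("EM-GMM fit: K = %d, d = %d, n = %d\n",
              x$K, ncol(x$means), nrow(x$gamma)))
  cat(sprintf("log-likelihood %.4f after %d iteration(s)%s\n",
              x$loglik_trace[length(x$loglik_trace)], x$n_iter,
              if (x$converged) " (converged)" else " (max_iter reached)"))
  cat("mixture weights:", paste(sprintf("%.3f", x$pi), collapse = " "), "\n")
  invisible(x)
}

#' Hard component assignments from responsibilities
#'
#' Argmax of each responsibility row; ties broken toward the lower
#' component index.
#'
#' @param model An `em_gmm` object.
#' @return Integer vector of component labels (1-based).
#' @export
hard_labels <- function(model) {
  max.col(model$gamma, ties.method = "first")
}

#' Order mixture components into poor / medium / good immune status
#'
#' Because the three-platform normalization orients all 15 axes so that
#' larger values indicate a younger-like profile, components are ranked by
#' the mean of their mean vectors: the highest becomes `"good"`, the
#' lowest `"poor"`. As a diagnostic, the per-age-year membership
#' proportion of each cluster is correlated with age (Spearman); a warning
#' is raised if the `"good"` cluster's correlation is not the most
#' negative. Ties in the centroid means are broken by component index
#' with a warning.
#'
#' @param model An `em_gmm` object with `K = 3`.
#' @param ages Numeric ages, one per row of the fitted data.
#' @return A `cluster_ordering`: list with `mapping` (named character
#'   vector, component -> label) and `diagnostics` (per-cluster rho, p).
#' @export
order_clusters <- function(model, ages) {
  if (model$K != 3L) stop("semantic ordering is defined for K = 3")
  labels <- hard_labels(model)
  if (length(ages) != length(labels)) stop("ages must match fitted rows")
  tab <- tabulate(labels, nbins = 3L)
  if (any(tab == 0L)) stop("empty hard cluster; cannot order components")
  level <- rowMeans(model$means)
  if (anyDuplicated(level)) {
    warning("tie in component mean levels; broken by component index")
  }
  rk <- rank(level, ties.method = "first")
  sem <- c("poor", "medium", "good")[rk]
  mapping <- setNames(sem, paste0("component", 1:3))

  yr <- floor(ages)
  diag_df <- NULL
  if (length(unique(yr)) >= 3L) {
    prop <- t(vapply(sort(unique(yr)), function(y) {
      tabulate(labels[yr == y], nbins = 3L) / sum(yr == y)
    }, numeric(3)))
    yrs <- sort(unique(yr))
    diag_df <- do.call(rbind, lapply(1:3, function(k) {
      sp <- tryCatch(spearman(prop[, k], yrs),
                     error = function(e) list(rho = NA_real_, p = NA_real_))
      data.frame(component = k, label = sem[k], rho = sp$rho, p = sp$p,
                 stringsAsFactors = FALSE)
    }))
    good_rho <- diag_df$rho[diag_df$label == "good"]
    if (!is.na(good_rho) && good_rho != min(diag_df$rho, na.rm = TRUE)) {
      warning("age diagnostic: the 'good' cluster's membership-vs-age rho is not the most negative")
    }
  }
  structure(list(mapping = mapping, diagnostics = diag_df),
            class = "cluster_ordering")
}

#' @export
print.cluster_ordering <- function(x, ...) {
  cat("Cluster ordering:", paste(names(x$mapping), x$mapping,
                                 sep = " -> ", collapse = ", "), "\n")
  if (!is.null(x$diagnostics)) {
    cat("membership-proportion vs age (Spearman):\n")
    print(format(x$diagnostics, digits = 3), row.names = FALSE)
  }
  invisible(x)
}

#' Semantic group label per subject
#'
#' @param model An `em_gmm` object with `K = 3`.
#' @param ordering A `cluster_ordering` from [order_clusters()].
#' @return Factor with levels poor < medium < good.
#' @export
semantic_labels <- function(model, ordering) {
  factor(unname(ordering$mapping[hard_labels(model)]),
         levels = c("poor", "medium", "good"))
}
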
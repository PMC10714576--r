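test_that("single-component fit reduces to the sample mean and MLE covariance", {
  set.seed(2)
  X <- matrix(rnorm(400), 100, 4)
  m <- fit_em_gmm(X, K = 1, seed = 1, restarts = 1, ridge = 1e-6)
  expect_equal(m$pi, 1)
  expect_equal(unname(m$means[1, ]), unname(colMeans(X)), tolerance = 1e-12)
  expect_equal(m$covariances[[1]],
               cov(X) * 99 / 100 + diag(1e-6, 4), tolerance = 1e-10)
  expect_true(m$converged)
  # closed form is reached by the first M-step; the trace holds at most
  # two further confirming evaluations
  expect_lte(m$n_iter, 3L)
})

test_that("EM recovers the parameters of well-separated spherical components", {
  mu <- rbind(c(0, 0, 0), c(6, 0, 0), c(0, 6, 6))
  covs <- replicate(3, diag(1, 3), simplify = FALSE)
  gm <- generate_gaussian_mixture(3000, c(0.3, 0.4, 0.3), mu, covs, seed = 4)
  fit <- fit_em_gmm(gm$X, K = 3, seed = 2, restarts = 5)
  # match fitted components to truth by nearest mean
  perm <- apply(fit$means, 1, function(m) which.min(colSums((t(mu) - m)^2)))
  expect_setequal(perm, 1:3)
  for (k in 1:3) {
    expect_lt(sqrt(max((fit$means[k, ] - mu[perm[k], ])^2)), 0.05)
  }
  expect_lt(max(abs(fit$pi[order(perm)] - c(0.3, 0.4, 0.3))), 0.02)
})

test_that("the log-likelihood trace is non-decreasing and responsibilities are normalized", {
  for (s in 1:5) {
    set.seed(s)
    X <- matrix(rnorm(150 * 3, sd = 1 + s / 5), 150, 3) +
      rep(sample(0:2, 150, TRUE), 3)
    m <- fit_em_gmm(X, K = 2 + s %% 2, seed = s, restarts = 2)
    expect_true(all(diff(m$loglik_trace) >= -1e-8))
    expect_equal(rowSums(m$gamma), rep(1, 150), tolerance = 1e-12)
    expect_equal(unname(colMeans(m$gamma)), unname(m$pi), tolerance = 1e-12)
    expect_equal(sum(m$pi), 1, tolerance = 1e-12)
    for (S in m$covariances) {
      expect_equal(S, t(S))
      expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)
    }
  }
})

test_that("the likelihood is invariant under component relabeling", {
  set.seed(9)
  X <- matrix(rnorm(300), 100, 3)
  m <- fit_em_gmm(X, K = 3, seed = 1, restarts = 2)
  ll <- immunoscore:::gmm_loglik(X, m$pi, m$means, m$covariances)
  perm <- c(3, 1, 2)
  ll_p <- immunoscore:::gmm_loglik(X, m$pi[perm], m$means[perm, ],
                                   m$covariances[perm])
  expect_equal(ll_p, ll, tolerance = 1e-10)
  expect_equal(ll, m$loglik_trace[length(m$loglik_trace)], tolerance = 1e-6)
})

test_that("fitted log-likelihood agrees with an independent EM implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  mu <- rbind(c(0, 0), c(5, 5), c(-5, 5))
  covs <- replicate(3, diag(1, 2), simplify = FALSE)
  gm <- generate_gaussian_mixture(1500, rep(1, 3) / 3, mu, covs, seed = 8)
  fit <- fit_em_gmm(gm$X, K = 3, seed = 3, restarts = 3, ridge = 1e-9)
  ref <- Mclust(gm$X, G = 3, modelNames = "VVV", verbose = FALSE)
  expect_lt(abs(fit$loglik_trace[length(fit$loglik_trace)] - ref$loglik) /
              abs(ref$loglik), 1e-3)
})

test_that("EM errors on degenerate inputs", {
  X <- matrix(rnorm(9), 3, 3)
  expect_error(fit_em_gmm(X, K = 3), "more observations")
})

test_that("cluster ordering ranks components by centroid level with age diagnostics", {
  set.seed(21)
  n <- 900
  lev <- sample(1:3, n, TRUE)
  X <- matrix(rnorm(n * 15, mean = c(0.3, 0.5, 0.7)[lev], sd = 0.03), n, 15)
  ages <- ifelse(lev == 3, sample(20:40, n, TRUE),
                 ifelse(lev == 2, sample(41:60, n, TRUE),
                        sample(61:84, n, TRUE)))
  m <- fit_em_gmm(X, K = 3, seed = 5, restarts = 3)
  ord <- order_clusters(m, ages)
  lvl <- rowMeans(m$means)
  expect_equal(unname(ord$mapping[which.min(lvl)]), "poor")
  expect_equal(unname(ord$mapping[which.max(lvl)]), "good")
  # high scores were concentrated in the young
  expect_lt(ord$diagnostics$rho[ord$diagnostics$label == "good"], 0)
  g <- semantic_labels(m, ord)
  expect_equal(levels(g), c("poor", "medium", "good"))
})

test_that("ordering requires K = 3 and non-empty clusters, with a deterministic tie rule", {
  set.seed(1)
  X <- matrix(rnorm(200), 100, 2)
  m2 <- fit_em_gmm(X, K = 2, seed = 1, restarts = 1)
  expect_error(order_clusters(m2, rep(20:29, 10)), "K = 3")
  m3 <- fit_em_gmm(matrix(rnorm(300), 100, 3), K = 3, seed = 1, restarts = 1)
  tied <- m3
  tied$means <- matrix(0.5, 3, 3)  # exact tie in centroid levels
  expect_warning(ord <- order_clusters(tied, rep(20:29, 10)), "tie")
  expect_equal(unname(ord$mapping), c("poor", "medium", "good"))
})
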
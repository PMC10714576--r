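# Shared fixture: labels driven by a handful of designated indexes so the
# importance machinery has a known signal to recover.
signal_cohort <- function(n, seed, signal = c(1, 2, 3), p = 15) {
  set.seed(seed)
  X <- matrix(runif(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  s <- rowMeans(X[, signal, drop = FALSE])
  y <- cut(s, quantile(s, c(0, 1 / 3, 2 / 3, 1)), include.lowest = TRUE,
           labels = c("poor", "medium", "good"))
  list(X = X, y = y)
}

test_that("stratified splitting preserves sizes, classes and determinism", {
  y <- factor(rep(c("a", "b", "c"), times = c(50, 30, 20)))
  sp <- split_cohort(y, fraction = 0.8, seed = 42)
  expect_length(sp$train, 80L)
  expect_length(sp$test, 20L)
  expect_equal(as.vector(table(y[sp$train])), c(40, 24, 16))
  sp2 <- split_cohort(y, fraction = 0.8, seed = 42)
  expect_identical(sp, sp2)
  sp3 <- split_cohort(y, fraction = 0.8, seed = 43)
  expect_false(identical(sp$train, sp3$train))
  expect_error(split_cohort(factor(rep("a", 20))), "2 classes")
  expect_error(split_cohort(factor(c(rep("a", 19), "b"))), "fewer than 2")
})

test_that("every model concentrates importance on the signal features", {
  sc <- signal_cohort(2000, seed = 1)
  runs <- importance_run(sc$X, sc$y, seed = 1)
  expect_equal(dim(runs), c(3L, 15L))
  expect_equal(rowSums(runs), c(rf = 1, lgb = 1, xgb = 1), tolerance = 1e-9)
  for (m in rownames(runs)) {
    top3 <- order(runs[m, ], decreasing = TRUE)[1:3]
    expect_setequal(top3, 1:3)
  }
})

test_that("importance is equivariant under feature permutation", {
  sc <- signal_cohort(800, seed = 2)
  perm <- c(4, 1, 15, 2, 3, 7, 6, 5, 9, 8, 11, 10, 13, 12, 14)
  Xp <- sc$X[, perm]
  colnames(Xp) <- colnames(sc$X)[perm]
  r1 <- importance_run(sc$X, sc$y, seed = 5)
  r2 <- importance_run(Xp, sc$y, seed = 5)
  # tree learners break split-gain ties by feature position, so
  # equivariance is near-exact per run for the greedy boosters ...
  for (m in c("lgb", "xgb")) {
    expect_lt(max(abs(unname(r2[m, ]) - unname(r1[m, perm]))), 0.02)
  }
  # ... and holds for all models in aggregate over repeated splits
  agg1 <- aggregate_weights(lapply(1:8, function(r) {
    importance_run(sc$X, sc$y, seed = 100 + r)
  }))
  agg2 <- aggregate_weights(lapply(1:8, function(r) {
    importance_run(Xp, sc$y, seed = 100 + r)
  }))
  expect_lt(max(abs(unname(agg2$weights) - unname(agg1$weights[perm]))), 0.03)
})

test_that("aggregation averages runs into normalized weights, order-independently", {
  v <- matrix(rep(c(0.5, 0.3, 0.2), 3), 3, 3, byrow = TRUE,
              dimnames = list(c("rf", "lgb", "xgb"), paste0("x", 1:3)))
  w <- aggregate_weights(list(v))
  expect_equal(unname(w$weights), c(0.5, 0.3, 0.2))
  r1 <- v; r2 <- v * matrix(c(1.2, 0.9, 0.9), 3, 3)
  r2 <- r2 / rowSums(r2)
  wa <- aggregate_weights(list(r1, r2))
  wb <- aggregate_weights(list(r2, r1))
  expect_equal(wa$weights, wb$weights)
  expect_equal(sum(wa$weights), 1, tolerance = 1e-9)
  expect_true(all(wa$weights >= 0))
  tab <- weights_table(wa)
  expect_equal(tab$mean, unname((tab$rf + tab$lgb + tab$xgb) / 3))
  expect_error(aggregate_weights(list(v, v[, 1:2])), "inconsistent")
})

test_that("repeated-split weights are stable across disjoint seed streams", {
  sc <- signal_cohort(800, seed = 3)
  w1 <- importance_weights(sc$X, sc$y, n_repeats = 20, seed = 1)
  w2 <- importance_weights(sc$X, sc$y, n_repeats = 20, seed = 77)
  expect_lt(max(abs(w1$weights - w2$weights)), 0.02)
})

test_that("classifier evaluation reports confusion-derived metrics and AUC", {
  # perfectly separable labels
  sc <- signal_cohort(400, seed = 4)
  y_sep <- factor(ifelse(sc$X[, 1] > 0.66, "good",
                         ifelse(sc$X[, 1] > 0.33, "medium", "poor")),
                  levels = c("poor", "medium", "good"))
  rep_c <- evaluate_classifiers(sc$X, y_sep, seed = 1)
  for (m in names(rep_c)) {
    expect_gt(rep_c[[m]]$accuracy, 0.9)
    expect_true(all(rep_c[[m]]$per_class$auc > 0.9))
    cm <- rep_c[[m]]$confusion
    expect_equal(rowSums(cm), table(y_sep[split_cohort(y_sep, seed = 1)$test]),
                 ignore_attr = TRUE)
  }
})

test_that("confusion metrics match hand arithmetic on 12 labeled points", {
  y_true <- factor(c("a", "a", "a", "a", "b", "b", "b", "b", "c", "c", "c", "c"))
  y_pred <- factor(c("a", "a", "b", "c", "b", "b", "b", "a", "c", "c", "a", "c"),
                   levels = levels(y_true))
  met <- immunoscore:::confusion_metrics(y_true, y_pred)
  expect_equal(met$accuracy, 8 / 12)
  pc <- met$per_class
  expect_equal(pc$precision[pc$group == "a"], 2 / 4)
  expect_equal(pc$recall[pc$group == "a"], 2 / 4)
  expect_equal(pc$precision[pc$group == "b"], 3 / 4)
  expect_equal(pc$recall[pc$group == "b"], 3 / 4)
  expect_equal(pc$f1[pc$group == "c"], 2 * (3 / 4) * (3 / 4) / (3 / 2))
})

test_that("rank-based AUC equals the trapezoidal ROC area", {
  skip_if_not_installed("pROC")
  set.seed(6)
  score <- c(rnorm(40, 1), rnorm(60))
  lab <- rep(c(TRUE, FALSE), c(40, 60))
  expect_equal(immunoscore:::rank_auc(score, lab),
               as.numeric(pROC::auc(pROC::roc(lab, score, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("weights survive a YAML round trip", {
  sc <- signal_cohort(400, seed = 8)
  w <- importance_weights(sc$X, sc$y, n_repeats = 2, seed = 3)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_importance_weights(w, f)
  w2 <- read_importance_weights(f)
  expect_equal(w2$weights, w$weights)
  expect_equal(w2$per_model, w$per_model)
  expect_equal(w2$n_repeats, w$n_repeats)
})
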
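# Per-index correlation with immune status, estimated as normalized
# feature importances from three tree-ensemble classifiers averaged over
# repeated stratified train/test splits.

#' Default hyperparameters for the three classifiers
#'
#' * `rf`: random forest, 100 trees, impurity (Gini) importance.
#' * `lgb`: leaf-wise histogram gradient boosting (LightGBM-style
#'   configuration grown with xgboost's `lossguide` policy): 31 leaves,
#'   unlimited depth, learning rate 0.1, 40 rounds, 256 histogram bins;
#'   gain importance.
#' * `xgb`: depth-wise gradient boosting: max depth 3, learning rate 0.1,
#'   100 rounds; gain importance.
#'
#' @return Named list of per-model hyperparameter lists.
#' @export
default_hyperparams <- function() {
  list(
    rf = list(ntree = 100L),
    lgb = list(num_leaves = 31L, learning_rate = 0.1, n_estimators = 40L,
               max_bin = 256L, max_depth = 0L),
    xgb = list(max_depth = 3L, learning_rate = 0.1, n_estimators = 100L)
  )
}

#' Stratified train/test split
#'
#' Splits samples into a training fraction and a held-out test set,
#' preserving class proportions; deterministic for a fixed seed.
#'
#' @param y Class labels (factor or vector), at least 2 classes, every
#'   class with at least 2 members.
#' @param fraction Training fraction (default 0.8).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_cohort <- function(y, fraction = 0.8, seed = 1L) {
  y <- as.factor(y)
  if (length(y) < 10L) stop("need at least 10 samples to split")
  if (nlevels(droplevels(y)) < 2L) stop("need at least 2 classes present")
  tab <- table(droplevels(y))
  if (any(tab < 2L)) {
    stop("class with fewer than 2 members: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  }
  set.seed(seed)
  train <- integer(0)
  for (cl in levels(droplevels(y))) {
    idx <- which(y == cl)
    n_tr <- round(fraction * length(idx))
    n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
    train <- c(train, sample(idx, n_tr))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(y), train))
}

.fit_rf <- function(Xtr, ytr, hp) {
  randomForest::randomForest(x = Xtr, y = ytr, ntree = hp$ntree)
}

.fit_xgb_generic <- function(Xtr, ytr, params, nrounds) {
  d <- xgboost::xgb.DMatrix(Xtr, label = as.integer(ytr) - 1L)
  params <- c(params, list(objective = "multi:softprob",
                           num_class = nlevels(ytr), nthread = 1L,
                           seed = sample.int(.Machine$integer.max, 1L)))
  xgboost::xgb.train(params = params, data = d, nrounds = nrounds, verbose = 0)
}

.fit_lgb <- function(Xtr, ytr, hp) {
  .fit_xgb_generic(Xtr, ytr,
                   list(tree_method = "hist", grow_policy = "lossguide",
                        max_leaves = hp$num_leaves, max_depth = hp$max_depth,
                        eta = hp$learning_rate, max_bin = hp$max_bin),
                   hp$n_estimators)
}

.fit_xgb <- function(Xtr, ytr, hp) {
  .fit_xgb_generic(Xtr, ytr,
                   list(max_depth = hp$max_depth, eta = hp$learning_rate),
                   hp$n_estimators)
}

.xgb_gain <- function(model, feature_names) {
  imp <- xgboost::xgb.importance(model = model)
  v <- setNames(rep(0, length(feature_names)), feature_names)
  v[imp$Feature] <- imp$Gain
  v
}

#' One importance experiment: split, train three models, extract importances
#'
#' Trains the three classifiers on a stratified 80% split and returns each
#' model's per-feature importance vector rescaled to sum to 1 (impurity
#' importance for the forest, gain importance for both boosting models),
#' which makes the three models commensurable.
#'
#' @param X Numeric matrix (n x p) of normalized index values.
#' @param y Class labels (immune-status groups).
#' @param seed Integer seed (drives the split and the model fits).
#' @param fraction Training fraction (default 0.8).
#' @param hyperparams See [default_hyperparams()].
#' @return Numeric matrix 3 x p (rows `rf`, `lgb`, `xgb`), each row
#'   summing to 1.
#' @export
importance_run <- function(X, y, seed = 1L, fraction = 0.8,
                           hyperparams = default_hyperparams()) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  sp <- split_cohort(y, fraction = fraction, seed = seed)
  Xtr <- X[sp$train, , drop = FALSE]
  ytr <- y[sp$train]
  p <- ncol(X)
  fn <- colnames(X) %||% paste0("x", seq_len(p))
  colnames(Xtr) <- fn

  set.seed(derive_seed(seed, 11L))
  rf <- .fit_rf(Xtr, ytr, hyperparams$rf)
  imp_rf <- setNames(rf$importance[, "MeanDecreaseGini"], fn)

  set.seed(derive_seed(seed, 12L))
  lgb <- .fit_lgb(Xtr, ytr, hyperparams$lgb)
  imp_lgb <- .xgb_gain(lgb, fn)

  set.seed(derive_seed(seed, 13L))
  xgb <- .fit_xgb(Xtr, ytr, hyperparams$xgb)
  imp_xgb <- .xgb_gain(xgb, fn)

  out <- rbind(rf = imp_rf / sum(imp_rf),
               lgb = imp_lgb / sum(imp_lgb),
               xgb = imp_xgb / sum(imp_xgb))
  colnames(out) <- fn
  out
}

#' Aggregate repeated importance runs into score weights
#'
#' The weight of index i is the mean of its normalized importance over all
#' runs and all three models; per-model means are retained for reporting.
#'
#' @param runs List of 3 x p matrices from [importance_run()].
#' @param fraction,seed Provenance recorded in the result.
#' @return An `importance_weights` object: list with `weights` (named,
#'   sums to 1), `per_model` (3 x p matrix of per-model means),
#'   `n_repeats`, `split_fraction`, `seed`.
#' @export
aggregate_weights <- function(runs, fraction = 0.8, seed = NA_integer_) {
  if (!length(runs)) stop("need at least one importance run")
  p <- ncol(runs[[1]])
  if (!all(vapply(runs, ncol, 0L) == p)) {
    stop("inconsistent importance vector lengths across runs")
  }
  per_model <- Reduce(`+`, runs) / length(runs)
  w <- colMeans(per_model)
  w <- w / sum(w)
  structure(list(weights = w, per_model = per_model,
                 n_repeats = length(runs), split_fraction = fraction,
                 seed = seed),
            class = "importance_weights")
}

#' Estimate index weights over repeated random splits
#'
#' Convenience wrapper running [importance_run()] `n_repeats` times with
#' split seeds derived from `seed`, then [aggregate_weights()].
#'
#' @inheritParams importance_run
#' @param n_repeats Number of repeated experiments (default 200).
#' @return An `importance_weights` object.
#' @export
importance_weights <- function(X, y, n_repeats = 200L, fraction = 0.8,
                               seed = 1L, hyperparams = default_hyperparams()) {
  runs <- lapply(seq_len(n_repeats), function(r) {
    importance_run(X, y, seed = derive_seed(seed, 1000L + r),
                   fraction = fraction, hyperparams = hyperparams)
  })
  aggregate_weights(runs, fraction = fraction, seed = seed)
}

#' @export
print.importance_weights <- function(x, ...) {
  cat(sprintf("Index weights from %d repeat(s), split fraction %.2f\n",
              x$n_repeats, x$split_fraction))
  print(round(sort(x$weights, decreasing = TRUE), 4))
  invisible(x)
}

#' Per-model and mean importance table
#'
#' @param w An `importance_weights` object.
#' @return Data frame with columns `index`, `rf`, `lgb`, `xgb`, `mean`.
#' @export
weights_table <- function(w) {
  data.frame(index = colnames(w$per_model),
             rf = w$per_model["rf", ], lgb = w$per_model["lgb", ],
             xgb = w$per_model["xgb", ],
             mean = colMeans(w$per_model), row.names = NULL,
             stringsAsFactors = FALSE)
}

# Per-class precision/recall/F1, accuracy and the confusion matrix from
# label vectors; classes absent from the test set yield NA metrics.
confusion_metrics <- function(y_true, y_pred) {
  lev <- levels(as.factor(y_true))
  y_true <- factor(y_true, levels = lev)
  y_pred <- factor(y_pred, levels = lev)
  cm <- table(truth = y_true, prediction = y_pred)
  per_class <- do.call(rbind, lapply(lev, function(cl) {
    tp <- cm[cl, cl]
    prec <- if (sum(cm[, cl]) > 0) tp / sum(cm[, cl]) else NA_real_
    rec <- if (sum(cm[cl, ]) > 0) tp / sum(cm[cl, ]) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0) {
      2 * prec * rec / (prec + rec)
    } else NA_real_
    data.frame(group = cl, precision = prec, recall = rec, f1 = f1,
               stringsAsFactors = FALSE)
  }))
  list(confusion = cm, per_class = per_class,
       accuracy = sum(diag(cm)) / sum(cm))
}

.predict_prob <- function(model, Xte, lev) {
  if (inherits(model, "randomForest")) {
    pr <- predict(model, Xte, type = "prob")
  } else {
    pr <- predict(model, xgboost::xgb.DMatrix(Xte))
    pr <- matrix(pr, ncol = length(lev), byrow = FALSE)
  }
  colnames(pr) <- lev
  pr
}

#' Evaluate the three classifiers on a held-out test set
#'
#' Trains the three models on the training split and reports, per model:
#' the confusion matrix, per-group precision/recall/F1, overall accuracy,
#' and one-vs-rest AUC per group (rank-based, equal to the trapezoidal
#' area under the ROC curve). Optionally adds k-fold cross-validation
#' accuracies.
#'
#' @inheritParams importance_run
#' @param cv_folds Optional number of cross-validation folds (e.g. 10);
#'   `NULL` (default) skips CV.
#' @return A `classifier_report`: named list per model with elements
#'   `confusion`, `per_class` (including `auc`), `accuracy`, and
#'   optionally `cv_accuracy`.
#' @export
evaluate_classifiers <- function(X, y, seed = 1L, fraction = 0.8,
                                 hyperparams = default_hyperparams(),
                                 cv_folds = NULL) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  lev <- levels(y)
  fn <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
  colnames(X) <- fn
  sp <- split_cohort(y, fraction = fraction, seed = seed)
  Xtr <- X[sp$train, , drop = FALSE]; ytr <- y[sp$train]
  Xte <- X[sp$test, , drop = FALSE]; yte <- y[sp$test]
  fitters <- list(rf = .fit_rf, lgb = .fit_lgb, xgb = .fit_xgb)
  report <- list()
  for (m in names(fitters)) {
    set.seed(derive_seed(seed, match(m, names(fitters)) + 20L))
    fit <- fitters[[m]](Xtr, ytr, hyperparams[[m]])
    prob <- .predict_prob(fit, Xte, lev)
    pred <- factor(lev[max.col(prob, ties.method = "first")], levels = lev)
    met <- confusion_metrics(yte, pred)
    met$per_class$auc <- vapply(lev, function(cl) {
      rank_auc(prob[, cl], yte == cl)
    }, numeric(1))
    if (!is.null(cv_folds)) {
      set.seed(derive_seed(seed, match(m, names(fitters)) + 40L))
      fold <- sample(rep(seq_len(cv_folds), length.out = length(y)))
      accs <- vapply(seq_len(cv_folds), function(f) {
        fit_f <- fitters[[m]](X[fold != f, , drop = FALSE], y[fold != f],
                              hyperparams[[m]])
        prob_f <- .predict_prob(fit_f, X[fold == f, , drop = FALSE], lev)
        pred_f <- lev[max.col(prob_f, ties.method = "first")]
        mean(pred_f == as.character(y[fold == f]))
      }, numeric(1))
      met$cv_accuracy <- accs
    }
    report[[m]] <- met
  }
  class(report) <- "classifier_report"
  report
}

#' @export
print.classifier_report <- function(x, ...) {
  for (m in names(x)) {
    cat(sprintf("%s: accuracy %.3f\n", m, x[[m]]$accuracy))
    print(format(x[[m]]$per_class, digits = 3), row.names = FALSE)
  }
  invisible(x)
}

#' Write / read index weights as YAML
#'
#' @param w An `importance_weights` object.
#' @param path Output/input YAML path.
#' @return `write_importance_weights` returns `path` invisibly;
#'   `read_importance_weights` returns an `importance_weights` object.
#' @export
write_importance_weights <- function(w, path) {
  yaml::write_yaml(list(
    weights = as.list(w$weights),
    per_model = lapply(seq_len(nrow(w$per_model)), function(i) {
      as.list(w$per_model[i, ])
    }),
    model_names = rownames(w$per_model),
    n_repeats = w$n_repeats, split_fraction = w$split_fraction,
    seed = w$seed), path, precision = 15)
  invisible(path)
}

#' @rdname write_importance_weights
#' @export
read_importance_weights <- function(path) {
  y <- yaml::read_yaml(path)
  per_model <- do.call(rbind, lapply(y$per_model, function(r) unlist(r)))
  rownames(per_model) <- y$model_names
  structure(list(weights = unlist(y$weights), per_model = per_model,
                 n_repeats = y$n_repeats, split_fraction = y$split_fraction,
                 seed = y$seed),
            class = "importance_weights")
}
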
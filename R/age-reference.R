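# Cubic age-reference curve for the immunity score and the
# healthy / sub-healthy assessment against it.

#' Fit the age-reference polynomial
#'
#' Fits ordinary least squares polynomials of each order in `orders` to
#' the (age, score) pairs and estimates each order's out-of-sample mean
#' squared error by seeded k-fold cross-validation. The cubic model
#' f(x) = a3 x^3 + a2 x^2 + a1 x + a0 is retained as the final reference
#' regardless of the MSE winner: higher orders can edge out the cubic on
#' MSE while generalizing worse, and the cubic captures the nonlinearity
#' of the score-age trend with the fewest terms. The full MSE table is
#' reported alongside.
#'
#' @param ages Ages in years (n >= 20, spanning >= 10 years).
#' @param scores Immunity scores.
#' @param orders Polynomial orders to compare (default 1:4).
#' @param cv_folds Cross-validation folds (default 5).
#' @param seed Integer seed for fold assignment.
#' @param final_order Order of the retained model (default 3).
#' @return An `age_reference`: list with `coefficients` (a0, a1, ...,
#'   ascending powers), `order`, `mse_table` (per-order CV MSE),
#'   `n`, `age_range`.
#' @export
fit_reference <- function(ages, scores, orders = 1:4, cv_folds = 5L,
                          seed = 1L, final_order = 3L) {
  n <- length(ages)
  if (n < 20L) stop("need at least 20 (age, score) pairs")
  if (length(scores) != n) stop("ages and scores must align")
  if (diff(range(ages)) < 10) stop("ages must span at least 10 years")
  for (k in unique(c(orders, final_order))) {
    if (length(unique(ages)) < k + 1L) {
      stop("rank-deficient design: order ", k, " needs at least ", k + 1L,
           " distinct ages")
    }
  }
  set.seed(seed)
  fold <- sample(rep(seq_len(cv_folds), length.out = n))
  cv_mse <- vapply(orders, function(k) {
    err <- vapply(seq_len(cv_folds), function(f) {
      tr <- fold != f
      fit <- lm(scores[tr] ~ poly(ages[tr], k, raw = TRUE))
      pred <- cbind(1, outer(ages[!tr], seq_len(k), `^`)) %*% coef(fit)
      mean((scores[!tr] - pred)^2)
    }, numeric(1))
    mean(err)
  }, numeric(1))
  fit <- lm(scores ~ poly(ages, final_order, raw = TRUE))
  coefs <- unname(coef(fit))
  names(coefs) <- paste0("a", seq_along(coefs) - 1L)
  structure(list(coefficients = coefs, order = final_order,
                 mse_table = data.frame(order = orders, cv_mse = cv_mse),
                 n = n, age_range = range(ages)),
            class = "age_reference")
}

#' Construct an age-reference model from known coefficients
#'
#' @param coefficients Numeric vector of coefficients in ascending powers
#'   (a0, a1, ...).
#' @param age_range Ages the model is considered valid for (default
#'   unbounded).
#' @return An `age_reference` object.
#' @export
age_reference_model <- function(coefficients, age_range = c(-Inf, Inf)) {
  coefs <- as.numeric(coefficients)
  names(coefs) <- paste0("a", seq_along(coefs) - 1L)
  structure(list(coefficients = coefs, order = length(coefs) - 1L,
                 mse_table = NULL, n = NA_integer_, age_range = age_range),
            class = "age_reference")
}

#' @export
print.age_reference <- function(x, ...) {
  cat(sprintf("age-reference polynomial, order %d\n", x$order))
  cat("coefficients (ascending powers):",
      paste(sprintf("%.4g", x$coefficients), collapse = ", "), "\n")
  if (!is.null(x$mse_table)) {
    cat("cross-validated MSE by order:\n")
    print(format(x$mse_table, digits = 4), row.names = FALSE)
  }
  invisible(x)
}

#' Reference immunity score at an age
#'
#' Evaluates the fitted polynomial (Horner scheme). Ages outside the fit
#' range trigger an extrapolation warning but still return a value.
#'
#' @param age Numeric vector of ages.
#' @param model An `age_reference` object.
#' @return Numeric vector of reference scores.
#' @export
reference_score <- function(age, model) {
  if (any(age < model$age_range[1] | age > model$age_range[2])) {
    warning("age outside the fitted range; extrapolating the reference curve")
  }
  co <- model$coefficients
  v <- rep(co[length(co)], length(age))
  for (k in rev(seq_len(length(co) - 1L))) v <- v * age + co[k]
  unname(v)
}

#' Assess immune status against the age reference
#'
#' A subject is `healthy` iff their immunity score is strictly greater
#' than the reference score for their age, otherwise `sub_healthy`
#' (scores exactly on the curve are sub-healthy). The margin
#' (score - reference) is reported.
#'
#' @param subjects Data frame with columns `age` and `score` (and
#'   optionally `subject_id`).
#' @param model An `age_reference` object.
#' @return An `assessment` data frame: `subject_id`, `age`, `score`,
#'   `reference`, `margin`, `status`.
#' @export
#' @examples
#' m <- age_reference_model(c(0.528))
#' assess(data.frame(age = 27, score = 0.604), m)
assess <- function(subjects, model) {
  ref <- reference_score(subjects$age, model)
  out <- data.frame(
    subject_id = subjects$subject_id %||% sprintf("S%05d", seq_len(nrow(subjects))),
    age = subjects$age, score = subjects$score, reference = ref,
    margin = subjects$score - ref,
    status = ifelse(subjects$score > ref, "healthy", "sub_healthy"),
    stringsAsFactors = FALSE)
  class(out) <- c("assessment", "data.frame")
  out
}

#' Write / read an age-reference model as YAML
#'
#' @param model An `age_reference` object.
#' @param path Output/input YAML path.
#' @return `write_age_reference` returns `path` invisibly;
#'   `read_age_reference` returns an `age_reference` object.
#' @export
write_age_reference <- function(model, path) {
  yaml::write_yaml(list(
    coefficients = as.list(model$coefficients),
    order = model$order,
    mse_table = if (is.null(model$mse_table)) NULL else {
      list(order = model$mse_table$order, cv_mse = model$mse_table$cv_mse)
    },
    n = model$n, age_range = as.numeric(model$age_range)), path, precision = 15)
  invisible(path)
}

#' @rdname write_age_reference
#' @export
read_age_reference <- function(path) {
  y <- yaml::read_yaml(path)
  m <- age_reference_model(unlist(y$coefficients),
                           age_range = unlist(y$age_range))
  if (!is.null(y$mse_table)) {
    m$mse_table <- data.frame(order = unlist(y$mse_table$order),
                              cv_mse = unlist(y$mse_table$cv_mse))
  }
  m$n <- y$n
  m
}
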
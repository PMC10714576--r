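# Log-scale Gaussian statistics per index and the three-platform
# normalization that maps every index into (0, 1).

#' Fit per-index log-scale Gaussian statistics
#'
#' Each of the 15 indexes is log-transformed (natural log) and summarized
#' by its mean `mu` and sample standard deviation `sigma` (n-1
#' denominator); on the filtered cohort these log values are approximately
#' Gaussian, which is what the three-platform transform assumes. Values of
#' exactly zero (possible for EO/BASO counts and their ratios) are replaced
#' by half the smallest positive value observed for that index before
#' logging; the substitution count is reported in a warning and the floor
#' is stored so that new individuals can be scored consistently.
#' Skewness and excess kurtosis of the log values are reported per index
#' as a normality diagnostic.
#'
#' @param panels Numeric matrix (n x 15) from [derive_panels()], n >= 2.
#' @return An `index_stats` data frame with columns `index`, `mu`,
#'   `sigma`, `direction`, `n`, `zero_floor`, `skewness`, `kurtosis`.
#' @export
fit_index_stats <- function(panels) {
  if (nrow(panels) < 2L) stop("need at least 2 panels to fit index statistics")
  nm <- cbc_index_names()
  if (!all(nm %in% colnames(panels))) {
    stop("panels must contain all 15 indexes")
  }
  dirmap <- index_direction_map()
  n_sub <- 0L
  rows <- lapply(nm, function(ix) {
    v <- panels[, ix]
    if (anyNA(v) || any(!is.finite(v))) stop("non-finite values in index ", ix)
    if (any(v < 0)) stop("negative values in index ", ix)
    floor_v <- NA_real_
    if (any(v == 0)) {
      pos <- v[v > 0]
      if (!length(pos)) stop("index ", ix, " is identically zero")
      floor_v <- min(pos) / 2
      n_sub <<- n_sub + sum(v == 0)
      v[v == 0] <- floor_v
    }
    lv <- log(v)
    s <- stats::sd(lv)
    if (s == 0) stop("zero variance in index ", ix)
    m <- mean(lv)
    z <- (lv - m) / (s * sqrt((length(lv) - 1) / length(lv)))
    data.frame(index = ix, mu = m, sigma = s,
               direction = unname(dirmap[[ix]]), n = length(lv),
               zero_floor = floor_v,
               skewness = mean(z^3), kurtosis = mean(z^4) - 3,
               stringsAsFactors = FALSE)
  })
  if (n_sub > 0L) {
    warning(sprintf("%d zero value(s) replaced by half the smallest positive value before logging",
                    n_sub))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("index_stats", "data.frame")
  out
}

#' @export
print.index_stats <- function(x, ...) {
  cat(sprintf("Log-scale index statistics (n = %d)\n", x$n[1]))
  print(format(as.data.frame(x)[, c("index", "mu", "sigma", "direction")],
               digits = 4), row.names = FALSE)
  invisible(x)
}

#' Spearman correlation of each index with age
#'
#' A diagnostic for the fixed age-direction map: reports the rank
#' correlation, its p-value, and the sign-inferred direction per index,
#' next to the fixed map used by the pipeline. The fixed map is never
#' overridden by this diagnostic.
#'
#' @param panels Numeric matrix (n x 15).
#' @param ages Numeric vector of ages (years), length n, not constant.
#' @return Data frame with columns `index`, `rho`, `p`, `inferred`,
#'   `fixed`, `agrees`.
#' @export
spearman_age_direction <- function(panels, ages) {
  if (nrow(panels) < 3L) stop("need at least 3 subjects")
  if (length(ages) != nrow(panels)) stop("ages must match panel rows")
  if (length(unique(ages)) < 2L) stop("age vector is constant; correlation undefined")
  dirmap <- index_direction_map()
  rows <- lapply(colnames(panels), function(ix) {
    sp <- spearman(panels[, ix], ages)
    inf <- if (sp$rho < 0) "decreasing_with_age" else "increasing_with_age"
    data.frame(index = ix, rho = sp$rho, p = sp$p, inferred = inf,
               fixed = unname(dirmap[[ix]]), agrees = inf == dirmap[[ix]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' The three-platform normalization transform
#'
#' Maps a log-scale index value into (0, 1) with a piecewise-Gaussian
#' sigmoid built from two mirrored Gaussian tails:
#' for an index that declines with age,
#' \deqn{\tilde x = \tfrac12 e^{-(x-\mu)^2/2\sigma^2} \ (x \le \mu),\quad
#'       1 - \tfrac12 e^{-(x-\mu)^2/2\sigma^2} \ (x > \mu),}
#' so a higher raw value yields a higher (younger-like) score; for an
#' index that rises with age the pointwise complement is used. The curve
#' has three flat "platforms": at 0 and 1 (saturation) and at 0.5 around
#' the population mean (the self-regulation region). The output is exactly
#' 0.5 at `x_log = mu` and is clamped to the largest open sub-interval of
#' (0, 1) representable in double precision.
#'
#' @param x_log Numeric vector of log-transformed values.
#' @param mu,sigma Log-scale mean and standard deviation (`sigma > 0`).
#' @param direction `"decreasing_with_age"` or `"increasing_with_age"`.
#' @return Numeric vector in (0, 1).
#' @export
#' @examples
#' three_platform(1, 1, 0.5, "decreasing_with_age")  # 0.5 at the mean
three_platform <- function(x_log, mu, sigma,
                           direction = c("decreasing_with_age",
                                         "increasing_with_age")) {
  direction <- match.arg(direction)
  stopifnot_scalar_number(mu, "mu")
  stopifnot_scalar_number(sigma, "sigma")
  if (sigma <= 0) stop("sigma must be positive")
  if (any(!is.finite(x_log))) stop("non-finite input to three_platform")
  g <- 0.5 * exp(-(x_log - mu)^2 / (2 * sigma^2))
  v <- ifelse(x_log <= mu, g, 1 - g)
  if (direction == "increasing_with_age") v <- 1 - v
  pmin(pmax(v, .Machine$double.xmin), 1 - .Machine$double.eps / 2)
}

#' Normalize a cohort's index panels
#'
#' Applies [three_platform()] column-wise using fitted [fit_index_stats()]
#' parameters (including each index's stored zero floor).
#'
#' @param panels Numeric matrix (n x 15) of raw index values.
#' @param stats An `index_stats` object fitted on a compatible index set.
#' @return Numeric matrix (n x 15) with all entries in (0, 1), columns in
#'   [cbc_index_names()] order.
#' @export
normalize_cohort <- function(panels, stats) {
  nm <- cbc_index_names()
  missing <- setdiff(nm, stats$index)
  if (length(missing)) {
    stop("index missing from stats: ", paste(missing, collapse = ", "))
  }
  missing_p <- setdiff(nm, colnames(panels))
  if (length(missing_p)) {
    stop("index missing from panels: ", paste(missing_p, collapse = ", "))
  }
  out <- matrix(NA_real_, nrow(panels), length(nm),
                dimnames = list(rownames(panels), nm))
  if (nrow(panels) == 0L) return(out)
  for (ix in nm) {
    row <- stats[stats$index == ix, ]
    v <- panels[, ix]
    if (!is.na(row$zero_floor)) v[v == 0] <- row$zero_floor
    if (any(v <= 0)) stop("non-positive values in index ", ix,
                          " cannot be log-transformed")
    out[, ix] <- three_platform(log(v), row$mu, row$sigma, row$direction)
  }
  out
}

#' Write / read index statistics as YAML
#'
#' Serializes the normalization parameter set (per index: mu, sigma,
#' direction, n, zero floor) so new individuals can be scored without
#' refitting.
#'
#' @param stats An `index_stats` object.
#' @param path Output/input YAML path.
#' @return `write_index_stats` returns `path` invisibly;
#'   `read_index_stats` returns an `index_stats` object.
#' @export
write_index_stats <- function(stats, path) {
  entries <- lapply(seq_len(nrow(stats)), function(i) {
    r <- stats[i, ]
    list(index = r$index, mu = r$mu, sigma = r$sigma,
         direction = r$direction, n = r$n,
         zero_floor = if (is.na(r$zero_floor)) NULL else r$zero_floor)
  })
  yaml::write_yaml(list(index_stats = entries), path, precision = 15)
  invisible(path)
}

#' @rdname write_index_stats
#' @export
read_index_stats <- function(path) {
  y <- yaml::read_yaml(path)$index_stats
  out <- do.call(rbind, lapply(y, function(e) {
    data.frame(index = e$index, mu = e$mu, sigma = e$sigma,
               direction = e$direction, n = e$n,
               zero_floor = e$zero_floor %||% NA_real_,
               skewness = NA_real_, kurtosis = NA_real_,
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("index_stats", "data.frame")
  out
}
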
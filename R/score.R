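# The continuous immunity score: weighted sum of the 15 normalized
# indexes, plus cohort-level distribution and age-trend summaries.

#' Immunity score of one normalized panel
#'
#' score = sum_i w_i * score_i over the 15 normalized index values. The
#' per-index addends are retained so a score can be explained.
#'
#' @param panel Named numeric vector of normalized index values in (0, 1).
#' @param weights An `importance_weights` object or named numeric vector
#'   summing to 1.
#' @return An `immunity_score`: list with `score` and `components` (the
#'   named addends, summing to `score`).
#' @export
#' @examples
#' z <- setNames(rep(0.5, 15), cbc_index_names())
#' w <- setNames(rep(1 / 15, 15), cbc_index_names())
#' immunity_score(z, w)$score  # 0.5
immunity_score <- function(panel, weights) {
  w <- .weights_vector(weights)
  missing <- setdiff(names(w), names(panel))
  if (length(missing)) {
    stop("index missing from panel: ", paste(missing, collapse = ", "))
  }
  comp <- w * panel[names(w)]
  structure(list(score = sum(comp), components = comp),
            class = "immunity_score")
}

#' @export
print.immunity_score <- function(x, ...) {
  cat(sprintf("immunity score: %.4f\n", x$score))
  invisible(x)
}

.weights_vector <- function(weights) {
  w <- if (inherits(weights, "importance_weights")) weights$weights else weights
  if (is.null(names(w))) stop("weights must be named by index")
  if (any(w < 0)) stop("weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-6) stop("weights must sum to 1")
  w
}

#' Immunity scores for a normalized cohort
#'
#' @param Z Numeric matrix (n x 15) of normalized index values.
#' @param weights See [immunity_score()].
#' @return Numeric vector of n scores, named by rownames of `Z`.
#' @export
score_cohort <- function(Z, weights) {
  w <- .weights_vector(weights)
  missing <- setdiff(names(w), colnames(Z))
  if (length(missing)) {
    stop("index missing from panel: ", paste(missing, collapse = ", "))
  }
  drop(Z[, names(w), drop = FALSE] %*% w)
}

#' Score distribution over fixed ranges
#'
#' Bins scores into half-open-left intervals `[a, b)` (the last bin is
#' closed on the right), by default < 0.2, 0.2-0.4, 0.4-0.6, 0.6-0.8 and
#' 0.8-1.
#'
#' @param scores Numeric vector of immunity scores.
#' @param bin_edges Strictly increasing edges (default
#'   `c(0, 0.2, 0.4, 0.6, 0.8, 1)`).
#' @return Data frame with `bin`, `n`, `pct`.
#' @export
score_distribution <- function(scores, bin_edges = c(0, 0.2, 0.4, 0.6, 0.8, 1)) {
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop("bin edges must be strictly increasing")
  }
  nb <- length(bin_edges) - 1L
  labels <- c(sprintf("<%.1f", bin_edges[2]),
              sprintf("%.1f-%.1f", bin_edges[-c(1, length(bin_edges))],
                      bin_edges[-(1:2)]))
  if (!length(scores)) {
    return(data.frame(bin = character(0), n = integer(0), pct = numeric(0)))
  }
  b <- cut(scores, breaks = bin_edges, right = FALSE,
           include.lowest = FALSE, labels = FALSE)
  b[scores == bin_edges[length(bin_edges)]] <- nb  # close the last bin
  tab <- tabulate(b, nbins = nb)
  data.frame(bin = labels, n = tab, pct = 100 * tab / length(scores),
             stringsAsFactors = FALSE)
}

#' Score trend with age
#'
#' Computes the median score per integer age year and two Spearman
#' correlations: the per-age-median rho (the cohort-level trend) and the
#' subject-level rho.
#'
#' @param scores Numeric immunity scores.
#' @param ages Ages in years (at least 3 distinct values).
#' @return A `score_age_trend`: list with `medians` (data frame `age`,
#'   `median_score`, `n`), `rho_medians`, `p_medians`, `rho_subjects`,
#'   `p_subjects`.
#' @export
score_age_trend <- function(scores, ages) {
  if (length(scores) != length(ages)) stop("scores and ages must align")
  yr <- floor(ages)
  if (length(unique(yr)) < 3L) stop("need at least 3 distinct ages")
  med <- vapply(sort(unique(yr)), function(a) median(scores[yr == a]),
                numeric(1))
  meds <- data.frame(age = sort(unique(yr)), median_score = med,
                     n = as.integer(table(yr)))
  sp_m <- spearman(meds$median_score, meds$age)
  sp_s <- spearman(scores, ages)
  structure(list(medians = meds, rho_medians = sp_m$rho, p_medians = sp_m$p,
                 rho_subjects = sp_s$rho, p_subjects = sp_s$p),
            class = "score_age_trend")
}

#' @export
print.score_age_trend <- function(x, ...) {
  cat(sprintf("score-age trend: per-age-median rho = %.4f, subject-level rho = %.4f\n",
              x$rho_medians, x$rho_subjects))
  invisible(x)
}
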
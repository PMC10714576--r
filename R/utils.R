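# Internal helpers shared across stages.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a child seed from a master seed and a stage offset, kept well below
# 2^31 so set.seed() always accepts it.
derive_seed <- function(seed, offset) {
  ((as.numeric(seed) * 48271 + as.numeric(offset) * 1299721) %% 2147483587) + 1
}

# Spearman rank correlation; cor.test warns on ties, which are expected with
# integer ages, so the warning is suppressed and the asymptotic p kept.
spearman <- function(x, y) {
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop("Spearman correlation undefined: a variable is constant")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

# Rank-based (Mann-Whitney) AUC, identical to the trapezoidal area under the
# empirical ROC curve. `positive` is a logical vector.
rank_auc <- function(score, positive) {
  pos <- score[positive]
  neg <- score[!positive]
  if (length(pos) == 0L || length(neg) == 0L) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name))
  }
}
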
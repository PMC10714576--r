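# Synthetic CBC cohorts with the statistical structure the scoring method
# assumes: log-normal counts with age-correlated drifts, a shared latent
# immune level, derived percentages and ratios, and a contaminated
# fraction that fails the inflammation filters. Also labeled Gaussian
# mixtures for clustering tests.

#' Configuration for the synthetic CBC cohort generator
#'
#' The five differential counts (NEUT, LYMPH, MONO, EO, BASO) are drawn
#' log-normally; WBC is their sum, and percentages and ratios are
#' deterministic functions of the counts, exactly as the panel derivation
#' recomputes them. Each log count is
#' `mu + drift * (age - 52)/10 + sd * (q * g * L + sqrt(1 - q^2) * eps)`,
#' where `L ~ N(0,1)` is a per-subject latent immune level (higher =
#' younger-like), `g` is +1 for counts that decline with age and -1 for
#' counts that rise, and `eps` is index-specific noise. Default baselines
#' (10^9/L at age 52): NEUT 3.5, LYMPH 1.9, MONO 0.42, EO 0.12, BASO
#' 0.03; log-sds 0.20, 0.22, 0.25, 0.50, 0.45; per-decade log drifts
#' -0.025, -0.09, +0.035, +0.09, +0.055 — signs matching the fixed index
#' direction map, magnitudes chosen so that the cohort reproduces a
#' strongly negative per-age-median score trend. A `contamination`
#' fraction of records receives an elevated procalcitonin (> 0.5 ng/mL,
#' as in bacterial infection), half of them additionally a neutrophilia
#' shift, so they fail the health filters.
#'
#' @param n Number of records.
#' @param seed Integer seed.
#' @param contamination Fraction in [0, 1) of contaminated records
#'   (default 0.05).
#' @param age_range Integer age range sampled uniformly (default 20-84).
#' @param male_fraction Probability a record is male (default 0.578).
#' @param latent_share Share `q` in [0, 1) of each index's log-sd carried
#'   by the shared latent immune level (default 0.4).
#' @param count_params Data frame with columns `index`, `log_mean`,
#'   `log_sd`, `drift_per_decade`, `latent_sign` for the five counts;
#'   `NULL` uses the defaults above.
#' @return A `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n, seed = 1L, contamination = 0.05,
                              age_range = c(20L, 84L),
                              male_fraction = 0.578,
                              latent_share = 0.4,
                              count_params = NULL) {
  if (is.null(count_params)) {
    count_params <- data.frame(
      index = c("neut", "lymph", "mono", "eo", "baso"),
      log_mean = log(c(3.5, 1.9, 0.42, 0.12, 0.03)),
      log_sd = c(0.20, 0.22, 0.25, 0.50, 0.45),
      drift_per_decade = c(-0.025, -0.09, 0.035, 0.09, 0.055),
      latent_sign = c(1, 1, -1, -1, -1),
      stringsAsFactors = FALSE)
  }
  if (n < 1L) stop("n must be positive")
  if (contamination < 0 || contamination >= 1) {
    stop("contamination must lie in [0, 1)")
  }
  if (any(count_params$log_sd <= 0)) stop("log-sds must be positive")
  if (latent_share < 0 || latent_share >= 1) {
    stop("latent_share must lie in [0, 1)")
  }
  if (!all(sign(count_params$drift_per_decade) == -count_params$latent_sign)) {
    warning("drift signs do not match the latent-sign (age-direction) convention")
  }
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 contamination = contamination, age_range = age_range,
                 male_fraction = male_fraction, latent_share = latent_share,
                 count_params = count_params),
            class = "cohort_sim_config")
}

#' Generate a synthetic CBC cohort
#'
#' Draws records according to a [cohort_sim_config()] and returns both the
#' records (same schema as [read_cbc_table()] produces) and a hidden-truth
#' sidecar for tests: the latent immune level, the contamination flag, and
#' whether the record's values violate the default health filters.
#'
#' @param cfg A `cohort_sim_config`.
#' @return List with `records` (a `cbc_cohort`) and `truth` (data frame
#'   `subject_id`, `latent`, `contaminated`, `violates_filters`).
#' @export
generate_cohort <- function(cfg) {
  if (!inherits(cfg, "cohort_sim_config")) stop("cfg must be a cohort_sim_config")
  set.seed(cfg$seed)
  n <- cfg$n
  p <- cfg$count_params
  age <- sample(seq(cfg$age_range[1], cfg$age_range[2]), n, replace = TRUE)
  sex <- ifelse(runif(n) < cfg$male_fraction, "male", "female")
  L <- rnorm(n)
  q <- cfg$latent_share
  counts <- sapply(seq_len(nrow(p)), function(i) {
    exp(p$log_mean[i] + p$drift_per_decade[i] * (age - 52) / 10 +
          p$log_sd[i] * (q * p$latent_sign[i] * L + sqrt(1 - q^2) * rnorm(n)))
  })
  colnames(counts) <- p$index

  # clean-record procalcitonin: low, log-normal around 0.05 ng/mL
  pct <- exp(rnorm(n, log(0.05), 0.5))
  pct <- pmin(pct, 0.45)

  contaminated <- rep(FALSE, n)
  m <- round(cfg$contamination * n)
  if (m > 0L) {
    idx <- sample.int(n, m)
    contaminated[idx] <- TRUE
    pct[idx] <- runif(m, 0.6, 5)          # bacterial-infection range
    neutrophilia <- idx[seq_len(floor(m / 2))]
    counts[neutrophilia, "neut"] <- counts[neutrophilia, "neut"] * 2.5
  }

  wbc <- rowSums(counts)
  records <- data.frame(
    subject_id = sprintf("SYN%06d", seq_len(n)), age = age, sex = sex,
    pct = pct, wbc = wbc,
    neut = counts[, "neut"], lymph = counts[, "lymph"],
    mono = counts[, "mono"], eo = counts[, "eo"], baso = counts[, "baso"],
    neut_pct = 100 * counts[, "neut"] / wbc,
    lymph_pct = 100 * counts[, "lymph"] / wbc,
    mono_pct = 100 * counts[, "mono"] / wbc,
    eo_pct = 100 * counts[, "eo"] / wbc,
    baso_pct = 100 * counts[, "baso"] / wbc,
    stringsAsFactors = FALSE)
  class(records) <- c("cbc_cohort", "data.frame")

  rep_f <- apply_health_filters(records)
  violates <- records$subject_id %in% rep_f$rejected$subject_id
  truth <- data.frame(subject_id = records$subject_id, latent = L,
                      contaminated = contaminated,
                      violates_filters = violates,
                      stringsAsFactors = FALSE)
  list(records = records, truth = truth)
}

#' Generate a labeled Gaussian mixture sample
#'
#' Component membership is multinomial in `pi`; points are drawn from the
#' corresponding multivariate Gaussian via its Cholesky factor.
#'
#' @param n Number of points.
#' @param pi Mixture weights (sum to 1).
#' @param means Matrix (K x d) of component means.
#' @param covariances List of K positive-definite d x d matrices.
#' @param seed Integer seed (fixed seed gives bit-identical output).
#' @return List with `X` (n x d matrix) and `labels` (integer vector).
#' @export
generate_gaussian_mixture <- function(n, pi, means, covariances, seed = 1L) {
  if (abs(sum(pi) - 1) > 1e-8) stop("mixture weights must sum to 1")
  if (any(pi < 0)) stop("mixture weights must be non-negative")
  means <- as.matrix(means)
  K <- length(pi)
  if (nrow(means) != K || length(covariances) != K) {
    stop("means and covariances must have one entry per component")
  }
  chols <- lapply(covariances, function(S) {
    tryCatch(chol(S), error = function(e) {
      stop("covariance matrix is not positive-definite", call. = FALSE)
    })
  })
  set.seed(seed)
  labels <- sample.int(K, n, replace = TRUE, prob = pi)
  d <- ncol(means)
  X <- matrix(rnorm(n * d), n, d)
  for (k in seq_len(K)) {
    rows <- labels == k
    if (any(rows)) {
      X[rows, ] <- X[rows, , drop = FALSE] %*% chols[[k]] +
        matrix(means[k, ], sum(rows), d, byrow = TRUE)
    }
  }
  list(X = X, labels = labels)
}
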
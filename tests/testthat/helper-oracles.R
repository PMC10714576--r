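# Independent brute-force oracles for the cluster-validity indices and
# small shared fixtures. These deliberately use naive O(n^2) loops and
# plain formula transcriptions, independent of the package's vectorized
# implementations.

brute_silhouette <- function(X, labels) {
  n <- nrow(X)
  d <- as.matrix(dist(X))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l) {
      mean(d[i, labels == l])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

brute_ch <- function(X, labels) {
  n <- nrow(X)
  k <- length(unique(labels))
  g <- colMeans(X)
  B <- 0; W <- 0
  for (l in unique(labels)) {
    Xi <- X[labels == l, , drop = FALSE]
    ci <- colMeans(Xi)
    B <- B + nrow(Xi) * sum((ci - g)^2)
    for (r in seq_len(nrow(Xi))) W <- W + sum((Xi[r, ] - ci)^2)
  }
  (B / W) * (n - k) / (k - 1)
}

brute_db <- function(X, labels) {
  labs <- sort(unique(labels))
  k <- length(labs)
  cent <- lapply(labs, function(l) colMeans(X[labels == l, , drop = FALSE]))
  sc <- vapply(seq_len(k), function(i) {
    Xi <- X[labels == labs[i], , drop = FALSE]
    mean(apply(Xi, 1L, function(r) sqrt(sum((r - cent[[i]])^2))))
  }, numeric(1))
  tot <- 0
  for (i in seq_len(k)) {
    best <- -Inf
    for (j in seq_len(k)) {
      if (j == i) next
      dij <- sqrt(sum((cent[[i]] - cent[[j]])^2))
      best <- max(best, (sc[i] + sc[j]) / dij)
    }
    tot <- tot + best
  }
  tot / k
}

naive_poly_eval <- function(age, coefs) {
  # ascending powers, term-by-term summation
  sapply(age, function(a) sum(coefs * a^(seq_along(coefs) - 1L)))
}

# A valid single CBC record with every index at a comfortable interior
# point of its retention range.
midpoint_record <- function(...) {
  rec <- data.frame(subject_id = "R1", age = 40, sex = "male", pct = 0.1,
                    wbc = 6.5, neut = 3.8, lymph = 1.9, mono = 0.5,
                    eo = 0.2, baso = 0.05,
                    neut_pct = 100 * 3.8 / 6.5, lymph_pct = 100 * 1.9 / 6.5,
                    mono_pct = 100 * 0.5 / 6.5, eo_pct = 100 * 0.2 / 6.5,
                    baso_pct = 100 * 0.05 / 6.5, stringsAsFactors = FALSE)
  dots <- list(...)
  for (nm in names(dots)) rec[[nm]] <- dots[[nm]]
  # keep percentages consistent with any overridden counts unless the
  # caller set them explicitly
  for (cc in c("neut", "lymph", "mono", "eo", "baso")) {
    pc <- paste0(cc, "_pct")
    if (!pc %in% names(dots)) rec[[pc]] <- 100 * rec[[cc]] / rec$wbc
  }
  rec
}

# Small clean cohort of n valid records around the midpoint, with noise.
toy_cohort <- function(n, seed = 1) {
  set.seed(seed)
  counts <- cbind(neut = exp(log(3.5) + rnorm(n, 0, 0.1)),
                  lymph = exp(log(1.9) + rnorm(n, 0, 0.1)),
                  mono = exp(log(0.45) + rnorm(n, 0, 0.1)),
                  eo = exp(log(0.15) + rnorm(n, 0, 0.2)),
                  baso = exp(log(0.04) + rnorm(n, 0, 0.2)))
  wbc <- rowSums(counts)
  df <- data.frame(subject_id = sprintf("T%04d", seq_len(n)),
                   age = sample(20:84, n, replace = TRUE),
                   sex = sample(c("male", "female"), n, replace = TRUE),
                   pct = 0.05, wbc = wbc, neut = counts[, "neut"],
                   lymph = counts[, "lymph"], mono = counts[, "mono"],
                   eo = counts[, "eo"], baso = counts[, "baso"],
                   stringsAsFactors = FALSE)
  for (i in seq_len(ncol(counts))) {
    df[[paste0(colnames(counts)[i], "_pct")]] <- 100 * counts[, i] / wbc
  }
  class(df) <- c("cbc_cohort", "data.frame")
  df
}
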
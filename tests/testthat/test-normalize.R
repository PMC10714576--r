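test_that("log-scale statistics match closed forms and reject degenerate input", {
  panels <- derive_panels(toy_cohort(100))
  # two-point closed form on a hand-built panel matrix
  m <- matrix(rep(c(exp(1), exp(3)), each = 15), nrow = 2, byrow = TRUE,
              dimnames = list(NULL, cbc_index_names()))
  m[1, ] <- exp(1); m[2, ] <- exp(3)
  st <- fit_index_stats(m)
  expect_equal(st$mu, rep(2, 15))
  expect_equal(st$sigma, rep(sqrt(2), 15))
  expect_equal(st$direction, unname(index_direction_map()[st$index]))

  const <- m; const[2, ] <- const[1, ]
  expect_error(fit_index_stats(const), "zero variance")
  expect_error(fit_index_stats(panels[1, , drop = FALSE]), "at least 2")
})

test_that("fitted log-mean recovers the generating parameters of a lognormal sample", {
  set.seed(11)
  v <- exp(rnorm(10000, 1.0, 0.3))
  m <- matrix(rep(v, 15), ncol = 15, dimnames = list(NULL, cbc_index_names()))
  st <- fit_index_stats(m)
  expect_lt(abs(st$mu[1] - 1.0), 0.01)
  expect_lt(abs(st$sigma[1] - 0.3), 0.01)
})

test_that("zero counts are floored at half the smallest positive value before logging", {
  m <- derive_panels(toy_cohort(50))
  m[1:3, "EO"] <- 0
  expect_warning(st <- fit_index_stats(m), "zero value")
  row <- st[st$index == "EO", ]
  expect_equal(row$zero_floor, min(m[-(1:3), "EO"]) / 2)
  Z <- suppressWarnings(normalize_cohort(m, st))
  expect_true(all(Z > 0 & Z < 1))
})

test_that("age-direction diagnostic reports rank correlations without overriding the map", {
  n <- 200
  ages <- seq_len(n) + 19
  panels <- derive_panels(toy_cohort(n))
  panels[, "WBC"] <- ages * 0.01 + 5          # strictly increasing in age
  d <- spearman_age_direction(panels, ages)
  expect_equal(d$rho[d$index == "WBC"], 1.0)
  expect_equal(d$inferred[d$index == "WBC"], "increasing_with_age")
  expect_equal(d$fixed[d$index == "WBC"], "decreasing_with_age")
  expect_false(d$agrees[d$index == "WBC"])
  expect_error(spearman_age_direction(panels, rep(30, n)), "constant")
})

test_that("an age-independent index shows near-zero rank correlation", {
  set.seed(5)
  n <- 2000
  panels <- derive_panels(toy_cohort(n))
  ages <- sample(20:84, n, replace = TRUE)
  d <- spearman_age_direction(panels, ages)
  expect_lt(abs(d$rho[d$index == "WBC"]), 0.06)
})

test_that("three-platform transform evaluates the printed tail formulas", {
  mu <- 1.3; s <- 0.4
  # exact midpoint for either direction
  expect_equal(three_platform(mu, mu, s, "decreasing_with_age"), 0.5)
  expect_equal(three_platform(mu, mu, s, "increasing_with_age"), 0.5)
  # one sd above the mean on the rising branch
  expect_equal(three_platform(mu + s, mu, s, "decreasing_with_age"),
               1 - 0.5 * exp(-1 / 2), tolerance = 1e-12)
  expect_equal(three_platform(mu + s, mu, s, "decreasing_with_age"),
               0.696735, tolerance = 1e-6)
  # two sds below the mean, age-increasing index scores high
  expect_equal(three_platform(mu - 2 * s, mu, s, "increasing_with_age"),
               1 - 0.5 * exp(-2), tolerance = 1e-12)
  expect_equal(three_platform(mu - 2 * s, mu, s, "increasing_with_age"),
               0.932332, tolerance = 1e-6)
  expect_error(three_platform(NaN, mu, s, "decreasing_with_age"), "finite")
  expect_error(three_platform(1, mu, 0, "decreasing_with_age"), "sigma")
})

test_that("the two directional forms are pointwise complements with the platform shape", {
  mu <- 0.7; s <- 0.25
  x <- seq(mu - 8 * s, mu + 8 * s, length.out = 4001)
  up <- three_platform(x, mu, s, "decreasing_with_age")
  dn <- three_platform(x, mu, s, "increasing_with_age")
  expect_equal(dn, 1 - up, tolerance = 1e-12)
  # symmetry around the mean
  d <- seq(0, 5 * s, length.out = 500)
  expect_equal(three_platform(mu + d, mu, s, "decreasing_with_age") +
                 three_platform(mu - d, mu, s, "decreasing_with_age"),
               rep(1, length(d)), tolerance = 1e-12)
  # monotone, continuous at mu, flat in the three platform regions
  expect_true(all(diff(up) >= 0))
  expect_true(all(diff(dn) <= 0))
  eps <- 1e-9
  expect_equal(three_platform(mu - eps, mu, s, "decreasing_with_age"), 0.5,
               tolerance = 1e-6)
  expect_equal(three_platform(mu + eps, mu, s, "decreasing_with_age"), 0.5,
               tolerance = 1e-6)
  slope <- function(x0) {
    (three_platform(x0 + 1e-6, mu, s, "decreasing_with_age") -
       three_platform(x0 - 1e-6, mu, s, "decreasing_with_age")) / 2e-6
  }
  expect_lt(abs(slope(mu)), 1e-4)
  expect_lt(abs(slope(mu + 7 * s)), 1e-6)
  expect_lt(abs(slope(mu - 7 * s)), 1e-6)
})

test_that("cohort normalization maps panels into (0,1) with 0.5 at the fitted mean", {
  panels <- derive_panels(toy_cohort(300, seed = 2))
  st <- fit_index_stats(panels)
  Z <- normalize_cohort(panels, st)
  expect_true(all(Z > 0 & Z < 1))
  at_mean <- matrix(exp(st$mu), nrow = 1,
                    dimnames = list(NULL, st$index))
  expect_equal(unname(normalize_cohort(at_mean, st)[1, ]), rep(0.5, 15))
  empty <- normalize_cohort(panels[0, , drop = FALSE], st)
  expect_equal(dim(empty), c(0L, 15L))
  expect_error(normalize_cohort(panels[, 1:10], st), "missing from panels")
})

test_that("index statistics survive a YAML round trip", {
  st <- fit_index_stats(derive_panels(toy_cohort(100)))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_index_stats(st, f)
  st2 <- read_index_stats(f)
  expect_equal(st2$mu, st$mu)
  expect_equal(st2$sigma, st$sigma)
  expect_equal(st2$direction, st$direction)
  Z1 <- normalize_cohort(derive_panels(toy_cohort(20, seed = 9)), st)
  Z2 <- normalize_cohort(derive_panels(toy_cohort(20, seed = 9)), st2)
  expect_equal(Z1, Z2)
})
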
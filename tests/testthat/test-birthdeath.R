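test_that("beta matches its closed forms and limits", {
  # pure-birth: beta = 1 - exp(-r t)
  expect_equal(bd_beta(0.1, 0, 10), 1 - exp(-1), tolerance = 1e-15)
  for (r in c(0.001, 0.05, 0.2)) {
    for (t in c(1, 50, 150)) {
      expect_equal(bd_beta(r, 0, t), 1 - exp(-r * t), tolerance = 1e-12)
    }
  }
  # with extinction: direct evaluation of (e^{rt} - 1)/(e^{rt} - eps)
  expect_equal(bd_beta(0.1, 0.5, 10), (exp(1) - 1) / (exp(1) - 0.5),
               tolerance = 1e-12)
  # beta -> 0 as t -> 0+, -> 1 as t -> Inf
  expect_lt(bd_beta(0.1, 0.5, 1e-8), 1e-6)
  expect_gt(bd_beta(0.1, 0.5, 1e4), 1 - 1e-6)
  # monotone increasing in eps at fixed (r, t)
  b <- bd_beta(0.1, seq(0, 0.95, by = 0.05), 10)
  expect_true(all(diff(b) > 0))
  # domain errors
  expect_error(bd_beta(0.1, 0, -1), "positive")
  expect_error(bd_beta(0.1, 1, 10), "eps")
  # alpha is the extinction-weighted companion
  expect_equal(bd_alpha(0.1, 0.5, 10), 0.5 * bd_beta(0.1, 0.5, 10))
})

test_that("parameter container enforces rate constraints", {
  p <- bd_params(0.05, 0.5)
  expect_equal(p$mu, 0.45)
  expect_equal(p$eps, 0.9)
  expect_error(bd_params(0.05, 0.04), "lam")
  expect_error(bd_params(0.05, -1), "positive")
})

test_that("log-likelihood equals the geometric mass in log space", {
  # n = 1: contribution is log(1 - beta)
  p <- bd_params(0.1, 0.5)
  b <- bd_beta(p$r, p$eps, 30)
  expect_equal(bd_loglik(p, 1, 30), log(1 - b))
  # beta = 0.5 at eps = 0, t = log(2)/r: clade of 4 gives 4 log(1/2)
  p0 <- bd_params(0.1, 0.1)
  t_half <- log(2) / 0.1
  expect_equal(bd_beta(p0$r, p0$eps, t_half), 0.5, tolerance = 1e-12)
  expect_equal(bd_loglik(p0, 4, t_half), 4 * log(0.5), tolerance = 1e-12)
  # additivity over clades
  set.seed(3)
  n <- sample(1:50, 6, replace = TRUE)
  t <- runif(6, 5, 100)
  parts <- vapply(1:6, function(i) bd_loglik(p, n[i], t[i]), numeric(1))
  expect_equal(bd_loglik(p, n, t), sum(parts), tolerance = 1e-12)
  # degenerate beta underflow with n > 1 yields -Inf, not an error
  expect_identical(bd_loglik(list(r = 1e-320, eps = 0), 5, 1), -Inf)
})

test_that("geometric clade-size mass normalizes to one", {
  for (b in c(0.2, 0.5, 0.9, 0.999)) {
    n_max <- ceiling(log(1e-14) / log(b))
    mass <- (1 - b) * b^(seq_len(n_max) - 1)
    expect_equal(sum(mass), 1, tolerance = 1e-12)
  }
})

test_that("compiled grid evaluation matches the naive per-point loop", {
  set.seed(42)
  g <- grid_spec(r_min = 0.005, r_max = 0.1, r_step = 0.005,
                 lam_min = 0.1, lam_max = 5, lam_step = 0.25)
  for (rep in 1:5) {
    t <- runif(12, 5, 120)
    # shared ages on purpose: exercises the aggregation path
    t[1:3] <- t[4]
    b <- bd_beta(0.04, 0.8, t)
    n <- pmax(1, ceiling(log1p(-runif(12)) / log(b)))
    fit <- grid_mle(n, t, grid = g)
    oracle <- brute_mle(n, t, g)
    expect_equal(fit$params_hat$r, oracle$r)
    expect_equal(fit$params_hat$lam, oracle$lam)
    expect_equal(fit$loglik_max, oracle$ll, tolerance = 1e-9)
  }
})

test_that("a single monotypic clade drives r to the grid minimum", {
  g <- grid_spec(r_max = 0.05, r_step = 0.005, lam_max = 5, lam_step = 0.5)
  fit <- grid_mle(1, 50, grid = g)
  # likelihood log(1 - beta) decreases in beta, so the smallest beta wins
  expect_equal(fit$params_hat$r, g$r_min)
  oracle <- brute_mle(1, 50, g)
  expect_equal(fit$params_hat$r, oracle$r)
  expect_equal(fit$params_hat$lam, oracle$lam)
})

test_that("profile region and confidence bounds behave by construction", {
  set.seed(7)
  t <- runif(80, 10, 120)
  b <- bd_beta(0.05, 0.9, t)
  n <- pmax(1, ceiling(log1p(-runif(80)) / log(b)))
  g <- grid_spec(r_step = 1e-3, lam_max = 10, lam_step = 0.05)
  fit <- grid_mle(n, t, grid = g)
  ci <- fit$profile_ci
  p <- fit$params_hat
  expect_true(ci$lower[ci$param == "r"] <= p$r && p$r <= ci$upper[ci$param == "r"])
  expect_true(ci$lower[ci$param == "lam"] <= p$lam && p$lam <= ci$upper[ci$param == "lam"])
  expect_true(ci$lower[ci$param == "mu"] <= p$mu && p$mu <= ci$upper[ci$param == "mu"])
  expect_true(all(fit$profile$loglik >= fit$loglik_max - fit$keep_delta))
  # keep_delta = 0 collapses the region to the MLE: zero-width intervals
  fit0 <- grid_mle(n, t, grid = g, keep_delta = 0)
  expect_equal(fit0$profile_ci$lower, fit0$profile_ci$upper)
  # more data shrinks the interval (same generating process)
  set.seed(7)
  t2 <- runif(800, 10, 120)
  b2 <- bd_beta(0.05, 0.9, t2)
  n2 <- pmax(1, ceiling(log1p(-runif(800)) / log(b2)))
  fit2 <- grid_mle(n2, t2, grid = g)
  width <- function(f) diff(unlist(f$profile_ci[f$profile_ci$param == "r", c("lower", "upper")]))
  expect_lt(width(fit2), width(fit))
})

test_that("clade-size bounds follow the printed tail formulas", {
  b05 <- clade_size_bounds(beta = 0.5)
  expect_equal(b05$k_upper, log(0.025) / log(0.5) + 1, tolerance = 1e-12)
  expect_equal(b05$k_lower, log(0.975) / log(0.5) + 1, tolerance = 1e-12)
  # frozen direct evaluations
  expect_equal(b05$k_upper, 6.321928, tolerance = 1e-6)
  expect_equal(b05$k_lower, 1.036526, tolerance = 1e-6)
  # monotone increasing in beta, k_lower <= k_upper, degenerate beta = 0
  bs <- clade_size_bounds(beta = c(0, 0.2, 0.5, 0.9, 0.99))
  expect_true(all(diff(bs$k_upper) > 0))
  expect_true(all(bs$k_lower <= bs$k_upper))
  expect_equal(unlist(bs[1, ]), c(k_lower = 1, k_upper = 1))
  expect_error(clade_size_bounds(beta = 1), "beta")
  # via parameters
  p <- bd_params(0.1, 0.1)
  expect_equal(clade_size_bounds(p, log(2) / 0.1)$k_upper, 6.321928,
               tolerance = 1e-6)
})

test_that("fit serialization round-trips the headline numbers", {
  set.seed(9)
  t <- runif(30, 10, 100)
  n <- pmax(1, ceiling(log1p(-runif(30)) / log(bd_beta(0.05, 0.5, t))))
  fit <- grid_mle(n, t, grid = grid_spec(r_step = 2e-3, lam_max = 5, lam_step = 0.25))
  tf <- tempfile(fileext = ".tsv")
  fit_table(list(demo = fit), tf)
  back <- read.delim(tf)
  expect_equal(back$r_hat, fit$params_hat$r)
  expect_equal(back$loglik, fit$loglik_max)
  expect_equal(back$n_clades, 30L)
})
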
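# Independent brute-force oracles used to cross-check the fast paths.

# naive grid maximization: loops every (r, lam) point and calls the scalar
# log-likelihood; returns the argmax with ties toward smallest r then lam
brute_mle <- function(n, t, grid) {
  ax <- list(
    r = seq(grid$r_min, grid$r_max, by = grid$r_step),
    lam = seq(grid$lam_min, grid$lam_max, by = grid$lam_step)
  )
  best <- list(ll = -Inf, r = NA, lam = NA)
  for (r in ax$r) {
    for (lam in ax$lam) {
      if (lam < r) next
      ll <- bd_loglik(list(r = r, eps = (lam - r) / lam), n, t)
      if (ll > best$ll) best <- list(ll = ll, r = r, lam = lam)
    }
  }
  best
}

# textbook chi-squared and Haberman adjusted residuals, written as the
# explicit O/E double loop
haberman_brute <- function(obs) {
  N <- sum(obs)
  rs <- rowSums(obs)
  cs <- colSums(obs)
  E <- outer(rs, cs) / N
  chi2 <- 0
  adj <- matrix(0, nrow(obs), ncol(obs))
  for (i in seq_len(nrow(obs))) {
    for (j in seq_len(ncol(obs))) {
      chi2 <- chi2 + (obs[i, j] - E[i, j])^2 / E[i, j]
      adj[i, j] <- (obs[i, j] - E[i, j]) /
        sqrt(E[i, j] * (1 - rs[i] / N) * (1 - cs[j] / N))
    }
  }
  list(chi2 = chi2, expected = E, adj = adj)
}

# minimal hand-built fit object with a known profile region, for
# classification tests that need fixed bounds
fixture_fit <- function(r, lam) {
  profile <- data.frame(r = r, lam = lam)
  profile$mu <- profile$lam - profile$r
  profile$eps <- profile$mu / profile$lam
  structure(
    list(params_hat = bd_params(r[1], lam[1]), loglik_max = 0,
         profile = profile, grid = grid_spec(), keep_delta = 1,
         n_clades = 0L),
    class = "bd_fit"
  )
}
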
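# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately naive (dense inverses, exhaustive scans,
# hand-rolled formulas) and independent of the implementation paths
# they check.

make_aging <- function(n = 60, p = 40, k = 10, noise = 0.03, seed = 1, ...) {
  simulate_aging_methylation(
    simulation_config(n, p, k, noise_sd = noise, seed = seed, ...)
  )
}

tiny_dataset <- function() {
  beta <- matrix(c(0.1, 0.9, 0.4, 0.6), 2, 2,
                 dimnames = list(c("s1", "s2"), c("cg1", "cg2")))
  methylation_dataset(beta, age = c(30, 60))
}

# Empirical-CDF scan oracle for the two-sample KS statistic.
ks_D_oracle <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  max(abs(vapply(grid, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
}

# Step-up BH from its definition: sort ascending, p_(i) * m / i, running
# minimum from the top, map back.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Dense-inverse GP posterior (explicit solve, no Cholesky reuse).
gp_posterior_oracle <- function(X, y_centered, Xnew, params) {
  K <- params$s2 * exp(-as.matrix(stats::dist(rbind(X, Xnew)))^2 /
                         (2 * params$l^2))
  n <- nrow(X)
  m <- nrow(Xnew)
  Ktr <- K[seq_len(n), seq_len(n), drop = FALSE]
  kst <- K[seq_len(n), n + seq_len(m), drop = FALSE]
  Kinv <- solve(Ktr + diag(params$sigma2, n))
  list(mu = as.vector(crossprod(kst, Kinv %*% y_centered)),
       var = unname(params$s2 - diag(crossprod(kst, Kinv %*% kst))))
}

# Exhaustive two-sided Mann-Whitney p-value by enumerating all
# assignments of the pooled ranks to group A.
mww_exact_oracle <- function(a, b) {
  na <- length(a)
  pooled <- c(a, b)
  u_of <- function(idx) {
    ra <- rank(pooled)[idx]
    sum(ra) - na * (na + 1) / 2
  }
  u_obs <- u_of(seq_len(na))
  all_u <- apply(utils::combn(length(pooled), na), 2, u_of)
  mu <- na * length(b) / 2
  mean(abs(all_u - mu) >= abs(u_obs - mu))
}
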
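# Brute-force grid/quadrature posterior for the 2-binary-indicator,
# one-factor ordinal-probit model.  Independent of the Gibbs sampler: the
# marginal likelihood of each response pattern is computed by numerical
# integration over the factor, and posterior means of (lambda1, lambda2,
# tau1, tau2) by summation over a 4-dimensional parameter grid, restricted
# to the orientation sum(lambda) > 0 (matching the sampler's sign
# resolution).
grid_oracle_2bin <- function(y, prior_var = 25, grid = seq(-6, 6, by = 0.2),
                             nodes = seq(-8, 8, by = 0.1)) {
  stopifnot(ncol(y) == 2, all(y %in% 0:1))
  w <- stats::dnorm(nodes) * (nodes[2] - nodes[1])
  # pattern counts
  n11 <- sum(y[, 1] == 1 & y[, 2] == 1)
  n10 <- sum(y[, 1] == 1 & y[, 2] == 0)
  n01 <- sum(y[, 1] == 0 & y[, 2] == 1)
  n00 <- sum(y[, 1] == 0 & y[, 2] == 0)

  # (lambda, tau) pairs for one indicator: G x G combinations
  G <- length(grid)
  lam <- rep(grid, times = G)   # varies fastest
  tau <- rep(grid, each = G)
  # P(y_j = 1 | eta_k) for every (lambda, tau) pair: (G^2) x K
  A <- stats::pnorm(outer(lam, nodes) - tau)
  Aw <- sweep(A, 2, w, `*`)
  P11 <- Aw %*% t(A)            # rows: indicator 1 pair, cols: indicator 2 pair
  P1dot <- rowSums(Aw)          # marginal P(y_j = 1)
  P10 <- matrix(P1dot, G^2, G^2) - P11
  P01 <- matrix(P1dot, G^2, G^2, byrow = TRUE) - P11
  P00 <- 1 - P11 - P10 - P01
  eps <- 1e-300
  logpost <- n11 * log(pmax(P11, eps)) + n10 * log(pmax(P10, eps)) +
    n01 * log(pmax(P01, eps)) + n00 * log(pmax(P00, eps))
  lp_prior <- stats::dnorm(lam, 0, sqrt(prior_var), log = TRUE) +
    stats::dnorm(tau, 0, sqrt(prior_var), log = TRUE)
  logpost <- logpost + lp_prior                 # indicator-1 prior (rows)
  logpost <- sweep(logpost, 2, lp_prior, `+`)   # indicator-2 prior (cols)
  # sign restriction: lambda1 + lambda2 > 0
  mask <- outer(lam, lam, `+`) > 0
  logpost[!mask] <- -Inf
  wpost <- exp(logpost - max(logpost))
  Z <- sum(wpost)
  list(lambda1 = sum(wpost * lam) / Z,
       lambda2 = sum(sweep(wpost, 2, lam, `*`)) / Z,
       tau1 = sum(wpost * tau) / Z,
       tau2 = sum(sweep(wpost, 2, tau, `*`)) / Z)
}
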
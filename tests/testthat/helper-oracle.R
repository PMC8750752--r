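# Independent oracles: per-record density loop, deterministic grid
# quadrature for small cells, and the thresholded-bivariate-normal phi
# coefficient.

# Plain per-record loop; deliberately avoids the package's vectorized path.
naive_cell_lp <- function(mu, sigma2, y, X, mu_sd = 20, logvar_sd = 10) {
  lp <- 0
  for (i in seq_along(y)) {
    m <- 0; v <- 0
    for (d in seq_along(mu)) {
      if (X[i, d] == 1) { m <- m + mu[d]; v <- v + sigma2[d] }
    }
    lp <- lp - 0.5 * log(2 * pi * v) - (y[i] - m)^2 / (2 * v)
  }
  for (d in seq_along(mu)) {
    lp <- lp - 0.5 * log(2 * pi * mu_sd^2) - mu[d]^2 / (2 * mu_sd^2)
    th <- log(sigma2[d])
    # LogNormal(0, logvar_sd^2) density on the variance scale
    lp <- lp - log(sigma2[d]) - 0.5 * log(2 * pi * logvar_sd^2) -
      th^2 / (2 * logvar_sd^2)
  }
  lp
}

# Posterior mean of each mu by brute-force quadrature over
# (mu_1..mu_D, theta_1..theta_D), theta = log sigma^2 gridded uniformly
# (the Jacobian e^theta is included). mu_range / theta_range are D-row
# matrices of (lo, hi).
grid_posterior_mean <- function(y, X, mu_range, theta_range, n_grid = 23) {
  D <- ncol(X)
  axes <- c(lapply(seq_len(D), function(d)
              seq(mu_range[d, 1], mu_range[d, 2], length.out = n_grid)),
            lapply(seq_len(D), function(d)
              seq(theta_range[d, 1], theta_range[d, 2],
                  length.out = n_grid)))
  grid <- as.matrix(expand.grid(axes))
  lp <- apply(grid, 1, function(par) {
    mu <- par[seq_len(D)]
    th <- par[D + seq_len(D)]
    naive_cell_lp(mu, exp(th), y, X) + sum(th)
  })
  w <- exp(lp - max(lp))
  colSums(grid[, seq_len(D), drop = FALSE] * w) / sum(w)
}

# phi coefficient of two Bernoulli indicators thresholded from a bivariate
# Normal with latent correlation rho.
phi_from_latent_rho <- function(rho, p1, p2) {
  z1 <- qnorm(p1); z2 <- qnorm(p2)
  f <- function(u) dnorm(u) * pnorm((z2 - rho * u) / sqrt(1 - rho^2))
  P11 <- integrate(f, -8, z1, rel.tol = 1e-10)$value
  (P11 - p1 * p2) / sqrt(p1 * (1 - p1) * p2 * (1 - p2))
}
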
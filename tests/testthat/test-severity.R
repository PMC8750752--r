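test_that("the cell log posterior matches closed forms and a naive loop", {
  prior <- hce_prior()
  # single record, single disease, zero residual
  lp <- cell_log_posterior(3, 1.5, y = 3, indicators = matrix(1, 1, 1),
                           prior)
  expect_equal(lp,
               -0.5 * log(2 * pi * 1.5) +
                 dnorm(3, 0, 20, log = TRUE) +
                 dlnorm(1.5, 0, 10, log = TRUE))

  # two active diseases: mean and variance add
  lp2 <- cell_log_posterior(c(2, 5), c(1, 1), y = 7,
                            indicators = matrix(1, 1, 2), prior)
  expect_equal(lp2,
               -0.5 * log(2 * pi * 2) +
                 sum(dnorm(c(2, 5), 0, 20, log = TRUE)) +
                 sum(dlnorm(c(1, 1), 0, 10, log = TRUE)))

  # arbitrary instance vs the per-record loop oracle
  set.seed(4)
  X <- matrix(rbinom(40 * 3, 1, 0.5), 40, 3)
  X[rowSums(X) == 0, 1] <- 1L
  y <- rnorm(40, 3, 1)
  mu <- c(1.2, 0.4, 2.5); s2 <- c(0.8, 1.3, 0.5)
  expect_equal(cell_log_posterior(mu, s2, y, X),
               naive_cell_lp(mu, s2, y, X))

  expect_error(cell_log_posterior(1, 1, y = c(1, 2),
                                  indicators = rbind(1, 0)),
               "excluded")
  expect_error(cell_log_posterior(1, -1, y = 1,
                                  indicators = matrix(1)),
               "positive")
})

test_that("the compiled likelihood agrees with the R density (up to the log-variance Jacobian)", {
  set.seed(5)
  X <- matrix(rbinom(30 * 2, 1, 0.6), 30, 2)
  X[rowSums(X) == 0, 2] <- 1L
  y <- rnorm(30, 4, 1.5)
  mu <- c(2, 1); s2 <- c(1.1, 0.7)
  ps <- hcedecomp:::pattern_stats(y, X)
  lp_cpp <- hcedecomp:::.cpp_cell_lp(ps$X, as.numeric(ps$n), ps$S, ps$SS,
                                     mu, log(s2), 20, 10)
  lp_r <- cell_log_posterior(mu, s2, y, X)
  expect_equal(lp_cpp, lp_r + sum(log(s2)))
})

test_that("split-chain R-hat behaves at its limits and under iid sampling", {
  expect_warning(r <- rhat(matrix(2, 100, 4)), "constant")
  expect_equal(r, 1.0)
  expect_warning(r2 <- rhat(cbind(rep(0, 100), rep(10, 100))), "differing")
  expect_equal(r2, Inf)

  set.seed(6)
  expect_lt(rhat(matrix(rnorm(4 * 4000), 4000, 4)), 1.01)
  expect_gt(rhat(cbind(rnorm(2000, 0), rnorm(2000, 10))), 2)
  expect_error(rhat(matrix(1, 10, 1)), "2 chains")
})

test_that("a single-disease cell recovers the sample mean at large n", {
  set.seed(7)
  y <- rnorm(2000, 3, 1)
  cell <- fit_cell(y, matrix(1, 2000, 1), seed = 8)
  expect_equal(cell$n_draws, 16000)  # 4 chains x 4000 retained
  expect_true(cell$converged)
  ci99 <- mean(y) + c(-1, 1) * qnorm(0.995) * sd(y) / sqrt(2000)
  expect_gt(cell$mu$mean, ci99[1])
  expect_lt(cell$mu$mean, ci99[2])
  # posterior summaries are consistent with the stored draws
  expect_equal(cell$mu$mean, mean(cell$mu_draws[, 1]))
  expect_equal(unname(cell$mu$q2.5),
               unname(quantile(cell$mu_draws[, 1], 0.025)))
})

test_that("cell fits are reproducible and drop indicator-free records", {
  set.seed(9)
  X <- rbind(matrix(rbinom(200 * 2, 1, 0.5), 200, 2), matrix(0, 5, 2))
  X[rowSums(X) == 0 & seq_len(205) <= 200, 1] <- 1L
  y <- c(rnorm(200, 2, 0.5), rep(0, 5))
  y[rowSums(X) == 0] <- 0
  m <- fast_mcmc()
  c1 <- fit_cell(y, X, mcmc = m, seed = 99)
  c2 <- fit_cell(y, X, mcmc = m, seed = 99)
  expect_identical(c1$mu, c2$mu)
  expect_identical(c1$sigma2, c2$sigma2)
  expect_equal(c1$n_dropped, sum(rowSums(X) == 0))
  expect_equal(c1$n_obs, 205 - c1$n_dropped)
})

test_that("never-observed diseases get no parameter and collinear designs are flagged", {
  set.seed(10)
  X5 <- matrix(0L, 100, 5)
  X5[, 1] <- 1L
  X5[1:40, 3] <- 1L
  y <- rnorm(100, 2, 0.5) + ifelse(X5[, 3] == 1, rnorm(100, 3, 0.5), 0)
  cell <- fit_cell(y, X5, mcmc = fast_mcmc(), seed = 1)
  expect_setequal(cell$diseases, c("circulatory", "neoplasms"))
  expect_setequal(cell$absent, c("ckd", "respiratory", "others"))
  expect_false(cell$rank_deficient)

  # two diseases that only ever co-occur
  Xc <- matrix(1L, 60, 2)
  expect_warning(cellc <- fit_cell(rnorm(60, 5, 1), Xc,
                                   mcmc = fast_mcmc(), seed = 2),
                 "rank deficient")
  expect_true(cellc$rank_deficient)
  # the prior still yields finite, regularized posteriors
  expect_true(all(is.finite(cellc$mu$mean)))
})

test_that("two-disease cells recover their true component means", {
  set.seed(11)
  n <- 900
  X <- rbind(cbind(rep(1, n / 3), 0), cbind(0, rep(1, n / 3)),
             cbind(rep(1, n / 3), rep(1, n / 3)))
  mu_true <- c(1.5, 4)
  y <- as.vector(X %*% mu_true) +
    rnorm(n, 0, sqrt(as.vector(X %*% (mu_true / 3)^2)))
  cell <- fit_cell(y, X, seed = 12)
  expect_true(cell$converged)
  expect_true(all(abs(cell$mu$mean - mu_true) <= 3 * cell$mu$sd))
})

test_that("whole-panel fits cover every nonempty cell deterministically", {
  panel <- filter_decedents(small_sim(150, seed = 41)$panel)
  m <- fast_mcmc()
  fit <- hce_fit(panel, "none", mcmc = m, seed = 5)
  expect_equal(length(fit$cells) + length(fit$skipped), 24)
  expect_named(fit$cells, paste0("all:", 0:23), ignore.order = TRUE)
  fit2 <- hce_fit(panel, "none", mcmc = m, seed = 5)
  expect_identical(coef(fit), coef(fit2))
  co <- coef(fit)
  expect_true(all(co$n_obs > 0))
  # posterior means non-negative on realistic synthetic defaults
  expect_true(all(co$mu_mean > -0.5))
})
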
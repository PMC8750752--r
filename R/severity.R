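#' Prior specification for the severity model
#'
#' Weakly informative priors shared across all (stratum, month, disease)
#' cells: component means mu ~ Normal(0, 20^2) in 100k-JPY units, component
#' variances sigma^2 ~ LogNormal(0, 10^2) (chosen so the variance cannot be
#' negative).
#'
#' @param mu_mean,mu_sd Normal prior on each component mean.
#' @param logvar_mean,logvar_sd LogNormal prior on each component variance
#'   (location and scale on the log-variance scale).
#' @return An object of class `hce_prior`.
#' @export
hce_prior <- function(mu_mean = 0, mu_sd = 20,
                      logvar_mean = 0, logvar_sd = 10) {
  stopifnot(mu_sd > 0, logvar_sd > 0)
  structure(list(mu_mean = mu_mean, mu_sd = mu_sd,
                 logvar_mean = logvar_mean, logvar_sd = logvar_sd),
            class = "hce_prior")
}

#' MCMC settings for the severity model
#'
#' Defaults follow the study protocol: 4 chains of 6000 iterations each,
#' the first 2000 discarded as warm-up, convergence declared when the
#' split-chain R-hat of every parameter and of the log posterior is at most
#' 1.05.
#'
#' @param chains Number of chains (>= 2; R-hat needs several).
#' @param iter Iterations per chain.
#' @param warmup Warm-up iterations discarded (and used for adaptation).
#' @param rhat_threshold Convergence threshold on R-hat.
#' @return An object of class `hce_mcmc`.
#' @export
hce_mcmc <- function(chains = 4, iter = 6000, warmup = 2000,
                     rhat_threshold = 1.05) {
  stopifnot(chains >= 2, warmup >= 1, iter > warmup, rhat_threshold > 1)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup),
                 rhat_threshold = rhat_threshold),
            class = "hce_mcmc")
}

#' Log posterior density of one severity-model cell
#'
#' The observed monthly total of a record is the sum of the latent
#' components of its active disease groups; because independent Normal
#' components sum to a Normal, the latent components integrate out
#' analytically and each record contributes a Normal density with mean
#' `sum(active mu)` and variance `sum(active sigma2)`. Priors (on the
#' sigma^2 scale) are added.
#'
#' @param mu,sigma2 Numeric vectors of component means and variances, one
#'   per modelled disease group.
#' @param y Numeric vector of observed monthly totals.
#' @param indicators 0/1 matrix (records x diseases); every row must have at
#'   least one active indicator.
#' @param prior An [hce_prior()].
#' @return The log posterior density (a single finite number).
#' @export
cell_log_posterior <- function(mu, sigma2, y, indicators,
                               prior = hce_prior()) {
  X <- as.matrix(indicators)
  stopifnot(length(mu) == ncol(X), length(sigma2) == ncol(X),
            length(y) == nrow(X))
  if (any(sigma2 <= 0)) stop("sigma2 must be positive")
  if (any(rowSums(X) == 0))
    stop("records with all indicators 0 must be excluded")
  mean_i <- as.vector(X %*% mu)
  var_i <- as.vector(X %*% sigma2)
  lp <- sum(stats::dnorm(y, mean_i, sqrt(var_i), log = TRUE)) +
    sum(stats::dnorm(mu, prior$mu_mean, prior$mu_sd, log = TRUE)) +
    sum(stats::dlnorm(sigma2, prior$logvar_mean, prior$logvar_sd,
                      log = TRUE))
  if (!is.finite(lp)) stop("non-finite log posterior")
  lp
}

#' Split-chain potential scale reduction factor (R-hat)
#'
#' The plain (not rank-normalized) split-chain R-hat: each chain is split
#' in half, and R-hat is computed from the between- and within-sequence
#' variances of the resulting 2C sequences.
#'
#' @param draws Matrix of draws, iterations x chains (>= 2 chains, >= 2
#'   draws each).
#' @return A single number >= 1 (up to floating point); 1.0 with a warning
#'   when all sequences are constant and equal, Inf with a warning when
#'   sequences are constant but unequal.
#' @export
rhat <- function(draws) {
  draws <- as.matrix(draws)
  if (ncol(draws) < 2) stop("R-hat requires at least 2 chains")
  if (nrow(draws) < 4) stop("R-hat requires at least 4 draws per chain")
  n2 <- nrow(draws) %/% 2L
  halves <- cbind(draws[seq_len(n2), , drop = FALSE],
                  draws[seq_len(n2) + n2, , drop = FALSE])
  W <- mean(apply(halves, 2, stats::var))
  B <- n2 * stats::var(colMeans(halves))
  if (W == 0) {
    if (B == 0) {
      warning("all chains constant and identical; R-hat defined as 1")
      return(1.0)
    }
    warning("zero within-chain variance with differing chains")
    return(Inf)
  }
  sqrt(((n2 - 1) / n2 * W + B / n2) / W)
}

# Collapse records to indicator patterns with sufficient statistics
# (n, sum y, sum y^2 per pattern). The cell likelihood depends on the data
# only through these.
pattern_stats <- function(y, X) {
  key <- apply(X, 1, paste, collapse = "")
  idx <- split(seq_along(y), key)
  pat <- do.call(rbind, lapply(names(idx), function(k)
    as.integer(strsplit(k, "")[[1]])))
  list(X = pat,
       n = vapply(idx, length, 0L),
       S = vapply(idx, function(i) sum(y[i]), 0),
       SS = vapply(idx, function(i) sum(y[i]^2), 0))
}

#' Fit the severity model in one (stratum, month) cell
#'
#' Estimates the posterior of the per-disease component means and variances
#' from the observed monthly totals and occurrence indicators of one cell,
#' by adaptive Metropolis-within-Gibbs over (mu, log sigma^2). Records with
#' no active indicator are excluded (and counted); disease groups never
#' observed in the cell get no parameter. Chains start from overdispersed
#' jitters around a ridge least-squares solution on the pattern means.
#'
#' @param y Numeric vector of observed monthly totals (100k JPY).
#' @param indicators 0/1 matrix or data.frame, records x 5 disease groups
#'   (columns named as [disease_groups()] or [indicator_columns()]).
#' @param prior An [hce_prior()].
#' @param mcmc An [hce_mcmc()].
#' @param seed Optional RNG seed for reproducibility.
#' @return Object of class `hce_cell`: posterior summaries (`mu`,
#'   `sigma2`), retained draws, per-parameter and log-posterior R-hat,
#'   `converged` flag, `n_obs`, dropped-record and design-rank notes.
#' @export
fit_cell <- function(y, indicators, prior = hce_prior(),
                     mcmc = hce_mcmc(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- as.matrix(indicators)
  if (is.null(colnames(X))) colnames(X) <- disease_groups()[seq_len(ncol(X))]
  colnames(X) <- sub("^ind_", "", colnames(X))
  storage.mode(X) <- "integer"

  drop0 <- rowSums(X) == 0
  n_dropped <- sum(drop0)
  y <- y[!drop0]
  X <- X[!drop0, , drop = FALSE]
  if (!length(y)) stop("cell has no record with an active indicator")

  active <- colSums(X) > 0
  absent <- colnames(X)[!active]
  X <- X[, active, drop = FALSE]
  D <- ncol(X)
  dis <- colnames(X)

  ps <- pattern_stats(y, X)
  rank_deficient <- qr(ps$X)$rank < D
  if (rank_deficient)
    warning("indicator design is rank deficient; posterior means in this ",
            "cell depend materially on the prior")

  # Ridge LS on pattern means for chain initialization.
  W <- diag(ps$n, nrow = length(ps$n))
  ybar <- ps$S / ps$n
  A <- crossprod(ps$X, W %*% ps$X) + diag(1e-3, D)
  mu0 <- as.vector(solve(A, crossprod(ps$X, W %*% ybar)))
  fitted <- as.vector(ps$X %*% mu0)
  resid_var <- max(sum(ps$SS - 2 * fitted * ps$S + ps$n * fitted^2) /
                     sum(ps$n), 1e-4)
  theta0 <- rep(log(resid_var / mean(rowSums(ps$X))), D)

  n_par <- 2L * D
  mu_init <- matrix(mu0, D, mcmc$chains) +
    matrix(stats::rnorm(D * mcmc$chains, 0, pmax(abs(mu0) * 0.25, 0.25)),
           D, mcmc$chains)
  theta_init <- matrix(theta0, D, mcmc$chains) +
    matrix(stats::rnorm(D * mcmc$chains, 0, 0.5), D, mcmc$chains)
  scale_init <- c(pmax(sqrt(resid_var / colSums(ps$X * ps$n)), 1e-3),
                  pmin(pmax(2 / sqrt(colSums(ps$X * ps$n)), 1e-3), 1))

  draws <- .cpp_mwg_sample(ps$X, as.numeric(ps$n), ps$S, ps$SS,
                           prior$mu_sd, prior$logvar_sd,
                           mu_init, theta_init, scale_init,
                           mcmc$iter, mcmc$warmup)
  kept <- dim(draws)[1]
  par_names <- c(paste0("mu_", dis), paste0("theta_", dis))

  rhats <- vapply(seq_len(n_par + 1L), function(j) rhat(draws[, j, ]), 0)
  names(rhats) <- c(par_names, "lp__")

  flat <- do.call(rbind, lapply(seq_len(mcmc$chains),
                                function(c) draws[, , c]))
  mu_draws <- flat[, seq_len(D), drop = FALSE]
  sig2_draws <- exp(flat[, D + seq_len(D), drop = FALSE])
  colnames(mu_draws) <- colnames(sig2_draws) <- dis

  summarize <- function(m) data.frame(
    disease = dis,
    mean = colMeans(m),
    sd = apply(m, 2, stats::sd),
    q2.5 = apply(m, 2, stats::quantile, 0.025),
    q97.5 = apply(m, 2, stats::quantile, 0.975),
    row.names = NULL)

  mu_sum <- summarize(mu_draws)
  mu_sum$rhat <- rhats[seq_len(D)]
  sig_sum <- summarize(sig2_draws)
  sig_sum$rhat <- rhats[D + seq_len(D)]

  structure(
    list(diseases = dis, absent = absent,
         mu = mu_sum, sigma2 = sig_sum,
         mu_draws = mu_draws, sigma2_draws = sig2_draws,
         lp_draws = flat[, n_par + 1L],
         rhat = rhats,
         converged = max(rhats) <= mcmc$rhat_threshold,
         rank_deficient = rank_deficient,
         n_obs = length(y), n_dropped = n_dropped,
         n_draws = kept * mcmc$chains,
         prior = prior, mcmc = mcmc),
    class = "hce_cell")
}

#' @export
print.hce_cell <- function(x, ...) {
  cat("Severity-model cell fit:", x$n_obs, "records,",
      length(x$diseases), "disease groups,", x$n_draws, "draws\n")
  cat(sprintf("max R-hat %.4f (%s)\n", max(x$rhat),
              if (x$converged) "converged" else "NOT converged"))
  print(cbind(x$mu[, c("disease", "mean", "sd", "q2.5", "q97.5")],
              rhat = round(x$mu$rhat, 4)), row.names = FALSE)
  invisible(x)
}

#' Fit the two-part expenditure model over a whole panel
#'
#' The main modelling entry point. Computes the frequency table for the
#' chosen stratification and fits the Bayesian severity decomposition
#' independently in every (stratum, month-before-death) cell (parameters
#' are not pooled across cells, so per-cell fitting is mathematically
#' identical to a joint fit). Cell fits are seeded deterministically from
#' `seed` and are independent of execution order.
#'
#' @param panel A filtered `hce_panel`.
#' @param scheme Stratification scheme, see [stratify()].
#' @param prior An [hce_prior()].
#' @param mcmc An [hce_mcmc()].
#' @param seed Integer seed governing all cell fits.
#' @param ttd Months before death to fit (default 0:23).
#' @param verbose Print per-cell progress.
#' @return Object of class `hce_fit` with elements `cells` (named
#'   `"stratum:ttd"` list of [fit_cell()] results), `frequency`,
#'   `scheme`, `n_g`, `skipped`, `converged`, and the call's settings.
#' @seealso [coef.hce_fit()], [predict.hce_fit()], [residuals.hce_fit()],
#'   [compute_ahce()], [reconstruction_report()]
#' @export
hce_fit <- function(panel, scheme = "none", prior = hce_prior(),
                    mcmc = hce_mcmc(), seed = 1L, ttd = 0:23,
                    verbose = FALSE) {
  st <- stratify(panel, scheme)
  n_g <- attr(st, "n_g")
  freq <- frequency_table(panel, scheme)
  rec <- merge(panel$records, st, by = "person_id")

  cells <- list()
  skipped <- character()
  idx <- 0L
  for (g in names(n_g)) {
    for (t in ttd) {
      idx <- idx + 1L
      sel <- rec$stratum == g & rec$ttd == t
      sub <- rec[sel, , drop = FALSE]
      ind <- as.matrix(sub[indicator_columns()])
      if (!nrow(sub) || !any(rowSums(ind) > 0)) {
        skipped <- c(skipped, paste0(g, ":", t))
        next
      }
      cell_seed <- (as.integer(seed) %% 100000L) * 10000L + idx
      if (verbose) message("fitting cell ", g, ":", t)
      cells[[paste0(g, ":", t)]] <-
        fit_cell(sub$total_cost, ind, prior, mcmc, seed = cell_seed)
    }
  }
  rh <- vapply(cells, function(c) max(c$rhat), 0)
  structure(
    list(cells = cells, frequency = freq, scheme = scheme, n_g = n_g,
         N = sum(n_g), ttd = ttd, skipped = skipped,
         max_rhat = if (length(rh)) max(rh) else NA_real_,
         converged = all(vapply(cells, `[[`, TRUE, "converged")),
         prior = prior, mcmc = mcmc, seed = seed,
         panel = panel),
    class = "hce_fit")
}
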
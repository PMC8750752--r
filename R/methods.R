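#' @export
print.hce_fit <- function(x, ...) {
  cat("Two-part (frequency-severity) expenditure decomposition\n")
  cat(sprintf("Scheme: %s (G = %d), N = %d persons, %d cells fit",
              x$scheme, length(x$n_g), x$N, length(x$cells)))
  if (length(x$skipped)) cat(",", length(x$skipped), "skipped")
  cat("\n")
  cat(sprintf("MCMC: %d chains x %d iter (%d warm-up); max R-hat %.4f (%s)\n",
              x$mcmc$chains, x$mcmc$iter, x$mcmc$warmup, x$max_rhat,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Posterior summaries of all fitted cells
#'
#' @param object An [hce_fit()].
#' @param ... Unused.
#' @return data.frame with one row per (stratum, ttd, disease): posterior
#'   mean/sd/95% credible interval of the component mean, posterior mean of
#'   the component variance, R-hat diagnostics, number of records, and the
#'   cell's convergence flag.
#' @export
coef.hce_fit <- function(object, ...) {
  rows <- lapply(names(object$cells), function(key) {
    cell <- object$cells[[key]]
    gs <- strsplit(key, ":", fixed = TRUE)[[1]]
    data.frame(stratum = gs[1], ttd = as.integer(gs[2]),
               disease = cell$mu$disease, n_obs = cell$n_obs,
               mu_mean = cell$mu$mean, mu_sd = cell$mu$sd,
               mu_q2.5 = cell$mu$q2.5, mu_q97.5 = cell$mu$q97.5,
               var_mean = cell$sigma2$mean,
               rhat_mu = cell$mu$rhat, rhat_var = cell$sigma2$rhat,
               rhat_lp = cell$rhat[["lp__"]],
               converged = cell$converged,
               rank_deficient = cell$rank_deficient)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
summary.hce_fit <- function(object, ...) {
  co <- coef(object)
  structure(list(scheme = object$scheme, n_g = object$n_g, N = object$N,
                 n_cells = length(object$cells),
                 skipped = object$skipped,
                 max_rhat = object$max_rhat, converged = object$converged,
                 n_unconverged = sum(!vapply(object$cells, `[[`, TRUE,
                                             "converged")),
                 coef = co, mcmc = object$mcmc),
            class = "summary.hce_fit")
}

#' @export
print.summary.hce_fit <- function(x, ...) {
  cat("Two-part expenditure model summary\n")
  cat(sprintf("Scheme %s: G = %d strata (", x$scheme, length(x$n_g)))
  cat(paste(sprintf("%s: %d", names(x$n_g), x$n_g), collapse = ", "))
  cat(sprintf("), N = %d\n", x$N))
  cat(sprintf("%d cells fit; max R-hat %.4f; %d unconverged cell(s)\n",
              x$n_cells, x$max_rhat, x$n_unconverged))
  if (length(x$skipped))
    cat("Skipped cells:", paste(x$skipped, collapse = ", "), "\n")
  cat("\nPosterior component means (100k JPY), first months:\n")
  print(utils::head(x$coef[, c("stratum", "ttd", "disease", "n_obs",
                               "mu_mean", "mu_sd", "mu_q2.5", "mu_q97.5")],
                    10), row.names = FALSE)
  invisible(x)
}

#' Predicted per-capita expenditures from a fitted decomposition
#'
#' @param object An [hce_fit()].
#' @param type `"ahce"` for the monthly per-capita table, `"cahce"` for its
#'   cumulative two-year sum.
#' @param ... Unused.
#' @return See [compute_ahce()] / [compute_cahce()].
#' @export
predict.hce_fit <- function(object, type = c("ahce", "cahce"), ...) {
  type <- match.arg(type)
  ahce <- compute_ahce(object)
  if (type == "ahce") ahce else compute_cahce(ahce)
}

#' Reconstruction residuals of a fitted decomposition
#'
#' @param object An [hce_fit()].
#' @param ... Unused.
#' @return Named numeric vector, per month before death, of actual minus
#'   estimated total expenditure (100k JPY).
#' @export
residuals.hce_fit <- function(object, ...) {
  rec <- reconstruction_report(object)
  rec <- rec[rec$ttd != "SUM", ]
  stats::setNames(rec$actual - rec$estimated, rec$ttd)
}

#' Plot per-capita expenditure trajectories
#'
#' Draws AHCE against months before death, one line per disease group,
#' one panel per stratum.
#'
#' @param x An [hce_fit()].
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.hce_fit <- function(x, ...) {
  ahce <- compute_ahce(x)
  strata <- names(x$n_g)
  old <- graphics::par(mfrow = c(1, length(strata)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (g in strata) {
    sub <- ahce[ahce$stratum == g, ]
    m <- matrix(NA_real_, length(x$ttd), 5,
                dimnames = list(x$ttd, disease_groups()))
    m[cbind(match(sub$ttd, x$ttd), match(sub$disease, disease_groups()))] <-
      sub$ahce
    graphics::matplot(x$ttd, m, type = "l", lty = 1, lwd = 2,
                      xlim = rev(range(x$ttd)),
                      xlab = "months before death",
                      ylab = "AHCE (100k JPY per capita)", main = g, ...)
    graphics::legend("topleft", legend = disease_groups(), lty = 1,
                     lwd = 2, col = seq_len(5), bty = "n", cex = 0.8)
  }
  invisible(x)
}
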
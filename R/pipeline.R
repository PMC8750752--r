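round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Per-capita average expenditure (AHCE) table
#'
#' AHCE is the elementwise product of the posterior-mean component cost and
#' the occurrence frequency, per (stratum, month before death, disease
#' group): the per-member expected monthly expenditure attributable to each
#' disease group. Wherever the frequency is 0 the AHCE is exactly 0 and no
#' posterior is required; a missing posterior where the frequency is
#' positive is an error.
#'
#' @param fit An [hce_fit()].
#' @return data.frame of class `hce_ahce` with columns `stratum`, `ttd`,
#'   `disease`, `frequency`, `mu_mean`, `ahce`, `converged`.
#' @export
compute_ahce <- function(fit) {
  freq <- fit$frequency
  out <- freq[, c("stratum", "ttd", "disease", "frequency")]
  out$mu_mean <- NA_real_
  out$converged <- NA
  for (i in seq_len(nrow(out))) {
    if (is.na(out$frequency[i]) || out$frequency[i] == 0) next
    cell <- fit$cells[[paste0(out$stratum[i], ":", out$ttd[i])]]
    if (is.null(cell))
      stop("no posterior for cell ", out$stratum[i], ":", out$ttd[i],
           " with positive frequency")
    j <- match(out$disease[i], cell$mu$disease)
    if (is.na(j))
      stop("no posterior for disease ", out$disease[i], " in cell ",
           out$stratum[i], ":", out$ttd[i], " with positive frequency")
    out$mu_mean[i] <- cell$mu$mean[j]
    out$converged[i] <- cell$converged
  }
  out$ahce <- ifelse(!is.na(out$frequency) & out$frequency == 0, 0,
                     out$mu_mean * out$frequency)
  structure(out, class = c("hce_ahce", "data.frame"),
            scheme = fit$scheme, n_g = fit$n_g)
}

#' Cumulative average expenditure (CAHCE) over the two years before death
#'
#' The exact sum of AHCE over months 0..23 before death, per stratum and
#' disease group. Missing months contribute 0 with a warning.
#'
#' @param ahce An [compute_ahce()] table.
#' @return data.frame of class `hce_cahce` with columns `stratum`,
#'   `disease`, `cahce`, `n_months`.
#' @export
compute_cahce <- function(ahce) {
  if (any(is.na(ahce$ahce)))
    warning("AHCE missing for some cells; they contribute 0 to CAHCE")
  by <- list(stratum = ahce$stratum, disease = ahce$disease)
  agg <- stats::aggregate(ifelse(is.na(ahce$ahce), 0, ahce$ahce),
                          by = by, FUN = sum)
  names(agg)[3] <- "cahce"
  nm <- stats::aggregate(!is.na(ahce$ahce), by = by, FUN = sum)
  names(nm)[3] <- "n_months"
  out <- merge(agg, nm, by = c("stratum", "disease"))
  if (any(out$n_months < 24))
    warning("fewer than 24 months present for some (stratum, disease)")
  out <- out[order(out$stratum, match(out$disease, disease_groups())), ]
  rownames(out) <- NULL
  structure(out, class = c("hce_cahce", "data.frame"))
}

#' Actual summed expenditure per month before death
#' @param panel An `hce_panel`.
#' @param ttd Months to report (default 0:23).
#' @return Named numeric vector of summed monthly totals (100k JPY).
#' @export
actual_totals <- function(panel, ttd = 0:23) {
  agg <- tapply(panel$records$total_cost,
                factor(panel$records$ttd, ttd), sum)
  agg[is.na(agg)] <- 0
  stats::setNames(as.numeric(agg), ttd)
}

#' Reconstruction-error audit of the fitted decomposition
#'
#' Compares, for every month before death, the actual summed expenditure
#' over all persons with the model's estimated total: the per-capita AHCE
#' multiplied by the stratum size and summed over strata and disease
#' groups. The error rate is (actual - estimated) / actual x 100; the
#' displayed rate is rounded half-up to two decimals.
#'
#' @param fit An [hce_fit()].
#' @param ahce Optionally a precomputed [compute_ahce()] table.
#' @return data.frame of class `hce_reconstruction` with one row per month
#'   plus a `SUM` row: `ttd`, `actual`, `estimated`, `error_rate` (full
#'   precision), `error_rate_display`.
#' @export
reconstruction_report <- function(fit, ahce = compute_ahce(fit)) {
  actual <- actual_totals(fit$panel, fit$ttd)
  n_g <- fit$n_g
  est <- vapply(fit$ttd, function(t) {
    sub <- ahce[ahce$ttd == t, ]
    sum(ifelse(is.na(sub$ahce), 0, sub$ahce) * n_g[sub$stratum])
  }, 0)
  out <- data.frame(ttd = as.character(fit$ttd), actual = as.numeric(actual),
                    estimated = est)
  out <- rbind(out, data.frame(ttd = "SUM", actual = sum(actual),
                               estimated = sum(est)))
  out$error_rate <- ifelse(out$actual == 0, NA_real_,
                           (out$actual - out$estimated) / out$actual * 100)
  if (any(out$actual == 0))
    warning("months with zero actual totals have undefined error rates")
  disp <- round_half_up(out$error_rate)
  disp[!is.na(disp) & disp == 0] <- 0  # avoid "-0.00%"
  out$error_rate_display <- sprintf("%.2f%%", disp)
  structure(out, class = c("hce_reconstruction", "data.frame"))
}

#' @export
print.hce_reconstruction <- function(x, ...) {
  cat("Reconstruction audit (actual vs estimated totals, 100k JPY)\n")
  print(data.frame(ttd = x$ttd, actual = round(x$actual, 0),
                   estimated = round(x$estimated, 0),
                   error_rate = x$error_rate_display), row.names = FALSE)
  invisible(x)
}

#' Run the full frequency-severity pipeline and write its artifacts
#'
#' Generates (or loads) a panel, applies the eligibility filters, fits the
#' model, and writes frequency.csv, posterior.csv, ahce.csv, cahce.csv,
#' reconstruction.csv, bf.csv (when the scheme has at least two strata) and
#' a run_report.json with the seed and convergence summary. Fails -- and
#' removes partial outputs -- if any cell misses the R-hat threshold,
#' unless `allow_unconverged`.
#'
#' @param config List with optional entries `generator` (an
#'   [generator_config()]), `panel_dir` (a directory readable by
#'   [read_panel()]; one of the two must be present), `scheme`, `prior`,
#'   `mcmc`, `bf_ttd`. A YAML file path is accepted when the yaml package
#'   is installed.
#' @param out_dir Output directory.
#' @param seed Integer seed for generation and fitting.
#' @param allow_unconverged Keep outputs even if some cell fails the R-hat
#'   criterion.
#' @return Invisibly, a list with the fit, tables, and file paths.
#' @export
run_pipeline <- function(config = list(), out_dir, seed = 1L,
                         allow_unconverged = FALSE) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    config <- yaml::read_yaml(config)
    if (!is.null(config$generator))
      config$generator <- do.call(generator_config, config$generator)
  }
  scheme <- config$scheme %||% "none"
  prior <- config$prior %||% hce_prior()
  mcmc <- config$mcmc %||% hce_mcmc()

  if (!is.null(config$panel_dir)) {
    panel <- read_panel(config$panel_dir)
  } else {
    gen <- config$generator %||% generator_config()
    panel <- generate_panel(gen, seed = seed)$panel
  }
  panel <- filter_decedents(panel)

  fit <- hce_fit(panel, scheme, prior, mcmc, seed = seed)
  if (!fit$converged && !allow_unconverged)
    stop(sprintf("max R-hat %.4f exceeds threshold %.2f; rerun with more ",
                 fit$max_rhat, mcmc$rhat_threshold),
         "iterations or allow_unconverged = TRUE")

  ahce <- compute_ahce(fit)
  cahce <- compute_cahce(ahce)
  recon <- reconstruction_report(fit, ahce)

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character()
  on.exit(if (!is.null(attr(written, "failed"))) unlink(written))
  wr <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(as.data.frame(df), path, row.names = FALSE)
    written <<- c(written, path)
  }
  ok <- FALSE
  tryCatch({
    wr(fit$frequency, "frequency.csv")
    wr(coef(fit), "posterior.csv")
    wr(ahce, "ahce.csv")
    wr(cahce, "cahce.csv")
    wr(recon[, c("ttd", "actual", "estimated", "error_rate",
                 "error_rate_display")], "reconstruction.csv")
    bf <- NULL
    if (length(fit$n_g) >= 2) {
      pairs <- utils::combn(names(fit$n_g), 2, simplify = FALSE)
      bf <- do.call(rbind, lapply(pairs, function(p)
        bf_table(fit, p[1], p[2], ttd = config$bf_ttd %||% 0:12)))
      wr(bf, "bf.csv")
    }
    report <- list(seed = seed, scheme = scheme,
                   n_persons = nrow(panel$persons),
                   n_records = nrow(panel$records),
                   n_cells = length(fit$cells),
                   skipped_cells = fit$skipped,
                   max_rhat = fit$max_rhat, converged = fit$converged,
                   mcmc = unclass(mcmc),
                   max_abs_error_rate =
                     max(abs(recon$error_rate[recon$ttd != "SUM"]),
                         na.rm = TRUE),
                   package_version =
                     as.character(utils::packageVersion("hcedecomp")))
    path <- file.path(out_dir, "run_report.json")
    jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    written <- c(written, path)
    ok <- TRUE
  }, finally = if (!ok) {
    unlink(written)
  })
  invisible(list(fit = fit, ahce = ahce, cahce = cahce,
                 reconstruction = recon, files = written))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
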
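#' Default synthetic-panel generator configuration
#'
#' Encodes the study conditions the analysis is exercised under: six
#' sex-by-age strata with realistic decedent shares, disease-group occurrence
#' probabilities that rise toward the month of death, component costs (in
#' 100k JPY) that rise nonlinearly toward death and decline with age, a
#' half-month attenuation of both occurrence and cost in the month of death,
#' and near-independent occurrences across disease groups (an optional
#' Gaussian-copula correlation between circulatory and CKD can be injected).
#'
#' Trajectories are exponential-in-time-to-death: `base + amp * exp(-t/tau)`,
#' evaluated at t = 0..23 months before death; at t = 0 both the occurrence
#' probability and the component mean are multiplied by
#' `death_month_attenuation` (the month of death is effectively half a
#' month). Component standard deviations are `sd_frac` times the component
#' mean, keeping negative draws rare so the Normal severity model is
#' near-correctly specified under the default `"redraw"` policy.
#'
#' @param n_persons Total decedents to simulate (>= 60 so all six strata are
#'   populated).
#' @param stratum_shares Named shares of the six sex-by-age strata; defaults
#'   mirror a large NHI decedent population (males 8.7/20.6/22.6%, females
#'   4.2/13.7/30.2% for ages 65-75/75-85/85-95).
#' @param occurrence,cost Per-disease `(base, amp, tau)` trajectory
#'   parameters for occurrence probability and component mean cost.
#' @param cost_age_factor Multiplier on component means per age group
#'   (older decedents incur lower costs).
#' @param sd_frac Component sd as a fraction of the component mean.
#' @param death_month_attenuation Multiplier applied to occurrence and mean
#'   at t = 0; default 0.5.
#' @param negative_cost_policy `"redraw"` (rejection; default) or
#'   `"truncate"` (clamp negative component draws to 0).
#' @param copula_rho Latent Gaussian correlation between the circulatory and
#'   CKD occurrence indicators (0 = independent, the default).
#' @param admission `(base, amp, tau)` of the inpatient-admission
#'   probability ramp, plus per-age multipliers.
#' @param seed Default RNG seed used by [generate_panel()].
#' @return An object of class `hce_generator_config`.
#' @export
generator_config <- function(
    n_persons = 3000,
    stratum_shares = c("M_65-75" = 0.087, "M_75-85" = 0.206,
                       "M_85-95" = 0.226, "F_65-75" = 0.042,
                       "F_75-85" = 0.137, "F_85-95" = 0.302),
    occurrence = list(
      circulatory = c(base = 0.50, amp = 0.00, tau = 1),
      ckd         = c(base = 0.06, amp = 0.00, tau = 1),
      neoplasms   = c(base = 0.33, amp = 0.13, tau = 5),
      respiratory = c(base = 0.28, amp = 0.18, tau = 4),
      others      = c(base = 0.72, amp = 0.06, tau = 4)),
    cost = list(
      circulatory = c(base = 0.50, amp = 0.00, tau = 1),
      ckd         = c(base = 3.50, amp = 0.00, tau = 1),
      neoplasms   = c(base = 1.20, amp = 2.20, tau = 4),
      respiratory = c(base = 0.70, amp = 2.55, tau = 3),
      others      = c(base = 0.80, amp = 1.60, tau = 4)),
    cost_age_factor = c("65-75" = 1.00, "75-85" = 0.85, "85-95" = 0.70),
    sd_frac = 1 / 3,
    death_month_attenuation = 0.5,
    negative_cost_policy = c("redraw", "truncate"),
    copula_rho = 0,
    admission = list(base = 0.15, amp = 0.50, tau = 1.75,
                     age_factor = c("65-75" = 1.00, "75-85" = 0.96,
                                    "85-95" = 0.88)),
    seed = 1L) {
  negative_cost_policy <- match.arg(negative_cost_policy)
  if (n_persons < 60)
    stop("n_persons must be >= 60 to populate all six strata")
  stopifnot(abs(sum(stratum_shares) - 1) < 1e-8,
            all(names(occurrence) == disease_groups()),
            all(names(cost) == disease_groups()),
            sd_frac > 0,
            death_month_attenuation > 0, death_month_attenuation <= 1,
            copula_rho >= -1, copula_rho <= 1)
  structure(
    list(n_persons = as.integer(n_persons), stratum_shares = stratum_shares,
         occurrence = occurrence, cost = cost,
         cost_age_factor = cost_age_factor, sd_frac = sd_frac,
         death_month_attenuation = death_month_attenuation,
         negative_cost_policy = negative_cost_policy,
         copula_rho = copula_rho, admission = admission,
         seed = as.integer(seed),
         window_start = "2012-11", window_end = "2018-10"),
    class = "hce_generator_config")
}

#' @export
print.hce_generator_config <- function(x, ...) {
  cat("Synthetic decedent-panel generator:", x$n_persons, "persons,",
      length(x$stratum_shares), "strata\n")
  cat("Death-month attenuation:", x$death_month_attenuation,
      "| negative-cost policy:", x$negative_cost_policy,
      "| copula rho:", x$copula_rho, "\n")
  invisible(x)
}

# Largest-remainder apportionment of n over shares (conserves the total).
apportion <- function(n, shares) {
  raw <- n * shares / sum(shares)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  stats::setNames(as.integer(base), names(shares))
}

traj <- function(par, t) par[["base"]] + par[["amp"]] * exp(-t / par[["tau"]])

#' Ground-truth parameter grid implied by a generator configuration
#'
#' Expands the parametric trajectories into the full (stratum, ttd, disease)
#' grid of occurrence probabilities `p`, component means `m` and component
#' sds `s` actually used by [generate_panel()], with the age factor and the
#' death-month attenuation applied. This is the recovery-test oracle.
#'
#' @param config An `hce_generator_config`.
#' @return data.frame with columns `stratum`, `ttd`, `disease`, `p`, `m`,
#'   `s`.
#' @export
true_parameters <- function(config) {
  strata <- names(config$stratum_shares)
  grid <- expand.grid(stratum = strata, ttd = 0:23,
                      disease = disease_groups(),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  age <- sub("^[MF]_", "", grid$stratum)
  p <- m <- numeric(nrow(grid))
  for (d in disease_groups()) {
    sel <- grid$disease == d
    p[sel] <- traj(config$occurrence[[d]], grid$ttd[sel])
    m[sel] <- traj(config$cost[[d]], grid$ttd[sel])
  }
  m <- m * config$cost_age_factor[age]
  att <- grid$ttd == 0
  p[att] <- p[att] * config$death_month_attenuation
  m[att] <- m[att] * config$death_month_attenuation
  p <- pmin(pmax(p, 0), 1)
  data.frame(grid, p = p, m = m, s = m * config$sd_frac)
}

#' Generate a synthetic decedent claims panel
#'
#' For every simulated decedent and every month t = 0..23 before death,
#' disease-group occurrence indicators are drawn Bernoulli(p) (independently
#' across groups unless `copula_rho` couples circulatory and CKD), and for
#' each occurring group a latent cost component is drawn
#' Normal(m, s^2), negatives handled per the configured policy. The
#' observed monthly total is the exact sum of the occurring components.
#' Fully reproducible from the seed.
#'
#' @param config An [generator_config()] object.
#' @param seed RNG seed; defaults to `config$seed`.
#' @param keep_components If TRUE, attach the latent per-disease component
#'   matrix as attribute `"components"` of the returned records (used by
#'   conservation audits).
#' @return A list of class `hce_sim` with elements `panel` (an
#'   [hce_panel()]), `true_params` (see [true_parameters()]), and `config`.
#'   The panel's records carry attributes `n_component_draws` and
#'   `n_redrawn` documenting the negative-draw rejection rate.
#' @export
generate_panel <- function(config = generator_config(), seed = config$seed,
                           keep_components = FALSE) {
  set.seed(seed)
  tp <- true_parameters(config)
  counts <- apportion(config$n_persons, config$stratum_shares)
  w0 <- month_index(config$window_start)
  w1 <- month_index(config$window_end)

  persons_l <- list()
  records_l <- list()
  comp_l <- list()
  n_draws <- 0L
  n_redrawn <- 0L
  pid <- 0L

  for (s_name in names(counts)) {
    n_g <- counts[[s_name]]
    if (n_g == 0) next
    sex <- sub("_.*", "", s_name)
    agegrp <- sub("^[MF]_", "", s_name)
    lo <- as.integer(substr(agegrp, 1, 2))
    hi <- if (agegrp == "85-95") 95L else as.integer(substr(agegrp, 4, 5)) - 1L

    ids <- sprintf("P%06d", pid + seq_len(n_g))
    pid <- pid + n_g
    ages <- sample(lo:hi, n_g, replace = TRUE)
    death <- sample(seq(w0 + 23L, w1), n_g, replace = TRUE)
    birth <- death - ages * 12L - sample(0:11, n_g, replace = TRUE)
    persons_l[[s_name]] <- data.frame(
      person_id = ids, sex = sex,
      birth_month = month_label(birth), death_month = month_label(death),
      coverage_months = 24L, stringsAsFactors = FALSE)

    sub <- tp[tp$stratum == s_name, ]
    pmat <- matrix(sub$p[order(match(sub$disease, disease_groups()),
                               sub$ttd)], nrow = 24)  # 24 x 5
    mmat <- matrix(sub$m[order(match(sub$disease, disease_groups()),
                               sub$ttd)], nrow = 24)
    smat <- matrix(sub$s[order(match(sub$disease, disease_groups()),
                               sub$ttd)], nrow = 24)

    nrow_g <- n_g * 24L
    t_vec <- rep(0:23, times = n_g)
    ind <- matrix(0L, nrow_g, 5)
    pv <- pmat[t_vec + 1L, , drop = FALSE]
    if (config$copula_rho != 0) {
      rho <- config$copula_rho
      z1 <- stats::rnorm(nrow_g)
      z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(nrow_g)
      ind[, 1] <- as.integer(z1 < stats::qnorm(pv[, 1]))
      ind[, 2] <- as.integer(z2 < stats::qnorm(pv[, 2]))
      for (d in 3:5)
        ind[, d] <- as.integer(stats::runif(nrow_g) < pv[, d])
    } else {
      u <- matrix(stats::runif(nrow_g * 5L), nrow_g, 5)
      ind <- matrix(as.integer(u < pv), nrow_g, 5)
    }

    comp <- matrix(0, nrow_g, 5)
    for (d in 1:5) {
      on <- which(ind[, d] == 1L)
      if (!length(on)) next
      mu_d <- mmat[t_vec[on] + 1L, d]
      sd_d <- smat[t_vec[on] + 1L, d]
      y <- stats::rnorm(length(on), mu_d, sd_d)
      n_draws <- n_draws + length(on)
      if (config$negative_cost_policy == "redraw") {
        bad <- which(y < 0)
        while (length(bad)) {
          n_redrawn <- n_redrawn + length(bad)
          n_draws <- n_draws + length(bad)
          y[bad] <- stats::rnorm(length(bad), mu_d[bad], sd_d[bad])
          bad <- bad[y[bad] < 0]
        }
      } else {
        n_redrawn <- n_redrawn + sum(y < 0)
        y <- pmax(y, 0)
      }
      comp[on, d] <- y
    }

    a <- config$admission
    a_prob <- pmin(pmax((a$base + a$amp * exp(-t_vec / a$tau)) *
                          a$age_factor[[agegrp]], 0), 1)

    rec <- data.frame(
      person_id = rep(ids, each = 24L), ttd = t_vec,
      total_cost = rowSums(comp),
      stringsAsFactors = FALSE)
    rec[indicator_columns()] <- as.data.frame(ind)
    rec$inpatient_flag <- as.integer(stats::runif(nrow_g) < a_prob)
    records_l[[s_name]] <- rec
    if (keep_components) comp_l[[s_name]] <- comp
  }

  persons <- do.call(rbind, persons_l)
  records <- do.call(rbind, records_l)
  rownames(persons) <- rownames(records) <- NULL
  panel <- hce_panel(persons, records, config$window_start,
                     config$window_end)
  attr(panel$records, "n_component_draws") <- n_draws
  attr(panel$records, "n_redrawn") <- n_redrawn
  if (keep_components) {
    comps <- do.call(rbind, comp_l)
    colnames(comps) <- disease_groups()
    attr(panel$records, "components") <- comps
  }
  structure(list(panel = panel, true_params = tp, config = config,
                 seed = seed),
            class = "hce_sim")
}

#' @export
print.hce_sim <- function(x, ...) {
  cat("Synthetic decedent panel (seed ", x$seed, ")\n", sep = "")
  print(x$panel)
  invisible(x)
}

#' Descriptive summary tables of a panel
#'
#' Mirrors the basic-statistics tables of a decedent-panel study: subject
#' counts and shares per stratum, occurrence counts per (stratum, ttd,
#' disease) with percentages of the total subject count, mean and sd of
#' total incurred expenditure among incurring records, and inpatient
#' admission ratios.
#'
#' @param panel An `hce_panel`.
#' @param scheme Stratification scheme, see [stratify()].
#' @return List of data.frames: `subjects`, `incurrence`,
#'   `mean_total_ihce`, `admission`.
#' @export
empirical_summary <- function(panel, scheme = "sex_age") {
  st <- stratify(panel, scheme)
  n_g <- attr(st, "n_g")
  N <- sum(n_g)
  rec <- merge(panel$records, st, by = "person_id")

  subjects <- data.frame(stratum = names(n_g), n = as.integer(n_g),
                         ratio = as.integer(n_g) / N)

  inc <- do.call(rbind, lapply(indicator_columns(), function(col) {
    agg <- stats::aggregate(rec[[col]],
                            by = list(stratum = rec$stratum, ttd = rec$ttd),
                            FUN = sum)
    agg$disease <- sub("^ind_", "", col)
    names(agg)[3] <- "count"
    agg
  }))
  inc$pct_total <- inc$count / N
  inc <- inc[order(inc$stratum, inc$ttd, match(inc$disease,
                                               disease_groups())), ]
  rownames(inc) <- NULL

  any_ind <- rowSums(rec[indicator_columns()]) > 0
  inc_rec <- rec[any_ind, ]
  mt <- stats::aggregate(inc_rec$total_cost,
                         by = list(stratum = inc_rec$stratum,
                                   ttd = inc_rec$ttd),
                         FUN = function(x) c(mean(x), stats::sd(x)))
  mean_total <- data.frame(stratum = mt$stratum, ttd = mt$ttd,
                           mean = mt$x[, 1], sd = mt$x[, 2])

  adm <- stats::aggregate(rec$inpatient_flag,
                          by = list(stratum = rec$stratum, ttd = rec$ttd),
                          FUN = mean)
  names(adm)[3] <- "ratio"

  list(subjects = subjects, incurrence = inc,
       mean_total_ihce = mean_total, admission = adm)
}
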
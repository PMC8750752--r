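stars_for_p <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Chi-square test of occurrence against a grouping
#'
#' Pearson chi-square (no continuity correction) on the 2 x K contingency
#' table of incurred / not-incurred against group membership, where the
#' not-incurred count is the full group size minus the incurrence count, at
#' one month before death for one disease group. The complementary
#' stratifier can be held fixed via `within` (e.g. test sex within one age
#' group).
#'
#' @param panel A filtered `hce_panel`.
#' @param t Month before death.
#' @param d Disease group label.
#' @param by `"age"` or `"sex"`: the grouping tested.
#' @param within Optional named filter, e.g. `c(sex = "M")` or
#'   `c(age = "65-75")`.
#' @return List of class `hce_test`: `statistic`, `df`, `p_value`, `stars`,
#'   `n`, `table`, `note`.
#' @export
incurrence_chisq <- function(panel, t, d, by = c("age", "sex"),
                             within = NULL) {
  by <- match.arg(by)
  stopifnot(d %in% disease_groups())
  p <- panel$persons
  ag <- age_group_of(age_at_death(panel)[p$person_id])
  keep <- rep(TRUE, nrow(p))
  if (!is.null(within)) {
    if (!is.null(within["sex"]) && !is.na(within["sex"]))
      keep <- keep & p$sex == within[["sex"]]
    if (!is.null(within["age"]) && !is.na(within["age"]))
      keep <- keep & ag == within[["age"]]
  }
  group <- if (by == "age") ag[keep] else p$sex[keep]
  ids <- p$person_id[keep]

  col <- paste0("ind_", d)
  rec <- panel$records[panel$records$ttd == t &
                         panel$records$person_id %in% ids, ]
  incurred_ids <- rec$person_id[rec[[col]] == 1]
  inc <- tapply(ids %in% incurred_ids, group, sum)
  tot <- table(group)
  tab <- rbind(incurred = as.integer(inc),
               not_incurred = as.integer(tot) - as.integer(inc))
  colnames(tab) <- names(tot)
  if (ncol(tab) < 2) stop("grouping has fewer than 2 groups")

  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  note <- sprintf("2x%d incurred/not vs %s at ttd %d, %s", ncol(tab), by,
                  t, d)
  if (any(ct$expected < 1)) {
    warning("expected cell count below 1")
    note <- paste(note, "(expected cell < 1)")
  }
  structure(list(statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p_value = unname(ct$p.value),
                 stars = stars_for_p(ct$p.value),
                 n = sum(tab), table = tab, note = note),
            class = "hce_test")
}

#' @export
print.hce_test <- function(x, ...) {
  cat(sprintf("%s\nstatistic = %.4g, df = %s, p = %.4g %s (n = %d)\n",
              x$note, x$statistic,
              if (is.null(x$df)) "-" else format(x$df), x$p_value,
              x$stars, x$n))
  invisible(x)
}

#' Rank tests on total incurred expenditure
#'
#' At one month before death, tests differences in total incurred
#' expenditure (the monthly total of records with at least one active
#' indicator; zero-claim person-months are excluded) across the three age
#' groups by Kruskal-Wallis, between age-group pairs by Wilcoxon rank-sum
#' with Bonferroni correction (times 3, capped at 1), and between the sexes
#' by Wilcoxon rank-sum.
#'
#' @param panel A filtered `hce_panel`.
#' @param t Month before death.
#' @param include_zero_claims Include person-months without any indicator
#'   (default FALSE).
#' @return List with elements `kruskal_wallis`, `pairwise_age` (data.frame
#'   with raw and Bonferroni-adjusted p), `wilcoxon_sex`; each test carries
#'   statistic, p and stars. Groups with fewer than 2 observations are
#'   skipped with a note.
#' @export
total_ihce_tests <- function(panel, t, include_zero_claims = FALSE) {
  p <- panel$persons
  ag <- age_group_of(age_at_death(panel)[p$person_id])
  rec <- panel$records[panel$records$ttd == t, ]
  if (!include_zero_claims)
    rec <- rec[rowSums(rec[indicator_columns()]) > 0, ]
  i <- match(rec$person_id, p$person_id)
  df <- data.frame(y = rec$total_cost, age = ag[i], sex = p$sex[i])

  small <- names(which(table(df$age) < 2))
  kw <- NULL
  if (length(unique(df$age)) >= 2 && !length(small)) {
    k <- stats::kruskal.test(y ~ factor(age), data = df)
    kw <- list(statistic = unname(k$statistic), df = unname(k$parameter),
               p_value = unname(k$p.value), stars = stars_for_p(k$p.value))
  }

  lev <- sort(unique(df$age))
  pw <- NULL
  if (length(lev) >= 2) {
    pairs <- utils::combn(lev, 2, simplify = FALSE)
    pw <- do.call(rbind, lapply(pairs, function(pr) {
      a <- df$y[df$age == pr[1]]; b <- df$y[df$age == pr[2]]
      if (length(a) < 2 || length(b) < 2)
        return(data.frame(pair = paste(pr, collapse = " vs "),
                          p_raw = NA, p_bonferroni = NA, stars = "",
                          note = "skipped: < 2 observations"))
      w <- stats::wilcox.test(a, b, exact = FALSE)
      p_adj <- min(w$p.value * 3, 1)
      data.frame(pair = paste(pr, collapse = " vs "),
                 p_raw = w$p.value, p_bonferroni = p_adj,
                 stars = stars_for_p(p_adj), note = "")
    }))
  }

  ws <- NULL
  a <- df$y[df$sex == "M"]; b <- df$y[df$sex == "F"]
  if (length(a) >= 2 && length(b) >= 2) {
    w <- stats::wilcox.test(a, b, exact = FALSE)
    ws <- list(statistic = unname(w$statistic),
               p_value = unname(w$p.value), stars = stars_for_p(w$p.value))
  }
  list(kruskal_wallis = kw, pairwise_age = pw, wilcoxon_sex = ws,
       n = nrow(df), t = t)
}

#' Pearson correlations of occurrence indicators at one month
#'
#' The 5 x 5 Pearson correlation matrix of the binary occurrence indicators
#' (equivalently the phi coefficient) over all person-months at a given
#' month before death. Constant columns yield NA entries, reported with a
#' warning.
#'
#' @param panel An `hce_panel`.
#' @param t Month before death.
#' @return 5 x 5 symmetric matrix with unit diagonal, dimnames
#'   [disease_groups()].
#' @export
occurrence_correlation <- function(panel, t) {
  rec <- panel$records[panel$records$ttd == t, indicator_columns()]
  if (nrow(rec) < 2) stop("need at least 2 records at t = ", t)
  m <- as.matrix(rec)
  colnames(m) <- disease_groups()
  const <- apply(m, 2, function(x) stats::sd(x) == 0)
  cm <- suppressWarnings(stats::cor(m))
  diag(cm) <- 1
  if (any(const))
    warning("constant indicator column(s): ",
            paste(disease_groups()[const], collapse = ", "),
            "; correlations undefined (NA)")
  cm
}

#' Inpatient admission ratio by stratum and month before death
#'
#' @param panel An `hce_panel` whose records carry `inpatient_flag`.
#' @param t Months before death (vectorized; default 0:23).
#' @param scheme Stratification scheme.
#' @return data.frame with columns `stratum`, `ttd`, `ratio` (share of the
#'   stratum's person-months flagged inpatient).
#' @export
admission_ratio <- function(panel, t = 0:23, scheme = "sex_age") {
  if (is.null(panel$records$inpatient_flag) ||
      all(panel$records$inpatient_flag == 0))
    warning("inpatient_flag absent or all zero; ratios reflect that")
  st <- stratify(panel, scheme)
  rec <- merge(panel$records[panel$records$ttd %in% t, ], st,
               by = "person_id")
  agg <- stats::aggregate(rec$inpatient_flag,
                          by = list(stratum = rec$stratum, ttd = rec$ttd),
                          FUN = mean)
  names(agg)[3] <- "ratio"
  agg[order(agg$stratum, agg$ttd), ]
}
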
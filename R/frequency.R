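#' Occurrence proportion of a disease group within a stratum-month
#'
#' The frequency part of the two-part model: the number of stratum members
#' with an occurrence indicator of 1, divided by the full stratum membership
#' `n_g` (not the number of claim records -- a person with no claims row in
#' a month contributes 0 to every indicator).
#'
#' @param indicators Matrix or data.frame of 0/1 occurrence indicators for
#'   the stratum's records in one month (one row per person with a record;
#'   persons without a record that month are implicit zeros).
#' @param n_g Number of persons in the stratum.
#' @return Named numeric vector of proportions, one per indicator column.
#' @export
compute_frequency <- function(indicators, n_g) {
  if (n_g <= 0) stop("empty stratum: frequency undefined")
  ind <- as.matrix(indicators)
  cnt <- colSums(ind)
  if (any(cnt > n_g))
    stop("more occurrences than stratum members; records are not unique")
  cnt / n_g
}

#' Frequency table over strata, months before death, and disease groups
#'
#' Assembles the complete F grid: for every stratum g, time to death t =
#' 0..23 and disease group d, the proportion of the stratum's members with
#' an occurrence. Also carries `pct_total`, the same count divided by the
#' total subject count N (the convention used by descriptive occurrence
#' tables); the two only coincide when G = 1.
#'
#' @param panel A filtered `hce_panel`.
#' @param scheme Stratification scheme, see [stratify()].
#' @return data.frame of class `hce_frequency` with columns `stratum`,
#'   `ttd`, `disease`, `count`, `n_g`, `frequency`, `pct_total`; attributes
#'   `scheme`, `n_g`, `N`.
#' @export
frequency_table <- function(panel, scheme = "none") {
  st <- stratify(panel, scheme)
  n_g <- attr(st, "n_g")
  N <- sum(n_g)
  rec <- merge(panel$records, st, by = "person_id")

  grid <- expand.grid(stratum = names(n_g), ttd = 0:23,
                      disease = disease_groups(),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  counts <- array(0L, dim = c(length(n_g), 24, 5),
                  dimnames = list(names(n_g), NULL, disease_groups()))
  for (d in seq_along(disease_groups())) {
    col <- indicator_columns()[d]
    tab <- tapply(rec[[col]], list(factor(rec$stratum, names(n_g)),
                                   factor(rec$ttd, 0:23)), sum)
    tab[is.na(tab)] <- 0L
    counts[, , d] <- tab
  }
  grid$count <- as.integer(counts[cbind(match(grid$stratum, names(n_g)),
                                        grid$ttd + 1L,
                                        match(grid$disease,
                                              disease_groups()))])
  grid$n_g <- as.integer(n_g[grid$stratum])
  grid$frequency <- ifelse(grid$n_g > 0, grid$count / grid$n_g, NA_real_)
  grid$pct_total <- grid$count / N
  if (any(grid$n_g == 0))
    warning("empty strata have undefined (NA) frequencies")
  grid <- grid[order(match(grid$stratum, names(n_g)), grid$ttd,
                     match(grid$disease, disease_groups())), ]
  rownames(grid) <- NULL
  structure(grid, class = c("hce_frequency", "data.frame"),
            scheme = scheme, n_g = n_g, N = N)
}
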
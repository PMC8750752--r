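#' Disease groups used throughout the package
#'
#' The five ICD-10 based disease groups, in the canonical order used by every
#' grid in the package: circulatory (I00--I99), chronic kidney disease (N18
#' and its subcodes), neoplasms (C00--D48), respiratory (J00--J99), and
#' others (the complement).
#'
#' @return Character vector of the five group labels.
#' @export
disease_groups <- function() {
  c("circulatory", "ckd", "neoplasms", "respiratory", "others")
}

#' Indicator column names corresponding to [disease_groups()]
#' @return Character vector `ind_circulatory`, ..., `ind_others`.
#' @export
indicator_columns <- function() {
  paste0("ind_", disease_groups())
}

#' Map ICD-10 codes to disease groups
#'
#' Every syntactically valid ICD-10 code (letter, two digits, optional
#' subcode such as `"N18.3"`) maps to exactly one of the five groups.
#' N18 takes precedence over the other N codes, which fall into `others`.
#'
#' @param codes Character vector of ICD-10 codes.
#' @return Character vector of group labels (see [disease_groups()]).
#' @examples
#' assign_disease_group(c("I63", "N18.3", "E11", "C50", "J44"))
#' @export
assign_disease_group <- function(codes) {
  codes <- toupper(trimws(as.character(codes)))
  ok <- grepl("^[A-Z][0-9]{2}(\\.[0-9A-Z]{1,4})?$", codes)
  if (any(!ok)) {
    stop("malformed ICD-10 code(s): ",
         paste(unique(codes[!ok]), collapse = ", "))
  }
  letter <- substr(codes, 1, 1)
  num <- as.integer(substr(codes, 2, 3))
  grp <- rep("others", length(codes))
  grp[letter == "I"] <- "circulatory"
  grp[letter == "J"] <- "respiratory"
  grp[letter == "C" | (letter == "D" & num <= 48)] <- "neoplasms"
  grp[letter == "N" & num == 18] <- "ckd"
  grp
}

# ---- calendar-month helpers (months since 0000-01, "YYYY-MM" strings) ----

month_index <- function(ym) {
  ym <- as.character(ym)
  ok <- grepl("^[0-9]{4}-[0-9]{2}$", ym) | is.na(ym)
  if (any(!ok)) stop("malformed month (expected YYYY-MM): ",
                     paste(unique(ym[!ok]), collapse = ", "))
  ifelse(is.na(ym), NA_integer_,
         as.integer(substr(ym, 1, 4)) * 12L + as.integer(substr(ym, 6, 7)) - 1L)
}

month_label <- function(idx) {
  sprintf("%04d-%02d", idx %/% 12L, idx %% 12L + 1L)
}

#' Construct a decedent claims panel
#'
#' Bundles person-level enrollment data with person-month claim records and
#' validates the invariants the models rely on: costs are finite,
#' non-negative and already normalized to 100,000 JPY units; indicators are
#' 0/1; a month with no disease indicator carries zero cost; every record's
#' person exists; and (person, ttd) pairs are unique.
#'
#' @param persons data.frame with columns `person_id`, `sex` ("M"/"F"),
#'   `birth_month`, `death_month` (`"YYYY-MM"`), `coverage_months`.
#' @param records data.frame with columns `person_id`, `ttd` (months before
#'   death, 0 = month of death), `total_cost` (100k JPY), the five indicator
#'   columns (see [indicator_columns()]), and optionally `inpatient_flag`.
#' @param window_start,window_end Study window, `"YYYY-MM"`.
#' @param unit Cost normalization note carried as metadata.
#' @return An object of class `hce_panel`.
#' @export
hce_panel <- function(persons, records,
                      window_start = "2012-11", window_end = "2018-10",
                      unit = "100,000 JPY") {
  persons <- as.data.frame(persons)
  records <- as.data.frame(records)

  need_p <- c("person_id", "sex", "birth_month", "death_month",
              "coverage_months")
  miss <- setdiff(need_p, names(persons))
  if (length(miss)) stop("persons is missing column(s): ",
                         paste(miss, collapse = ", "))
  need_r <- c("person_id", "ttd", "total_cost", indicator_columns())
  miss <- setdiff(need_r, names(records))
  if (length(miss)) stop("records is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(records$inpatient_flag)) records$inpatient_flag <- 0L

  persons$person_id <- as.character(persons$person_id)
  records$person_id <- as.character(records$person_id)
  if (anyDuplicated(persons$person_id))
    stop("duplicated person_id in persons")
  if (!all(persons$sex %in% c("M", "F")))
    stop("sex must be 'M' or 'F'")
  if (any(persons$coverage_months < 0, na.rm = TRUE))
    stop("coverage_months must be >= 0")
  month_index(persons$birth_month)  # validates format
  month_index(persons$death_month)

  if (!is.numeric(records$total_cost) ||
      any(!is.finite(records$total_cost)) || any(records$total_cost < 0))
    stop("total_cost must be finite and non-negative")
  records$ttd <- as.integer(records$ttd)
  if (any(is.na(records$ttd)) || any(records$ttd < 0))
    stop("ttd must be a non-negative integer")
  ind <- as.matrix(records[indicator_columns()])
  if (!all(ind %in% c(0, 1)))
    stop("indicator columns must contain only 0/1 (columns ",
         paste(indicator_columns(), collapse = ", "), ")")
  if (!all(records$inpatient_flag %in% c(0, 1)))
    stop("inpatient_flag must be 0/1")
  no_ind <- rowSums(ind) == 0
  if (any(no_ind & records$total_cost > 0))
    stop("records with all indicators 0 must have total_cost 0")
  if (!all(records$person_id %in% persons$person_id))
    stop("records reference unknown person_id(s)")
  if (anyDuplicated(records[c("person_id", "ttd")]))
    stop("(person_id, ttd) pairs must be unique")

  structure(
    list(persons = persons, records = records,
         meta = list(window_start = window_start, window_end = window_end,
                     unit = unit)),
    class = "hce_panel")
}

#' @export
print.hce_panel <- function(x, ...) {
  cat("Decedent claims panel:", nrow(x$persons), "persons,",
      nrow(x$records), "person-month records\n")
  cat("Study window:", x$meta$window_start, "to", x$meta$window_end,
      "| cost unit:", x$meta$unit, "\n")
  fr <- attr(x, "filter_report")
  if (!is.null(fr)) {
    cat("Filtered panel; exclusions:\n")
    for (i in seq_len(nrow(fr)))
      cat(sprintf("  %-28s %d\n", fr$reason[i], fr$n[i]))
  }
  invisible(x)
}

#' Age at death in completed years
#' @param panel An `hce_panel`.
#' @return Named integer vector (names are person ids).
#' @export
age_at_death <- function(panel) {
  b <- month_index(panel$persons$birth_month)
  d <- month_index(panel$persons$death_month)
  stats::setNames(as.integer((d - b) %/% 12L), panel$persons$person_id)
}

#' Age group of an age at death
#'
#' Half-open groups `[65,75)`, `[75,85)`, `[85,95]`; the upper endpoint 95 is
#' included so that every decedent aged between 65 and 95 lands in exactly
#' one group.
#'
#' @param age Numeric vector of ages in years.
#' @return Character vector among `"65-75"`, `"75-85"`, `"85-95"`.
#' @export
age_group_of <- function(age) {
  if (any(is.na(age)) || any(age < 65) || any(age > 95))
    stop("age at death must lie in [65, 95]")
  ifelse(age < 75, "65-75", ifelse(age < 85, "75-85", "85-95"))
}

#' Apply the decedent eligibility filters
#'
#' Retains persons who died inside the study window, had at least
#' `min_coverage` months of coverage, and whose age at death (completed
#' years) lies within `age_range`. Claim records outside time-to-death
#' 0..23 are dropped. Persons with a missing birth or death month are
#' excluded and counted in the attached filter report.
#'
#' @param panel An `hce_panel`.
#' @param min_coverage Minimum coverage months (default 24, i.e. two years).
#' @param age_range Closed age interval at death, default `c(65, 95)`.
#' @return The filtered `hce_panel`, with a `filter_report` attribute.
#' @export
filter_decedents <- function(panel, min_coverage = 24, age_range = c(65, 95)) {
  p <- panel$persons
  b <- month_index(p$birth_month)
  d <- month_index(p$death_month)
  w0 <- month_index(panel$meta$window_start)
  w1 <- month_index(panel$meta$window_end)

  missing_dates <- is.na(b) | is.na(d)
  age <- ifelse(missing_dates, NA, (d - b) %/% 12L)
  out_window <- !missing_dates & (d < w0 | d > w1)
  short_cov <- !missing_dates & !out_window & p$coverage_months < min_coverage
  bad_age <- !missing_dates & !out_window & !short_cov &
    (age < age_range[1] | age > age_range[2])
  keep <- !(missing_dates | out_window | short_cov | bad_age)

  report <- data.frame(
    reason = c("missing birth/death month", "death outside window",
               sprintf("coverage < %d months", min_coverage),
               sprintf("age outside [%g, %g]", age_range[1], age_range[2])),
    n = c(sum(missing_dates), sum(out_window), sum(short_cov), sum(bad_age)))

  persons <- p[keep, , drop = FALSE]
  rec <- panel$records
  rec <- rec[rec$person_id %in% persons$person_id &
               rec$ttd >= 0 & rec$ttd <= 23, , drop = FALSE]
  rownames(persons) <- rownames(rec) <- NULL
  out <- hce_panel(persons, rec, panel$meta$window_start,
                   panel$meta$window_end, panel$meta$unit)
  attr(out, "filter_report") <- report
  out
}

#' Stratify a panel by sex, age group, or both
#'
#' @param panel A filtered `hce_panel`.
#' @param scheme One of `"none"` (G = 1), `"sex"` (G = 2), `"age"` (G = 3),
#'   `"sex_age"` (G = 6).
#' @return data.frame with columns `person_id`, `stratum` (factor carrying
#'   all G levels); attributes `scheme` and `n_g` (per-stratum person
#'   counts). Empty strata are kept as levels and flagged with a warning.
#' @export
stratify <- function(panel, scheme = c("none", "sex", "age", "sex_age")) {
  scheme <- match.arg(scheme)
  p <- panel$persons
  ages <- age_at_death(panel)
  ag <- age_group_of(ages[p$person_id])
  lev_age <- c("65-75", "75-85", "85-95")
  stratum <- switch(scheme,
    none = factor(rep("all", nrow(p)), levels = "all"),
    sex = factor(p$sex, levels = c("M", "F")),
    age = factor(ag, levels = lev_age),
    sex_age = factor(paste(p$sex, ag, sep = "_"),
                     levels = paste(rep(c("M", "F"), each = 3),
                                    lev_age, sep = "_")))
  out <- data.frame(person_id = p$person_id, stratum = stratum,
                    stringsAsFactors = FALSE)
  n_g <- table(stratum)
  if (any(n_g == 0))
    warning("empty strata: ", paste(names(n_g)[n_g == 0], collapse = ", "))
  attr(out, "scheme") <- scheme
  attr(out, "n_g") <- as.integer(n_g)
  names(attr(out, "n_g")) <- names(n_g)
  out
}

#' Write a panel to a directory as persons.csv and claims.csv
#' @param panel An `hce_panel`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(panel$persons, file.path(dir, "persons.csv"),
                   row.names = FALSE)
  utils::write.csv(panel$records, file.path(dir, "claims.csv"),
                   row.names = FALSE)
  meta <- panel$meta
  writeLines(sprintf("%s=%s", names(meta), unlist(meta)),
             file.path(dir, "panel_meta.txt"))
  invisible(dir)
}

#' Read a panel written by [write_panel()]
#' @param dir Directory containing persons.csv and claims.csv.
#' @return An `hce_panel`.
#' @export
read_panel <- function(dir) {
  pf <- file.path(dir, "persons.csv")
  cf <- file.path(dir, "claims.csv")
  if (!file.exists(pf)) stop("missing persons.csv in ", dir)
  if (!file.exists(cf)) stop("missing claims.csv in ", dir)
  persons <- utils::read.csv(pf, colClasses = c(person_id = "character"))
  records <- utils::read.csv(cf, colClasses = c(person_id = "character"))
  meta <- list(window_start = "2012-11", window_end = "2018-10",
               unit = "100,000 JPY")
  mf <- file.path(dir, "panel_meta.txt")
  if (file.exists(mf)) {
    kv <- strsplit(readLines(mf), "=", fixed = TRUE)
    for (x in kv) if (length(x) == 2 && x[1] %in% names(meta))
      meta[[x[1]]] <- x[2]
  }
  hce_panel(persons, records, meta$window_start, meta$window_end, meta$unit)
}
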
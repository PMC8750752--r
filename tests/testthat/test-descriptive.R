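# Builds a panel with exact incurrence counts: n_m males / n_f females in
# one age group, of whom k_m / k_f have a CKD claim at month t.
count_panel <- function(n_m, k_m, n_f, k_f, t = 6) {
  persons <- rbind(make_persons(n_m, sex = "M", prefix = "M"),
                   make_persons(n_f, sex = "F", prefix = "F"))
  inc <- c(persons$person_id[seq_len(k_m)],
           persons$person_id[n_m + seq_len(k_f)])
  records <- make_records(inc, t, 1.0, c(0, 1, 0, 0, 0))
  hce_panel(persons, records)
}

test_that("the incurrence chi-square equals the textbook 2xK construction", {
  panel <- count_panel(10699, 691, 5154, 299)
  res <- incurrence_chisq(panel, 6, "ckd", by = "sex")
  ref <- chisq.test(matrix(c(691, 10008, 299, 4855), 2, byrow = TRUE),
                    correct = FALSE)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p_value, unname(ref$p.value))
  expect_equal(res$df, 1)
  expect_equal(res$n, 15853)
  expect_equal(res$stars, "")
  # hand value: chi-square ~ 2.57, p ~ 0.11 for these printed counts
  expect_equal(res$statistic, 2.5662, tolerance = 1e-4)

  # exactly equal rates: statistic 0, p = 1
  eq <- count_panel(100, 20, 50, 10)
  req <- incurrence_chisq(eq, 6, "ckd", by = "sex")
  expect_equal(req$statistic, 0)
  expect_equal(req$p_value, 1)
})

test_that("the chi-square holds its nominal size under the null", {
  set.seed(19)
  n_m <- 150; n_f <- 150; p0 <- 0.3
  reject <- logical(200)
  for (i in seq_len(200)) {
    panel <- count_panel(n_m, rbinom(1, n_m, p0), n_f, rbinom(1, n_f, p0))
    reject[i] <- incurrence_chisq(panel, 6, "ckd", by = "sex")$p_value < 0.05
  }
  rate <- mean(reject)
  expect_lt(abs(rate - 0.05), 2 * sqrt(0.05 * 0.95 / 200) + 1e-9)
})

test_that("rank tests on total incurred costs use the right samples and corrections", {
  # three identical age groups: Kruskal-Wallis cannot reject
  persons <- rbind(make_persons(30, age = 70, prefix = "a"),
                   make_persons(30, age = 80, prefix = "b"),
                   make_persons(30, age = 90, prefix = "c"))
  y <- rep(c(1, 2, 3, 4, 5, 6), 15)
  records <- make_records(persons$person_id, 2, rep(y[1:30], 3)[1:90],
                          c(1, 0, 0, 0, 0))
  records$total_cost <- rep(y[1:30], 3)
  panel <- hce_panel(persons, records)
  res <- total_ihce_tests(panel, 2)
  expect_equal(res$kruskal_wallis$p_value, 1)
  expect_equal(res$kruskal_wallis$df, 2)
  expect_equal(res$pairwise_age$p_bonferroni,
               pmin(res$pairwise_age$p_raw * 3, 1))
  expect_true(all(res$pairwise_age$p_bonferroni <= 1))

  # zero-claim person-months are excluded from the severity samples
  extra <- make_persons(5, age = 70, prefix = "z")
  zrec <- make_records(extra$person_id, 2, 0, c(0, 0, 0, 0, 0))
  panel2 <- hce_panel(rbind(persons, extra), rbind(records, zrec))
  expect_equal(total_ihce_tests(panel2, 2)$n, 90)
  expect_equal(total_ihce_tests(panel2, 2, include_zero_claims = TRUE)$n,
               95)
})

test_that("age-graded costs are detected by the rank tests on synthetic data", {
  sim <- small_sim(2000, seed = 61)
  panel <- filter_decedents(sim$panel)
  res <- total_ihce_tests(panel, 1)
  expect_lt(res$kruskal_wallis$p_value, 0.001)
  expect_equal(res$kruskal_wallis$stars, "***")
  expect_true(all(res$pairwise_age$p_bonferroni < 0.05))
})

test_that("occurrence correlations are phi coefficients with NA for constant columns", {
  persons <- make_persons(100)
  set.seed(20)
  ind <- matrix(0L, 100, 5)
  ind[, 1] <- rbinom(100, 1, 0.5)
  ind[, 2] <- ind[, 1]            # perfectly co-occurring pair
  ind[, 5] <- 1L                  # constant column
  ind[rowSums(ind) == 0, 4] <- 1L
  records <- make_records(persons$person_id, 0, rowSums(ind), ind)
  panel <- hce_panel(persons, records)
  expect_warning(cm <- occurrence_correlation(panel, 0), "neoplasms")
  expect_equal(cm["circulatory", "ckd"], 1)
  expect_true(all(is.na(cm["others", c("circulatory", "ckd")])))
  expect_equal(diag(cm), setNames(rep(1, 5), disease_groups()))
  expect_equal(cm, t(cm))
})

test_that("admission ratios are exact shares and ramp toward death", {
  persons <- make_persons(20)
  rec0 <- make_records(persons$person_id, 0, 1, c(1, 0, 0, 0, 0),
                       inpatient = 1L)
  rec1 <- make_records(persons$person_id, 1, 1, c(1, 0, 0, 0, 0),
                       inpatient = 0L)
  panel <- hce_panel(persons, rbind(rec0, rec1))
  ar <- admission_ratio(panel, 0:1, scheme = "none")
  expect_equal(ar$ratio[ar$ttd == 0], 1)
  expect_warning(ar1 <- admission_ratio(hce_panel(persons, rec1), 1,
                                        scheme = "none"),
                 "inpatient_flag")
  expect_equal(ar1$ratio, 0)

  sim <- small_sim(2000, seed = 62)
  ar <- admission_ratio(sim$panel, c(0, 6, 12), scheme = "none")
  r <- setNames(ar$ratio, ar$ttd)
  expect_gt(r[["0"]], r[["6"]])
  expect_gt(r[["6"]], r[["12"]])
})
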
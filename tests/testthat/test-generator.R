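test_that("generation is deterministic in the seed and conserves totals", {
  s1 <- generate_panel(generator_config(n_persons = 150), seed = 9,
                       keep_components = TRUE)
  s2 <- generate_panel(generator_config(n_persons = 150), seed = 9,
                       keep_components = TRUE)
  expect_identical(s1$panel$records, s2$panel$records)
  expect_identical(s1$panel$persons, s2$panel$persons)
  s3 <- generate_panel(generator_config(n_persons = 150), seed = 10)
  expect_false(identical(s1$panel$records$total_cost,
                         s3$panel$records$total_cost))

  comp <- attr(s1$panel$records, "components")
  ind <- as.matrix(s1$panel$records[indicator_columns()])
  expect_identical(s1$panel$records$total_cost, rowSums(comp * ind))
  expect_true(all(comp[ind == 0] == 0))
})

test_that("degenerate occurrence configurations behave exactly", {
  zero <- lapply(disease_groups(),
                 function(d) c(base = 0, amp = 0, tau = 1))
  names(zero) <- disease_groups()
  sim <- generate_panel(generator_config(n_persons = 100,
                                         occurrence = zero), seed = 3)
  expect_true(all(sim$panel$records$total_cost == 0))
  expect_true(all(as.matrix(sim$panel$records[indicator_columns()]) == 0))
})

test_that("sample means converge to the configured component mean", {
  # single always-occurring disease: law of large numbers at one month
  occ <- lapply(disease_groups(), function(d) c(base = 0, amp = 0, tau = 1))
  names(occ) <- disease_groups()
  occ$circulatory <- c(base = 1, amp = 0, tau = 1)
  cfg <- generator_config(n_persons = 2000, occurrence = occ,
                          cost_age_factor = c("65-75" = 1, "75-85" = 1,
                                              "85-95" = 1))
  sim <- generate_panel(cfg, seed = 21)
  rec <- sim$panel$records[sim$panel$records$ttd == 3, ]
  m_true <- sim$true_params$m[sim$true_params$ttd == 3 &
                                sim$true_params$disease == "circulatory"][1]
  s_true <- m_true / 3
  expect_lt(abs(mean(rec$total_cost) - m_true),
            3 * s_true / sqrt(nrow(rec)))
})

test_that("stratum apportionment matches the configured shares exactly", {
  cfg <- generator_config(n_persons = 10000)
  counts <- hcedecomp:::apportion(cfg$n_persons, cfg$stratum_shares)
  expect_equal(unname(counts[["M_65-75"]]), 870)
  expect_equal(sum(counts), 10000)
  odd <- hcedecomp:::apportion(99991L, cfg$stratum_shares)
  expect_equal(sum(odd), 99991L)
  expect_error(generator_config(n_persons = 59), ">= 60")
})

test_that("death-month attenuation halves month-zero parameters", {
  tp <- true_parameters(generator_config())
  m65 <- tp[tp$stratum == "M_65-75", ]
  for (d in disease_groups()) {
    sub <- m65[m65$disease == d, ]
    m0 <- sub$m[sub$ttd == 0]; m1 <- sub$m[sub$ttd == 1]
    p0 <- sub$p[sub$ttd == 0]; p1 <- sub$p[sub$ttd == 1]
    # flat trajectories: exactly half the adjacent month; decaying ones:
    # half the (slightly larger) month-zero formula value
    expect_gte(m0 / m1, 0.5 - 1e-12)
    expect_lte(m0 / m1, 0.5 * exp(1 / 3) + 1e-12)
    expect_gte(p0 / p1, 0.5 - 1e-12)
  }
  flat <- m65[m65$disease == "circulatory", ]
  expect_equal(flat$m[flat$ttd == 0], 0.5 * flat$m[flat$ttd == 1])
})

test_that("default trajectories honor the calibrated orderings", {
  tp <- true_parameters(generator_config())
  resp <- tp[tp$stratum == "F_85-95" & tp$disease == "respiratory", ]
  expect_gt(resp$p[resp$ttd == 1] / resp$p[resp$ttd == 12], 1.4)
  expect_lt(resp$p[resp$ttd == 1] / resp$p[resp$ttd == 12], 1.6)
  expect_gt(resp$m[resp$ttd == 1] / resp$m[resp$ttd == 12], 3.0)
  expect_lt(resp$m[resp$ttd == 1] / resp$m[resp$ttd == 12], 4.0)
  # CKD costliest, circulatory cheapest, in every stratum and month
  by_cell <- split(tp, list(tp$stratum, tp$ttd))
  expect_true(all(vapply(by_cell, function(s)
    s$m[s$disease == "ckd"] == max(s$m) &&
      s$m[s$disease == "circulatory"] == min(s$m), TRUE)))
  # older strata are uniformly cheaper
  for (d in disease_groups()) {
    young <- tp$m[tp$stratum == "M_65-75" & tp$disease == d]
    old <- tp$m[tp$stratum == "M_85-95" & tp$disease == d]
    expect_true(all(old <= young))
  }
  # non-increasing mean trajectories in t for the rising diseases
  for (d in c("neoplasms", "respiratory", "others")) {
    m <- tp$m[tp$stratum == "F_65-75" & tp$disease == d]
    expect_true(all(diff(m[-1]) <= 0))  # t = 1..23; t = 0 is attenuated
  }
})

test_that("negative component draws are rare under the redraw policy", {
  sim <- generate_panel(generator_config(n_persons = 2000), seed = 13)
  frac <- attr(sim$panel$records, "n_redrawn") /
    attr(sim$panel$records, "n_component_draws")
  expect_lt(frac, 0.002)
  expect_true(all(sim$panel$records$total_cost >= 0))
})

test_that("occurrences are near-independent by default and the copula injects the configured association", {
  sim <- generate_panel(generator_config(n_persons = 5000), seed = 17)
  cm <- occurrence_correlation(sim$panel, 6)
  off <- cm[upper.tri(cm)]
  expect_true(all(abs(off) < 0.05))

  dep <- generate_panel(generator_config(n_persons = 5000,
                                         copula_rho = 0.30), seed = 18)
  cmd <- occurrence_correlation(dep$panel, 6)
  target <- phi_from_latent_rho(0.30, 0.50, 0.06)
  expect_lt(abs(cmd["circulatory", "ckd"] - target), 0.03)
  expect_lt(abs(cmd["circulatory", "ckd"] - 0.11), 0.04)
  # other pairs stay uncorrelated
  expect_true(all(abs(cmd[upper.tri(cmd)][-1]) < 0.05 |
                    is.na(cmd[upper.tri(cmd)][-1])))
})

test_that("empirical summaries agree with the generating parameters", {
  sim <- generate_panel(generator_config(n_persons = 4000), seed = 23)
  es <- empirical_summary(sim$panel, "sex_age")
  expect_equal(sum(es$subjects$n), 4000)
  expect_equal(es$subjects$ratio,
               unname(hcedecomp:::apportion(
                 4000, generator_config()$stratum_shares) / 4000),
               tolerance = 1e-12)

  tp <- sim$true_params
  merged <- merge(es$incurrence,
                  tp[c("stratum", "ttd", "disease", "p", "m")],
                  by = c("stratum", "ttd", "disease"))
  n_g <- stats::setNames(es$subjects$n, es$subjects$stratum)
  prop <- merged$count / n_g[merged$stratum]
  sd3 <- 3 * sqrt(merged$p * (1 - merged$p) / n_g[merged$stratum])
  expect_gt(mean(abs(prop - merged$p) <= sd3), 0.97)
  expect_true(all(abs(prop - merged$p) <= 5 * pmax(sd3 / 3, 1e-3)))

  # mean per-capita total = sum_d p*m (independence identity), within 3 sd
  rec <- sim$panel$records
  for (t in c(1, 12)) {
    sub <- tp[tp$ttd == t, ]
    y <- rec$total_cost[rec$ttd == t]
    se <- stats::sd(y) / sqrt(length(y))
    expect_lt(abs(mean(y) - sum(sub$p * sub$m * n_g[sub$stratum]) /
                    sum(n_g)), 3 * se)
  }
})
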
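# hcedecomp

Bayesian disease-group decomposition of end-of-life health care
expenditures from decedent claims panels.

## The problem

Monthly reimbursement claims record each person's **total** expenditure
plus the ICD-10 codes billed that month — not how much of the total belongs
to which disease. For decedents observed over their last two years, this
package decomposes monthly totals into five ICD-10 disease groups
(circulatory I00–I99, chronic kidney disease N18, neoplasms C00–D48,
respiratory J00–J99, others), by stratum (sex, age group at death, or
both) and by time to death *t* = 0..23 months, replacing the subjective
"primary disease" attribution with an objective model-based allocation.

It is a two-part (frequency–severity) model:

* **Frequency** — the occurrence proportion
  `F_gtd = (1/N_g) Σ_i I_igtd`, an exact count ratio over the full stratum
  membership.
* **Severity** — the observed monthly total is a sum of latent Normal
  disease components over the active indicators,

  ```
  Y_igt = Σ_d Y_igtd · I_igtd,   Y_igtd ~ Normal(μ_gtd, σ²_gtd)
  ```

  with weakly informative priors `μ ~ Normal(0, 20²)`,
  `σ² ~ LogNormal(0, 10²)` (costs in 100,000-JPY units), fitted per
  (stratum, month) cell by a compiled adaptive Metropolis-within-Gibbs
  sampler: 4 chains × 6000 iterations, 2000 warm-up, convergence declared
  when split-chain R̂ of every parameter and the log posterior is ≤ 1.05.
* **Aggregation** — per-capita expenditures
  `AHCE_gtd = μ̂_gtd · F_gtd` and their two-year sums
  `CAHCE_gd = Σ_t AHCE_gtd`, audited by reconstructing actual monthly
  totals (error rate `(actual − estimated)/actual × 100`). Stratum
  contrasts are tested by directional Bayes factors on the posterior
  draws, binned on the 1/3/20/150 evidence scale.

Real panels of this kind are licensed and non-public, so the package ships
a calibrated synthetic decedent-panel generator with known ground truth
(occurrence and cost trajectories rising toward death, costs declining
with age, a half-month attenuation in the month of death, near-independent
disease occurrences) used by all shipped checks. See the vignette
`vignettes/expenditure-decomposition.Rmd` for the model, calibration and
limitations.

## Worked example

```r
library(hcedecomp)

sim   <- generate_panel(generator_config(n_persons = 2000), seed = 2026)
panel <- filter_decedents(sim$panel)
fit   <- hce_fit(panel, scheme = "age", seed = 2026)
fit
#> Two-part (frequency-severity) expenditure decomposition
#> Scheme: age (G = 3), N = 2000 persons, 72 cells fit
#> MCMC: 4 chains x 6000 iter (2000 warm-up); max R-hat 1.0180 (converged)

fit$cells[["65-75:1"]]     # one cell: ages 65-75, one month before death
#> Severity-model cell fit: 247 records, 5 disease groups, 16000 draws
#> max R-hat 1.0180 (converged)
#>      disease      mean         sd      q2.5     q97.5   rhat
#>  circulatory 0.6094667 0.05514006 0.5085762 0.7295144 1.0008
#>          ckd 3.4128136 0.38296396 2.6665235 4.1928107 1.0010
#>    neoplasms 2.8255151 0.13685126 2.5526944 3.0962866 1.0002
#>  respiratory 2.6187093 0.12457908 2.3675624 2.8662307 1.0026
#>       others 2.0508153 0.08903360 1.8752148 2.2254929 1.0026
```

The posterior component means are in 100,000-JPY units: a month before
death, a CKD claim carries about 340,000 JPY of the monthly total, while a
circulatory claim carries only about 61,000 JPY. Cumulative per-capita
expenditure over the last two years, by age group:

```r
subset(predict(fit, type = "cahce"), disease == "neoplasms")
#>    stratum   disease     cahce n_months
#> 3    65-75 neoplasms 13.476306       24
#> 8    75-85 neoplasms 11.144609       24
#> 13   85-95 neoplasms  9.314573       24
```

— about 1.35M JPY per capita for neoplasms in the youngest group,
declining with age. The reconstruction audit compares actual and estimated
totals per month:

```r
head(as.data.frame(reconstruction_report(fit))[
  c("ttd", "actual", "estimated", "error_rate_display")], 4)
#>   ttd   actual estimated error_rate_display
#> 1   0 2120.716  2120.776              0.00%
#> 2   1 6921.647  6921.314              0.00%
#> 3   2 5690.736  5690.518              0.01%
#> 4   3 4896.343  4896.696             -0.01%

bf_table(fit, "65-75", "85-95", ttd = 1)
#>    stratum_pair ttd     disease      bf display stars    evidence sign
#> 1 65-75 - 85-95   1 circulatory     Inf   > 150   *** very_strong    1
#> 2 65-75 - 85-95   1         ckd 61.7451    61.7    **      strong    1
#> 3 65-75 - 85-95   1   neoplasms     Inf   > 150   *** very_strong    1
#> 4 65-75 - 85-95   1 respiratory     Inf   > 150   *** very_strong    1
#> 5 65-75 - 85-95   1      others     Inf   > 150   *** very_strong    1
```

The Bayes factors say the younger group's component costs exceed the
oldest group's with at least strong evidence in every disease group —
exactly the age gradient the generator encodes. `run_pipeline()` wraps the
whole sequence and writes `frequency.csv`, `posterior.csv`, `ahce.csv`,
`cahce.csv`, `bf.csv`, `reconstruction.csv` and a JSON run report.

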
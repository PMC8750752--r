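# Small hand-built panels for unit tests.

make_persons <- function(n, sex = "M", age = 70, death = "2018-01",
                         coverage = 24, prefix = "X") {
  death_idx <- hcedecomp:::month_index(death)
  data.frame(
    person_id = sprintf("%s%04d", prefix, seq_len(n)),
    sex = rep_len(sex, n),
    birth_month = hcedecomp:::month_label(death_idx - rep_len(age, n) * 12L),
    death_month = rep_len(death, n),
    coverage_months = rep_len(coverage, n),
    stringsAsFactors = FALSE)
}

# One record per person at a single ttd; ind is a 0/1 matrix (n x 5) or a
# vector recycled across the five groups.
make_records <- function(person_ids, ttd, total_cost, ind,
                         inpatient = 0L) {
  n <- length(person_ids)
  if (is.vector(ind)) ind <- matrix(rep(ind, each = n), n, 5)
  rec <- data.frame(person_id = person_ids, ttd = ttd,
                    total_cost = total_cost, stringsAsFactors = FALSE)
  rec[indicator_columns()] <- as.data.frame(ind)
  rec$inpatient_flag <- rep_len(inpatient, n)
  rec
}

small_sim <- function(n = 200, seed = 5, ...) {
  generate_panel(generator_config(n_persons = n, ...), seed = seed)
}

fast_mcmc <- function() hce_mcmc(chains = 2, iter = 1200, warmup = 400)
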
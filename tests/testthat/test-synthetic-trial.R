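test_that("design layout is balanced", {
  d <- crossover_design()
  expect_equal(nrow(d), 24)
  # each (treatment, period) cell has 6 cows
  expect_true(all(table(d$treatment, d$period) == 6))
  # each cow appears once per period with opposite treatments
  per_cow <- split(d, d$cow_id)
  for (cd in per_cow) {
    expect_equal(sort(cd$period), c(1L, 2L))
    expect_equal(sort(unique(cd$treatment)), c("CON", "HEMP"))
  }
  # blocks split 2/2 across sequences
  expect_true(all(table(unique(d[c("cow_id", "block", "sequence")])$block,
                        unique(d[c("cow_id", "block",
                                   "sequence")])$sequence) == 2))
  expect_error(crossover_design(cows_per_block = 3))
  expect_error(crossover_design(washout_d = -1))
})

test_that("simulation is deterministic and honours the linear truth", {
  a <- simulate_trial(seed = 5)
  b <- simulate_trial(seed = 5)
  expect_identical(a$animal_days, b$animal_days)
  expect_identical(a$excreta, b$excreta)
  expect_identical(a$truth, b$truth)

  # noise-free: every HEMP cow-day DMI = baseline + effect exactly
  tr <- simulate_trial(effects = noise_free_effects(-1.9), seed = 1)
  ad <- tr$animal_days
  dmi_eff <- noise_free_effects()$responses$dmi
  blk <- rep_len(dmi_eff$block, 3)
  expected <- 17.4 - 1.9 * (ad$treatment == "HEMP") +
    dmi_eff$period * (ad$period == 2) + blk[ad$block]
  expect_equal(ad$dmi_kg_d, expected)
  expect_equal(tr$n_truncated, 0L)
})

test_that("treatment-effect recovery over replicates is unbiased", {
  eff <- effect_spec()
  eff$responses$dmi <- response_spec(17.4, treatment = -1.9,
                                     cow_sd = 1.5, residual_sd = 0.8)
  # keep milk N output fixed so the N ledger stays feasible at low intakes
  eff$responses$milk <- response_spec(20)
  eff$responses$protein_pct <- response_spec(3.6)
  des <- crossover_design()
  set.seed(31)
  diffs <- vapply(1:200, function(r) {
    tr <- simulate_trial(des, eff, seed = sample.int(1e8, 1))
    cm <- tapply(tr$truth$dmi_kg_d, tr$truth$treatment, mean)
    cm[["HEMP"]] - cm[["CON"]]
  }, 0)
  # MC error of the mean of cell-mean differences
  expect_lt(abs(mean(diffs) + 1.9), 4 * sd(diffs) / sqrt(length(diffs)))
})

test_that("negative generated yields are truncated and counted", {
  # near-dry cows: milk draws cross zero and must be clamped (milk keeps
  # the N ledger feasible, unlike near-zero intake which is rejected)
  eff <- effect_spec()
  eff$responses$milk <- response_spec(0.5, cow_sd = 0, residual_sd = 2)
  tr <- suppressWarnings(simulate_trial(effects = eff, seed = 3))
  expect_gt(tr$n_truncated, 0)
  expect_true(all(tr$animal_days$milk_kg_d >= 0))

  # near-zero intake makes the N ledger infeasible and is rejected loudly
  eff2 <- effect_spec()
  eff2$responses$dmi <- response_spec(0.1, cow_sd = 0, residual_sd = 0)
  expect_error(simulate_trial(effects = eff2, seed = 3),
               "infeasible N ledger")
})

test_that("excreta construction attains the stated truths exactly", {
  # CP degradability 0.641, noise off -> fecal N = 0.359 x intake N
  eff <- noise_free_effects()
  eff$digestibility$cp <- c(0.641, 0.641)
  tr <- simulate_trial(effects = eff, seed = 2)
  truth <- tr$truth
  expect_equal(truth$n_feces_g_d, 0.359 * truth$n_intake_g_d,
               tolerance = 1e-12)

  # zero OM digestibility -> fecal OM equals OM intake
  feed <- feed_spec()
  days <- tr$animal_days[tr$animal_days$cow_id == "cow01" &
                           tr$animal_days$period == 1, ]
  # (in)digestible mass bookkeeping: near-zero OM digestibility forces
  # near-total DM indigestibility too, else fecal ash would go negative
  ex0 <- simulate_excreta(days, feed,
                          c(dm = 0.05, om = 1e-3, energy = 0.5, cp = 0.6),
                          urine_kg_d = 11.5, n_retention_g_d = 0)
  om_intake <- days$dmi_kg_d * feed$om_fraction
  fec_om <- ex0$feces_fresh_kg * ex0$feces_dm_fraction *
    (1 - ex0$feces_ash_g_per_kg_dm / 1000)
  expect_equal(fec_om, om_intake * (1 - 1e-3), tolerance = 1e-9)
  expect_error(
    simulate_excreta(days, feed,
                     c(dm = 0.5, om = 1e-3, energy = 0.5, cp = 0.6),
                     urine_kg_d = 11.5, n_retention_g_d = 0),
    "negative fecal ash")

  # random truths on many cow-days round-trip through the balance stage
  set.seed(8)
  for (i in 1:25) {
    dig <- c(dm = runif(1, 0.55, 0.75), om = runif(1, 0.6, 0.78),
             energy = runif(1, 0.55, 0.75), cp = runif(1, 0.55, 0.75))
    # feasibility: fecal ash must be non-negative
    if ((1 - dig["dm"]) < (1 - dig["om"]) * feed$om_fraction) next
    ex <- simulate_excreta(days, feed, dig, urine_kg_d = 11,
                           n_retention_g_d = 10)
    bal <- period_summary(days, ex, feed)
    expect_equal(bal$dig_dm, unname(dig["dm"]), tolerance = 1e-12)
    expect_equal(bal$dig_om, unname(dig["om"]), tolerance = 1e-12)
    expect_equal(bal$dig_energy, unname(dig["energy"]), tolerance = 1e-12)
    expect_equal(bal$cp_degradability, unname(dig["cp"]), tolerance = 1e-12)
  }

  # infeasible ledger is rejected with a diagnostic
  expect_error(
    simulate_excreta(days, feed,
                     c(dm = 0.65, om = 0.67, energy = 0.65, cp = 0.65),
                     urine_kg_d = 11, n_retention_g_d = 1e4),
    "infeasible N ledger")
})
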
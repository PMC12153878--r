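test_that("CO2 partition and mRQ follow the printed stoichiometry", {
  expect_equal(fermentative_co2(0), 0)
  expect_equal(fermentative_co2(511), 868.7)
  expect_equal(fermentative_co2(100), 170)
  expect_error(fermentative_co2(-1), ">= 0")

  expect_equal(metabolic_co2(1000, 0), 1000)
  expect_equal(metabolic_co2(5500, 511), 4631.3)
  expect_error(metabolic_co2(100, 100), "exceeds")

  expect_equal(metabolic_rq(1000, 1000), 1)
  expect_equal(metabolic_rq(4631.3, 5000), 0.92626)
  expect_equal(metabolic_rq(0, 5000), 0)
  expect_error(metabolic_rq(100, 0), "> 0")
})

test_that("oxidation and heat production match the arithmetic oracle", {
  # printed examples
  expect_equal(as.numeric(fat_oxidation(1000, 1000, 0)), 0)
  expect_equal(as.numeric(fat_oxidation(1000, 900, 0)), 167)
  expect_warning(f <- fat_oxidation(1000, 900, 100), "lipogenesis")
  expect_equal(as.numeric(f), -25)
  expect_equal(attr(f, "flag"), "negative")

  expect_equal(as.numeric(carbohydrate_oxidation(0, 0, 0)), 0)
  expect_equal(as.numeric(carbohydrate_oxidation(1000, 1000, 0)), 1340)
  expect_equal(as.numeric(carbohydrate_oxidation(5000, 4631.3, 93.2)),
               oracle_cox(5000, 4631.3, 93.2)) # = 4754.931
  expect_equal(oracle_cox(5000, 4631.3, 93.2), 4754.931)

  expect_equal(heat_production(0, 0, 0, 0), 0)
  expect_equal(heat_production(1, 0, 0, 0), 16.18)
  expect_equal(heat_production(5000, 5500, 511, 93.2), 106842.862)

  # property: oracle equivalence on random tuples
  set.seed(1)
  for (i in 1:50) {
    o2 <- runif(1, 3000, 9000); co2 <- runif(1, 3000, 9000)
    ch4 <- runif(1, 0, co2 / 1.7); nu <- runif(1, 0, 200)
    mco2 <- metabolic_co2(co2, ch4)
    expect_equal(suppressWarnings(as.numeric(fat_oxidation(o2, mco2, nu))),
                 oracle_fox(o2, mco2, nu), tolerance = 1e-12)
    expect_equal(heat_production(o2, co2, ch4, nu),
                 oracle_hp(o2, co2, ch4, nu), tolerance = 1e-12)
  }

  # linearity of the Brouwer form
  x <- c(5000, 5500, 511, 93.2)
  for (a in c(0, 0.5, 2, 7)) {
    expect_equal(heat_production(a * x[1], a * x[2], a * x[3], a * x[4]),
                 a * heat_production(x[1], x[2], x[3], x[4]))
  }
})

test_that("partition conservation holds for every processed day", {
  set.seed(42)
  for (i in 1:20) {
    co2 <- runif(1, 4000, 8000); ch4 <- runif(1, 100, co2 / 1.7)
    expect_equal(metabolic_co2(co2, ch4) + fermentative_co2(ch4), co2)
  }
})

test_that("trace integration inverts the measurement geometry", {
  dC <- 511 / (24 * 30000) # constant CH4 excess at 30 m3/h
  tt <- seq(0, 48, by = 0.1)
  tr <- chamber_trace(tt, o2_in = 0.2095, o2_out = 0.2095,
                      co2_in = 0.0004, co2_out = 0.0004,
                      ch4_in = 0, ch4_out = dC,
                      airflow_m3_h = 30, recovery = 1)
  v <- integrate_gas_exchange(tr)
  expect_equal(v$ch4_l_d, 511, tolerance = 1e-9)
  expect_equal(v$o2_l_d, 0)
  expect_equal(v$co2_l_d, 0)
  expect_true(v$valid)

  tr997 <- chamber_trace(tt, 0.2095, 0.2095, 0.0004, 0.0004, 0, dC,
                         airflow_m3_h = 30, recovery = 0.997)
  expect_equal(integrate_gas_exchange(tr997)$ch4_l_d, 511 / 0.997,
               tolerance = 1e-9) # 512.5
})

test_that("gaps flag the day invalid and windows are validated", {
  tt <- c(seq(0, 10, by = 0.1), seq(11, 48, by = 0.1)) # 60-min hole
  tr <- chamber_trace(tt, 0.2095, 0.2095, 0.0004, 0.0005, 0, 1e-4,
                      airflow_m3_h = 30)
  v <- integrate_gas_exchange(tr)
  expect_false(v$valid)
  expect_match(v$flags, "gap")
  expect_error(integrate_gas_exchange(tr, window = c(0, 72)),
               "not covered")
  # negative integrated production flagged, not zeroed
  tr2 <- chamber_trace(seq(0, 48, 0.1), 0.2095, 0.2095, 0.0004, 0.0004,
                       ch4_in = 1e-4, ch4_out = 0, airflow_m3_h = 30,
                       recovery = 1)
  v2 <- integrate_gas_exchange(tr2)
  expect_lt(v2$ch4_l_d, 0)
  expect_match(v2$flags, "negative_ch4")
})

test_that("summarize_day normalizes to DMI and metabolic weight", {
  gd <- summarize_day(o2_l_d = 6640, co2_l_d = 6975, ch4_l_d = 511,
                      nu_g_d = 93.2, dmi_kg = 17.6, mbw = 124,
                      ecm_kg = 29.5)
  expect_equal(gd$ch4_per_dmi_l_kg, 511 / 17.6) # 29.03
  expect_equal(gd$mco2_l_d + gd$co2_ferm_l_d, gd$co2_l_d)
  expect_equal(gd$hp_kj_d, oracle_hp(6640, 6975, 511, 93.2))
  expect_equal(gd$hp_per_mbw_kj, gd$hp_kj_d / 124)
  expect_equal(summarize_day(6640, 6975, 511, 93.2, 17.6, 124,
                             ecm_kg = 29.5)$ch4_per_ecm_l_kg, 511 / 29.5)
  expect_error(summarize_day(6640, 6975, 511, 93.2, dmi_kg = 0, mbw = 124),
               "dmi")
  # the printed-scale spot check: HP 140740 kJ/d over mBW 124
  expect_equal(140740 / 124, 1135, tolerance = 1e-4)
})
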
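test_that("metabolic body weight", {
  expect_equal(metabolic_bw(1), 1)
  expect_equal(metabolic_bw(625), 125) # 5^4 ^ 0.75 = 5^3
  expect_error(metabolic_bw(0), "> 0")
})

test_that("ECM and milk energy match the printed formulas", {
  expect_equal(ecm(0, 4, 3.5), 0)
  expect_equal(ecm(29.8, 4.06, 3.63), oracle_ecm(29.8, 4.06, 3.63))
  expect_equal(ecm(29.8, 4.06, 3.63), 30.4823, tolerance = 1e-4)
  expect_equal(ecm(1, 0, 0), 1.05 / 3.28)
  # degree-1 homogeneity in yield
  expect_equal(ecm(2 * 29.8, 4.06, 3.63), 2 * ecm(29.8, 4.06, 3.63))

  expect_equal(milk_energy(40.6, 36.3, 49.9, 0), 0)
  expect_equal(milk_energy(0, 0, 0, 10), 0)
  expect_equal(milk_energy(40.6, 36.3, 49.9, 29.8),
               oracle_milk_energy(40.6, 36.3, 49.9, 29.8))
  expect_equal(milk_energy(40.6, 36.3, 49.9, 29.8), 97.2166,
               tolerance = 1e-4)
})

test_that("MEI and energy balance", {
  expect_equal(mei(11.45, 17.6), 201.52)
  expect_equal(mei(11.45, 0), 0)
  expect_error(mei(-1, 10), ">= 0")

  expect_equal(as.numeric(energy_balance(0, 0, 0)), 0)
  expect_equal(as.numeric(energy_balance(201.52, 140.74, 29.5)),
               201.52 - 140.74 - 29.5 * 3.14) # -31.85
  # the literal printed factor flips the sign and is flagged
  eb_slip <- energy_balance(201.52, 140.74, 29.5,
                            ecm_energy_mj_per_kg = 0.00314)
  expect_equal(as.numeric(eb_slip), 60.68737, tolerance = 1e-5)
  expect_match(attr(eb_slip, "factor_note"), "implausible")
})

test_that("N partition, NUE, EUE", {
  np <- n_partition(dmi_kg = 17.6, feed_n_g_kg_dm = 24.67,
                    milk_kg = 29.8, protein_pct = 3.63,
                    feces_dm_kg = 5.5, feces_n_g_kg_dm = 28,
                    urine_kg = 11.5, urine_n_g_kg = 8.10)
  expect_equal(np$n_intake_g_d, 17.6 * 24.67) # 434.2
  expect_equal(np$n_milk_g_d, 29.8 * 36.3 / 6.38) # 169.55
  expect_equal(np$n_urine_g_d, 93.15)
  expect_equal(np$n_feces_g_d, 154)

  # detached urinal: urinary N undefined and flagged
  np2 <- n_partition(17.6, 24.67, 29.8, 3.63, 5.5, 28,
                     urine_kg = NA, urine_n_g_kg = 8.1)
  expect_true(is.na(np2$n_urine_g_d))
  expect_equal(np2$flag, "urine_missing")

  expect_equal(nue(169.55, 434.1), 169.55 / 434.1) # 0.3906
  expect_equal(nue(0, 100), 0)
  expect_error(nue(10, 0), "> 0")
  expect_equal(eue(97.22, 201.52), 97.22 / 201.52) # 0.4824
  expect_error(eue(10, 0), "> 0")
})

test_that("apparent digestibility", {
  expect_equal(apparent_digestibility(10, 0), 1)
  expect_equal(apparent_digestibility(10, 10), 0)
  expect_equal(apparent_digestibility(434.1, 155.8), 0.64110,
               tolerance = 1e-4)
  # scale invariance
  expect_equal(apparent_digestibility(434.1, 155.8),
               apparent_digestibility(4.341, 1.558))
  expect_error(apparent_digestibility(0, 1), "> 0")
})

test_that("period_summary averages the collection window", {
  feed <- feed_spec()
  one_day <- data.frame(dmi_kg_d = 17.6, milk_kg_d = 29.8, fat_pct = 4.06,
                        protein_pct = 3.63, lactose_pct = 4.99,
                        bw_kg = 625)
  ex_one <- simulate_excreta(cbind(one_day, cow_id = "c", period = 1L,
                                   treatment = "HEMP", day = 15L),
                             feed, c(dm = 0.66, om = 0.67, energy = 0.65,
                                     cp = 0.64),
                             urine_kg_d = 11.5, n_retention_g_d = 15)
  four_same <- one_day[rep(1, 4), ]
  ex_four <- ex_one[rep(1, 4), ]
  s1 <- period_summary(one_day, ex_one, feed)
  s4 <- period_summary(four_same, ex_four, feed)
  expect_equal(s1[setdiff(names(s1), "flag")],
               s4[setdiff(names(s4), "flag")])

  # distinct days -> arithmetic means drive every quantity
  four <- one_day[rep(1, 4), ]
  four$dmi_kg_d <- c(16, 17, 18, 19)
  ex4 <- simulate_excreta(cbind(four, cow_id = "c", period = 1L,
                                treatment = "HEMP", day = 15:18),
                          feed, c(dm = 0.66, om = 0.67, energy = 0.65,
                                  cp = 0.64),
                          urine_kg_d = 11.5, n_retention_g_d = 15)
  s <- period_summary(four, ex4, feed)
  expect_equal(s$dmi_kg_d, 17.5)
  expect_equal(s$mei_mj_d, mei(feed$me_mj_per_kg_dm, 17.5))
  expect_equal(s$dig_dm, 0.66, tolerance = 1e-12)

  expect_error(period_summary(one_day[0, ], ex_one, feed), "no valid days")
})
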
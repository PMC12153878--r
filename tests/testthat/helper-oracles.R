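# Independently coded oracles. These restate the arithmetic directly from
# the printed formulas and never call the implementation under test.

oracle_fox <- function(o2, mco2, nu) 1.67 * o2 - 1.67 * mco2 - 1.92 * nu
oracle_cox <- function(o2, mco2, nu) 4.55 * mco2 - 3.21 * o2 - 2.87 * nu
oracle_hp <- function(o2, co2, ch4, nu) {
  16.18 * o2 + 5.02 * co2 - 2.17 * ch4 - 5.99 * nu
}
oracle_ecm <- function(milk, fat, prot) {
  milk * ((0.38 * fat + 0.21 * prot + 1.05) / 3.28)
}
oracle_milk_energy <- function(fat, prot, lact, milk) {
  (0.038 * fat + 0.024 * prot + 0.017 * lact) * milk
}

# studentized-range tail probability by direct numerical integration of the
# range distribution for k equal-variance means (independent route from
# stats::ptukey, which ruminbal uses internally)
oracle_tukey_p <- function(q, k, df) {
  inner <- function(x) {
    # P(range of k std normals <= q*s) given scaled sd s = x
    f <- function(z) k * stats::dnorm(z) *
      (stats::pnorm(z) - stats::pnorm(z - q * x))^(k - 1)
    stats::integrate(f, -Inf, Inf, rel.tol = 1e-10)$value
  }
  fchi <- function(x) { # density of sqrt(chi2_df/df)
    stats::dchisq(x^2 * df, df) * 2 * x * df
  }
  1 - stats::integrate(function(x) {
    vapply(x, function(xi) inner(xi) * fchi(xi), 0)
  }, 0, Inf, rel.tol = 1e-8)$value
}

# fast sufficient-statistic Monte Carlo of the crossover TOST procedure
mc_tost_power <- function(n, cv, theta0, limits, alpha, reps, seed) {
  set.seed(seed)
  sw <- sqrt(log(1 + cv^2))
  df <- n - 2
  se <- sw * sqrt(2 / n)
  est <- stats::rnorm(reps, log(theta0), se)
  se_hat <- se * sqrt(stats::rchisq(reps, df) / df)
  tcrit <- stats::qt(1 - alpha, df)
  mean((est - log(limits[1])) / se_hat > tcrit &
         (est - log(limits[2])) / se_hat < -tcrit)
}

mc_ttest_power <- function(n, d, alpha, reps, seed) {
  set.seed(seed)
  df <- 2 * n - 2
  tt <- stats::rnorm(reps, d * sqrt(n / 2), 1) /
    sqrt(stats::rchisq(reps, df) / df)
  mean(abs(tt) > stats::qt(1 - alpha / 2, df))
}

# null / effect crossover replicate generator for calibration tests
sim_crossover_response <- function(design, effect = 0, cow_sd = 1.5,
                                   residual_sd = 0.8, baseline = 17.4) {
  d <- design
  cow_idx <- as.integer(factor(d$cow_id))
  cow_eff <- stats::rnorm(max(cow_idx), 0, cow_sd)[cow_idx]
  trt <- attr(design, "treatments")[1]
  d$y <- baseline + effect * (d$treatment == trt) + cow_eff +
    stats::rnorm(nrow(d), 0, residual_sd)
  d
}

noise_free_effects <- function(dmi_treatment = -1.9) {
  eff <- effect_spec()
  for (nm in names(eff$responses)) {
    eff$responses[[nm]]$cow_sd <- 0
    eff$responses[[nm]]$residual_sd <- 0
  }
  eff$responses$dmi$treatment <- dmi_treatment
  eff$emission_cow_sd[] <- 0
  eff$emission_residual_sd[] <- 0
  eff$digestibility_cow_sd <- 0
  eff$diurnal_amplitude <- 0
  eff
}
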
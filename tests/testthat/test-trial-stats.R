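test_that("robust z scores flag gross outliers only", {
  # median = 1 and raw MAD = 0 here, so the off-median point is infinitely
  # many MADs out: flagged, with the degenerate-scale warning
  expect_warning(fl <- robust_z_outliers(c(1, 1, 1, 1, 100), 3.5),
                 "degenerate")
  expect_equal(which(fl), 5L)

  y <- c(10, 11, 9, 10.5, 9.5, 30)
  fy <- robust_z_outliers(y, threshold = 3.5)
  med <- median(y); madr <- median(abs(y - med))
  z_oracle <- (y - med) / (1.4826 * madr)
  expect_equal(attr(fy, "z"), z_oracle)
  expect_equal(which(fy), 6L)

  expect_warning(fc <- robust_z_outliers(rep(2, 5)), "degenerate")
  expect_false(any(fc))
  expect_error(robust_z_outliers(c(1, 2)), ">= 3")

  set.seed(1)
  fl_norm <- robust_z_outliers(rnorm(1e4), threshold = 3.5)
  expect_lt(mean(fl_norm), 0.01)
})

test_that("intake exclusion rule is strict at the boundary", {
  rec <- data.frame(cow_id = c("a", "b", "c"), period = 1L,
                    dmi_kg_d = c(10, 17.6, 12.4), mbw_kg075 = 124)
  out <- exclusion_filter(rec)
  expect_equal(out$exclusions$cow_id, "a") # 10/124 = 0.0806 < 0.1
  expect_true("b" %in% out$retained$cow_id) # 0.142 retained
  expect_true("c" %in% out$retained$cow_id) # exactly 0.1 retained
  expect_match(out$exclusions$reason, "DMI/mBW")
})

test_that("balanced noise-free data give the exact planted effect", {
  tr <- simulate_trial(effects = noise_free_effects(-1.9), seed = 1)
  f <- suppressWarnings(fit_crossover_model(tr$truth, model_spec("dmi_kg_d")))
  est <- f$emm$emm[f$emm$group == "HEMP"] - f$emm$emm[f$emm$group == "CON"]
  expect_equal(est, -1.9, tolerance = 1e-8)
})

test_that("zero cow variance triggers the singularity fallback to lm", {
  set.seed(17)
  d <- sim_crossover_response(crossover_design(), cow_sd = 0,
                              residual_sd = 0.8)
  f <- suppressWarnings(fit_crossover_model(d, model_spec("y")))
  expect_equal(f$path, "lm")
  expect_equal(f$anova$df2[f$anova$term == "group"],
               nrow(d) - 6) # classical residual df
})

test_that("EMMs on balanced complete data equal raw cell means", {
  set.seed(21)
  d <- sim_crossover_response(crossover_design(), effect = -1.9)
  f <- fit_crossover_model(d, model_spec("y"))
  expect_equal(f$path, "lmm")
  raw <- tapply(d$y, d$treatment, mean)
  expect_equal(f$emm$emm[match(names(raw), f$emm$group)],
               as.numeric(raw), tolerance = 1e-8)
  # contrast and EMM difference agree
  expect_equal(f$contrasts$estimate,
               diff(rev(f$emm$emm)), tolerance = 1e-10)
})

test_that("REML likelihood machinery agrees with lme4", {
  set.seed(4)
  d <- sim_crossover_response(crossover_design())
  spec <- model_spec("y")
  dd <- ruminbal:::.prepare_model_frame(d, spec)
  fit <- ruminbal:::.quiet_lmer(y ~ group + period + sequence + block +
                                  (1 | cow), dd)
  mm <- model.matrix(y ~ group + period + sequence + block, dd)
  Z <- model.matrix(~ 0 + cow, dd)
  vc <- as.data.frame(lme4::VarCorr(fit))
  vp <- c(vc$vcov[vc$grp == "cow"], vc$vcov[vc$grp == "Residual"])
  pieces <- ruminbal:::.reml_pieces(dd$y, mm, Z, vp)
  n <- nrow(mm); p <- ncol(mm)
  # -2 REML loglik up to its additive constant (n - p) log(2 pi)
  expect_equal(pieces$neg2ll + (n - p) * log(2 * pi),
               -2 * as.numeric(stats::logLik(fit)), tolerance = 1e-6)
  expect_equal(unname(pieces$beta), unname(lme4::fixef(fit)),
               tolerance = 1e-6)
  expect_equal(unname(as.matrix(pieces$vcov_beta)),
               unname(as.matrix(vcov(fit))), tolerance = 1e-6)
})

test_that("Satterthwaite df reproduce the classical balanced-case values", {
  # in a balanced 2x2 crossover with a cow intercept, within-cow effects
  # (group, period) carry n_obs - n_cows - 2 = 10 df and between-cow
  # effects (sequence) n_cows - blocks... here 8 df; check against the
  # known partition rather than another package
  set.seed(13)
  d <- sim_crossover_response(crossover_design(), cow_sd = 3,
                              residual_sd = 0.5) # strong ICC
  f <- fit_crossover_model(d, model_spec("y"))
  an <- f$anova
  expect_equal(an$df2[an$term == "group"], 10, tolerance = 0.2)
  expect_equal(an$df2[an$term == "period"], 10, tolerance = 0.2)
  expect_equal(an$df2[an$term == "sequence"], 8, tolerance = 0.3)
})

test_that("forced transformations and the gamma path back-transform", {
  set.seed(5)
  d <- sim_crossover_response(crossover_design(), baseline = 20,
                              cow_sd = 1, residual_sd = 0.5)
  flog <- fit_crossover_model(d, model_spec("y", transformation = "log2"))
  expect_equal(flog$transformation, "log2")
  expect_true(all(flog$emm$emm > 15)) # back-transformed to response scale
  expect_equal(flog$emm$emm, 2^flog$emm$emm_link)
  fgam <- fit_crossover_model(d, model_spec("y", transformation = "gamma"))
  expect_true(fgam$path %in% c("glmm-gamma", "lm"))
  if (fgam$path == "glmm-gamma") {
    expect_equal(fgam$emm$emm, exp(fgam$emm$emm_link))
  }
})

test_that("empty cells and missing levels raise named errors", {
  d <- sim_crossover_response(crossover_design())
  expect_error(fit_crossover_model(d[d$treatment == "CON", ],
                                   model_spec("y")),
               "both treatment levels")
  d2 <- d[!(d$treatment == "HEMP" & d$period == 1), ]
  expect_error(fit_crossover_model(d2, model_spec("y")), "empty cell")
})

test_that("Tukey-Kramer reduces to the t test for two groups", {
  ct <- data.frame(estimate = 1.3, se = 0.5, df = 10)
  expect_equal(tukey_kramer(ct, n_means = 2),
               2 * pt(abs(1.3 / 0.5), 10, lower.tail = FALSE),
               tolerance = 1e-6) # ptukey quadrature accuracy
  # three equal groups, equal means -> p near 1
  ct3 <- data.frame(estimate = c(0.001, 0.001, 0), se = 1, df = 100)
  expect_true(all(tukey_kramer(ct3, n_means = 3) > 0.999))
  # numeric-integration oracle for a 3-group case
  tval <- 2.2; df <- 14
  p_pkg <- tukey_kramer(data.frame(estimate = tval, se = 1, df = df),
                        n_means = 3)
  expect_equal(p_pkg, oracle_tukey_p(sqrt(2) * tval, 3, df),
               tolerance = 1e-6)
})

test_that("TOST sample size is internally consistent", {
  expect_error(tost_sample_size(theta0 = 0.75), "on or outside")
  n <- as.integer(tost_sample_size())
  expect_equal(n %% 2, 0L)
  expect_gte(tost_power(n), 0.8)
  expect_lt(tost_power(n - 2), 0.8)
  # monotonicity: doubling CV increases n strictly
  expect_gt(as.integer(tost_sample_size(cv = 0.30)), n)
  # power monotone nondecreasing in n
  pws <- vapply(seq(4, 24, 2), tost_power, 0)
  expect_true(all(diff(pws) >= -1e-12))
})

test_that("t-test sample size matches the classical value and scaling", {
  n1 <- as.integer(t_power_n(1.0))
  expect_equal(n1, 17L)
  expect_gte(t_test_power(17, 1), 0.8)
  expect_lt(t_test_power(16, 1), 0.8)
  n_half <- as.integer(t_power_n(0.5))
  expect_equal(n_half, 64L) # classical value; approx 4x the d = 1 size
  # large d, modest power -> design minimum
  expect_lte(as.integer(t_power_n(5, power = 0.51)), 3L)
})
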
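#' Crossover design layout
#'
#' Builds the cow-period layout of a 2x2 crossover feeding trial: cows
#' enter in blocks, each block is split equally between the two treatment
#' sequences, and every cow receives both diets in opposite order across
#' the two periods. The default reproduces a 12-cow, 3-block trial with
#' 21-d feeding periods separated by a 14-d washout.
#'
#' @param n_blocks Number of blocks (default 3).
#' @param cows_per_block Cows per block; must be even (default 4).
#' @param treatments Character length-2: treatment and control labels.
#' @param period_length_d Feeding-period length, days (default 21).
#' @param washout_d Washout between periods, days (default 14, >= 0).
#' @return A data frame of class `crossover_design` with one row per
#'   cow-period: `cow_id`, `block`, `sequence`, `period`, `treatment`.
#' @export
#' @examples
#' d <- crossover_design()
#' table(d$treatment, d$period) # 6 cows per cell
crossover_design <- function(n_blocks = 3, cows_per_block = 4,
                             treatments = c("HEMP", "CON"),
                             period_length_d = 21, washout_d = 14) {
  stopifnot(n_blocks >= 1, cows_per_block >= 2,
            cows_per_block %% 2 == 0, length(treatments) == 2,
            washout_d >= 0, period_length_d >= 1)
  n_cows <- n_blocks * cows_per_block
  seq_labels <- c(paste(treatments, collapse = "-"),
                  paste(rev(treatments), collapse = "-"))
  cows <- data.frame(
    cow_id = sprintf("cow%02d", seq_len(n_cows)),
    block = rep(seq_len(n_blocks), each = cows_per_block),
    sequence = rep(rep(seq_labels, each = cows_per_block / 2), n_blocks),
    stringsAsFactors = FALSE
  )
  out <- merge(cows, data.frame(period = c(1L, 2L)), by = NULL)
  first <- out$sequence == seq_labels[1]
  out$treatment <- ifelse((first & out$period == 1L) |
                            (!first & out$period == 2L),
                          treatments[1], treatments[2])
  out <- out[order(out$cow_id, out$period), ]
  rownames(out) <- NULL
  attr(out, "treatments") <- treatments
  attr(out, "period_length_d") <- period_length_d
  attr(out, "washout_d") <- washout_d
  class(out) <- c("crossover_design", class(out))
  out
}

#' Per-response effect specification
#'
#' One response's linear generating model: baseline (control, period 1,
#' block-average) plus additive treatment, period and block shifts, a
#' cow-level random intercept and day-level residual noise.
#'
#' @param baseline Control-diet mean.
#' @param treatment Additive effect of the test diet (treatment minus
#'   control).
#' @param period Additive effect of period 2 vs period 1.
#' @param block Numeric vector of per-block shifts (recycled).
#' @param cow_sd SD of the cow random intercept (>= 0).
#' @param residual_sd SD of the day-level residual (>= 0).
#' @return A `response_spec` list.
#' @export
response_spec <- function(baseline, treatment = 0, period = 0,
                          block = 0, cow_sd = 0, residual_sd = 0) {
  stopifnot(cow_sd >= 0, residual_sd >= 0)
  structure(list(baseline = baseline, treatment = treatment,
                 period = period, block = block, cow_sd = cow_sd,
                 residual_sd = residual_sd), class = "response_spec")
}

#' Ground-truth effect specification for the synthetic trial
#'
#' Collects everything the generator holds true: per-response linear
#' effects, per-cow gas-exchange rates, digestibility and nitrogen-ledger
#' truths, and urine output. Defaults are anchored to the chamber-period
#' marginal means of the motivating 12-cow hemp-vs-soy crossover trial.
#' The N ledger closes by construction: urinary N is derived as
#' N intake - fecal N - milk N - retention.
#'
#' @param responses Named list of [response_spec()]s. Must include `dmi`,
#'   `milk`, `fat_pct`, `protein_pct`, `lactose_pct`, `bw`.
#' @param emission_baseline Named numeric (`o2`, `co2`, `ch4`): control
#'   daily gas rates, L/d (`o2` = consumption).
#' @param emission_treatment Additive treatment effects on the gas rates.
#' @param emission_cow_sd Cow-level SDs of the gas rates.
#' @param emission_residual_sd Cow-period residual SDs of the gas rates
#'   (within-cow, between-period variation of the measured daily rate).
#' @param diurnal_amplitude Relative amplitude of the 24-h emission
#'   sinusoid passed to the chamber simulator (default 0.1).
#' @param digestibility Named list `dm`, `om`, `energy`, `cp`, each a
#'   length-2 vector (treatment, control) of true fractions.
#' @param digestibility_cow_sd SD of a single cow-period deviation shared
#'   by all four digestibility truths (a good or poor digestion period
#'   shifts DM, OM, energy and CP together; the shared draw also keeps
#'   the fecal ash balance feasible). Stored in the truth table.
#' @param urine_kg_d Length-2 (treatment, control) true urine mass, kg/d.
#' @param n_retention_g_d Length-2 (treatment, control) true N retention,
#'   g/d (may be negative: body-protein mobilization).
#' @param measurement_noise_rel Relative SD of multiplicative measurement
#'   noise applied to recorded excreta masses (0 = recorded equals truth).
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(
    responses = list(
      dmi = response_spec(17.4, treatment = 0.2, period = 0.3,
                          block = c(-0.3, 0, 0.3),
                          cow_sd = 1.5, residual_sd = 0.8),
      milk = response_spec(29.7, treatment = 0.1, period = -0.5,
                           block = c(-1, 0, 1),
                           cow_sd = 4.0, residual_sd = 1.0),
      fat_pct = response_spec(4.23, treatment = -0.17, period = 0.05,
                              cow_sd = 0.5, residual_sd = 0.15),
      protein_pct = response_spec(3.59, treatment = 0.04, period = 0.10,
                                  cow_sd = 0.15, residual_sd = 0.05),
      lactose_pct = response_spec(4.99, treatment = 0, period = 0.02,
                                  cow_sd = 0.10, residual_sd = 0.03),
      bw = response_spec(639, treatment = -20, period = 3,
                         block = c(-15, 0, 15),
                         cow_sd = 40, residual_sd = 5),
      water = response_spec(80, treatment = -5, period = 0,
                            cow_sd = 8, residual_sd = 4)
    ),
    emission_baseline = c(o2 = 6838, co2 = 7110, ch4 = 522),
    emission_treatment = c(o2 = -200, co2 = -135, ch4 = -11),
    emission_cow_sd = c(o2 = 200, co2 = 200, ch4 = 40),
    emission_residual_sd = c(o2 = 120, co2 = 120, ch4 = 25),
    diurnal_amplitude = 0.1,
    digestibility = list(dm = c(0.657, 0.675), om = c(0.674, 0.689),
                         energy = c(0.651, 0.671), cp = c(0.641, 0.652)),
    digestibility_cow_sd = 0.01,
    urine_kg_d = c(11.5, 11.1),
    n_retention_g_d = c(20, -7),
    measurement_noise_rel = 0) {
  needed <- c("dmi", "milk", "fat_pct", "protein_pct", "lactose_pct", "bw")
  if (!all(needed %in% names(responses))) {
    stop("`responses` must include: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(emission_baseline > 0),
            all(emission_baseline + emission_treatment > 0),
            all(emission_cow_sd >= 0),
            all(emission_residual_sd >= 0),
            digestibility_cow_sd >= 0,
            all(urine_kg_d > 0),
            measurement_noise_rel >= 0)
  for (d in digestibility) stopifnot(all(d > 0), all(d < 1))
  structure(list(responses = responses,
                 emission_baseline = emission_baseline,
                 emission_treatment = emission_treatment,
                 emission_cow_sd = emission_cow_sd,
                 emission_residual_sd = emission_residual_sd,
                 diurnal_amplitude = diurnal_amplitude,
                 digestibility = digestibility,
                 digestibility_cow_sd = digestibility_cow_sd,
                 urine_kg_d = urine_kg_d,
                 n_retention_g_d = n_retention_g_d,
                 measurement_noise_rel = measurement_noise_rel),
            class = "effect_spec")
}

# per-cow reproducible sub-seeds derived from one master seed
.cow_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate a complete synthetic crossover trial
#'
#' Generates per-cow-day intake/milk/body-weight records, matching excreta
#' records and a truth table holding every latent quantity (cow effects,
#' realized cell means, gas-exchange rates, digestibilities, the full
#' nitrogen ledger, heat production and energy balance), so that every
#' downstream stage can be checked against known ground truth.
#'
#' Randomness is fully determined by `seed`; each cow draws from its own
#' derived sub-stream, so regenerating a subset of cows reproduces their
#' records bit-for-bit.
#'
#' @param design A [crossover_design()].
#' @param effects An [effect_spec()].
#' @param feeds Named list of [feed_spec()]s, one per treatment label.
#' @param days Integer vector of trial days forming the collection window
#'   (default 15:18).
#' @param seed Integer RNG seed.
#' @return A list of class `synthetic_trial`: `design`, `animal_days`,
#'   `excreta`, `truth` (one row per cow-period), `n_truncated`.
#' @export
#' @examples
#' trial <- simulate_trial(seed = 42)
#' head(trial$truth[, c("cow_id", "period", "treatment", "nue", "eue")])
simulate_trial <- function(design = crossover_design(),
                           effects = effect_spec(),
                           feeds = list(HEMP = feed_spec(),
                                        CON = feed_spec(
                                          ge_j_per_g_dm = 18647,
                                          cp_g_per_kg_dm = 152.17,
                                          ash_g_per_kg_dm = 64.33)),
                           days = 15:18, seed = 1) {
  stopifnot(inherits(design, "crossover_design"),
            inherits(effects, "effect_spec"))
  treatments <- attr(design, "treatments")
  if (!all(treatments %in% names(feeds))) {
    stop("`feeds` must be named by treatment: ",
         paste(treatments, collapse = ", "), call. = FALSE)
  }
  cows <- unique(design[, c("cow_id", "block", "sequence")])
  seeds <- .cow_seeds(seed, nrow(cows))
  n_truncated <- 0L
  rows <- list(); exrows <- list(); truths <- list()
  gases <- c("o2", "co2", "ch4")
  for (ci in seq_len(nrow(cows))) {
    set.seed(seeds[ci])
    cow <- cows[ci, ]
    cow_eff <- vapply(effects$responses,
                      function(r) stats::rnorm(1, 0, r$cow_sd), 0)
    cow_gas <- stats::rnorm(3, 0, effects$emission_cow_sd)
    names(cow_gas) <- gases
    for (p in 1:2) {
      drow <- design[design$cow_id == cow$cow_id & design$period == p, ]
      trt <- drow$treatment
      is_trt <- as.integer(trt == treatments[1])
      tix <- if (is_trt == 1L) 1L else 2L
      feed <- feeds[[trt]]
      # daily animal records
      day_df <- data.frame(
        cow_id = cow$cow_id, block = cow$block, sequence = cow$sequence,
        period = p, treatment = trt, day = days,
        stringsAsFactors = FALSE
      )
      for (nm in names(effects$responses)) {
        r <- effects$responses[[nm]]
        blk <- rep_len(r$block, max(cow$block))[cow$block]
        mu <- r$baseline + r$treatment * is_trt +
          r$period * (p == 2) + blk + cow_eff[[nm]]
        vals <- mu + stats::rnorm(length(days), 0, r$residual_sd)
        if (nm %in% c("dmi", "milk") && any(vals < 0)) {
          n_truncated <- n_truncated + sum(vals < 0)
          vals[vals < 0] <- 0
        }
        day_df[[nm]] <- vals
      }
      names(day_df)[names(day_df) == "dmi"] <- "dmi_kg_d"
      names(day_df)[names(day_df) == "milk"] <- "milk_kg_d"
      names(day_df)[names(day_df) == "bw"] <- "bw_kg"
      names(day_df)[names(day_df) == "water"] <- "water_l_d"

      # cow-period latent truths
      # one shared deviation: digestive efficiency moves all four
      # fractions together, which also preserves the fecal mass balance
      dig_eps <- stats::rnorm(1, 0, effects$digestibility_cow_sd)
      dig <- vapply(effects$digestibility, function(d) {
        min(max(d[tix] + dig_eps, 1e-3), 1 - 1e-3)
      }, 0)
      gas_rates <- effects$emission_baseline +
        effects$emission_treatment * is_trt + cow_gas +
        stats::rnorm(3, 0, effects$emission_residual_sd)
      urine_kg <- effects$urine_kg_d[tix]
      retention <- effects$n_retention_g_d[tix]

      ex <- .make_excreta(day_df, feed, dig, urine_kg, retention,
                          effects$measurement_noise_rel)
      truths[[length(truths) + 1L]] <- .make_truth(
        drow, day_df, feed, dig, gas_rates, urine_kg, retention,
        ex$n_urine_g_d, ex$urine_n_g_per_kg)
      rows[[length(rows) + 1L]] <- day_df
      exrows[[length(exrows) + 1L]] <- ex$records
    }
  }
  out <- list(design = design,
              animal_days = do.call(rbind, rows),
              excreta = do.call(rbind, exrows),
              truth = do.call(rbind, truths),
              n_truncated = n_truncated,
              seed = seed)
  class(out) <- "synthetic_trial"
  out
}

# Build excreta records for one cow-period so every digestibility and
# N-flow truth is attained exactly when measurement noise is off.
# Fecal composition follows from the four digestibility truths; urinary N
# closes the ledger: N_u = N_intake - N_feces - N_milk - retention.
.make_excreta <- function(day_df, feed, dig, urine_kg, retention,
                          noise_rel) {
  dmi <- day_df$dmi_kg_d
  mean_dmi <- mean(dmi)
  n_intake <- mean_dmi * feed$n_g_per_kg_dm
  # product of window means, matching the downstream estimator
  n_milk <- mean(day_df$milk_kg_d) * mean(day_df$protein_pct) * 10 / 6.38
  n_feces <- (1 - dig[["cp"]]) * n_intake
  n_urine <- n_intake - n_feces - n_milk - retention
  if (n_urine < 0) {
    stop(sprintf(
      "infeasible N ledger for %s period %d: implied urinary N = %.1f g/d",
      day_df$cow_id[1], day_df$period[1], n_urine), call. = FALSE)
  }
  urine_conc <- n_urine / urine_kg

  fec_dm_kg <- (1 - dig[["dm"]]) * dmi
  fec_om_kg <- (1 - dig[["om"]]) * feed$om_fraction * dmi
  fec_ash_g_kg <- (fec_dm_kg - fec_om_kg) / fec_dm_kg * 1000
  if (any(fec_ash_g_kg < 0)) {
    stop("infeasible digestibility truths: negative fecal ash",
         call. = FALSE)
  }
  fec_ge_j_g <- (1 - dig[["energy"]]) * feed$ge_j_per_g_dm * dmi /
    (fec_dm_kg * 1000) * 1000
  fec_n_g_kg <- (1 - dig[["cp"]]) * feed$n_g_per_kg_dm * dmi / fec_dm_kg
  dm_fraction <- 0.15 # typical cattle feces; only the product matters
  fresh <- fec_dm_kg / dm_fraction
  urine_rec <- rep(urine_kg, nrow(day_df))
  if (noise_rel > 0) {
    fresh <- fresh * (1 + stats::rnorm(length(fresh), 0, noise_rel))
    urine_rec <- urine_rec * (1 + stats::rnorm(length(urine_rec), 0,
                                               noise_rel))
  }
  records <- data.frame(
    cow_id = day_df$cow_id, period = day_df$period,
    treatment = day_df$treatment, day = day_df$day,
    feces_fresh_kg = fresh,
    feces_dm_fraction = dm_fraction,
    feces_n_g_per_kg_dm = fec_n_g_kg,
    feces_ge_j_per_g_dm = fec_ge_j_g,
    feces_ash_g_per_kg_dm = fec_ash_g_kg,
    urine_kg_d = urine_rec,
    urine_n_g_per_kg = urine_conc,
    stringsAsFactors = FALSE
  )
  list(records = records, n_urine_g_d = n_urine,
       urine_n_g_per_kg = urine_conc)
}

.make_truth <- function(drow, day_df, feed, dig, gas_rates, urine_kg,
                        retention, n_urine, urine_conc) {
  mean_dmi <- mean(day_df$dmi_kg_d)
  mean_milk <- mean(day_df$milk_kg_d)
  fat <- mean(day_df$fat_pct); prot <- mean(day_df$protein_pct)
  lact <- mean(day_df$lactose_pct)
  n_intake <- mean_dmi * feed$n_g_per_kg_dm
  n_feces <- (1 - dig[["cp"]]) * n_intake
  n_milk <- mean_milk * prot * 10 / 6.38
  mei_mj <- mei(feed$me_mj_per_kg_dm, mean_dmi)
  menergy <- milk_energy(fat * 10, prot * 10, lact * 10, mean_milk)
  ecm_kg <- ecm(mean_milk, fat, prot)
  hp_kj <- heat_production(gas_rates[["o2"]], gas_rates[["co2"]],
                           gas_rates[["ch4"]], n_urine)
  data.frame(
    cow_id = drow$cow_id, block = drow$block, sequence = drow$sequence,
    period = drow$period, treatment = drow$treatment,
    dmi_kg_d = mean_dmi, milk_kg_d = mean_milk,
    mbw_kg075 = metabolic_bw(mean(day_df$bw_kg)),
    o2_l_d = gas_rates[["o2"]], co2_l_d = gas_rates[["co2"]],
    ch4_l_d = gas_rates[["ch4"]],
    dig_dm = dig[["dm"]], dig_om = dig[["om"]],
    dig_energy = dig[["energy"]], cp_degradability = dig[["cp"]],
    n_intake_g_d = n_intake, n_feces_g_d = n_feces,
    n_milk_g_d = n_milk, n_urine_g_d = n_urine,
    n_retention_g_d = retention,
    urine_kg_d = urine_kg, urine_n_g_per_kg = urine_conc,
    ecm_kg_d = ecm_kg, milk_energy_mj_d = menergy, mei_mj_d = mei_mj,
    hp_kj_d = hp_kj,
    eb_mj_d = as.numeric(energy_balance(mei_mj, hp_kj / 1000, ecm_kg)),
    nue = n_milk / n_intake, eue = menergy / mei_mj,
    stringsAsFactors = FALSE
  )
}

#' Standalone excreta simulation
#'
#' Re-derives the excreta records of an existing synthetic trial (or of a
#' bare animal-day table) from digestibility and N-ledger truths; exposed
#' so the allocation logic can be exercised directly. See
#' [simulate_trial()] for the construction rules.
#'
#' @param animal_days Animal-day records for one cow-period (columns as
#'   produced by [simulate_trial()]).
#' @param feed A [feed_spec()].
#' @param digestibility Named numeric: `dm`, `om`, `energy`, `cp` truths.
#' @param urine_kg_d True daily urine mass, kg.
#' @param n_retention_g_d True N retention, g/d.
#' @param measurement_noise_rel Relative measurement noise (default 0).
#' @return Data frame of excreta records (one per day).
#' @export
simulate_excreta <- function(animal_days, feed, digestibility,
                             urine_kg_d, n_retention_g_d,
                             measurement_noise_rel = 0) {
  stopifnot(inherits(feed, "feed_spec"),
            all(c("dm", "om", "energy", "cp") %in% names(digestibility)))
  .make_excreta(animal_days, feed, digestibility, urine_kg_d,
                n_retention_g_d, measurement_noise_rel)$records
}
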
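#' Stoichiometric constants for indirect calorimetry
#'
#' Fixed coefficients used throughout the gas-exchange calculations:
#' the fermentative CO2 factor (1.7 L CO2 per L CH4), the Frayn
#' fat/carbohydrate oxidation coefficients and the Brouwer heat-production
#' coefficients. Gas volumes are in litres per day, urinary nitrogen in
#' grams per day, heat production in kilojoules per day.
#'
#' @return A named list with elements `co2_ferm_per_ch4`, `fox`, `cox`
#'   and `hp` (each a named numeric vector of coefficients).
#' @export
#' @examples
#' stoichiometric_constants()$hp
stoichiometric_constants <- function() {
  list(
    co2_ferm_per_ch4 = 1.7,
    fox = c(o2 = 1.67, mco2 = -1.67, nu = -1.92),
    cox = c(mco2 = 4.55, o2 = -3.21, nu = -2.87),
    hp  = c(o2 = 16.18, co2 = 5.02, ch4 = -2.17, nu = -5.99)
  )
}

#' Fermentative CO2 production from methane
#'
#' Enteric CH4 and fermentative CO2 arise together in the rumen; the
#' fermentative share of total CO2 is taken as 1.7 L per L CH4.
#'
#' @param ch4_l Methane production, L (or L/d). Must be non-negative.
#' @return Fermentative CO2 in the same units as `ch4_l`.
#' @export
#' @examples
#' fermentative_co2(511) # 868.7
fermentative_co2 <- function(ch4_l) {
  if (any(!is.finite(ch4_l)) || any(ch4_l < 0)) {
    stop("`ch4_l` must be finite and >= 0", call. = FALSE)
  }
  1.7 * ch4_l
}

#' Metabolic (tissue) CO2 production
#'
#' Total chamber CO2 minus the fermentative fraction (1.7 x CH4).
#'
#' @param co2_total_l Total CO2 production, L/d.
#' @param ch4_l Methane production, L/d.
#' @return Metabolic CO2, L/d.
#' @export
metabolic_co2 <- function(co2_total_l, ch4_l) {
  if (any(co2_total_l < 0) || any(ch4_l < 0)) {
    stop("gas volumes must be >= 0", call. = FALSE)
  }
  ferm <- fermentative_co2(ch4_l)
  if (any(co2_total_l < ferm)) {
    stop("fermentative CO2 (1.7 * CH4) exceeds total CO2", call. = FALSE)
  }
  co2_total_l - ferm
}

#' Metabolic respiratory quotient
#'
#' @param mco2_l Metabolic CO2 production, L/d.
#' @param o2_l O2 consumption, L/d; must be > 0.
#' @return mCO2 / O2 (dimensionless).
#' @export
metabolic_rq <- function(mco2_l, o2_l) {
  if (any(o2_l <= 0)) stop("`o2_l` must be > 0 for mRQ", call. = FALSE)
  if (any(mco2_l < 0)) stop("`mco2_l` must be >= 0", call. = FALSE)
  mco2_l / o2_l
}

#' Net fat oxidation (Frayn stoichiometry)
#'
#' FOX (g/d) = 1.67*O2 - 1.67*mCO2 - 1.92*Nu. Negative values indicate net
#' lipogenesis and are returned as-is with a `flag` attribute rather than
#' clamped.
#'
#' @param o2_l O2 consumption, L/d.
#' @param mco2_l Metabolic CO2 production, L/d.
#' @param nu_g Urinary nitrogen excretion, g/d.
#' @return Fat oxidation in g/d, with attribute `flag = "negative"` where
#'   the result is below zero.
#' @export
fat_oxidation <- function(o2_l, mco2_l, nu_g) {
  .check_nonneg(o2_l = o2_l, mco2_l = mco2_l, nu_g = nu_g)
  k <- stoichiometric_constants()$fox
  out <- k[["o2"]] * o2_l + k[["mco2"]] * mco2_l + k[["nu"]] * nu_g
  if (any(out < 0)) {
    warning("negative fat oxidation (net lipogenesis regime)", call. = FALSE)
    attr(out, "flag") <- ifelse(out < 0, "negative", "")
  }
  out
}

#' Net carbohydrate oxidation (Frayn stoichiometry)
#'
#' COX (g/d) = 4.55*mCO2 - 3.21*O2 - 2.87*Nu. Negative results are flagged,
#' not clamped, as for [fat_oxidation()].
#'
#' @inheritParams fat_oxidation
#' @return Carbohydrate oxidation in g/d.
#' @export
carbohydrate_oxidation <- function(o2_l, mco2_l, nu_g) {
  .check_nonneg(o2_l = o2_l, mco2_l = mco2_l, nu_g = nu_g)
  k <- stoichiometric_constants()$cox
  out <- k[["mco2"]] * mco2_l + k[["o2"]] * o2_l + k[["nu"]] * nu_g
  if (any(out < 0)) {
    warning("negative carbohydrate oxidation", call. = FALSE)
    attr(out, "flag") <- ifelse(out < 0, "negative", "")
  }
  out
}

#' Heat production (Brouwer equation)
#'
#' HP (kJ/d) = 16.18*O2 + 5.02*CO2 - 2.17*CH4 - 5.99*Nu. Note that the
#' CO2 term uses TOTAL CO2 production, not the metabolic fraction; the
#' oxidation equations use metabolic CO2. Both conventions exist in the
#' literature; this package keeps them as printed side by side.
#'
#' @param o2_l O2 consumption, L/d.
#' @param co2_total_l Total CO2 production, L/d.
#' @param ch4_l CH4 production, L/d.
#' @param nu_g Urinary N excretion, g/d.
#' @return Heat production, kJ/d.
#' @export
#' @examples
#' heat_production(5000, 5500, 511, 93.2)
heat_production <- function(o2_l, co2_total_l, ch4_l, nu_g) {
  .check_nonneg(o2_l = o2_l, co2_total_l = co2_total_l,
                ch4_l = ch4_l, nu_g = nu_g)
  k <- stoichiometric_constants()$hp
  k[["o2"]] * o2_l + k[["co2"]] * co2_total_l +
    k[["ch4"]] * ch4_l + k[["nu"]] * nu_g
}

.check_nonneg <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    x <- args[[nm]]
    if (any(!is.finite(x)) || any(x < 0)) {
      stop(sprintf("`%s` must be finite and >= 0", nm), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Daily gas-exchange summary for one chamber day
#'
#' Combines integrated daily gas volumes with urinary N into the derived
#' calorimetry quantities (fermentative/metabolic CO2, mRQ, FOX, COX, HP)
#' and normalizes them to intake and metabolic body weight.
#'
#' @param o2_l_d,co2_l_d,ch4_l_d Daily O2 consumption and CO2/CH4
#'   production, L/d.
#' @param nu_g_d Urinary N excretion, g/d (held constant across the
#'   measurement window).
#' @param dmi_kg Dry matter intake, kg/d; must be > 0.
#' @param mbw Metabolic body weight, kg^0.75; must be > 0.
#' @param ecm_kg Optional energy-corrected milk yield, kg/d, for CH4/ECM.
#' @return A one-row data frame of class `gas_exchange_daily` with the raw
#'   volumes, derived quantities and normalized metrics (`ch4_per_dmi_l_kg`,
#'   `hp_per_mbw_kj`, `fox_per_mbw_g`, `cox_per_mbw_g`, `hp_per_dmi_kj`,
#'   and `ch4_per_ecm_l_kg` when `ecm_kg` is given).
#' @export
summarize_day <- function(o2_l_d, co2_l_d, ch4_l_d, nu_g_d,
                          dmi_kg, mbw, ecm_kg = NA_real_) {
  if (dmi_kg <= 0) stop("`dmi_kg` must be > 0", call. = FALSE)
  if (mbw <= 0) stop("`mbw` must be > 0", call. = FALSE)
  co2f <- fermentative_co2(ch4_l_d)
  mco2 <- metabolic_co2(co2_l_d, ch4_l_d)
  mrq <- metabolic_rq(mco2, o2_l_d)
  fox <- suppressWarnings(as.numeric(fat_oxidation(o2_l_d, mco2, nu_g_d)))
  cox <- suppressWarnings(as.numeric(
    carbohydrate_oxidation(o2_l_d, mco2, nu_g_d)))
  hp <- heat_production(o2_l_d, co2_l_d, ch4_l_d, nu_g_d)
  out <- data.frame(
    o2_l_d = o2_l_d, co2_l_d = co2_l_d, ch4_l_d = ch4_l_d,
    co2_ferm_l_d = co2f, mco2_l_d = mco2, mrq = mrq,
    nu_g_d = nu_g_d, fox_g_d = fox, cox_g_d = cox, hp_kj_d = hp,
    ch4_per_dmi_l_kg = ch4_l_d / dmi_kg,
    ch4_per_ecm_l_kg = if (is.finite(ecm_kg) && ecm_kg > 0)
      ch4_l_d / ecm_kg else NA_real_,
    hp_per_mbw_kj = hp / mbw,
    fox_per_mbw_g = fox / mbw,
    cox_per_mbw_g = cox / mbw,
    hp_per_dmi_kj = hp / dmi_kg
  )
  class(out) <- c("gas_exchange_daily", class(out))
  out
}

#' Integrate a chamber trace to daily gas volumes
#'
#' Inverts the respiration-chamber measurement geometry: the instantaneous
#' gas release is airflow times the outlet-minus-inlet concentration excess,
#' integrated with the trapezoid rule over the native sampling grid and
#' divided by the chamber recovery rate. O2 consumption uses inlet minus
#' outlet. The result is rescaled to litres per day.
#'
#' The window boundaries need not coincide with sample times; boundary
#' values are linearly interpolated (partial intervals prorated). Gaps in
#' the grid longer than `max_gap_min` flag the day invalid; negative
#' integrated production is flagged, never silently zeroed.
#'
#' @param trace A [chamber_trace()] object.
#' @param window Numeric length-2, start/end of the integration window in
#'   hours on the trace's time axis (default the full trace).
#' @param max_gap_min Longest tolerated sampling gap, minutes (default 30).
#' @return A one-row data frame with `o2_l_d`, `co2_l_d`, `ch4_l_d`,
#'   `valid` (logical) and `flags` (character).
#' @export
integrate_gas_exchange <- function(trace, window = NULL, max_gap_min = 30) {
  stopifnot(inherits(trace, "chamber_trace"))
  tt <- trace$time_h
  if (is.null(window)) window <- range(tt)
  if (window[1] < min(tt) - 1e-9 || window[2] > max(tt) + 1e-9) {
    stop("integration window not covered by trace", call. = FALSE)
  }
  flags <- character(0)
  valid <- TRUE
  inwin <- tt >= window[1] & tt <= window[2]
  gaps_h <- diff(tt[inwin])
  if (length(gaps_h) == 0L) stop("window contains < 2 samples", call. = FALSE)
  if (max(gaps_h) * 60 > max_gap_min + 1e-9) {
    valid <- FALSE
    flags <- c(flags, sprintf("gap>%gmin", max_gap_min))
  }
  window_d <- (window[2] - window[1]) / 24
  out <- list()
  for (gas in c("o2", "co2", "ch4")) {
    dC <- trace[[paste0(gas, "_out")]] - trace[[paste0(gas, "_in")]]
    if (gas == "o2") dC <- -dC # consumption
    rate_m3_h <- dC * trace$airflow_m3_h          # instantaneous release
    vol_m3 <- .trapz_window(tt, rate_m3_h, window)
    vol_l_d <- vol_m3 * 1000 / trace$recovery / window_d
    if (vol_l_d < 0) flags <- c(flags, paste0("negative_", gas))
    out[[paste0(gas, "_l_d")]] <- vol_l_d
  }
  data.frame(o2_l_d = out$o2_l_d, co2_l_d = out$co2_l_d,
             ch4_l_d = out$ch4_l_d, valid = valid,
             flags = paste(flags, collapse = ";"))
}

# trapezoid integral of y(t) over [w1, w2] with linear interpolation at the
# window boundaries; t strictly increasing, units: t in hours -> result in
# y-units * hours ... here m3/h * h = m3
.trapz_window <- function(t, y, window) {
  w1 <- window[1]; w2 <- window[2]
  ends <- stats::approx(t, y, xout = c(w1, w2))$y
  keep <- t > w1 & t < w2
  tt <- c(w1, t[keep], w2)
  yy <- c(ends[1], y[keep], ends[2])
  sum(diff(tt) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2)
}
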
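#' Construct a chamber trace object
#'
#' Container for one respiration-chamber occupancy: inlet and outlet volume
#' fractions for O2, CO2 and CH4 on a common time grid, plus airflow and
#' the chamber's gas recovery rate.
#'
#' @param time_h Strictly increasing sample times, hours from the start of
#'   the occupancy (the native grid is 6 min = 0.1 h).
#' @param o2_in,o2_out,co2_in,co2_out,ch4_in,ch4_out Volume fractions in
#'   \[0, 1\], recycled to the grid length.
#' @param airflow_m3_h Airflow through the chamber, m3/h (> 0).
#' @param recovery Gas recovery rate in (0, 1]; integrated volumes are
#'   divided by it.
#' @param chamber_id Optional identifier.
#' @return An object of class `chamber_trace`.
#' @export
chamber_trace <- function(time_h, o2_in, o2_out, co2_in, co2_out,
                          ch4_in, ch4_out, airflow_m3_h,
                          recovery = 0.997, chamber_id = NA_character_) {
  n <- length(time_h)
  if (n < 2L || any(diff(time_h) <= 0)) {
    stop("`time_h` must be strictly increasing with >= 2 samples",
         call. = FALSE)
  }
  fr <- list(o2_in = o2_in, o2_out = o2_out, co2_in = co2_in,
             co2_out = co2_out, ch4_in = ch4_in, ch4_out = ch4_out)
  fr <- lapply(fr, rep_len, n)
  for (nm in names(fr)) {
    if (any(fr[[nm]] < 0) || any(fr[[nm]] > 1)) {
      stop(sprintf("`%s` outside [0, 1]", nm), call. = FALSE)
    }
  }
  if (airflow_m3_h <= 0) stop("`airflow_m3_h` must be > 0", call. = FALSE)
  if (recovery <= 0 || recovery > 1) {
    stop("`recovery` must be in (0, 1]", call. = FALSE)
  }
  structure(c(list(time_h = time_h), fr,
              list(airflow_m3_h = airflow_m3_h, recovery = recovery,
                   chamber_id = chamber_id)),
            class = "chamber_trace")
}

#' @export
print.chamber_trace <- function(x, ...) {
  cat(sprintf(
    "<chamber_trace> %d samples over %.1f h, airflow %.1f m3/h, recovery %.3f\n",
    length(x$time_h), diff(range(x$time_h)), x$airflow_m3_h, x$recovery))
  invisible(x)
}

#' Simulate a respiration-chamber gas trace
#'
#' Well-mixed single-compartment chamber: V dC/dt = Q C_in + E(t) - Q C_out,
#' solved exactly on each sampling interval (E piecewise constant at the
#' interval midpoint). O2 has negative E (consumption). The reported outlet
#' excess (C_out - C_in) is scaled by `recovery` and perturbed with i.i.d.
#' Gaussian noise; negative concentrations after noise are clipped to zero
#' and counted in the `clipped` attribute.
#'
#' Emission can follow a 24-h sinusoid: E(t) = E0 (1 + a sin(2 pi t / 24)),
#' emulating diurnal feeding-driven variation (the within-day profile of a
#' real cow is not modelled beyond this).
#'
#' @param emission_l_d Named vector: daily mean gas exchange rates, L/d,
#'   e.g. `c(o2 = 6640, co2 = 6975, ch4 = 511)` where `o2` is consumption.
#' @param hours Trace duration in hours (default 60 h: 12 h settle-in plus
#'   a 48-h measurement window).
#' @param chamber_volume_m3 Chamber volume (default 50; only the washout
#'   time constant V/Q depends on it).
#' @param airflow_m3_h Airflow, m3/h (default 30).
#' @param inlet_fractions Ambient inlet fractions (defaults O2 0.2095,
#'   CO2 0.0004, CH4 0).
#' @param sample_interval_min Sampling interval, minutes (default 6).
#' @param noise_sd Gaussian noise SD on the outlet fraction. Either a
#'   single number applied to all gases, or the default `"relative"`:
#'   1\% of each gas's steady-state excess.
#' @param noise_rel Relative noise level used when `noise_sd = "relative"`
#'   (default 0.01).
#' @param diurnal_amplitude Relative amplitude of the 24-h sinusoid
#'   (default 0 = constant emission).
#' @param recovery Gas recovery rate (default 0.997).
#' @param init `"inlet"` (spec default, C(0) = C_in) or `"steady"` (start
#'   at the steady state of the mean emission).
#' @param seed Optional integer seed for the noise draws.
#' @param chamber_id Optional identifier.
#' @return A [chamber_trace()] with attribute `truth` (the emission input)
#'   and `clipped` (count of clipped samples).
#' @export
simulate_chamber_trace <- function(emission_l_d,
                                   hours = 60,
                                   chamber_volume_m3 = 50,
                                   airflow_m3_h = 30,
                                   inlet_fractions = c(o2 = 0.2095,
                                                       co2 = 0.0004,
                                                       ch4 = 0),
                                   sample_interval_min = 6,
                                   noise_sd = "relative",
                                   noise_rel = 0.01,
                                   diurnal_amplitude = 0,
                                   recovery = 0.997,
                                   init = c("inlet", "steady"),
                                   seed = NULL,
                                   chamber_id = NA_character_) {
  init <- match.arg(init)
  stopifnot(chamber_volume_m3 > 0, airflow_m3_h > 0,
            recovery > 0, recovery <= 1)
  if (any(emission_l_d <= 0)) stop("emission rates must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  gases <- c("o2", "co2", "ch4")
  if (!all(gases %in% names(emission_l_d))) {
    stop("`emission_l_d` needs named entries o2, co2, ch4", call. = FALSE)
  }
  dt <- sample_interval_min / 60
  tt <- seq(0, hours, by = dt)
  Q <- airflow_m3_h
  V <- chamber_volume_m3
  k <- Q / V
  clipped <- 0L
  cols <- list(time_h = tt)
  for (gas in gases) {
    sign <- if (gas == "o2") -1 else 1   # O2 is consumed
    E0 <- sign * emission_l_d[[gas]] / 1000 / 24   # m3/h
    Cin <- inlet_fractions[[gas]]
    # exact update for dX/dt = E(t)/V - k X with X = C - C_in,
    # E held at its midpoint value over each step
    X <- numeric(length(tt))
    X[1] <- if (init == "steady") E0 / Q else 0
    for (i in seq_along(tt)[-1]) {
      tm <- (tt[i - 1] + tt[i]) / 2
      Et <- E0 * (1 + diurnal_amplitude * sin(2 * pi * tm / 24))
      X[i] <- X[i - 1] * exp(-k * dt) + (Et / Q) * (1 - exp(-k * dt))
    }
    excess <- recovery * X
    sd_gas <- if (identical(noise_sd, "relative")) {
      noise_rel * abs(E0) / Q
    } else noise_sd
    if (sd_gas > 0) excess <- excess + stats::rnorm(length(tt), 0, sd_gas)
    cout <- Cin + excess
    nclip <- sum(cout < 0)
    if (nclip > 0) {
      clipped <- clipped + nclip
      cout[cout < 0] <- 0
    }
    cols[[paste0(gas, "_in")]] <- rep(Cin, length(tt))
    cols[[paste0(gas, "_out")]] <- cout
  }
  tr <- chamber_trace(cols$time_h, cols$o2_in, cols$o2_out, cols$co2_in,
                      cols$co2_out, cols$ch4_in, cols$ch4_out,
                      airflow_m3_h = Q, recovery = recovery,
                      chamber_id = chamber_id)
  attr(tr, "truth") <- emission_l_d
  attr(tr, "clipped") <- clipped
  if (clipped > 0) {
    warning(sprintf("%d outlet samples clipped at 0 after noise", clipped),
            call. = FALSE)
  }
  tr
}
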
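#' Two-parameter Windkessel pressure response to a half-sine pulse train
#'
#' Demonstration of the unsteady behaviour of a single outlet: the ODE
#' `C dP/dt = Q_in(t) - (P - P_ref)/R` is solved piecewise-analytically for
#' an inflow made of half-sine systolic pulses (`Q = A sin(pi t / Ts)` over
#' the systolic fraction of each cycle, zero in diastole). With `C = 0` the
#' outlet is purely resistive and the pressure is the inflow scaled by `R`
#' plus the reference pressure. The clamp-prediction pipeline itself is
#' steady; this operation exists to show that the calibrated R,C pairs
#' produce physiologically shaped pressure waveforms.
#'
#' @param outlet a list with `resistance` (mmHg·min/ml), `compliance`
#'   (ml/mmHg) and `reference_pressure` (mmHg), e.g. one row of
#'   `network$outlets` coerced with `as.list()`.
#' @param amplitude peak inflow, ml/min (> 0).
#' @param period cycle length in seconds (> 0).
#' @param n_cycles number of cardiac cycles simulated; with time constant
#'   `RC` the periodic steady state is reached once `n_cycles * period`
#'   exceeds a few time constants.
#' @param systolic_fraction fraction of the cycle occupied by the half-sine
#'   pulse (default 0.5).
#' @param samples_per_cycle output sampling density.
#' @return data.frame with `time_s`, `inflow_ml_min`, `pressure_mmHg`.
#' @export
windkessel_waveform <- function(outlet, amplitude, period, n_cycles = 10,
                                systolic_fraction = 0.5,
                                samples_per_cycle = 200) {
  outlet <- as.list(outlet)
  R <- outlet$resistance
  C <- outlet$compliance %||% 0
  pref <- outlet$reference_pressure %||% 0
  if (!is.finite(amplitude) || amplitude <= 0)
    hf_error("domain_error", "amplitude must be > 0 (ml/min)")
  if (!is.finite(period) || period <= 0)
    hf_error("domain_error", "period must be > 0 (s)")
  if (!is.finite(R) || R <= 0) hf_error("domain_error", "outlet resistance must be > 0")
  if (!is.finite(C) || C < 0) hf_error("domain_error", "outlet compliance must be >= 0")
  if (systolic_fraction <= 0 || systolic_fraction > 1)
    hf_error("domain_error", "systolic_fraction must lie in (0, 1]")

  Tm <- period / 60                 # work in minutes: R*C is then minutes
  ts <- systolic_fraction * Tm
  td <- Tm - ts
  w <- pi / ts                      # rad/min over the systolic half-sine

  times <- seq(0, n_cycles * Tm, length.out = n_cycles * samples_per_cycle + 1)
  inflow <- vapply(times, function(t) {
    s <- t %% Tm
    if (s < ts) amplitude * sin(w * s) else 0
  }, numeric(1))

  if (C == 0) {
    pressure <- pref + inflow * R
    return(data.frame(time_s = times * 60, inflow_ml_min = inflow,
                      pressure_mmHg = pressure))
  }

  tau <- R * C
  a <- amplitude * R / (1 + (w * tau)^2)
  # particular solution during systole: a*(sin(ws) - w*tau*cos(ws)) + pref
  part <- function(s) pref + a * (sin(w * s) - w * tau * cos(w * s))
  pressure <- numeric(length(times))
  p0 <- pref                        # start relaxed at the reference pressure
  cycle_start <- 0
  k <- 1
  for (cyc in seq_len(n_cycles)) {
    # systole
    p_sys0 <- p0
    while (k <= length(times) && times[k] <= cycle_start + ts + 1e-15) {
      s <- times[k] - cycle_start
      pressure[k] <- part(s) + (p_sys0 - part(0)) * exp(-s / tau)
      k <- k + 1
    }
    p0 <- part(ts) + (p_sys0 - part(0)) * exp(-ts / tau)
    # diastole: pure relaxation toward pref
    if (td > 0) {
      dia_start <- cycle_start + ts
      while (k <= length(times) && times[k] <= dia_start + td + 1e-15) {
        s <- times[k] - dia_start
        pressure[k] <- pref + (p0 - pref) * exp(-s / tau)
        k <- k + 1
      }
      p0 <- pref + (p0 - pref) * exp(-td / tau)
    }
    cycle_start <- cycle_start + Tm
  }
  data.frame(time_s = times * 60, inflow_ml_min = inflow, pressure_mmHg = pressure)
}
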
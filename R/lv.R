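#' Left-ventricular parameters
#'
#' The ventricle is modeled as a time-varying elastance
#' `P_lv(t) = E(t) * (V_lv - V0)` driven by a smooth two-phase (rise/decay)
#' activation, a standard 0D surrogate for a piston-driven compliant sac that
#' exposes contractility, heart rate and stroke volume as independent knobs.
#'
#' @param E_max Peak elastance (mmHg/mL) at unit contractility scale.
#' @param E_min Baseline (diastolic) elastance (mmHg/mL).
#' @param V0 Unstressed volume (mL).
#' @param systolic_fraction Fraction of the cycle spent in the activation
#'   upstroke plus downstroke.
#' @param contractility_scale Dimensionless multiplier on the elastance
#'   excursion `E_max - E_min` (and hence, pointwise, on the activation
#'   slope).
#' @param rise_fraction Fraction of the systolic interval taken by the
#'   activation upstroke (the activation peak time).
#' @return List of class `lv_params`.
#' @export
lv_params <- function(E_max = 2.0, E_min = 0.045, V0 = 10,
                      systolic_fraction = 0.40, contractility_scale = 1,
                      rise_fraction = 0.45) {
  if (!(E_max > E_min && E_min > 0))
    stop("need E_max > E_min > 0", call. = FALSE)
  if (!(systolic_fraction > 0 && systolic_fraction < 1))
    stop("systolic_fraction must lie in (0, 1)", call. = FALSE)
  if (contractility_scale < 0)
    stop("contractility_scale must be nonnegative", call. = FALSE)
  if (!(rise_fraction > 0 && rise_fraction < 1))
    stop("rise_fraction must lie in (0, 1)", call. = FALSE)
  structure(list(E_max = E_max, E_min = E_min, V0 = V0,
                 systolic_fraction = systolic_fraction,
                 contractility_scale = contractility_scale,
                 rise_fraction = rise_fraction), class = "lv_params")
}

#' Time-varying elastance
#'
#' Periodic activation with period `60/hr` seconds: a raised-cosine upstroke
#' to the activation peak, a raised-cosine decay back to baseline, then a
#' diastolic plateau at `E_min`. The curve has a continuous first derivative
#' and evaluates to `E_min` at the cycle start and to
#' `E_min + contractility_scale * (E_max - E_min)` at the activation peak.
#'
#' @param t Time (s), vectorized; must be nonnegative.
#' @param lv An [lv_params()] object.
#' @param hr Heart rate (bpm).
#' @return Elastance (mmHg/mL) at each `t`.
#' @export
#' @examples
#' lv <- lv_params()
#' elastance_curve(0, lv, 75)                        # E_min
#' elastance_curve(lv_activation_peak_time(lv, 75), lv, 75)
elastance_curve <- function(t, lv, hr) {
  stopifnot(inherits(lv, "lv_params"), hr > 0)
  if (any(t < 0)) stop("t must be nonnegative", call. = FALSE)
  T <- 60 / hr
  t_sys <- lv$systolic_fraction * T
  t_rise <- lv$rise_fraction * t_sys
  tc <- t %% T
  e <- numeric(length(tc))
  up <- tc < t_rise
  e[up] <- 0.5 * (1 - cos(pi * tc[up] / t_rise))
  dn <- !up & tc < t_sys
  e[dn] <- 0.5 * (1 + cos(pi * (tc[dn] - t_rise) / (t_sys - t_rise)))
  lv$E_min + lv$contractility_scale * (lv$E_max - lv$E_min) * e
}

#' Activation peak time of the elastance curve
#' @inheritParams elastance_curve
#' @return Time (s) within the cycle at which the elastance peaks.
#' @export
lv_activation_peak_time <- function(lv, hr) {
  lv$rise_fraction * lv$systolic_fraction * 60 / hr
}

#' Valve parameters
#'
#' One-way valves are modeled as smoothed diodes: the conductance follows a
#' logistic curve in the pressure drop so the system right-hand side stays
#' smooth for the fixed-step integrator. No regurgitation is allowed,
#' matching prosthetic one-way valves.
#'
#' @param open_resistance Resistance of the fully open valve (mmHg s/mL).
#' @param transition_width Pressure scale of the opening transition (mmHg).
#' @return List of class `valve_params` (with `allows_backflow = FALSE`).
#' @export
valve_params <- function(open_resistance = 0.05, transition_width = 0.5) {
  if (open_resistance <= 0) stop("open_resistance must be positive", call. = FALSE)
  if (transition_width <= 0) stop("transition_width must be positive", call. = FALSE)
  structure(list(open_resistance = open_resistance,
                 transition_width = transition_width,
                 allows_backflow = FALSE), class = "valve_params")
}

#' Valve conductance
#'
#' Logistic conductance `1 / (R_open * (1 + exp(-dp / w)))`: approximately
#' `1/R_open` when the forward pressure drop is much larger than the
#' transition width, approximately zero when it is much smaller than minus
#' the width, and monotone nondecreasing in between.
#'
#' @param dp Pressure drop across the valve (mmHg), vectorized.
#' @param valve A [valve_params()] object.
#' @return Conductance (mL/s per mmHg).
#' @export
valve_conductance <- function(dp, valve) {
  stopifnot(inherits(valve, "valve_params"))
  1 / (valve$open_resistance * (1 + exp(-dp / valve$transition_width)))
}

#' Valve flow
#'
#' Flow through the smoothed diode: [valve_conductance()] times the pressure
#' drop, clamped at zero for reverse drops. It is therefore nonnegative for
#' every `dp` - the valve never carries backflow, and a circuit at rest
#' (zero drop) carries no leak - and approaches `dp / R_open` when wide
#' open.
#'
#' @inheritParams valve_conductance
#' @return Flow (mL/s).
#' @export
valve_flow <- function(dp, valve) {
  stopifnot(inherits(valve, "valve_params"))
  pmax(0, dp) * valve_conductance(dp, valve)
}
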
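G_ACCEL <- 9.80665

#' Simulate the closed hydraulic loop
#'
#' Integrates the full circuit - elastance ventricle, one-way aortic and
#' mitral valves, R-L-C aorta ladder with terminal outlet units, two-chamber
#' Windkessel, reservoir and passive atrium - with a fixed-step fourth-order
#' Runge-Kutta scheme until periodic steady state (cycle-to-cycle maximum
#' pressure difference below `convergence_tol` at every monitored node), then
#' records `output_cycles` further cycles at `output_fs`.
#'
#' @param config A [circuit_config()].
#' @return Object of class `sim_result` with elements `records` (named list
#'   of [waveform_record()]s for sites `LA`, `LV`, `ascending_aorta`,
#'   `abdominal_aorta`), `volumes` (data.frame `t`, `total_ml`),
#'   `valve_events` (per-valve open/close times in seconds from the start of
#'   the recorded window), `valve_flow` (data.frame of aortic/mitral flow in
#'   mL/s), `co_measured` (L/min), `converged`, `cycles_run`, `ladder`,
#'   `effective_pwv` and the input `config`.
#' @export
simulate <- function(config) {
  stopifnot(inherits(config, "circuit_config"))
  ladder <- build_aorta_ladder(
    config$aorta_geometry, config$target_pwv,
    target_ac = if (config$match == "ac") config$target_ac else NULL,
    fluid = config$fluid, taper = config$stiffness_taper)
  n <- nrow(ladder$compartments)
  K <- length(ladder$terminals)
  lv <- config$lv
  af <- config$afterload
  num <- config$numerics

  # Viscoelastic wall: under "distribute" the static-compliance deficit
  # target_ac - C_tube - C_syringes is spread along the tube as a slow creep
  # compliance behind a relaxation resistance (Voigt-type wall). At wave
  # frequencies the tube then behaves with its wave-speed-true stiffness,
  # while quasi-statically the sealed system exhibits the full configured
  # compliance - which is exactly how a lossy elastomer tube reconciles a
  # high foot-to-foot wave speed with a large statically measured
  # compliance.
  A_term <- ladder$compartments$area_m2[ladder$terminals]
  syr_c <- rep(af$per_branch_outlet$syringe_compliance, K)
  deficit <- 0
  if (config$match == "distribute" && !is.null(config$target_ac) &&
      !is.na(config$target_ac)) {
    deficit <- max(0, config$target_ac - ladder$total_compliance - sum(syr_c))
  }
  C_fast <- ladder$compartments$C_si
  Cw <- pmax(comp_to_si(deficit) * C_fast / sum(C_fast), 1e-16)
  Rw <- config$wall_relaxation_time / Cw
  static_compliance <- ladder$total_compliance + sum(syr_c) + deficit
  # syringe port resistance: proportional to the characteristic impedance
  # rho * c / A of the terminal compartment, so outlets absorb rather than
  # re-reflect high-frequency wave energy (clamps still set the steady
  # resistance)
  c_term <- ladder$compartments$wave_speed_m_s[ladder$terminals]
  R_port <- af$port_resistance_scale * config$fluid$density * c_term / A_term

  T <- 60 / config$hr
  t_sys <- lv$systolic_fraction * T
  E_min_si <- res_to_si(lv$E_min)
  Pven0 <- config$fluid$density * G_ACCEL * config$venous_head
  out_every <- max(1L, as.integer(round(1 / (num$output_fs * num$dt))))

  pars <- list(
    n = n, parent = as.integer(ladder$parent - 1L),
    C = C_fast, R = ladder$compartments$R_si,
    L = ladder$compartments$L_si,
    Cw = Cw, Rw = Rw,
    K = K, tcomp = as.integer(ladder$terminals - 1L),
    tRcl = rep(res_to_si(af$per_branch_outlet$clamp_resistance *
                           af$outlet_resistance_scale), K),
    tCsyr = comp_to_si(syr_c),
    tRs = R_port,
    V0lv = lv$V0 * M3_PER_ML,
    Cla = comp_to_si(config$la_compliance),
    Cres = comp_to_si(config$reservoir_compliance),
    Pven0 = Pven0,
    Cch1 = comp_to_si(af$chamber1_compliance),
    Cch2 = comp_to_si(af$chamber2_compliance),
    Ric = res_to_si(af$inter_chamber_resistance),
    Rout = res_to_si(af$chamber_out_resistance),
    Rven = res_to_si(config$venous_resistance),
    Rav = res_to_si(config$valves$aortic$open_resistance),
    Rmv = res_to_si(config$valves$mitral$open_resistance),
    wv = mmHg_to_Pa(config$valves$aortic$transition_width),
    E_min = E_min_si,
    E_amp = res_to_si(lv$contractility_scale * (lv$E_max - lv$E_min)),
    T = T, t_rise = lv$rise_fraction * t_sys, t_sys = t_sys,
    dt = num$dt, max_cycles = as.integer(num$max_cycles),
    out_cycles = as.integer(num$output_cycles), out_every = out_every,
    tol = mmHg_to_Pa(num$convergence_tol),
    tap_asc = as.integer(ladder$tap_map[["ascending_aorta"]] - 1L),
    tap_abd = as.integer(ladder$tap_map[["abdominal_aorta"]] - 1L),
    V_unstressed = (ladder$unstressed_volume_ml + lv$V0 + 120 + 500) * M3_PER_ML
  ) # 120/500 mL: nominal atrial and reservoir content for volume bookkeeping

  # initialize near the expected operating point: arterial nodes at the
  # configured prime pressure, chambers at their (low) steady-state fraction
  # of it, atrium and reservoir at the venous head, ventricle filled to the
  # diastolic equilibrium
  Pinit <- mmHg_to_Pa(num$init_arterial_pressure)
  # The ventricle starts at end-diastolic volume, above its cycle mean; with
  # a finite reservoir that surplus would otherwise drain venously and bias
  # the preload, so the reservoir starts short by the estimated LV surplus
  # (half the estimated ejected volume).
  edv_exc <- Pven0 / E_min_si
  esv_exc <- Pinit / (E_min_si + pars$E_amp)
  lv_surplus <- max(0, (edv_exc - esv_exc) / 2)
  y0 <- c(C_fast * Pinit,                             # compartment volumes
          numeric(n),                                 # link flows
          Cw * Pinit,                                 # wall creep volumes
          comp_to_si(syr_c) * Pinit,                  # syringe volumes
          comp_to_si(af$chamber1_compliance) * (0.25 * Pinit),
          comp_to_si(af$chamber2_compliance) * (0.15 * Pinit),
          -lv_surplus,                                # reservoir excess volume
          comp_to_si(config$la_compliance) * Pven0,
          lv$V0 * M3_PER_ML + Pven0 / E_min_si)

  raw <- .simulate_core(pars, y0)
  if (!raw$converged)
    warning("simulation did not reach periodic steady state within ",
            num$max_cycles, " cycles", call. = FALSE)

  m <- raw$samples_per_cycle
  fs <- 1 / raw$dt_out
  out <- raw$out
  t <- (seq_len(nrow(out)) - 1) * raw$dt_out
  P <- Pa_to_mmHg(out[, 1:4])
  Q <- lmin_from_si(out[, 5:8])
  asc_tap <- ladder$tap_map[["ascending_aorta"]]
  abd_tap <- ladder$tap_map[["abdominal_aorta"]]
  meta_common <- list(preset = config$preset %||% "custom", hr = config$hr,
                      units = "time_s,pressure_mmHg,flow_L_per_min")
  records <- list(
    LA = waveform_record("LA", fs, pressure = P[, 2], meta = meta_common),
    LV = waveform_record("LV", fs, pressure = P[, 1], meta = meta_common),
    ascending_aorta = waveform_record(
      "ascending_aorta", fs, pressure = P[, 3], flow = Q[, 3],
      meta = c(meta_common,
               diameter_mm = ladder$compartments$diameter_mm[asc_tap])),
    abdominal_aorta = waveform_record(
      "abdominal_aorta", fs, pressure = P[, 4], flow = Q[, 4],
      meta = c(meta_common,
               diameter_mm = ladder$compartments$diameter_mm[abd_tap]))
  )

  qav_mls <- out[, 5] / M3_PER_ML
  qmv_mls <- out[, 6] / M3_PER_ML
  structure(list(
    records = records,
    volumes = data.frame(t = t, total_ml = out[, 9] / M3_PER_ML),
    valve_events = list(aortic = valve_events(t, qav_mls),
                        mitral = valve_events(t, qmv_mls)),
    valve_flow = data.frame(t = t, aortic_ml_s = qav_mls, mitral_ml_s = qmv_mls),
    co_measured = lmin_from_si(raw$co_si),
    converged = raw$converged,
    cycles_run = raw$cycles_run,
    samples_per_cycle = m,
    ladder = ladder,
    effective_pwv = ladder$effective_pwv,
    static_compliance = static_compliance,
    syringe_compliance = syr_c,
    config = config
  ), class = "sim_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# open/close times from threshold crossings of a valve flow trace
valve_events <- function(t, q_mls, threshold = 1) {
  above <- q_mls > threshold
  d <- diff(above)
  list(open = t[which(d == 1) + 1], close = t[which(d == -1) + 1])
}

#' @export
print.sim_result <- function(x, ...) {
  cat("<sim_result> preset:", x$config$preset %||% "custom",
      if (x$converged) "(converged" else "(NOT converged",
      "after", x$cycles_run, "cycles)\n")
  cat(sprintf("  CO %.2f L/min at %.0f bpm; effective wave speed %.2f m/s\n",
              x$co_measured, x$config$hr, x$effective_pwv))
  invisible(x)
}

#' Calibrate the elastance to a target cardiac output
#'
#' The pump is neither a flow nor a pressure source, so cardiac output is an
#' emergent quantity. This helper adjusts `E_max` by a bounded secant
#' iteration (at most `max_iter` simulations) until the measured output is
#' within `tol` of the target.
#'
#' @param config A [circuit_config()].
#' @param target_co Target cardiac output (L/min).
#' @param tol Acceptable absolute error (L/min).
#' @param max_iter Maximum number of simulations.
#' @return List with the calibrated `config`, the final `sim` and the
#'   achieved `co`.
#' @export
calibrate_co <- function(config, target_co = 5, tol = 0.1, max_iter = 8) {
  stopifnot(target_co > 0)
  e <- config$lv$E_max
  sim <- simulate(config)
  co <- sim$co_measured
  it <- 1
  e_prev <- e; co_prev <- co
  while (abs(co - target_co) > tol && it < max_iter) {
    e_new <- if (it == 1 || abs(co - co_prev) < 1e-9) {
      max(config$lv$E_min * 1.05, e * target_co / max(co, 1e-6))
    } else {
      max(config$lv$E_min * 1.05,
          e + (target_co - co) * (e - e_prev) / (co - co_prev))
    }
    e_prev <- e; co_prev <- co; e <- e_new
    config$lv$E_max <- e
    sim <- simulate(config)
    co <- sim$co_measured
    it <- it + 1
  }
  list(config = config, sim = sim, co = co, iterations = it)
}
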
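#' Afterload parameters
#'
#' The arterial load distal to the aorta: each terminal branch ends in an
#' outlet unit - a half-filled air syringe acting as a compliance shunt at
#' the outlet node, followed by a clamp acting as the exit resistance - and
#' the collected outflow passes through a pair of air chambers joined by an
#' inter-chamber resistance valve before returning to the venous reservoir.
#' Tightening the outlet clamps is expressed by `outlet_resistance_scale`
#' (>= 1 models clamping).
#'
#' @param chamber1_compliance,chamber2_compliance Air-chamber compliances
#'   (mL/mmHg).
#' @param inter_chamber_resistance Resistance between the chambers
#'   (mmHg s/mL).
#' @param chamber_out_resistance Resistance from the second chamber to the
#'   reservoir (mmHg s/mL).
#' @param outlet_resistance_scale Dimensionless multiplier on every clamp
#'   resistance.
#' @param syringe_compliance Minimum outlet-unit syringe compliance
#'   (mL/mmHg); when the configuration targets a total static compliance the
#'   syringes absorb the part the tube itself does not provide.
#' @param clamp_resistance Outlet-unit clamp resistance (mmHg s/mL), shared
#'   by all terminal branches.
#' @param port_resistance_scale Dimensionless factor on each syringe port
#'   resistance relative to the characteristic impedance `rho c / A` of its
#'   terminal branch. 1 gives a matched (fully absorbing) high-frequency
#'   termination; smaller values let the syringes charge faster within
#'   systole at the price of stronger wave re-reflection.
#' @return List of class `afterload_params`.
#' @export
afterload_params <- function(chamber1_compliance = 0.25,
                             chamber2_compliance = 0.25,
                             inter_chamber_resistance = 0.15,
                             chamber_out_resistance = 0.10,
                             outlet_resistance_scale = 1,
                             syringe_compliance = 0.05,
                             clamp_resistance = 4.0,
                             port_resistance_scale = 4) {
  vals <- c(chamber1_compliance, chamber2_compliance, inter_chamber_resistance,
            chamber_out_resistance, syringe_compliance, clamp_resistance,
            port_resistance_scale)
  if (any(vals <= 0))
    stop("afterload compliances and resistances must be positive", call. = FALSE)
  if (outlet_resistance_scale < 1)
    stop("outlet_resistance_scale must be >= 1 (clamps only tighten)", call. = FALSE)
  structure(list(chamber1_compliance = chamber1_compliance,
                 chamber2_compliance = chamber2_compliance,
                 inter_chamber_resistance = inter_chamber_resistance,
                 chamber_out_resistance = chamber_out_resistance,
                 outlet_resistance_scale = outlet_resistance_scale,
                 port_resistance_scale = port_resistance_scale,
                 per_branch_outlet = list(syringe_compliance = syringe_compliance,
                                          clamp_resistance = clamp_resistance)),
            class = "afterload_params")
}

#' Full circuit configuration
#'
#' Assembles every parameter of the closed loop: heart rate, ventricular
#' elastance, atrial and reservoir properties, aortic geometry with its
#' stiffness targets, afterload, valves, fluid and numerics. Defaults
#' reproduce the baseline operating point (75 bpm, cardiac output near
#' 5 L/min, LVEDP near 7 mmHg, systolic/diastolic aortic pressure near
#' 121/81 mmHg) with the mid-range aorta (wave speed 12.6 m/s, compliance
#' 1.51 mL/mmHg).
#'
#' @param hr Heart rate (bpm).
#' @param lv An [lv_params()] object.
#' @param la_compliance Left-atrial compliance (mL/mmHg); the atrium is a
#'   passive compartment (no active kick).
#' @param venous_head Reservoir height (m); the venous base pressure is
#'   `rho * g * venous_head`.
#' @param venous_resistance Resistance from the reservoir into the atrium
#'   (mmHg s/mL).
#' @param reservoir_compliance Hydraulic compliance of the reservoir column
#'   (mL/mmHg); finite so that volume redistribution between the arterial
#'   and venous sides moves the venous pressure.
#' @param aorta_geometry Segment table, see [aorta_segments()].
#' @param target_pwv Aorta wave speed (m/s).
#' @param target_ac Total static arterial compliance (mL/mmHg) or `NULL`.
#' @param match How to reconcile the wave-speed and compliance targets,
#'   which are mutually inconsistent under Bramwell-Hill for a purely
#'   elastic tube of this geometry: `"distribute"` (default) keeps the tube
#'   wave-speed-true and spreads the compliance deficit
#'   `target_ac - C_tube - C_syringes` along the wall as a slow viscoelastic
#'   (creep) compliance with relaxation time `wall_relaxation_time` - the
#'   sealed-system static compliance then equals `target_ac` while wave
#'   fronts still travel near `target_pwv`, as in a lossy elastomer tube;
#'   `"ac"` rescales the elastic tube compliances so the tube alone matches
#'   `target_ac`, lowering the effective wave speed; `"pwv"` keeps the
#'   geometric compliances and ignores `target_ac`.
#' @param wall_relaxation_time Creep time constant of the viscoelastic wall
#'   (s) used by `match = "distribute"`.
#' @param stiffness_taper Distal-to-root wave-speed ratio of the aorta (see
#'   [build_aorta_ladder()]); a compliant root with a stiffer distal aorta
#'   is what produces the physiological downstream pulse-pressure
#'   amplification.
#' @param afterload An [afterload_params()] object.
#' @param valves List with `aortic` and `mitral` [valve_params()] objects.
#' @param fluid List with `density` (kg/m^3) and `viscosity` (Pa s); default
#'   is water at room temperature.
#' @param numerics List with `dt` (s), `max_cycles`, `convergence_tol`
#'   (mmHg), `output_fs` (Hz), `output_cycles`, `init_arterial_pressure`
#'   (mmHg).
#' @param preset Optional preset label carried in metadata.
#' @return List of class `circuit_config`.
#' @export
circuit_config <- function(hr = 75,
                           lv = lv_params(),
                           la_compliance = 10,
                           venous_head = 0.095,
                           venous_resistance = 0.02,
                           reservoir_compliance = 4,
                           aorta_geometry = aorta_segments(),
                           target_pwv = 12.6,
                           target_ac = 1.51,
                           match = c("distribute", "ac", "pwv"),
                           wall_relaxation_time = 0.05,
                           stiffness_taper = 3,
                           afterload = afterload_params(),
                           valves = list(aortic = valve_params(0.04),
                                         mitral = valve_params(0.012)),
                           fluid = list(density = 998, viscosity = 0.00089),
                           numerics = list(),
                           preset = NULL) {
  match <- match.arg(match)
  # enough recorded cycles for at least ~2.5 s of signal at any heart rate
  num <- utils::modifyList(list(dt = 1e-4, max_cycles = 50, convergence_tol = 0.5,
                                output_fs = 1000,
                                output_cycles = max(4, ceiling(2.5 * hr / 60)),
                                init_arterial_pressure = 94), numerics)
  if (hr <= 0) stop("hr must be positive", call. = FALSE)
  if (num$dt <= 0) stop("dt must be positive", call. = FALSE)
  if (num$convergence_tol <= 0) stop("convergence_tol must be positive", call. = FALSE)
  if (la_compliance <= 0 || venous_resistance <= 0 || reservoir_compliance <= 0)
    stop("atrial/venous parameters must be positive", call. = FALSE)
  if (venous_head < 0) stop("venous_head must be nonnegative", call. = FALSE)
  if (wall_relaxation_time <= 0)
    stop("wall_relaxation_time must be positive", call. = FALSE)
  if (stiffness_taper < 1)
    stop("stiffness_taper must be >= 1", call. = FALSE)
  stopifnot(inherits(lv, "lv_params"), inherits(afterload, "afterload_params"),
            inherits(valves$aortic, "valve_params"),
            inherits(valves$mitral, "valve_params"))
  validate_segments(aorta_geometry)
  structure(list(hr = hr, lv = lv, la_compliance = la_compliance,
                 venous_head = venous_head, venous_resistance = venous_resistance,
                 reservoir_compliance = reservoir_compliance,
                 aorta_geometry = aorta_geometry,
                 target_pwv = target_pwv, target_ac = target_ac, match = match,
                 wall_relaxation_time = wall_relaxation_time,
                 stiffness_taper = stiffness_taper,
                 afterload = afterload, valves = valves, fluid = fluid,
                 numerics = num, preset = preset),
            class = "circuit_config")
}

#' @export
print.circuit_config <- function(x, ...) {
  cat("<circuit_config>", if (!is.null(x$preset)) paste0(" preset: ", x$preset), "\n",
      sep = "")
  cat(sprintf("  hr %.0f bpm; E_max %.2f * scale %.2f mmHg/mL; venous head %.3f m\n",
              x$hr, x$lv$E_max, x$lv$contractility_scale, x$venous_head))
  cat(sprintf("  aorta: wave speed %.1f m/s, compliance %s mL/mmHg (match %s)\n",
              x$target_pwv,
              if (is.null(x$target_ac)) "geometric" else format(x$target_ac), x$match))
  invisible(x)
}

# Table of fabricated-aorta stiffness grades: wave speed (m/s) and total
# compliance (mL/mmHg) for grades 1 (most compliant) to 8 (stiffest).
aorta_grades <- function() {
  data.frame(grade = 1:8,
             pwv = c(5.6, 10.6, 12.6, 16.6, 17.3, 18.0, 19.7, 21.7),
             ac = c(2.28, 1.78, 1.51, 1.43, 1.31, 1.19, 0.83, 0.71),
             material = c("silicone", "latex", "latex", "latex", "latex",
                          "latex", "latex", "silicone"))
}

#' Scenario presets
#'
#' Named configurations spanning the study grid: a baseline (75 bpm, cardiac
#' output near 5 L/min, LVEDP near 7 mmHg, total peripheral resistance near
#' 18.85 mmHg min/L, mid-range aorta stiffness), cardiac-output levels
#' `co_2` .. `co_5`, heart rates `hr_50` .. `hr_125`, aorta stiffness grades
#' `aorta_1` .. `aorta_8`, contractility levels, a high-resistance scenario,
#' and low/high preload. Each intervention preset changes only its own knob
#' relative to baseline: preload presets move only the venous head,
#' contractility presets only the contractility scale, `high_tpr` only the
#' outlet clamp scale.
#'
#' @param name Preset name; one of `baseline`, `low_contractility`,
#'   `high_contractility`, `co_2`..`co_5`, `hr_50`, `hr_75`, `hr_100`,
#'   `hr_125`, `aorta_1`..`aorta_8`, `high_tpr`, `low_preload`,
#'   `high_preload`.
#' @param ... Overrides passed on to [circuit_config()].
#' @return A `circuit_config`.
#' @export
#' @examples
#' make_preset("aorta_3")$target_pwv  # 12.6 m/s
make_preset <- function(name, ...) {
  grades <- aorta_grades()
  presets <- c("baseline", "low_contractility", "high_contractility",
               paste0("co_", 2:5), paste0("hr_", c(50, 75, 100, 125)),
               paste0("aorta_", 1:8), "high_tpr", "low_preload", "high_preload")
  if (!is.character(name) || length(name) != 1 || !(name %in% presets))
    stop("unknown preset ", if (is.character(name)) sQuote(name) else "",
         "; valid presets: ", paste(presets, collapse = ", "), call. = FALSE)
  args <- list(preset = name)
  if (name %in% c("low_contractility", "high_contractility")) {
    # contractility grades follow the measured LV dp/dt ratios
    # (low/normal = 937.4/1432.7, high/normal = 2558.3/1432.7)
    s <- if (name == "low_contractility") 0.65 else 1.79
    args$lv <- lv_params(contractility_scale = s)
  } else if (grepl("^co_", name)) {
    k <- as.numeric(sub("co_", "", name))
    # reduced stroke volume through a smaller elastance excursion; factors
    # chosen once so the measured output lands near the nominal level
    f <- c(`2` = 0.16, `3` = 0.29, `4` = 0.52, `5` = 1)[as.character(k)]
    base <- lv_params()
    args$lv <- lv_params(E_max = base$E_min + f * (base$E_max - base$E_min))
  } else if (grepl("^hr_", name)) {
    args$hr <- as.numeric(sub("hr_", "", name))
  } else if (grepl("^aorta_", name)) {
    g <- grades[grades$grade == as.integer(sub("aorta_", "", name)), ]
    args$target_pwv <- g$pwv
    args$target_ac <- g$ac
  } else if (name == "high_tpr") {
    args$afterload <- afterload_params(outlet_resistance_scale = 2.2)
  } else if (name == "low_preload") {
    args$venous_head <- 0.03
  } else if (name == "high_preload") {
    args$venous_head <- 0.18
  }
  do.call(circuit_config, utils::modifyList(args, list(...)))
}
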
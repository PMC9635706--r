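# Unit conversion between the interface units (mmHg, mL, L/min, bpm) and the
# SI units (Pa, m^3, s) used internally by the circuit model.

PA_PER_MMHG <- 133.322
M3_PER_ML <- 1e-6

#' @keywords internal
mmHg_to_Pa <- function(x) x * PA_PER_MMHG

#' @keywords internal
Pa_to_mmHg <- function(x) x / PA_PER_MMHG

# compliance mL/mmHg <-> m^3/Pa
comp_to_si <- function(x) x * M3_PER_ML / PA_PER_MMHG
comp_from_si <- function(x) x / M3_PER_ML * PA_PER_MMHG

# resistance mmHg*s/mL <-> Pa*s/m^3 (inertance mmHg*s^2/mL uses same factor)
res_to_si <- function(x) x * PA_PER_MMHG / M3_PER_ML
res_from_si <- function(x) x / PA_PER_MMHG * M3_PER_ML

# flow L/min <-> m^3/s
lmin_to_si <- function(x) x * 1e-3 / 60
lmin_from_si <- function(x) x * 60 / 1e-3
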
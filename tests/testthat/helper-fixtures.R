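# Shared fixtures: cached simulations and constructed waveforms.

.sim_cache <- new.env(parent = emptyenv())

# memoized preset simulation so several test files can share one run
cached_sim <- function(name, ...) {
  key <- paste(name, rlang::hash(list(...)), sep = "_")
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- simulate(make_preset(name, ...))
  .sim_cache[[key]]
}

# straight main-path-only aorta: the clean wave-propagation test rig
straight_geometry <- function(compartment_length_mm = 10) {
  g <- aorta_segments(compartment_length_mm)
  g[g$name %in% c("ascending_aorta", "aortic_arch", "thoracic_aorta",
                  "abdominal_aorta", "iliac_artery"), ]
}

# elastic (no creep), untapered tube with absorbing outlet: waves travel at
# exactly the configured speed
elastic_tube_config <- function(output_fs = 2000) {
  make_preset("baseline", match = "pwv", stiffness_taper = 1,
              aorta_geometry = straight_geometry(),
              lv = lv_params(systolic_fraction = 0.25),
              afterload = afterload_params(port_resistance_scale = 1,
                                           syringe_compliance = 0.3),
              numerics = list(output_fs = output_fs))
}

# periodic arterial-like pulse train with a smooth rounded foot
make_pulse_train <- function(hr = 75, fs = 1000, dur = 4, sbp = 120, dbp = 80) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  T <- 60 / hr
  ph <- (t %% T) / T
  # arterial-like shape: steep upstroke (15% of the cycle), slower decline
  rise <- 0.5 * (1 - cos(pi * ph / 0.15))
  fall <- 0.5 * (1 + cos(pi * (ph - 0.15) / 0.40))
  dbp + (sbp - dbp) * ifelse(ph < 0.15, rise, ifelse(ph < 0.55, fall, 0))
}

# single type-A beat with a constructed inflection: a primary rise to a
# brief plateau at a known pressure (Pi), then a reflected rise to the
# augmented systolic peak, then a slow decay. Pi = 105 mmHg by construction.
make_augmented_beat <- function(fs = 1000, dur = 0.8) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  step <- function(t, t0, t1) {
    x <- pmin(1, pmax(0, (t - t0) / (t1 - t0)))
    0.5 * (1 - cos(pi * x))
  }
  p <- 80 + 25 * step(t, 0.02, 0.12) +          # primary: plateau at 105
    15 * step(t, 0.17, 0.25) -                  # reflection: peak at 120
    40 * step(t, 0.30, 0.75)                    # diastolic decay
  list(t = t, pressure = p, fs = fs, pi_true = 105)
}
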
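test_that("a passive ventricle pumps essentially nothing", {
  cfg <- make_preset("baseline", lv = lv_params(contractility_scale = 0),
                     numerics = list(max_cycles = 10))
  sim <- suppressWarnings(simulate(cfg))
  expect_lt(sim$co_measured, 0.05)
})

test_that("two runs with the same configuration are bit-identical", {
  a <- simulate(make_preset("baseline", numerics = list(max_cycles = 6,
                                                        output_cycles = 2)))
  b <- simulate(make_preset("baseline", numerics = list(max_cycles = 6,
                                                        output_cycles = 2)))
  expect_identical(a$records$ascending_aorta$pressure,
                   b$records$ascending_aorta$pressure)
  expect_identical(a$volumes$total_ml, b$volumes$total_ml)
  expect_identical(a$co_measured, b$co_measured)
})

test_that("converged baseline conserves volume and keeps valve flows one-way", {
  sim <- cached_sim("baseline")
  expect_true(sim$converged)
  v <- sim$volumes$total_ml
  expect_lt((max(v) - min(v)) / mean(v), 1e-3)
  expect_gte(min(sim$valve_flow$aortic_ml_s), -1e-9)
  expect_gte(min(sim$valve_flow$mitral_ml_s), -1e-9)
})

test_that("baseline mean pressure balances flow times configured resistance", {
  sim <- cached_sim("baseline")
  af <- sim$config$afterload
  r_total <- af$per_branch_outlet$clamp_resistance *
    af$outlet_resistance_scale / length(sim$ladder$terminals) +
    af$inter_chamber_resistance + af$chamber_out_resistance      # mmHg s/mL
  p_ven <- sim$config$fluid$density * 9.80665 * sim$config$venous_head / 133.322
  asc <- sim$records$ascending_aorta
  beats <- detect_beats(asc$pressure, asc$fs, hr_hint = sim$config$hr)
  map <- mean_pressure(asc$pressure, beats)
  co_mls <- sim$co_measured * 1000 / 60
  expect_equal(map, co_mls * r_total + p_ven, tolerance = 0.05 * map)
})

test_that("pressure feet arrive at the configured wave speed on an elastic tube", {
  sim <- cached_sim("baseline", match = "pwv", stiffness_taper = 1,
                    aorta_geometry = straight_geometry(),
                    lv = lv_params(systolic_fraction = 0.25),
                    afterload = afterload_params(port_resistance_scale = 1,
                                                 syringe_compliance = 0.3),
                    numerics = list(output_fs = 2000))
  m <- sim$samples_per_cycle
  p1 <- sim$records$ascending_aorta$pressure[1:m]
  p2 <- sim$records$abdominal_aorta$pressure[1:m]
  fs <- sim$records$ascending_aorta$fs
  arrival <- function(x) {
    base <- min(x[1:round(0.2 * m)])
    which(x > base + 0.02 * (max(x) - base))[1] / fs
  }
  transit <- arrival(p2) - arrival(p1)
  expect_equal(0.27 / transit, 12.6, tolerance = 0.1 * 12.6)  # oracle: d / c
})

test_that("non-convergence is reported, not hidden", {
  cfg <- make_preset("baseline", numerics = list(max_cycles = 2,
                                                 output_cycles = 2))
  expect_warning(sim <- simulate(cfg), "steady state")
  expect_false(sim$converged)
})

test_that("simulation records carry the four measurement sites", {
  sim <- cached_sim("baseline")
  expect_named(sim$records, c("LA", "LV", "ascending_aorta", "abdominal_aorta"))
  expect_s3_class(sim$records$LV, "waveform_record")
  expect_false(is.null(sim$records$ascending_aorta$flow))
  # valve events: one opening per recorded cycle
  n_cycles <- length(sim$records$LV$pressure) / sim$samples_per_cycle
  expect_equal(length(sim$valve_events$aortic$open), n_cycles)
})

test_that("cardiac-output calibration converges to the target", {
  cal <- calibrate_co(make_preset("baseline"), target_co = 4, tol = 0.15,
                      max_iter = 6)
  expect_lt(abs(cal$co - 4), 0.15)
})
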
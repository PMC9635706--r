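test_that("ensemble averaging preserves identical beats and shrinks noise", {
  fs <- 1000
  p <- make_pulse_train(hr = 75, fs = fs, dur = 4.2)
  rec <- waveform_record("other", fs, p)
  b <- detect_beats(p, fs)
  ens <- ensemble_average_beat(rec, b)
  w <- p[b$onsets[1]:b$onsets[2]]
  expect_equal(length(ens$pressure), length(w), tolerance = 2)
  expect_equal(ens$pressure[1:min(length(w), length(ens$pressure))],
               w[1:min(length(w), length(ens$pressure))], tolerance = 1e-6)

  # seeded noise: averaging n beats shrinks the residual roughly as 1/sqrt(n)
  set.seed(11)
  long <- make_pulse_train(hr = 75, fs = fs, dur = 17)
  noisy <- long + rnorm(length(long), sd = 2)
  bl <- detect_beats(noisy, fs, hr_hint = 75)
  ensn <- ensemble_average_beat(waveform_record("other", fs, noisy), bl)
  n_beats <- sum(bl$accepted)
  m <- length(ensn$pressure)
  clean <- p[b$onsets[1]:b$onsets[2]]
  cleanm <- approx(seq_along(clean), clean, xout = seq(1, length(clean),
                                                       length.out = m))$y
  resid <- sd(ensn$pressure - cleanm)
  expect_lt(resid, 2 / sqrt(n_beats) * 2.5)
  expect_gt(n_beats, 10)

  # single beat passes through with a warning
  short <- p[1:900]
  bs <- structure(list(onsets = c(1L, 801L), foot_times = c(0, 0.8),
                       upstroke_idx = c(10L, 810L), accepted = FALSE,
                       hr_estimate = 75, fs = fs), class = "beat_index")
  expect_warning(e1 <- ensemble_average_beat(waveform_record("other", fs, short), bs),
                 "fewer than 2")
  expect_equal(e1$pressure, short[1:801])
})

test_that("input impedance matches a purely resistive load", {
  fs <- 1000
  t <- seq(0, 0.799, by = 1 / fs)
  p <- 100 + 10 * sin(2 * pi * 1.25 * t) + 4 * sin(2 * pi * 2.5 * t + 1)
  q <- p / 1.2                      # mL/s through R = 1.2 mmHg s/mL
  z <- input_impedance(p, q, fs, k_max = 5)
  expect_equal(z$spectrum$modulus[z$spectrum$reliable],
               rep(1.2, sum(z$spectrum$reliable)), tolerance = 1e-9)
  expect_equal(z$spectrum$phase[z$spectrum$reliable],
               rep(0, sum(z$spectrum$reliable)), tolerance = 1e-9)
  expect_equal(z$spectrum$frequency[2], 1.25)
  expect_error(input_impedance(p - 100, q - mean(q), fs), "zero mean flow")
})

test_that("input impedance matches the two-element Windkessel closed form", {
  fs <- 1000
  R <- 1.1    # mmHg s/mL
  C <- 1.4    # mL/mmHg
  t <- seq(0, 0.799, by = 1 / fs)
  f0 <- 1.25
  q <- 80 + 30 * sin(2 * pi * f0 * t) + 15 * sin(2 * pi * 2 * f0 * t + 0.5) +
    8 * sin(2 * pi * 3 * f0 * t - 1)
  # synthesize P through Z(w) = R / (1 + i w R C) harmonic by harmonic
  n <- length(q)
  qf <- fft(q) / n
  zf <- complex(real = 0, imaginary = 0) * numeric(n)
  k <- 0:(n - 1)
  freq <- ifelse(k <= n / 2, k, k - n) * fs / n
  zw <- R / (1 + 1i * 2 * pi * freq * R * C)
  p <- Re(fft(qf * zw, inverse = TRUE))
  z <- input_impedance(p, q, fs, k_max = 3)
  for (j in 1:4) {
    w <- 2 * pi * z$spectrum$frequency[j]
    expect_equal(z$spectrum$modulus[j], R / sqrt(1 + (w * R * C)^2),
                 tolerance = 0.01 * R)
    expect_equal(z$spectrum$phase[j], -atan(w * R * C), tolerance = 0.01 * pi)
  }
})

test_that("impedance harmonic 0 equals mean pressure over mean flow", {
  sim <- cached_sim("baseline")
  asc <- sim$records$ascending_aorta
  b <- detect_beats(asc$pressure, asc$fs, hr_hint = 75)
  ens <- ensemble_average_beat(asc, b)
  q_mls <- ens$flow * 1000 / 60
  z <- input_impedance(ens$pressure, q_mls, ens$fs)
  co_lmin <- mean(ens$flow)
  expect_equal(z$r0_mmHg_min_L, tpr(mean(ens$pressure), co_lmin),
               tolerance = 1e-3 * z$r0_mmHg_min_L)
  # input resistance exceeds the high-frequency plateau
  expect_gt(z$spectrum$modulus[1], mean(z$spectrum$modulus[11:16]))
})

test_that("wave intensity vanishes for constant velocity and is forward for waterhammer", {
  fs <- 1000
  t <- seq(0, 0.799, by = 1 / fs)
  p <- 90 + 25 * exp(-((t - 0.2) / 0.05)^2)
  expect_lt(max(abs(wave_intensity(p, rep(0.2, length(p)), fs)$di)), 1e-6)
  expect_true(all(wave_intensity(p, rep(0.2, length(p)), fs,
                                 convention = "per-sample")$di == 0))
  # forward wave: P - P0 = rho c U, i.e. U proportional to the excess pressure
  u <- (p - 90) * 133.322 / (998 * 12.6)
  for (conv in c("time-normalized", "per-sample")) {
    di <- wave_intensity(p, u, fs, convention = conv)$di
    expect_gte(min(di), -1e-9 * max(abs(di)))
  }
})

test_that("the two wave-intensity conventions agree after rate normalization", {
  fs <- 1000
  t <- seq(0, 0.799, by = 1 / fs)
  p <- 90 + 20 * sin(2 * pi * 2 * t) + 5 * sin(2 * pi * 5 * t)
  u <- 0.1 + 0.08 * sin(2 * pi * 2 * t - 0.3)
  a <- wave_intensity(p, u, fs, convention = "per-sample")$di * fs^2
  b <- wave_intensity(p, u, fs, convention = "time-normalized")$di
  core <- 50:730
  expect_equal(a[core], b[core], tolerance = 0.05 * max(abs(b)))
})

test_that("wave-intensity peaks are labeled from constructed lobes", {
  fs <- 1000
  t <- seq(0, 0.599, by = 1 / fs)
  di <- 100 * exp(-((t - 0.08) / 0.02)^2) - 25 * exp(-((t - 0.18) / 0.025)^2) +
    40 * exp(-((t - 0.30) / 0.02)^2)
  wi <- structure(list(t = t, di = di, fs = fs, convention = "time-normalized",
                       peaks = NULL), class = "wave_intensity")
  wi <- detect_wi_peaks(wi)
  expect_equal(wi$peaks$label, c("Wf1", "Wb", "Wf2"))
  expect_equal(wi$peaks$time, c(0.08, 0.18, 0.30), tolerance = 2 / fs)
  expect_true(wi$peaks$amplitude[1] > 0 && wi$peaks$amplitude[2] < 0 &&
                wi$peaks$amplitude[3] > 0)

  wi0 <- detect_wi_peaks(structure(list(t = t, di = rep(0, length(t)), fs = fs,
                                        convention = "time-normalized",
                                        peaks = NULL), class = "wave_intensity"))
  expect_equal(nrow(wi0$peaks), 0)

  hump <- detect_wi_peaks(structure(list(t = t,
                                         di = exp(-((t - 0.1) / 0.04)^2),
                                         fs = fs, convention = "time-normalized",
                                         peaks = NULL), class = "wave_intensity"))
  expect_equal(hump$peaks$label, "Wf1")
})

test_that("foot-to-foot transit recovers constructed delays exactly", {
  for (fs in c(500, 1000, 2000)) {
    p <- make_pulse_train(hr = 75, fs = fs, dur = 4)
    for (delay_ms in c(2, 5, 10, 20)) {
      lag <- as.integer(round(delay_ms / 1000 * fs))
      if (lag < 1) next
      pd <- c(rep(p[1], lag), p[1:(length(p) - lag)])
      est <- foot_to_foot_pwv(p, pd, fs, path_distance = 0.12)
      expect_equal(est$transit_time, lag / fs, tolerance = 1 / fs + 1e-9)
    }
    expect_error(foot_to_foot_pwv(p, p, fs, 0.12), "transit|unresolvable")
  }
  expect_error(foot_to_foot_pwv(make_pulse_train(), make_pulse_train(), 1000, -1),
               "positive")
})

test_that("simulated feet travel at the ladder's configured speed", {
  sim <- cached_sim("baseline", match = "pwv", stiffness_taper = 1,
                    aorta_geometry = straight_geometry(),
                    lv = lv_params(systolic_fraction = 0.25),
                    afterload = afterload_params(port_resistance_scale = 1,
                                                 syringe_compliance = 0.3),
                    numerics = list(output_fs = 2000))
  est <- foot_to_foot_pwv(sim$records$ascending_aorta$pressure,
                          sim$records$abdominal_aorta$pressure,
                          sim$records$ascending_aorta$fs, 0.27)
  expect_equal(est$pwv, 12.6, tolerance = 0.1 * 12.6)
})

test_that("velocity from flow follows the area law", {
  expect_equal(velocity_from_flow(5, 24), (5 / 60000) / (pi * 0.024^2 / 4),
               tolerance = 1e-9)
  expect_equal(velocity_from_flow(5, 24), 0.184, tolerance = 0.002)
  expect_equal(velocity_from_flow(0, 24), 0)
  expect_equal(velocity_from_flow(5, 48), velocity_from_flow(5, 24) / 4,
               tolerance = 1e-12)
  expect_error(velocity_from_flow(5, 0), "positive")
})

test_that("fifteen harmonics reconstruct simulated beats almost completely", {
  sim <- cached_sim("baseline")
  asc <- sim$records$ascending_aorta
  b <- detect_beats(asc$pressure, asc$fs, hr_hint = 75)
  p <- ensemble_average_beat(asc, b)$pressure
  n <- length(p)
  pf <- fft(p) / n
  idx <- 0:(n - 1)
  recon <- vapply(idx, function(i)
    Re(pf[1]) + sum(2 * Re(pf[2:16] * exp(2i * pi * (1:15) * i / n))), numeric(1))
  expect_gt(1 - var(p - recon) / var(p), 0.99)
})
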
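fabricated_beats <- function(onsets, fs = 1000) {
  structure(list(onsets = as.integer(onsets),
                 foot_times = (onsets - 1) / fs,
                 upstroke_idx = as.integer(onsets + 5),
                 accepted = rep(TRUE, length(onsets) - 1),
                 hr_estimate = 60 * fs / stats::median(diff(onsets)), fs = fs),
            class = "beat_index")
}

test_that("beat feet of an exact periodic pulse are found on the grid", {
  fs <- 1000
  p <- make_pulse_train(hr = 75, fs = fs, dur = 4)
  b <- detect_beats(p, fs)
  expect_true(all(abs(diff(b$onsets) - 800) <= 1))
  expect_equal(b$hr_estimate, 75, tolerance = 0.5 / 75)
})

test_that("beat detection is robust to 5% pulse-pressure noise", {
  fs <- 1000
  p <- make_pulse_train(hr = 75, fs = fs, dur = 4)
  set.seed(42)
  noisy <- p + rnorm(length(p), sd = 0.05 * (max(p) - min(p)))
  b0 <- detect_beats(p, fs)
  b1 <- detect_beats(noisy, fs)
  expect_equal(length(b1$onsets), length(b0$onsets))
  expect_true(all(abs(b1$onsets - b0$onsets) <= 3))
})

test_that("degenerate inputs raise detection errors", {
  expect_error(detect_beats(rep(90, 4000), 1000), "flat|upstroke")
  expect_error(detect_beats(make_pulse_train(dur = 1), 1000), "2 s")
  expect_error(detect_beats(make_pulse_train(), 50), "100 Hz")
})

test_that("per-beat extrema match closed forms and brute force", {
  fs <- 1000
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  p <- 100 + 20 * sin(2 * pi * t / 0.8)
  b <- fabricated_beats(seq(1, 3201, by = 800))
  ex <- extract_extrema(p, b)
  expect_equal(ex$sbp, 120, tolerance = 1e-3)
  expect_equal(ex$dbp, 80, tolerance = 1e-3)
  expect_equal(ex$pp, 40, tolerance = 2e-3)
  # brute-force oracle on a single beat window
  w <- p[1:801]
  expect_equal(ex$per_beat$sbp[1], max(w))
  expect_equal(ex$per_beat$dbp[1], min(w))
  # constant trace through fabricated feet
  exc <- extract_extrema(rep(90, 4000), b)
  expect_equal(exc$sbp, 90)
  expect_equal(exc$pp, 0)
})

test_that("time-averaged mean pressure integrates whole beats", {
  fs <- 1000
  b <- fabricated_beats(seq(1, 3201, by = 800))
  expect_equal(mean_pressure(rep(94.25, 4000), b), 94.25)
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  p <- 100 + 20 * sin(2 * pi * t / 0.8)
  expect_equal(mean_pressure(p, b), 100, tolerance = 1e-3)
  # discrete-mean oracle on one exact beat window
  one <- fabricated_beats(c(1, 801))
  expect_equal(mean_pressure(p, one), mean(p[1:800]), tolerance = 0.01)
})

test_that("one-third rule and form factor reproduce printed arithmetic", {
  expect_equal(round(map_onethird(121.20, 80.78), 2), 94.25)
  expect_equal(map_onethird(120, 60), 80)
  expect_equal(map_onethird(80, 80), 80)
  expect_error(map_onethird(70, 80), ">=")

  expect_equal(round(form_factor(94.25, 121.20, 80.78), 2), 0.33)
  expect_equal(form_factor(80, 120, 80), 0)
  expect_equal(form_factor(120, 120, 80), 1)
  expect_error(form_factor(90, 100, 100), "undefined")
})

test_that("augmentation index recovers a constructed inflection", {
  beat <- make_augmented_beat()
  ai <- augmentation_index(beat$pressure, beat$fs)
  expect_true(ai$defined)
  # Pi by construction: the plateau where the reflected wave takes off
  expect_lt(abs(ai$pi - beat$pi_true), 1)
  expect_equal(ai$aix, 100 * ai$ap / (ai$sbp - ai$dbp), tolerance = 1e-9)
  # direct formula check on constructed numbers
  expect_equal(100 * 10 / 40, 25)

  # single smooth bump has no reflected take-off
  t <- seq(0, 0.799, by = 1e-3)
  gauss <- 80 + 40 * exp(-((t - 0.2) / 0.06)^2)
  expect_false(augmentation_index(gauss, 1000)$defined)
  expect_error(augmentation_index(gauss[1:100], 1000), "0.2 s")
})

test_that("dp/dt max matches analytic slopes", {
  fs <- 1000
  t <- seq(0, 3.999, by = 1 / fs)
  b <- fabricated_beats(seq(1, 3201, by = 800))
  ramp <- 500 * t
  expect_equal(dpdt_max(ramp, fs, b), 500, tolerance = 0.01 * 500)
  sine <- 100 + 20 * sin(2 * pi * 1.25 * t)
  expect_equal(dpdt_max(sine, fs, b), 20 * 2 * pi * 1.25, tolerance = 0.01 * 157.1)
  expect_equal(dpdt_max(rep(90, 4000), fs, b), 0)
})

test_that("LVEDP reads the pre-upstroke plateau", {
  fs <- 1000
  one <- function(t0, t) {
    ifelse(t < t0, 7, ifelse(t < t0 + 0.15, 7 + (t - t0) / 0.15 * 110,
                             pmax(7, 117 - (t - t0 - 0.15) / 0.2 * 110)))
  }
  t <- seq(0, 3.999, by = 1 / fs)
  p <- sapply(t %% 0.8, function(x) one(0.2, x))
  b <- detect_beats(p, fs)
  expect_equal(lvedp_extract(p, fs, b), 7, tolerance = 0.5)
  expect_identical(lvedp_extract(p, fs, b), lvedp_extract(p, fs, b))
})

test_that("TPR and stroke volume reproduce the clinical arithmetic", {
  expect_equal(tpr(94.25, 5), 18.85)
  expect_equal(tpr(100, 5), 20)
  expect_error(tpr(94, 0), "positive")

  sv <- stroke_volume(5, 75)
  expect_equal(sv$sv, 1000 * 5 / 75)
  expect_equal(sv$sv_rounded, 67)
  expect_equal(stroke_volume(2, 125)$sv_rounded, 16)
  expect_equal(stroke_volume(5, 50)$sv_rounded, 100)
  expect_error(stroke_volume(5, 0), "positive")
})

test_that("inflation compliance fits exact and noisy lines", {
  p <- seq(0, 10, by = 0.5)
  v <- 1.51 * p + 3
  expect_equal(compliance_from_inflation(v, p), 1.51, tolerance = 1e-9)
  set.seed(7)
  p2 <- seq(0.5, 10, length.out = 20)
  v2 <- 2.28 * p2 + rnorm(20, sd = 0.02)
  expect_equal(compliance_from_inflation(v2, p2), 2.28, tolerance = 0.05 * 2.28)
  expect_error(compliance_from_inflation(c(1, 2), c(5, 5)), "degenerate")
  expect_error(compliance_from_inflation(1, 5), "two matched")
})

test_that("summary fills derivable indices and reasons the rest", {
  sim <- cached_sim("baseline")
  s <- summarize(sim$records$ascending_aorta, hr = 75)
  for (k in c("sbp", "dbp", "pp", "map_timeavg", "map_onethird", "ff",
              "dpdt_max", "co", "sv", "tpr"))
    expect_true(k %in% names(s$values), info = k)
  expect_true(s$values$dbp <= s$values$map_timeavg &&
                s$values$map_timeavg <= s$values$sbp)
  expect_true(s$values$ff >= 0 && s$values$ff <= 1)
  expect_equal(s$absent$lvedp, "site")

  sl <- summarize(sim$records$LA, hr = 75)
  expect_equal(sl$absent$lvedp, "site")
  expect_equal(sl$absent$co, "no flow")
  expect_equal(sl$absent$tpr, "no flow")

  slv <- summarize(sim$records$LV, hr = 75)
  expect_true("lvedp" %in% names(slv$values))
})

test_that("indices are invariant to time offset and resampling", {
  fs <- 1000
  p <- make_pulse_train(hr = 75, fs = fs, dur = 4)
  rec1 <- waveform_record("other", fs, p)
  # constant time offset: identical samples, shifted time base
  rec2 <- waveform_record("other", fs, p, t = (seq_along(p) - 1) / fs + 10)
  s1 <- summarize(rec1, hr = 75)
  s2 <- summarize(rec2, hr = 75)
  expect_equal(s1$values$sbp, s2$values$sbp)
  expect_equal(s1$values$map_timeavg, s2$values$map_timeavg)
  # fs doubling by exact resampling
  p2 <- approx(seq_along(p), p, xout = seq(1, length(p), by = 0.5))$y
  s3 <- summarize(waveform_record("other", 2 * fs, p2), hr = 75)
  for (k in c("sbp", "dbp", "map_timeavg", "ff"))
    expect_equal(s3$values[[k]], s1$values[[k]], tolerance = 0.01,
                 info = k)
  expect_equal(s3$values$dpdt_max, s1$values$dpdt_max, tolerance = 0.015 * s1$values$dpdt_max)
})

test_that("irregular beats are rejected from ensemble statistics", {
  fs <- 1000
  # 0.8 s beats with one 1.2 s outlier
  on <- c(0, 800, 1600, 2800, 3600) + 1
  b <- fabricated_beats(on)
  spacing <- diff(on)
  accepted <- abs(spacing - median(spacing)) <= 0.2 * median(spacing)
  expect_equal(sum(accepted), 3)
})
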
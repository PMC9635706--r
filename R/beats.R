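# Per-beat scalar indices from pressure traces: beat feet by the
# intersecting-tangent rule, systolic/diastolic/mean pressures, form factor,
# augmentation, dp/dt max, LVEDP, and the derived circulation indices.

# zero-phase 4th-order Butterworth low-pass (default 25 Hz); identity when
# the signal is too short or the cutoff is above Nyquist. The signal is
# extended by odd reflection at both ends before filtering so that filter
# start-up transients do not corrupt boundary derivatives.
lowpass <- function(x, fs, cutoff = 25) {
  n <- length(x)
  if (cutoff >= fs / 2 || n < 24) return(x)
  bf <- signal::butter(4, cutoff / (fs / 2))
  pad <- min(n - 1, as.integer(round(fs / 4)))
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- as.numeric(signal::filtfilt(bf, xp))
  y[(pad + 1):(pad + n)]
}

# central-difference derivative (one-sided at the ends), per second
deriv <- function(x, fs) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
  d[1] <- (x[2] - x[1]) * fs
  d[n] <- (x[n] - x[n - 1]) * fs
  d
}

# Fractional foot times (s) by the intersecting-tangent rule: the tangent at
# the point of maximal upstroke slope intersected with the horizontal line
# through the preceding minimum.
find_feet <- function(pressure, fs, hr_hint = NULL) {
  n <- length(pressure)
  if (diff(range(pressure)) < 1e-9)
    stop("no detectable upstrokes: signal is flat", call. = FALSE)
  ps <- lowpass(pressure, fs)
  dp <- deriv(ps, fs)
  peak_slope <- max(dp)
  if (peak_slope <= 0)
    stop("no detectable upstrokes: no rising segment", call. = FALSE)
  thr <- 0.5 * peak_slope
  above <- dp >= thr
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  idx_up <- mapply(function(s, e) s - 1 + which.max(dp[s:e]),
                   starts[runs$values], ends[runs$values])
  # merge upstroke candidates closer than 0.25 s (sub-beat slope bumps)
  if (length(idx_up) > 1) {
    keep <- c()
    cur <- idx_up[1]
    for (i in idx_up[-1]) {
      if ((i - cur) / fs < 0.25) {
        if (dp[i] > dp[cur]) cur <- i
      } else {
        keep <- c(keep, cur); cur <- i
      }
    }
    idx_up <- c(keep, cur)
  }
  period <- if (!is.null(hr_hint)) 60 / hr_hint
            else if (length(idx_up) > 1) stats::median(diff(idx_up)) / fs
            else n / fs
  feet <- upstrokes <- numeric(0)
  for (u in idx_up) {
    w0 <- max(1L, u - as.integer(round(0.45 * period * fs)))
    # robust minimum: a low quantile resists the downward bias a plain
    # minimum acquires from residual noise over a long diastole
    pmin <- unname(stats::quantile(ps[w0:u], 0.02, type = 7))
    foot <- (u - 1) / fs - (ps[u] - pmin) / dp[u]
    if (foot >= (w0 - 1.5) / fs) {
      feet <- c(feet, foot)
      upstrokes <- c(upstrokes, u)
    }
  }
  if (!length(feet))
    stop("no detectable upstrokes", call. = FALSE)
  list(foot_times = feet, upstroke_idx = upstrokes)
}

#' Detect beats in a pressure trace
#'
#' Locates the foot of every beat by the intersecting-tangent rule (the
#' tangent at the point of maximal upstroke slope intersected with the
#' horizontal through the preceding minimum). Beats whose spacing deviates
#' more than 20% from the median spacing are flagged as rejected and are
#' excluded from ensemble statistics downstream.
#'
#' @param pressure Pressure samples (mmHg); at least 2 s of signal.
#' @param fs Sampling rate (Hz), at least 100.
#' @param hr_hint Optional expected heart rate (bpm).
#' @return Object of class `beat_index`: `onsets` (sample indices of beat
#'   feet), `foot_times` (fractional, s), `accepted` (per inter-foot
#'   interval), `hr_estimate` (bpm), `fs`.
#' @export
detect_beats <- function(pressure, fs, hr_hint = NULL) {
  if (fs < 100) stop("fs must be at least 100 Hz", call. = FALSE)
  if (length(pressure) / fs < 2) stop("need at least 2 s of signal", call. = FALSE)
  ft <- find_feet(pressure, fs, hr_hint)
  onsets <- pmin(length(pressure), pmax(1L, as.integer(round(ft$foot_times * fs)) + 1L))
  keep <- !duplicated(onsets)
  onsets <- onsets[keep]
  foot_times <- ft$foot_times[keep]
  spacing <- diff(onsets)
  accepted <- if (length(spacing))
    abs(spacing - stats::median(spacing)) <= 0.2 * stats::median(spacing)
  else logical(0)
  hr_estimate <- if (length(spacing)) 60 * fs / stats::median(spacing) else NA_real_
  structure(list(onsets = onsets, foot_times = foot_times,
                 upstroke_idx = ft$upstroke_idx[keep], accepted = accepted,
                 hr_estimate = hr_estimate, fs = fs), class = "beat_index")
}

# accepted complete-beat windows as a list of index ranges; falls back to
# every window when the spacing filter rejects all of them
beat_windows <- function(beats, n) {
  on <- beats$onsets
  if (length(on) < 2) {
    if (length(on) == 1 && on[1] + 3 < n) return(list(c(on[1], n)))
    stop("fewer than one complete beat", call. = FALSE)
  }
  w <- Map(c, on[-length(on)], on[-1])
  wa <- w[beats$accepted]
  if (length(wa)) wa else w
}

#' Per-beat systolic and diastolic extrema
#'
#' @param pressure Pressure samples (mmHg).
#' @param beats A [detect_beats()] result.
#' @return List with `per_beat` (data.frame `sbp`, `dbp`, `pp`) and the
#'   across-beat medians `sbp`, `dbp`, `pp`.
#' @export
extract_extrema <- function(pressure, beats) {
  w <- beat_windows(beats, length(pressure))
  per <- do.call(rbind, lapply(w, function(r) {
    seg <- pressure[r[1]:r[2]]
    data.frame(sbp = max(seg), dbp = min(seg))
  }))
  per$pp <- per$sbp - per$dbp
  list(per_beat = per, sbp = stats::median(per$sbp),
       dbp = stats::median(per$dbp), pp = stats::median(per$pp))
}

#' Time-averaged mean pressure over whole beats
#'
#' Trapezoidal time average between the first and last detected foot (an
#' integer number of beats).
#'
#' @inheritParams extract_extrema
#' @return Mean pressure (mmHg).
#' @export
mean_pressure <- function(pressure, beats) {
  on <- beats$onsets
  if (length(on) < 2) {
    seg <- pressure
  } else {
    seg <- pressure[on[1]:on[length(on)]]
  }
  m <- length(seg)
  if (m < 2) stop("fewer than one complete beat", call. = FALSE)
  (sum(seg) - (seg[1] + seg[m]) / 2) / (m - 1)
}

#' Mean pressure by the one-third rule
#'
#' `DBP + (SBP - DBP) / 3`, the classic cuff-style estimate of mean arterial
#' pressure.
#'
#' @param sbp,dbp Systolic and diastolic pressures (mmHg).
#' @return Mean pressure (mmHg).
#' @export
#' @examples
#' map_onethird(121.20, 80.78)  # 94.25 to printed precision
map_onethird <- function(sbp, dbp) {
  if (any(sbp < dbp)) stop("sbp must be >= dbp", call. = FALSE)
  dbp + (sbp - dbp) / 3
}

#' Form factor
#'
#' Ratio of the mean pulse pressure to the pulse pressure,
#' `(MAP - DBP) / (SBP - DBP)`; a dimensionless pulse-shape index.
#'
#' @param map Mean pressure (mmHg).
#' @inheritParams map_onethird
#' @return Form factor in `[0, 1]`.
#' @export
#' @examples
#' form_factor(94.25, 121.20, 80.78)  # 0.33 at two decimals
form_factor <- function(map, sbp, dbp) {
  if (any(sbp == dbp)) stop("form factor undefined for zero pulse pressure",
                            call. = FALSE)
  if (any(sbp < dbp) || any(map < dbp) || any(map > sbp))
    stop("need dbp <= map <= sbp", call. = FALSE)
  (map - dbp) / (sbp - dbp)
}

#' Augmentation index of a single beat
#'
#' Finds the inflection pressure `Pi` as the last negative-to-positive zero
#' crossing of the smoothed second derivative between the beat foot and the
#' systolic peak (the take-off of the reflected wave, type-A waveform), then
#' reports the augmented pressure `AP = SBP - Pi` and
#' `AIx = 100 * AP / PP`. A beat with no such crossing (no visible
#' reflection) is flagged undefined rather than raising an error.
#'
#' @param pressure One representative (e.g., ensemble-averaged) beat (mmHg),
#'   starting at or near its foot; at least 0.2 s long.
#' @param fs Sampling rate (Hz).
#' @return List with `aix` (percent), `ap`, `pi`, `sbp`, `dbp`, `defined`,
#'   `reason`.
#' @export
augmentation_index <- function(pressure, fs) {
  n <- length(pressure)
  if (n / fs < 0.2) stop("beat shorter than 0.2 s", call. = FALSE)
  ps <- lowpass(pressure, fs)
  foot <- which.min(ps[1:max(2, round(0.3 * n))])
  peak <- which.max(ps)
  sbp <- max(pressure)
  dbp <- min(pressure)
  und <- function(reason) list(aix = NA_real_, ap = NA_real_, pi = NA_real_,
                               sbp = sbp, dbp = dbp, defined = FALSE,
                               reason = reason)
  if (peak <= foot + 3) return(und("no systolic upstroke"))
  d2 <- deriv(deriv(ps, fs), fs)
  lo <- foot + max(2L, as.integer(round(0.05 * n)))
  hi <- peak - 2L
  if (hi <= lo) return(und("no room between foot and peak"))
  win <- lo:hi
  s <- sign(d2[win])
  cross <- which(s[-length(s)] < 0 & s[-1] >= 0)
  if (!length(cross)) return(und("no inflection"))
  j <- win[cross[length(cross)]]
  # linear interpolation of the crossing position
  frac <- if (d2[j + 1] != d2[j]) -d2[j] / (d2[j + 1] - d2[j]) else 0
  p_i <- ps[j] + frac * (ps[j + 1] - ps[j])
  ap <- sbp - p_i
  pp <- sbp - dbp
  list(aix = 100 * ap / pp, ap = ap, pi = p_i, sbp = sbp, dbp = dbp,
       defined = TRUE, reason = NULL)
}

#' Maximal rate of pressure rise
#'
#' Median over accepted beats of the maximum of the smoothed first
#' derivative (central difference after a zero-phase 25 Hz low-pass).
#'
#' @inheritParams extract_extrema
#' @param fs Sampling rate (Hz).
#' @return dp/dt max (mmHg/s).
#' @export
dpdt_max <- function(pressure, fs, beats) {
  dp <- deriv(lowpass(pressure, fs), fs)
  w <- beat_windows(beats, length(pressure))
  stats::median(vapply(w, function(r) max(dp[r[1]:r[2]]), numeric(1)))
}

#' Left ventricular end-diastolic pressure
#'
#' Pressure at the foot of each ventricular upstroke (the end of diastole),
#' median across beats. The foot location from the intersecting-tangent rule
#' is refined for the ventricular trace by walking back from the point of
#' maximal upstroke slope to where the smoothed slope last fell below 5% of
#' its peak: on a gradually accelerating isovolumic rise the raw tangent
#' intersection lands a few tens of milliseconds into the upstroke and would
#' overread the end-diastolic level.
#'
#' @param lv_pressure LV pressure samples (mmHg).
#' @inheritParams dpdt_max
#' @return LVEDP (mmHg).
#' @export
lvedp_extract <- function(lv_pressure, fs, beats) {
  dp <- deriv(lowpass(lv_pressure, fs), fs)
  vals <- vapply(beats$upstroke_idx, function(u) {
    thr <- 0.05 * dp[u]
    j <- u
    lim <- max(1L, u - as.integer(round(0.25 * fs)))
    while (j > lim && dp[j] > thr) j <- j - 1L
    lv_pressure[j]
  }, numeric(1))
  stats::median(vals)
}

#' Total peripheral resistance
#'
#' `MAP / CO` with venous pressure neglected, the convention that makes the
#' printed clinical arithmetic exact (e.g., 94.25 / 5 = 18.85).
#'
#' @param map Mean arterial pressure (mmHg).
#' @param co Cardiac output (L/min).
#' @return Resistance (mmHg min/L).
#' @export
tpr <- function(map, co) {
  if (any(co <= 0)) stop("co must be positive", call. = FALSE)
  map / co
}

#' Stroke volume from cardiac output and heart rate
#'
#' @param co Cardiac output (L/min).
#' @param hr Heart rate (bpm).
#' @return List with `sv` (mL/beat, full precision) and `sv_rounded`
#'   (nearest mL).
#' @export
#' @examples
#' stroke_volume(5, 75)$sv_rounded  # 67 mL/beat
stroke_volume <- function(co, hr) {
  if (any(hr <= 0)) stop("hr must be positive", call. = FALSE)
  sv <- 1000 * co / hr
  list(sv = sv, sv_rounded = round(sv))
}

#' Static compliance from an inflation series
#'
#' Least-squares slope of added volume against measured pressure, the bench
#' estimate of total compliance from incremental inflation.
#'
#' @param volumes Added volumes (mL).
#' @param pressures Equilibrium pressures (mmHg).
#' @return Compliance (mL/mmHg).
#' @export
compliance_from_inflation <- function(volumes, pressures) {
  if (length(volumes) < 2 || length(volumes) != length(pressures))
    stop("need at least two matched volume/pressure points", call. = FALSE)
  if (stats::sd(pressures) == 0)
    stop("degenerate inflation series: pressures are constant", call. = FALSE)
  unname(stats::coef(stats::lm(volumes ~ pressures))[2])
}

# dicrotic notch: first local minimum after the systolic peak followed by a
# rebound of at least `prominence` mmHg, searched in the first 70% of the beat
find_notch <- function(pressure, fs, prominence = 0.5) {
  ps <- lowpass(pressure, fs)
  n <- length(ps)
  peak <- which.max(ps)
  hi <- min(n - 1, round(0.7 * n))
  j <- peak + 1
  while (j < hi) {
    if (ps[j] < ps[j - 1] && ps[j] <= ps[j + 1]) {
      reb <- max(ps[j:min(n, j + round(0.15 * n))]) - ps[j]
      if (reb >= prominence) return((j - 1) / fs)
    }
    j <- j + 1
  }
  NULL
}
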
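# Frequency- and energy-domain analyses: input impedance harmonics, wave
# intensity with peak labeling, foot-to-foot pulse wave velocity.

#' Ensemble-average beat
#'
#' Resamples every accepted beat to the median beat length and averages
#' pointwise; paired channels (flow, velocity) are averaged over the same
#' windows so pressure/flow alignment is preserved.
#'
#' @param record A [waveform_record()].
#' @param beats A [detect_beats()] result for the record's pressure channel.
#' @return A single-beat [waveform_record()]. With fewer than two accepted
#'   beats the available beat is returned unchanged with a warning.
#' @export
ensemble_average_beat <- function(record, beats) {
  stopifnot(inherits(record, "waveform_record"))
  w <- beat_windows(beats, length(record$pressure))
  chans <- c(list(pressure = record$pressure),
             if (!is.null(record$flow)) list(flow = record$flow),
             if (!is.null(record$velocity)) list(velocity = record$velocity))
  if (length(w) < 2) {
    warning("fewer than 2 accepted beats: returning the single beat unchanged",
            call. = FALSE)
    r <- w[[1]]
    out <- lapply(chans, function(x) x[r[1]:r[2]])
  } else {
    m <- as.integer(round(stats::median(vapply(w, function(r) r[2] - r[1] + 1,
                                               numeric(1)))))
    out <- lapply(chans, function(x) {
      rows <- vapply(w, function(r) {
        seg <- x[r[1]:r[2]]
        stats::approx(seq_along(seg), seg, xout = seq(1, length(seg),
                                                      length.out = m))$y
      }, numeric(m))
      rowMeans(rows)
    })
  }
  waveform_record(record$site, record$fs, out$pressure, flow = out$flow,
                  velocity = out$velocity,
                  meta = c(record$meta, ensemble = TRUE))
}

wrap_phase <- function(x) {
  w <- x - 2 * pi * round(x / (2 * pi))
  w[w <= -pi] <- w[w <= -pi] + 2 * pi
  w
}

#' Aortic input impedance spectrum
#'
#' Discrete Fourier harmonics 0..`k_max` of one beat-periodic pressure/flow
#' pair: the modulus is `|p_k| / |q_k|` and the phase is
#' `arg(p_k) - arg(q_k)` wrapped to `(-pi, pi]`. Harmonic 0 is the ratio of
#' mean pressure to mean flow (the input resistance). Harmonics whose flow
#' amplitude is negligible are flagged unreliable rather than dropped.
#'
#' @param pressure One beat of pressure (mmHg).
#' @param flow The simultaneous flow (mL/s), same length.
#' @param fs Sampling rate (Hz).
#' @param k_max Highest harmonic (default 15, covering clinical impedance
#'   plots).
#' @return Object of class `impedance_spectrum`: data.frame with
#'   `harmonic`, `frequency` (Hz), `modulus` (mmHg s/mL), `phase` (rad),
#'   `reliable`; plus `r0_mmHg_min_L`, the harmonic-0 modulus in clinical
#'   units.
#' @export
input_impedance <- function(pressure, flow, fs, k_max = 15) {
  n <- length(pressure)
  if (length(flow) != n) stop("pressure and flow lengths differ", call. = FALSE)
  if (k_max >= n / 2) k_max <- floor(n / 2) - 1
  pf <- stats::fft(pressure) / n
  qf <- stats::fft(flow) / n
  if (abs(Re(qf[1])) < 1e-12)
    stop("zero mean flow: harmonic 0 undefined", call. = FALSE)
  k <- 0:k_max
  p_k <- pf[k + 1]
  q_k <- qf[k + 1]
  reliable <- Mod(q_k) >= 1e-9 * Mod(q_k[2])
  modulus <- Mod(p_k) / Mod(q_k)
  phase <- wrap_phase(Arg(p_k) - Arg(q_k))
  phase[1] <- 0
  spec <- data.frame(harmonic = k, frequency = k * fs / n, modulus = modulus,
                     phase = phase, reliable = reliable)
  structure(list(spectrum = spec,
                 r0_mmHg_min_L = modulus[1] * 1000 / 60,
                 fs = fs, n = n), class = "impedance_spectrum")
}

#' @export
print.impedance_spectrum <- function(x, ...) {
  cat(sprintf("<impedance_spectrum> %d harmonics; R0 = %.2f mmHg*min/L\n",
              nrow(x$spectrum) - 1, x$r0_mmHg_min_L))
  print(utils::head(x$spectrum, 6))
  invisible(x)
}

#' Wave intensity
#'
#' The product of incremental pressure and velocity changes. Two
#' conventions: `"per-sample"` uses the literal sample-to-sample increments
#' `dI_i = (P_{i+1} - P_i) * (U_{i+1} - U_i)` (units depend on the sampling
#' interval); `"time-normalized"` (default) uses smoothed time derivatives
#' `dI = (dP/dt) * (dU/dt)` in mmHg m s^-3, which is sampling-rate
#' invariant. Both have the same zero-crossing structure: positive wave
#' intensity marks net forward-traveling waves, negative marks backward
#' (reflected) waves.
#'
#' @param pressure Pressure samples (mmHg).
#' @param velocity Simultaneous velocity samples (m/s), same length.
#' @param fs Sampling rate (Hz).
#' @param convention `"time-normalized"` or `"per-sample"`.
#' @return Object of class `wave_intensity`: `t`, `di`, `convention`;
#'   `peaks` is filled by [detect_wi_peaks()].
#' @export
wave_intensity <- function(pressure, velocity, fs,
                           convention = c("time-normalized", "per-sample")) {
  convention <- match.arg(convention)
  n <- length(pressure)
  if (length(velocity) != n)
    stop("pressure and velocity lengths differ", call. = FALSE)
  if (convention == "per-sample") {
    di <- c(diff(pressure) * diff(velocity), 0)
  } else {
    di <- deriv(lowpass(pressure, fs), fs) * deriv(lowpass(velocity, fs), fs)
  }
  structure(list(t = (seq_len(n) - 1) / fs, di = di, fs = fs,
                 convention = convention, peaks = NULL),
            class = "wave_intensity")
}

local_extrema <- function(x, maxima = TRUE) {
  s <- if (maxima) x else -x
  which(diff(sign(diff(s))) < 0) + 1
}

#' Label the canonical wave-intensity peaks
#'
#' The physiological pattern is a large forward compression peak in early
#' systole (Wf1, ventricular ejection), a smaller backward compression
#' excursion (Wb, reflections), and a moderate forward decompression peak in
#' late systole (Wf2, ventricular relaxation). Peaks below
#' `min_prominence * max(|dI|)` are reported absent, never fabricated.
#'
#' @param wi A [wave_intensity()] result.
#' @param min_prominence Amplitude threshold as a fraction of `max(|dI|)`.
#' @return The `wave_intensity` object with a `peaks` data.frame
#'   (`label`, `amplitude`, `time`).
#' @export
detect_wi_peaks <- function(wi, min_prominence = 0.05) {
  stopifnot(inherits(wi, "wave_intensity"))
  di <- wi$di
  n <- length(di)
  peaks <- data.frame(label = character(0), amplitude = numeric(0),
                      time = numeric(0), stringsAsFactors = FALSE)
  amax <- max(abs(di))
  if (amax > 0) {
    thr <- min_prominence * amax
    # Wf1: largest positive peak in the first half (early systole)
    half <- seq_len(ceiling(n / 2))
    cand <- intersect(c(local_extrema(di, TRUE), which.max(di)), half)
    cand <- cand[di[cand] > thr]
    if (length(cand)) {
      i1 <- cand[which.max(di[cand])]
      peaks <- rbind(peaks, data.frame(label = "Wf1", amplitude = di[i1],
                                       time = wi$t[i1]))
      after <- if (i1 < n) (i1 + 1):n else integer(0)
      if (length(after)) {
        ib <- after[which.min(di[after])]
        if (di[ib] < -thr) {
          peaks <- rbind(peaks, data.frame(label = "Wb", amplitude = di[ib],
                                           time = wi$t[ib]))
          later <- if (ib < n) (ib + 1):n else integer(0)
          cand2 <- intersect(c(local_extrema(di, TRUE), which.max(di[later]) + ib),
                             later)
          cand2 <- cand2[di[cand2] > thr]
          if (length(cand2)) {
            i2 <- cand2[which.max(di[cand2])]
            peaks <- rbind(peaks, data.frame(label = "Wf2", amplitude = di[i2],
                                             time = wi$t[i2]))
          }
        }
      }
    }
  }
  wi$peaks <- peaks
  wi
}

#' Foot-to-foot pulse wave velocity
#'
#' Locates the foot of each propagating wave at a proximal and a distal site
#' by the intersecting-tangent rule, takes the median per-beat transit time,
#' and divides the known path distance by it.
#'
#' @param p_prox,p_dist Pressure traces (mmHg) sharing a time base.
#' @param fs Sampling rate (Hz).
#' @param path_distance Centerline distance between the sites (m).
#' @return Object of class `pwv_estimate`: `pwv` (m/s), `transit_time` (s),
#'   `path_distance`, `foot_times` (first matched proximal/distal pair).
#' @export
foot_to_foot_pwv <- function(p_prox, p_dist, fs, path_distance) {
  if (path_distance <= 0) stop("path_distance must be positive", call. = FALSE)
  fp <- find_feet(p_prox, fs)$foot_times
  fd <- find_feet(p_dist, fs)$foot_times
  period <- if (length(fp) > 1) stats::median(diff(fp)) else length(p_prox) / fs
  transits <- c()
  pair <- NULL
  for (tp in fp) {
    nxt <- fd[fd > tp + 1e-12 & fd < tp + 0.9 * period]
    if (length(nxt)) {
      transits <- c(transits, nxt[1] - tp)
      if (is.null(pair)) pair <- c(proximal = tp, distal = nxt[1])
    }
  }
  if (!length(transits))
    stop("transit time not resolvable: no distal foot follows a proximal foot",
         call. = FALSE)
  tt <- stats::median(transits)
  if (tt < 1 / fs - 1e-9)
    stop("transit time below one sample: sites unresolvable at this sampling rate",
         call. = FALSE)
  structure(list(pwv = path_distance / tt, transit_time = tt,
                 path_distance = path_distance, foot_times = pair,
                 n_beats = length(transits)), class = "pwv_estimate")
}

#' @export
print.pwv_estimate <- function(x, ...) {
  cat(sprintf("<pwv_estimate> %.2f m/s (transit %.1f ms over %.3f m, %d beats)\n",
              x$pwv, 1000 * x$transit_time, x$path_distance, x$n_beats))
  invisible(x)
}

#' Cross-sectionally averaged velocity from volumetric flow
#'
#' `U = Q / (pi d^2 / 4)`, converting L/min and mm to SI.
#'
#' @param flow Flow samples (L/min).
#' @param diameter Lumen diameter (mm).
#' @return Velocity (m/s).
#' @export
#' @examples
#' velocity_from_flow(5, 24)  # ~0.184 m/s
velocity_from_flow <- function(flow, diameter) {
  if (diameter <= 0) stop("diameter must be positive", call. = FALSE)
  area <- pi * (diameter / 1000)^2 / 4
  lmin_to_si(flow) / area
}
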
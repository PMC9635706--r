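#' Summarize a waveform record into scalar indices
#'
#' Fills every derivable per-recording index - systolic/diastolic/mean/pulse
#' pressure, form factor, augmentation, dp/dt max, LVEDP (ventricular site
#' only), stroke volume, cardiac output, total peripheral resistance, static
#' compliance (when inflation data are supplied) and the dicrotic-notch time.
#' Indices that cannot be computed are reported absent with a reason code;
#' a single failed index never aborts the summary.
#'
#' @param record A [waveform_record()].
#' @param co Cardiac output (L/min); if missing and the record carries a
#'   flow channel, the mean flow is used.
#' @param hr Heart rate (bpm); defaults to the beat-detection estimate.
#' @param inflation Optional list with `volumes` (mL) and `pressures`
#'   (mmHg) from a static inflation run, for the compliance estimate.
#' @return Object of class `feature_summary`: `values` (named list) and
#'   `absent` (named list of reason codes).
#' @export
summarize <- function(record, co = NULL, hr = NULL, inflation = NULL) {
  stopifnot(inherits(record, "waveform_record"))
  values <- list()
  absent <- list()
  put <- function(name, expr, reason_prefix = NULL) {
    v <- tryCatch(expr, error = function(e) {
      absent[[name]] <<- conditionMessage(e)
      NULL
    })
    if (!is.null(v)) values[[name]] <<- v
    invisible(v)
  }

  beats <- tryCatch(detect_beats(record$pressure, record$fs, hr_hint = hr),
                    error = function(e) e)
  if (inherits(beats, "error")) {
    absent$beats <- conditionMessage(beats)
    return(structure(list(site = record$site, values = values, absent = absent),
                     class = "feature_summary"))
  }

  ex <- put("extrema", extract_extrema(record$pressure, beats))
  if (!is.null(ex)) {
    values$sbp <- ex$sbp; values$dbp <- ex$dbp; values$pp <- ex$pp
    values$extrema <- NULL
  }
  put("map_timeavg", mean_pressure(record$pressure, beats))
  if (!is.null(values$sbp))
    put("map_onethird", map_onethird(values$sbp, values$dbp))
  if (!is.null(values$map_timeavg) && !is.null(values$sbp)) {
    map_c <- min(max(values$map_timeavg, values$dbp), values$sbp)
    put("ff", form_factor(map_c, values$sbp, values$dbp))
  }
  put("dpdt_max", dpdt_max(record$pressure, record$fs, beats))

  ens <- tryCatch(suppressWarnings(ensemble_average_beat(record, beats)),
                  error = function(e) NULL)
  if (!is.null(ens)) {
    ai <- tryCatch(augmentation_index(ens$pressure, ens$fs),
                   error = function(e) NULL)
    if (!is.null(ai) && isTRUE(ai$defined)) {
      values$aix <- ai$aix; values$ap <- ai$ap; values$pi <- ai$pi
    } else {
      absent$aix <- if (is.null(ai)) "beat too short" else ai$reason
    }
    notch <- find_notch(ens$pressure, ens$fs)
    if (!is.null(notch)) values$notch_time <- notch else
      absent$notch_time <- "not detectable"
  }

  if (record$site == "LV") {
    put("lvedp", lvedp_extract(record$pressure, record$fs, beats))
  } else {
    absent$lvedp <- "site"
  }

  hr_use <- hr %||% beats$hr_estimate
  values$hr_estimate <- beats$hr_estimate
  co_use <- co %||% (if (!is.null(record$flow)) mean(record$flow) else NULL)
  if (is.null(co_use)) {
    absent$co <- "no flow"
    absent$sv <- "no flow"
    absent$tpr <- "no flow"
  } else {
    values$co <- co_use
    if (co_use > 0) {
      put("sv", stroke_volume(co_use, hr_use)$sv)
      if (!is.null(values$map_timeavg)) put("tpr", tpr(values$map_timeavg, co_use))
    } else {
      absent$sv <- "nonpositive cardiac output"
      absent$tpr <- "nonpositive cardiac output"
    }
  }

  if (!is.null(inflation)) {
    put("ac", compliance_from_inflation(inflation$volumes, inflation$pressures))
  } else {
    absent$ac <- "no inflation data"
  }

  structure(list(site = record$site, values = values, absent = absent),
            class = "feature_summary")
}

#' @export
print.feature_summary <- function(x, ...) {
  cat("<feature_summary> site", x$site, "\n")
  num <- vapply(x$values, function(v) is.numeric(v) && length(v) == 1, logical(1))
  v <- unlist(x$values[num])
  for (nm in names(v)) cat(sprintf("  %-12s %8.3f\n", nm, v[[nm]]))
  if (length(x$absent))
    cat("  absent:", paste(sprintf("%s (%s)", names(x$absent),
                                   unlist(x$absent)), collapse = "; "), "\n")
  invisible(x)
}

#' Analyze a record into a serializable report
#'
#' Runs [summarize()], and when the companion channels are present also the
#' input-impedance spectrum (pressure + flow), wave intensity with peak
#' labels (pressure + velocity, or flow plus a lumen diameter), all computed
#' on the ensemble-averaged beat. Provenance (configuration hash, package
#' version) is attached for reproducibility.
#'
#' @inheritParams summarize
#' @param diameter Optional lumen diameter (mm) to convert flow to velocity
#'   for wave intensity; defaults to the record's `diameter_mm` metadata.
#' @param k_max Harmonics for the impedance spectrum.
#' @return A nested list ready for [write_report()].
#' @export
analyze_record <- function(record, co = NULL, hr = NULL, inflation = NULL,
                           diameter = NULL, k_max = 15) {
  fs <- record$fs
  summ <- summarize(record, co = co, hr = hr, inflation = inflation)
  report <- list(site = record$site, features = summ$values,
                 absent = summ$absent)

  beats <- tryCatch(detect_beats(record$pressure, fs, hr_hint = hr),
                    error = function(e) NULL)
  ens <- if (!is.null(beats))
    tryCatch(suppressWarnings(ensemble_average_beat(record, beats)),
             error = function(e) NULL)

  if (!is.null(ens) && !is.null(ens$flow)) {
    z <- tryCatch(input_impedance(ens$pressure, lmin_to_si(ens$flow) / M3_PER_ML,
                                  fs, k_max = k_max),
                  error = function(e) NULL)
    if (!is.null(z)) {
      report$impedance <- list(r0_mmHg_min_L = z$r0_mmHg_min_L,
                               harmonics = z$spectrum)
    } else report$absent$impedance <- "impedance not computable"
  } else report$absent$impedance <- "no flow"

  dia <- diameter %||% record$meta$diameter_mm
  u <- if (!is.null(ens)) {
    if (!is.null(ens$velocity)) ens$velocity
    else if (!is.null(ens$flow) && !is.null(dia))
      velocity_from_flow(ens$flow, as.numeric(dia))
  }
  if (!is.null(u)) {
    wi <- detect_wi_peaks(wave_intensity(ens$pressure, u, fs))
    report$wave_intensity <- list(convention = wi$convention, peaks = wi$peaks)
  } else report$absent$wave_intensity <- "no velocity"

  report$provenance <- list(
    package = "pulserig",
    version = as.character(utils::packageVersion("pulserig")),
    record_meta = record$meta,
    config_hash = config_hash(list(meta = record$meta, co = co, hr = hr,
                                   diameter = diameter, k_max = k_max)))
  report
}
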
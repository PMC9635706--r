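#' Waveform record
#'
#' One measurement site's uniformly sampled trace: pressure (mmHg) and
#' optionally flow (L/min) and/or velocity (m/s), with sampling rate and
#' free-form metadata.
#'
#' @param site One of `"LA"`, `"LV"`, `"ascending_aorta"`,
#'   `"abdominal_aorta"`, `"other"`.
#' @param fs Sampling rate (Hz).
#' @param pressure Pressure samples (mmHg).
#' @param flow Optional flow samples (L/min), same length.
#' @param velocity Optional velocity samples (m/s), same length.
#' @param t Optional time vector (s); must be uniform at `1/fs` within
#'   1e-6 s. Defaults to `(0:(n-1))/fs`.
#' @param meta Named list of metadata (preset, hr, units audit, ...).
#' @return Object of class `waveform_record`.
#' @export
waveform_record <- function(site, fs, pressure, flow = NULL, velocity = NULL,
                            t = NULL, meta = list()) {
  sites <- c("LA", "LV", "ascending_aorta", "abdominal_aorta", "other")
  if (!site %in% sites)
    stop("site must be one of: ", paste(sites, collapse = ", "), call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("fs must be a single positive sampling rate (Hz)", call. = FALSE)
  n <- length(pressure)
  if (n < 2) stop("pressure must contain at least two samples", call. = FALSE)
  if (is.null(t)) t <- (seq_len(n) - 1) / fs
  if (length(t) != n) stop("t and pressure lengths differ", call. = FALSE)
  dtv <- diff(t)
  if (any(abs(dtv - 1 / fs) > 1e-6))
    stop("t must be uniformly spaced at 1/fs within 1e-6 s (first offending row: ",
         which(abs(dtv - 1 / fs) > 1e-6)[1] + 1, ")", call. = FALSE)
  for (ch in list(flow, velocity))
    if (!is.null(ch) && length(ch) != n)
      stop("all channels must share the pressure length", call. = FALSE)
  structure(list(site = site, fs = fs, t = as.numeric(t),
                 pressure = as.numeric(pressure),
                 flow = if (!is.null(flow)) as.numeric(flow),
                 velocity = if (!is.null(velocity)) as.numeric(velocity),
                 meta = meta), class = "waveform_record")
}

#' @export
print.waveform_record <- function(x, ...) {
  cat(sprintf("<waveform_record> site %s, %d samples at %g Hz (%.2f s)%s%s\n",
              x$site, length(x$pressure), x$fs,
              length(x$pressure) / x$fs,
              if (!is.null(x$flow)) ", flow" else "",
              if (!is.null(x$velocity)) ", velocity" else ""))
  invisible(x)
}

#' Write a waveform record as CSV
#'
#' The dialect is self-describing: leading comment lines `# key=value`
#' (`site`, `fs` and `units` are mandatory, other metadata keys follow),
#' then a header `time_s,pressure_mmHg[,flow_L_per_min][,velocity_m_per_s]`
#' and numeric rows at full double precision.
#'
#' @param record A [waveform_record()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_waveform_csv <- function(record, path) {
  stopifnot(inherits(record, "waveform_record"))
  cols <- c("time_s", "pressure_mmHg",
            if (!is.null(record$flow)) "flow_L_per_min",
            if (!is.null(record$velocity)) "velocity_m_per_s")
  meta <- record$meta
  meta$site <- NULL; meta$fs <- NULL; meta$units <- NULL
  hdr <- c(sprintf("# site=%s", record$site),
           sprintf("# fs=%.10g", record$fs),
           sprintf("# units=%s", paste(cols, collapse = ",")),
           if (length(meta)) sprintf("# %s=%s", names(meta),
                                     vapply(meta, format, character(1))))
  dat <- cbind(record$t, record$pressure, record$flow, record$velocity)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(cols, collapse = ","), con)
  utils::write.table(format(dat, digits = 17, trim = TRUE, scientific = FALSE),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a waveform CSV
#'
#' Parses the dialect written by [write_waveform_csv()] and validates the
#' record invariants (mandatory metadata, uniform time base).
#'
#' @param path File path.
#' @return A [waveform_record()].
#' @export
read_waveform_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  meta_lines <- lines[is_meta & cumsum(!is_meta) == 0]
  kv <- regmatches(meta_lines, regexec("^#\\s*([^=]+)=(.*)$", meta_lines))
  meta <- stats::setNames(lapply(kv, function(m) m[3]),
                          vapply(kv, function(m) trimws(m[2]), character(1)))
  for (key in c("site", "fs", "units"))
    if (is.null(meta[[key]]))
      stop("waveform CSV is missing mandatory metadata key ", sQuote(key),
           call. = FALSE)
  body <- lines[!is_meta]
  header <- strsplit(body[1], ",")[[1]]
  dat <- utils::read.csv(text = paste(body, collapse = "\n"),
                         header = TRUE, colClasses = "numeric")
  if (!identical(names(dat)[1:2], c("time_s", "pressure_mmHg")))
    stop("waveform CSV must start with time_s,pressure_mmHg columns", call. = FALSE)
  fs <- as.numeric(meta$fs)
  dtv <- diff(dat$time_s)
  bad <- which(abs(dtv - 1 / fs) > 1e-6)
  if (length(bad))
    stop("non-uniform time base at row ", bad[1] + 1, " of the data block",
         call. = FALSE)
  extra <- meta[setdiff(names(meta), c("site", "fs", "units"))]
  extra$units <- meta$units
  waveform_record(meta$site, fs, dat$pressure_mmHg,
                  flow = dat[["flow_L_per_min"]],
                  velocity = dat[["velocity_m_per_s"]],
                  t = dat$time_s, meta = extra)
}

round2 <- function(x) if (is.numeric(x)) round(x, 2) else x

#' Write an analysis report as JSON
#'
#' Serializes an analysis report with stable key ordering; every numeric
#' entry is written at full precision and mirrored at two decimals under
#' `printed`, so comparisons against published, rounded figures need no
#' re-rounding downstream. Provenance (configuration hash, package version)
#' is always included.
#'
#' @param report A list as produced by [analyze_record()] (or any nested
#'   list of scalars).
#' @param path Output path for the JSON file.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path) {
  mirror <- function(x) {
    if (is.list(x)) lapply(x, mirror) else round2(x)
  }
  payload <- list(report = report, printed = mirror(report),
                  provenance = report$provenance %||% list())
  payload$report$provenance <- NULL
  payload$printed$provenance <- NULL
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Hash a configuration for provenance
#'
#' Stable hash over every field of a configuration object; any change to any
#' field changes the hash.
#'
#' @param config Any R object (normally a `circuit_config`).
#' @return Character hash.
#' @export
config_hash <- function(config) rlang::hash(config)
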
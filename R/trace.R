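#' Uniformly sampled time series
#'
#' `time_trace()` is the container every pipeline stage works on: a numeric
#' vector sampled at a fixed rate, with a session-relative start time and a
#' free-text label (channel or animal identifier). Sample `i` (1-based) covers
#' the half-open interval `[t0 + (i-1)/rate, t0 + i/rate)`.
#'
#' @param values numeric vector, at least one sample; must be finite after
#'   ingestion (see [read_trace_csv()] for the NA policy applied to files).
#' @param rate sampling rate in samples/s, finite and > 0.
#' @param t0 session-relative time of the first sample, seconds.
#' @param label free-text identifier.
#' @return an object of class `TimeTrace`.
#' @seealso [trace_times()], [trace_duration()], [read_trace_csv()]
#' @export
time_trace <- function(values, rate, t0 = 0, label = "") {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("TimeTrace needs at least one sample")
  if (!is.finite(rate) || rate <= 0) stop("rate must be finite and > 0")
  if (anyNA(values) || any(!is.finite(values)))
    stop("TimeTrace values must be finite (NaN/Inf rejected at ingestion)")
  structure(
    list(values = values, rate = rate, t0 = t0, label = as.character(label)),
    class = "TimeTrace"
  )
}

#' @export
print.TimeTrace <- function(x, ...) {
  cat(sprintf("<TimeTrace> %s: %d samples @ %.6g Hz, t0 = %.6g s, span %.6g s\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$values), x$rate, x$t0, trace_duration(x)))
  invisible(x)
}

#' @export
length.TimeTrace <- function(x) length(x$values)

#' Sample timestamps of a trace
#' @param trace a [time_trace()] object.
#' @return numeric vector of sample start times (s).
#' @export
trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$values) - 1L) / trace$rate
}

#' Total recorded span of a trace in seconds
#' @param trace a [time_trace()] object.
#' @return duration in seconds (`n / rate`).
#' @export
trace_duration <- function(trace) length(trace$values) / trace$rate

#' Extract the samples covering a half-open time window
#'
#' @param trace a [time_trace()] object.
#' @param start,end window in seconds, half-open `[start, end)`.
#' @return numeric vector of samples whose start time falls in the window.
#' @keywords internal
trace_window <- function(trace, start, end) {
  i0 <- ceiling((start - trace$t0) * trace$rate - 1e-9) + 1L
  i1 <- ceiling((end - trace$t0) * trace$rate - 1e-9)
  i0 <- max(i0, 1L)
  i1 <- min(i1, length(trace$values))
  if (i1 < i0) return(numeric(0))
  trace$values[i0:i1]
}

#' Half-open time interval
#'
#' Plumbing type for bout and stimulus windows: `[start, end)` in seconds.
#'
#' @param start,end numeric, `end > start`.
#' @return a one-row data.frame with columns `start`, `end`, `duration`.
#' @export
interval <- function(start, end) {
  if (any(end <= start)) stop("interval requires end > start")
  data.frame(start = start, end = end, duration = end - start)
}

# --- file I/O -----------------------------------------------------------

#' Read a trace from long-format CSV
#'
#' Accepts either a two-column `time_s,value` file (rate inferred from the
#' median time step; sampling must be uniform) or a single `value` column with
#' the rate given in a header comment `# rate_hz=<x>` or via the `rate`
#' argument. NA gaps shorter than `max_gap_s` are linearly interpolated and
#' logged; longer runs are rejected, since interpolating across them would
#' fabricate behavior.
#'
#' @param path CSV file path (UTF-8, '.' decimal).
#' @param rate sampling rate override (samples/s); required for value-only
#'   files with no `# rate_hz=` header.
#' @param label label for the returned trace; defaults to the file name.
#' @param max_gap_s longest NA run (seconds) repaired by linear
#'   interpolation. Default 0.5 s.
#' @return a [time_trace()].
#' @export
read_trace_csv <- function(path, rate = NULL, label = basename(path),
                           max_gap_s = 0.5) {
  header <- readLines(path, n = 5L)
  rate_line <- grep("^#\\s*rate_hz\\s*=", header, value = TRUE)
  if (length(rate_line) && is.null(rate))
    rate <- as.numeric(sub("^#\\s*rate_hz\\s*=\\s*", "", rate_line[1L]))
  df <- utils::read.csv(path, comment.char = "#")
  if ("time_s" %in% names(df) && "value" %in% names(df)) {
    dt <- diff(df$time_s)
    if (any(dt <= 0)) stop("time_s must be strictly increasing")
    if (max(abs(dt - stats::median(dt))) > stats::median(dt) * 1e-3)
      stop("non-uniform sampling in ", path)
    rate <- 1 / stats::median(dt)
    t0 <- df$time_s[1L]
    vals <- df$value
  } else if ("value" %in% names(df)) {
    if (is.null(rate)) stop("value-only CSV needs a rate (argument or '# rate_hz=' header)")
    t0 <- 0
    vals <- df$value
  } else stop("expected columns time_s,value or value in ", path)
  vals <- repair_na_gaps(vals, rate, max_gap_s)
  time_trace(vals, rate = rate, t0 = t0, label = label)
}

#' Write a trace to long-format CSV
#' @param trace a [time_trace()].
#' @param path output path. A `# rate_hz=` header line is written first.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# rate_hz=%.10g", trace$rate), con)
  utils::write.csv(
    data.frame(time_s = trace_times(trace), value = trace$values),
    con, row.names = FALSE
  )
  invisible(path)
}

# Linear interpolation over short NA runs; long runs are a hard error.
repair_na_gaps <- function(vals, rate, max_gap_s) {
  if (!anyNA(vals)) {
    if (any(!is.finite(vals))) stop("non-finite values in trace file")
    return(vals)
  }
  r <- rle(is.na(vals))
  worst <- max(r$lengths[r$values]) / rate
  if (worst > max_gap_s)
    stop(sprintf("NA run of %.3g s exceeds the %.3g s repair limit", worst, max_gap_s))
  idx <- which(!is.na(vals))
  if (length(idx) < 2L) stop("too few non-missing samples to interpolate")
  out <- stats::approx(idx, vals[idx], xout = seq_along(vals), rule = 2)$y
  ct_log("repaired %d missing samples by linear interpolation", sum(is.na(vals)))
  out
}

# --- configuration ------------------------------------------------------

#' Default analysis parameters
#'
#' Every numeric parameter used by the pipeline, with the study protocol's
#' values as defaults, as a nested list. Override by editing the list or via
#' a YAML file ([read_config()]).
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    filtering = list(
      motion_cutoff_hz   = 0.5,   # motion-index low-pass
      velocity_cutoff_hz = 0.3,   # open-field velocity low-pass
      order              = 1L,
      photometry_tau_s   = 0.1    # exponential smoothing time constant
    ),
    bouts = list(
      spontaneous = list(amp_threshold = 0.5, min_active_s = 2.0, min_passive_s = 0.5),
      evoked      = list(amp_threshold = 0.5, min_active_s = 2.7, min_passive_s = 0.5),
      velocity    = list(amp_threshold = 6.0, min_active_s = 1.0, min_pre_low_s = 2.0),
      evoked_window_s = 2.0
    ),
    photometry = list(
      baseline_stim_s = 3, baseline_spont_s = 5, post_margin_s = 5,
      onset_z_crossing = 2, onset_sustain_s = 0.2,
      correlogram_bin_hz = 1, correlogram_max_lag_s = 10
    ),
    zebrafish = list(
      tail_angle_threshold_rad = 0.65, tail_min_duration_s = 1.0,
      bin_px = 10L, dff_baseline_quantile = 0.10,
      baseline_s = 5, response_s = 10, alpha = 0.05,
      frame_rate_hz = 2.33, tail_rate_hz = 120
    ),
    tracing = list(
      min_cells_adjacent = 5, min_animals = 4,
      max_spread_outside = 0.30, max_neuronal_frac = 0.005
    ),
    stats = list(alpha_normality = 0.05)
  )
}

#' Read analysis parameters from a YAML file
#'
#' Values present in the file override [default_config()]; everything else
#' keeps its default.
#'
#' @param path YAML file path.
#' @return nested named list with the same shape as [default_config()].
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  modifyList(default_config(), user)
}

# --- logging ------------------------------------------------------------

# INFO-level logging: every operation reports its parameters and I/O sizes.
# Silence with options(copingtrace.verbose = FALSE).
ct_log <- function(fmt, ...) {
  if (isTRUE(getOption("copingtrace.verbose", FALSE)))
    message(sprintf(paste0("[copingtrace] ", fmt), ...))
  invisible(NULL)
}
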
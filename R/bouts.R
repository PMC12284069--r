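#' Bout-detection parameters
#'
#' Amplitude- and duration-thresholding parameters for segmenting a motion
#' or velocity trace into active-coping (AC) and passive-coping (PC) bouts.
#' The three modes carry the study protocol's final thresholds as defaults:
#'
#' * `spontaneous` — 0.5 a.u. amplitude, 2 s minimum AC, 0.5 s minimum PC;
#' * `evoked` — as spontaneous but minimum AC raised to 2.7 s, filtering out
#'   the initial startle response to the stimulus;
#' * `velocity` — open-field locomotion events: 6 cm/s, 1 s minimum event,
#'   and at least 2 s of continuously low velocity beforehand.
#'
#' @param mode one of `"spontaneous"`, `"evoked"`, `"velocity"`.
#' @param amp_threshold amplitude threshold (a.u. motion index or cm/s).
#' @param min_active_s minimum active-bout duration, s.
#' @param min_passive_s minimum passive-bout duration, s (gaps shorter than
#'   this between two active runs are absorbed into the active region).
#' @param min_pre_low_s velocity mode only: minimum preceding sub-threshold
#'   period, s.
#' @return a `DetectionParams` list.
#' @export
detection_params <- function(mode = c("spontaneous", "evoked", "velocity"),
                             amp_threshold = NULL, min_active_s = NULL,
                             min_passive_s = NULL, min_pre_low_s = NULL) {
  mode <- match.arg(mode)
  cfg <- default_config()$bouts[[mode]]
  p <- list(
    mode = mode,
    amp_threshold = amp_threshold %||% cfg$amp_threshold,
    min_active_s  = min_active_s  %||% cfg$min_active_s,
    min_passive_s = min_passive_s %||% (cfg$min_passive_s %||% 0),
    min_pre_low_s = min_pre_low_s %||% (cfg$min_pre_low_s %||% 0)
  )
  if (!is.finite(p$amp_threshold)) stop("amp_threshold must be finite")
  if (p$min_active_s < 0 || p$min_passive_s < 0 || p$min_pre_low_s < 0)
    stop("durations must be >= 0")
  structure(p, class = "DetectionParams")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a validated bout segmentation
#'
#' An alternating AC/PC partition of a session. Invariants enforced:
#' bouts are time-ordered, non-overlapping, tile the session span exactly,
#' and states strictly alternate.
#'
#' @param states character vector of `"AC"`/`"PC"`.
#' @param starts,ends bout boundaries in seconds (half-open intervals).
#' @param session_start,session_end session span in seconds.
#' @return a `BoutSegmentation`: data.frame with columns `state`, `start`,
#'   `end`, `duration` plus a `session_span` attribute.
#' @export
bout_segmentation <- function(states, starts, ends, session_start, session_end) {
  df <- data.frame(state = states, start = starts, end = ends,
                   duration = ends - starts, stringsAsFactors = FALSE)
  tol <- 1e-9
  if (nrow(df)) {
    if (any(df$duration <= 0)) stop("bouts must have positive duration")
    if (abs(df$start[1L] - session_start) > tol ||
        abs(df$end[nrow(df)] - session_end) > tol)
      stop("bouts must tile the session span")
    if (nrow(df) > 1L) {
      if (any(abs(df$start[-1L] - df$end[-nrow(df)]) > tol))
        stop("bouts must be contiguous")
      if (any(df$state[-1L] == df$state[-nrow(df)]))
        stop("states must strictly alternate")
    }
    if (!all(df$state %in% c("AC", "PC"))) stop("states must be AC or PC")
  }
  structure(df, class = c("BoutSegmentation", "data.frame"),
            session_span = c(session_start, session_end))
}

#' Segment a filtered trace into alternating AC/PC bouts
#'
#' The detection contract, applied once and in this order:
#' 1. binarize — a sample is an active candidate iff its value is at or
#'    above `amp_threshold` (a tie counts as active);
#' 2. merge — any sub-threshold run shorter than `min_passive_s` flanked by
#'    supra-threshold runs on both sides is absorbed into the surrounding
#'    active region (a PC bout shorter than the minimum cannot exist between
#'    two AC bouts);
#' 3. prune — any resulting active run shorter than `min_active_s` is
#'    reassigned to passive;
#' 4. emit the alternating partition.
#'
#' The caller is responsible for low-pass filtering the trace first
#' ([detect_bouts_filtered()] composes filter and detection). Active runs
#' touching the trace edge are kept if they meet the minimum duration within
#' the recorded span; the first and last PC bouts may be shorter than
#' `min_passive_s` (session truncation).
#'
#' @param filtered_trace a low-pass filtered [time_trace()].
#' @param params a [detection_params()] object.
#' @return a [bout_segmentation()].
#' @export
detect_bouts <- function(filtered_trace, params = detection_params("spontaneous")) {
  stopifnot(inherits(filtered_trace, "TimeTrace"))
  x <- filtered_trace$values
  if (length(x) == 0L) stop("empty trace")
  rate <- filtered_trace$rate
  dt <- 1 / rate
  eps <- 1e-9
  if (trace_duration(filtered_trace) < params$min_active_s - eps)
    warning("trace shorter than min_active_s; emitting a single PC bout")

  active <- x >= params$amp_threshold
  r <- rle(active)
  # merge: interior sub-threshold runs shorter than min_passive_s
  if (length(r$lengths) > 2L) {
    interior <- seq(2L, length(r$lengths) - 1L)
    gap <- interior[!r$values[interior] &
                      r$lengths[interior] * dt < params$min_passive_s - eps]
    if (length(gap)) {
      r$values[gap] <- TRUE
      r <- rle(inverse.rle(r))
    }
  }
  # prune: active runs shorter than min_active_s
  short <- r$values & (r$lengths * dt < params$min_active_s - eps)
  if (any(short)) {
    r$values[short] <- FALSE
    r <- rle(inverse.rle(r))
  }
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths
  t0 <- filtered_trace$t0
  seg <- bout_segmentation(
    states = ifelse(r$values, "AC", "PC"),
    starts = t0 + starts_i * dt, ends = t0 + ends_i * dt,
    session_start = t0, session_end = t0 + length(x) * dt
  )
  ct_log("detect_bouts: mode=%s n=%d -> %d AC bouts", params$mode,
         length(x), sum(seg$state == "AC"))
  seg
}

#' Filter and segment in one step
#'
#' Convenience wrapper: zero-phase Butterworth low-pass at the mode's cutoff
#' (0.5 Hz for motion index, 0.3 Hz for open-field velocity), then
#' [detect_bouts()].
#'
#' @inheritParams detect_bouts
#' @param trace raw [time_trace()].
#' @param cutoff_hz low-pass cutoff; defaults to the mode's protocol value.
#' @param order Butterworth design order (default 1).
#' @return a [bout_segmentation()].
#' @export
detect_bouts_filtered <- function(trace, params = detection_params("spontaneous"),
                                  cutoff_hz = NULL, order = 1L) {
  cfgf <- default_config()$filtering
  cutoff_hz <- cutoff_hz %||%
    if (params$mode == "velocity") cfgf$velocity_cutoff_hz else cfgf$motion_cutoff_hz
  detect_bouts(lowpass_butterworth(trace, cutoff_hz, order = order), params)
}

#' Summarize a bout segmentation
#'
#' Totals, counts, duration lists, and fixed-width time-bin aggregates. A
#' bout contributes duration to each bin proportionally to its overlap with
#' the bin; a bout's count is assigned to the bin containing its onset.
#'
#' @param seg a [bout_segmentation()].
#' @param bin_s bin width in seconds (> 0). Default 60 (1-min bins).
#' @return a `BoutSummary` list: `total_active_s`, `n_active_bouts`,
#'   `active_durations`, `passive_durations`, `per_bin_active_s`,
#'   `per_bin_counts`, `bin_s`.
#' @export
summarize_bouts <- function(seg, bin_s = 60) {
  stopifnot(inherits(seg, "BoutSegmentation"), bin_s > 0)
  span <- attr(seg, "session_span")
  ac <- seg[seg$state == "AC", , drop = FALSE]
  n_bins <- max(1L, ceiling((span[2L] - span[1L]) / bin_s - 1e-9))
  per_act <- numeric(n_bins)
  per_cnt <- integer(n_bins)
  bin_edges <- span[1L] + bin_s * (0:n_bins)
  if (nrow(ac)) {
    for (i in seq_len(nrow(ac))) {
      ov <- pmax(0, pmin(ac$end[i], bin_edges[-1L]) - pmax(ac$start[i], bin_edges[-(n_bins + 1L)]))
      per_act <- per_act + ov
      onset_bin <- min(n_bins, 1L + floor((ac$start[i] - span[1L]) / bin_s + 1e-9))
      per_cnt[onset_bin] <- per_cnt[onset_bin] + 1L
    }
  }
  structure(list(
    total_active_s = sum(ac$duration),
    n_active_bouts = nrow(ac),
    active_durations = ac$duration,
    passive_durations = seg$duration[seg$state == "PC"],
    per_bin_active_s = per_act,
    per_bin_counts = per_cnt,
    bin_s = bin_s
  ), class = "BoutSummary")
}

#' Detect open-field velocity events
#'
#' Supra-threshold runs at least `min_active_s` long that are preceded by at
#' least `min_pre_low_s` of continuously sub-threshold velocity. A run whose
#' onset is closer to the recording start than `min_pre_low_s` is rejected,
#' since the required quiet period cannot be verified.
#'
#' @param velocity a [time_trace()] of velocity (cm/s), already low-pass
#'   filtered (0.3 Hz in the protocol).
#' @param params a [detection_params()] with `mode = "velocity"`.
#' @return data.frame of event intervals (`start`, `end`, `duration`),
#'   possibly empty.
#' @export
detect_velocity_events <- function(velocity, params = detection_params("velocity")) {
  stopifnot(inherits(velocity, "TimeTrace"))
  x <- velocity$values
  dt <- 1 / velocity$rate
  eps <- 1e-9
  r <- rle(x >= params$amp_threshold)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths
  prev_len <- c(0, r$lengths[-length(r$lengths)])   # 0 = no preceding run
  keep <- which(
    r$values &
      r$lengths * dt >= params$min_active_s - eps &
      prev_len * dt >= params$min_pre_low_s - eps   # rle alternation: prev run is sub-threshold
  )
  t0 <- velocity$t0
  out <- data.frame(start = t0 + starts_i[keep] * dt,
                    end = t0 + ends_i[keep] * dt)
  out$duration <- out$end - out$start
  ct_log("detect_velocity_events: %d events", nrow(out))
  out
}

#' Probability of stimulus-evoked AC bouts
#'
#' A stimulus counts as responded iff an AC bout *onset* falls inside
#' `[stim, stim + response_window_s)`; an AC bout already ongoing at the
#' stimulus does not count. The response probability is the fraction of
#' stimuli responded to.
#'
#' @param seg a [bout_segmentation()].
#' @param stim_times stimulus times in seconds, within the session span.
#' @param response_window_s latency window after each stimulus, s. The
#'   protocol does not fix this value; default 2 s, recorded in the output.
#' @return list with `responded` (logical per stimulus), `probability`, and
#'   `response_window_s`.
#' @export
evoked_response <- function(seg, stim_times, response_window_s = 2) {
  stopifnot(inherits(seg, "BoutSegmentation"))
  if (length(stim_times) == 0L) stop("empty stimulus list")
  if (response_window_s < 0) stop("response_window_s must be >= 0")
  onsets <- seg$start[seg$state == "AC"]
  responded <- vapply(stim_times, function(s)
    any(onsets >= s & onsets < s + response_window_s), logical(1))
  list(responded = responded,
       probability = mean(responded),
       response_window_s = response_window_s)
}

#' Write a bout segmentation to CSV
#' @param seg a [bout_segmentation()].
#' @param path output CSV path; columns `state,start_s,end_s,duration_s`.
#' @return `path`, invisibly.
#' @export
write_bouts_csv <- function(seg, path) {
  utils::write.csv(
    data.frame(state = seg$state, start_s = seg$start, end_s = seg$end,
               duration_s = seg$duration),
    path, row.names = FALSE)
  invisible(path)
}

#' Read a bout segmentation from CSV
#' @param path CSV written by [write_bouts_csv()].
#' @param session_start,session_end session span; defaults to the first
#'   bout's start and last bout's end.
#' @return a [bout_segmentation()].
#' @export
read_bouts_csv <- function(path, session_start = NULL, session_end = NULL) {
  df <- utils::read.csv(path)
  bout_segmentation(df$state, df$start_s, df$end_s,
                    session_start %||% df$start_s[1L],
                    session_end %||% df$end_s[nrow(df)])
}
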
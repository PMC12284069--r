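#' Fiber-photometry session container
#'
#' A calcium-sensitive signal channel (465/473 nm GCaMP or 570 nm jRGECO1a)
#' with an optional calcium-independent isosbestic channel (405 nm) recorded
#' through the same fiber. When the isosbestic channel is present it must
#' share the signal channel's rate and length.
#'
#' @param signal a [time_trace()] of raw fluorescence.
#' @param isosbestic optional [time_trace()] (405 nm), same rate and length.
#' @param animal_id animal identifier.
#' @param sensor indicator name, e.g. `"GCaMP6f"`, `"GCaMP8s"`, `"jRGECO1a"`.
#' @return a `PhotometrySession` list.
#' @export
photometry_session <- function(signal, isosbestic = NULL, animal_id = "",
                               sensor = "GCaMP6f") {
  stopifnot(inherits(signal, "TimeTrace"))
  if (!is.null(isosbestic)) {
    stopifnot(inherits(isosbestic, "TimeTrace"))
    if (isosbestic$rate != signal$rate ||
        length(isosbestic$values) != length(signal$values))
      stop("isosbestic channel must match the signal channel's rate and length")
  }
  structure(list(signal = signal, isosbestic = isosbestic,
                 animal_id = as.character(animal_id), sensor = sensor),
            class = "PhotometrySession")
}

#' Read a photometry session from CSV
#'
#' Expects columns `time_s`, `ch465` (or `ch570`) and optionally `ch405`.
#'
#' @param path CSV path.
#' @param animal_id,sensor passed to [photometry_session()].
#' @return a `PhotometrySession`.
#' @export
read_photometry_csv <- function(path, animal_id = "", sensor = "GCaMP6f") {
  df <- utils::read.csv(path, comment.char = "#")
  sig_col <- intersect(c("ch465", "ch473", "ch570"), names(df))[1L]
  if (is.na(sig_col)) stop("no signal column (ch465/ch473/ch570) in ", path)
  dt <- stats::median(diff(df$time_s))
  sig <- time_trace(df[[sig_col]], rate = 1 / dt, t0 = df$time_s[1L], label = sig_col)
  iso <- if ("ch405" %in% names(df))
    time_trace(df$ch405, rate = 1 / dt, t0 = df$time_s[1L], label = "ch405")
  photometry_session(sig, iso, animal_id = animal_id, sensor = sensor)
}

#' Isosbestic motion-artifact correction
#'
#' Removes movement and fiber-bending artifacts shared between the
#' calcium-dependent channel and the 405 nm isosbestic channel by
#' subtracting a fitted isosbestic estimate and dividing by it:
#' `corrected(t) = (signal(t) - iso_fit(t)) / iso_fit(t)`, a unitless
#' dF/F-like quantity.
#'
#' `iso_fit` is the isosbestic trace least-squares affine-scaled onto the
#' signal channel (`iso_fit = a + b * iso`), the standard practice that
#' makes the correction invariant to the two channels' different gains and
#' offsets. `method = "raw"` instead subtracts and divides by the unscaled
#' isosbestic trace.
#'
#' @param session a [photometry_session()]; the isosbestic channel must be
#'   present (a session without one is passed through unchanged with a
#'   warning) and `iso_fit` strictly positive.
#' @param method `"fitted"` (default) or `"raw"`.
#' @return corrected [time_trace()] (unitless).
#' @export
isosbestic_correct <- function(session, method = c("fitted", "raw")) {
  method <- match.arg(method)
  stopifnot(inherits(session, "PhotometrySession"))
  sig <- session$signal
  if (is.null(session$isosbestic)) {
    warning("no isosbestic channel; returning the signal unchanged")
    return(sig)
  }
  iso <- session$isosbestic$values
  if (method == "fitted") {
    fit <- stats::lm.fit(cbind(1, iso), sig$values)
    iso_fit <- as.numeric(cbind(1, iso) %*% fit$coefficients)
  } else {
    if (any(iso <= 0)) stop("raw isosbestic correction requires positive 405 nm values")
    iso_fit <- iso
  }
  if (any(iso_fit <= 0)) stop("fitted isosbestic estimate has non-positive values")
  out <- (sig$values - iso_fit) / iso_fit
  ct_log("isosbestic_correct: method=%s n=%d", method, length(out))
  time_trace(out, rate = sig$rate, t0 = sig$t0,
             label = paste0(sig$label, "_corrected"))
}

#' Standard photometry preprocessing
#'
#' The canonical preprocessing chain: exponential smoothing of both raw
#' channels (time constant `tau_s`, 0.1 s in the protocol) followed by
#' isosbestic motion-artifact correction.
#'
#' @param session a [photometry_session()].
#' @param tau_s smoothing time constant, s.
#' @param method passed to [isosbestic_correct()].
#' @return corrected, smoothed [time_trace()].
#' @export
photometry_preprocess <- function(session, tau_s = 0.1, method = "fitted") {
  sm <- photometry_session(
    smooth_time_constant(session$signal, tau_s),
    if (!is.null(session$isosbestic)) smooth_time_constant(session$isosbestic, tau_s),
    animal_id = session$animal_id, sensor = session$sensor)
  isosbestic_correct(sm, method = method)
}

# sample index containing time t (1-based)
sample_index <- function(trace, t) {
  as.integer(floor((t - trace$t0) * trace$rate + 1e-9)) + 1L
}

#' Z-score one peri-event trial against its pre-event baseline
#'
#' Extracts `[onset - baseline_s, onset + post_s)` and standardizes it by the
#' mean and population SD of the baseline window. The baseline window can be
#' anchored elsewhere than the event (`baseline_end`), which implements the
#' rule that a PC bout is z-scored against the baseline of the AC bout that
#' precedes it.
#'
#' @param trace corrected [time_trace()].
#' @param onset event onset time, s.
#' @param baseline_s baseline window length before `baseline_end`, s (3 s for
#'   stimulus trials, 5 s for spontaneous AC in the protocol).
#' @param post_s extracted window after onset, s.
#' @param baseline_end right edge of the baseline window; defaults to
#'   `onset`.
#' @return list with `z` (may carry trailing `NA` where the window runs past
#'   the recording), `time` (s relative to onset, contains 0), `mu`, `sigma`;
#'   or `NULL` when the baseline window is not fully inside the trace (the
#'   trial is dropped and logged).
#' @export
zscore_trial <- function(trace, onset, baseline_s, post_s, baseline_end = onset) {
  stopifnot(inherits(trace, "TimeTrace"))
  nbase <- as.integer(round(baseline_s * trace$rate))
  npost <- as.integer(round(post_s * trace$rate))
  if (nbase < 2L) stop("baseline window must contain at least 2 samples")
  ib_end <- sample_index(trace, baseline_end)   # first sample at/after anchor
  ib0 <- ib_end - nbase
  if (ib0 < 1L) {
    ct_log("zscore_trial: baseline before trace start; trial at %.3g s dropped", onset)
    return(NULL)
  }
  base <- trace$values[ib0:(ib_end - 1L)]
  mu <- mean(base)
  sigma <- sqrt(mean((base - mu)^2))           # population SD
  if (sigma == 0) stop("degenerate baseline: zero variance")
  i_on <- sample_index(trace, onset)
  idx <- (i_on - nbase):(i_on + npost - 1L)
  vals <- rep(NA_real_, length(idx))
  ok <- idx >= 1L & idx <= length(trace$values)
  vals[ok] <- trace$values[idx[ok]]
  list(z = (vals - mu) / sigma,
       time = (seq_along(idx) - nbase - 1L) / trace$rate,
       mu = mu, sigma = sigma)
}

#' Build an event-aligned z-scored matrix
#'
#' One z-scored row per event ([zscore_trial()]), with per-trial event
#' durations and animal ids carried along so rows can be sorted shortest to
#' longest for heatmap display. Events whose baseline window starts before
#' the recording are dropped (logged); windows that run past the end are
#' NA-padded.
#'
#' @param trace corrected [time_trace()].
#' @param events data.frame with columns `onset`, `duration`, and optionally
#'   `baseline_end` (see [zscore_trial()]); build from a segmentation with
#'   [ac_events()] or [pc_events()].
#' @param baseline_s baseline window, s.
#' @param post_s window after onset, s; default `max(duration) + 5`.
#' @param animal_id recycled per-trial animal identifier.
#' @return an `EventAlignedMatrix`: list with `z` (trials x time), `time_axis`,
#'   `baseline_s`, `event_durations`, `animal_ids`, `n_dropped`.
#' @export
build_aligned_matrix <- function(trace, events, baseline_s = 5, post_s = NULL,
                                 animal_id = "") {
  if (nrow(events) < 1L) stop("need at least one event")
  if (is.null(events$baseline_end)) events$baseline_end <- events$onset
  post_s <- post_s %||% (max(events$duration) + default_config()$photometry$post_margin_s)
  rows <- lapply(seq_len(nrow(events)), function(i)
    zscore_trial(trace, events$onset[i], baseline_s, post_s,
                 baseline_end = events$baseline_end[i]))
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) stop("all events dropped (baseline windows out of range)")
  z <- do.call(rbind, lapply(rows[keep], `[[`, "z"))
  structure(list(
    z = z,
    time_axis = rows[keep][[1L]]$time,
    baseline_s = baseline_s,
    event_durations = events$duration[keep],
    animal_ids = rep_len(as.character(animal_id), sum(keep)),
    n_dropped = sum(!keep)
  ), class = "EventAlignedMatrix")
}

#' AC-bout events from a segmentation
#' @param seg a [bout_segmentation()].
#' @return data.frame `onset`, `duration` (one row per AC bout).
#' @export
ac_events <- function(seg) {
  ac <- seg[seg$state == "AC", , drop = FALSE]
  data.frame(onset = ac$start, duration = ac$duration)
}

#' PC-bout events z-score-anchored to the preceding AC bout
#'
#' For each AC -> PC transition, the PC bout's baseline is the window ending
#' at the *AC* bout's onset — one shared baseline per transition, so the AC
#' and PC bouts of a transition are standardized on the same footing.
#'
#' @param seg a [bout_segmentation()].
#' @return data.frame `onset`, `duration`, `baseline_end` (one row per PC
#'   bout that follows an AC bout).
#' @export
pc_events <- function(seg) {
  i_ac <- which(seg$state == "AC")
  i_pc <- i_ac + 1L
  ok <- i_pc <= nrow(seg)
  data.frame(onset = seg$start[i_pc[ok]],
             duration = seg$duration[i_pc[ok]],
             baseline_end = seg$start[i_ac[ok]])
}

#' Sort an aligned matrix by event duration
#' @param mat an `EventAlignedMatrix`.
#' @param decreasing sort order; default shortest first.
#' @return the matrix with rows (and per-trial metadata) reordered.
#' @export
sort_by_duration <- function(mat, decreasing = FALSE) {
  o <- order(mat$event_durations, decreasing = decreasing)
  mat$z <- mat$z[o, , drop = FALSE]
  mat$event_durations <- mat$event_durations[o]
  mat$animal_ids <- mat$animal_ids[o]
  mat
}

#' Combine aligned matrices from several animals
#' @param mats list of `EventAlignedMatrix` sharing a time axis.
#' @return a single `EventAlignedMatrix`.
#' @export
rbind_aligned <- function(mats) {
  stopifnot(length(mats) >= 1L)
  out <- mats[[1L]]
  for (m in mats[-1L]) {
    if (length(m$time_axis) != length(out$time_axis))
      stop("matrices must share a time axis")
    out$z <- rbind(out$z, m$z)
    out$event_durations <- c(out$event_durations, m$event_durations)
    out$animal_ids <- c(out$animal_ids, m$animal_ids)
    out$n_dropped <- out$n_dropped + m$n_dropped
  }
  out
}

#' Per-animal normalization of z-scored traces
#'
#' Divides every trial of an animal by that animal's maximum z-score across
#' all of its trials in the matrix, so each animal's post-normalization
#' maximum is exactly 1 and animals with different indicator expression are
#' comparable on one heatmap. Idempotent, and independent across animals.
#'
#' @param mat an `EventAlignedMatrix` with per-trial `animal_ids`.
#' @return the matrix with `z` rescaled per animal.
#' @export
normalize_per_animal <- function(mat) {
  stopifnot(inherits(mat, "EventAlignedMatrix"))
  for (a in unique(mat$animal_ids)) {
    rows <- mat$animal_ids == a
    mx <- max(mat$z[rows, , drop = FALSE], na.rm = TRUE)
    if (!is.finite(mx) || mx <= 0)
      stop("animal ", a, " has non-positive maximum z; cannot normalize")
    mat$z[rows, ] <- mat$z[rows, ] / mx
  }
  mat
}

#' Last-second AC vs PC amplitude comparison
#'
#' For every AC -> PC transition, z-scores both bouts against the shared
#' baseline ending at the AC onset, takes the mean z over the last second of
#' each bout, and compares the paired AC/PC values with a two-tailed
#' Wilcoxon signed-rank test. Transitions in which either bout is shorter
#' than 1 s, or whose baseline window leaves the recording, are dropped and
#' logged.
#'
#' @param trace corrected [time_trace()].
#' @param seg a [bout_segmentation()].
#' @param baseline_s baseline window before the AC onset, s (default 5).
#' @return list with `pairs` (data.frame `ac_last`, `pc_last`), `test`
#'   ([signed_rank_test()] result), `n_dropped`.
#' @export
state_amplitude_comparison <- function(trace, seg, baseline_s = 5) {
  i_ac <- which(seg$state == "AC")
  i_ac <- i_ac[i_ac + 1L <= nrow(seg)]
  ac_last <- pc_last <- numeric(0)
  dropped <- 0L
  for (i in i_ac) {
    ac <- seg[i, ]; pc <- seg[i + 1L, ]
    if (ac$duration < 1 || pc$duration < 1) { dropped <- dropped + 1L; next }
    zb <- zscore_trial(trace, ac$start, baseline_s, post_s = 1 / trace$rate)
    if (is.null(zb)) { dropped <- dropped + 1L; next }
    last_ac <- trace_window(trace, ac$end - 1, ac$end)
    last_pc <- trace_window(trace, pc$end - 1, pc$end)
    if (!length(last_ac) || !length(last_pc)) { dropped <- dropped + 1L; next }
    ac_last <- c(ac_last, (mean(last_ac) - zb$mu) / zb$sigma)
    pc_last <- c(pc_last, (mean(last_pc) - zb$mu) / zb$sigma)
  }
  if (!length(ac_last)) stop("no usable AC -> PC transitions")
  test <- signed_rank_test(ac_last, pc_last, alternative = "two.sided")
  ct_log("state_amplitude_comparison: %d pairs, %d dropped", length(ac_last), dropped)
  list(pairs = data.frame(ac_last = ac_last, pc_last = pc_last),
       test = test, n_dropped = dropped)
}

#' Calcium rise time of one aligned trial
#'
#' Time from bout onset to the trial's maximum z within
#' `[0, bout_duration + post_margin_s]`. Flagged unreliable when the peak
#' does not rise above the baseline level (z = 0 by construction of the
#' aligned row), i.e. there is no detectable rise.
#'
#' @param z one aligned row (z-scores).
#' @param time_axis times of `z` relative to onset, s.
#' @param bout_duration bout duration, s.
#' @param post_margin_s extra search window after bout offset, s (default 0).
#' @return list `rise_time_s`, `peak_z`, `bout_duration_s`, `reliable`.
#' @export
rise_time <- function(z, time_axis, bout_duration, post_margin_s = 0) {
  win <- which(time_axis >= 0 & time_axis <= bout_duration + post_margin_s & !is.na(z))
  if (!length(win)) stop("no samples in the rise window")
  ipk <- win[which.max(z[win])]
  list(rise_time_s = time_axis[ipk], peak_z = z[ipk],
       bout_duration_s = bout_duration, reliable = z[ipk] > 0)
}

#' Rise points for every trial of an aligned matrix
#' @param mat an `EventAlignedMatrix`.
#' @param post_margin_s extra search window after each bout offset, s.
#' @return data.frame `rise_time_s`, `peak_z`, `bout_duration_s`, `reliable`.
#' @export
rise_points <- function(mat, post_margin_s = 0) {
  rows <- lapply(seq_len(nrow(mat$z)), function(i)
    rise_time(mat$z[i, ], mat$time_axis, mat$event_durations[i], post_margin_s))
  do.call(rbind, lapply(rows, as.data.frame))
}

#' Regression of calcium rise time on bout duration
#'
#' Ordinary least squares of `rise_time_s` on `bout_duration_s`; the
#' goodness of fit is the squared Pearson correlation.
#'
#' @param points data.frame from [rise_points()] (unreliable rows are kept
#'   or removed by the caller).
#' @return list `slope`, `intercept`, `r_squared`, `p_value`, `slope_ci`
#'   (95% confidence interval), `n`.
#' @export
rise_duration_regression <- function(points) {
  if (nrow(points) < 3L) stop("need at least 3 points")
  if (stats::var(points$bout_duration_s) == 0) stop("zero variance in bout durations")
  fit <- stats::lm(rise_time_s ~ bout_duration_s, data = points)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = s$r.squared,
       p_value = s$coefficients[2L, 4L],
       slope_ci = unname(stats::confint(fit)[2L, ]),
       n = nrow(points))
}

#' Onset-latency difference between two aligned signals
#'
#' For matrices aligned to the same events (e.g. jRGECO neurons and GCaMP
#' astrocytes), the per-event onset is the first post-event time at which z
#' reaches `z_crossing` and stays there for at least `sustain_s`. Returns
#' per-event latency differences (b minus a; positive when b lags) and a
#' paired signed-rank test on the differences. Events in which either signal
#' never crosses are excluded and logged.
#'
#' @param mat_a,mat_b `EventAlignedMatrix` objects over the same events.
#' @param z_crossing onset threshold in z units (default 2).
#' @param sustain_s required supra-threshold dwell, s (default 0.2).
#' @return list `latency_diff_s` (per kept event), `test`, `n_excluded`.
#' @export
onset_latency <- function(mat_a, mat_b, z_crossing = 2, sustain_s = 0.2) {
  if (nrow(mat_a$z) != nrow(mat_b$z)) stop("matrices must cover the same events")
  onset_of <- function(z, tax, rate) {
    need <- max(1L, as.integer(round(sustain_s * rate)))
    post <- which(tax >= 0)
    above <- !is.na(z[post]) & z[post] >= z_crossing
    r <- rle(above)
    ends <- cumsum(r$lengths)
    k <- which(r$values & r$lengths >= need)
    if (!length(k)) return(NA_real_)
    tax[post[ends[k[1L]] - r$lengths[k[1L]] + 1L]]
  }
  rate_a <- 1 / stats::median(diff(mat_a$time_axis))
  rate_b <- 1 / stats::median(diff(mat_b$time_axis))
  on_a <- apply(mat_a$z, 1L, onset_of, tax = mat_a$time_axis, rate = rate_a)
  on_b <- apply(mat_b$z, 1L, onset_of, tax = mat_b$time_axis, rate = rate_b)
  ok <- is.finite(on_a) & is.finite(on_b)
  if (!any(ok)) stop("no event crossed the onset threshold in both signals")
  d <- on_b[ok] - on_a[ok]
  ct_log("onset_latency: %d events, %d excluded", sum(ok), sum(!ok))
  list(latency_diff_s = d,
       test = signed_rank_test(d, alternative = "two.sided"),
       n_excluded = sum(!ok))
}

#' Calcium-kinematic cross-correlogram
#'
#' Mean-bins the calcium and kinematic (velocity or motion-index) traces at
#' `bin_hz` (1 Hz in the protocol) and computes the Pearson correlation at
#' integer-bin lags. Positive lag means the calcium signal follows the
#' kinematic signal: `r(lag) = cor(kin(t), ca(t + lag))`.
#'
#' @param ca,kinematic [time_trace()] objects covering the same span.
#' @param bin_hz bin rate (default 1 Hz).
#' @param max_lag_s largest lag magnitude, s.
#' @return data.frame `lag_s`, `r`.
#' @export
ca_velocity_correlogram <- function(ca, kinematic, bin_hz = 1, max_lag_s = 10) {
  bin_mean <- function(tr) {
    per <- as.integer(round(tr$rate / bin_hz))
    if (per < 1L) stop("bin_hz above the trace rate")
    nb <- length(tr$values) %/% per
    colMeans(matrix(tr$values[seq_len(nb * per)], nrow = per))
  }
  a <- bin_mean(ca); k <- bin_mean(kinematic)
  nb <- min(length(a), length(k))
  if (nb < 10L) stop("fewer than 10 bins; trace too short for a correlogram")
  a <- a[seq_len(nb)]; k <- k[seq_len(nb)]
  lags <- seq(-round(max_lag_s * bin_hz), round(max_lag_s * bin_hz))
  r <- vapply(lags, function(l) {
    if (l >= 0) stats::cor(k[seq_len(nb - l)], a[seq_len(nb - l) + l])
    else stats::cor(k[seq_len(nb + l) - l], a[seq_len(nb + l)])
  }, numeric(1))
  data.frame(lag_s = lags / bin_hz, r = r)
}

#' Export an aligned matrix as wide CSV plus JSON sidecar
#'
#' The CSV has one row per trial with the time offsets as header; the JSON
#' sidecar records durations, animal ids and the baseline parameter.
#'
#' @param mat an `EventAlignedMatrix`.
#' @param path CSV path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_aligned_csv <- function(mat, path) {
  m <- as.data.frame(mat$z)
  names(m) <- sprintf("t%+.4f", mat$time_axis)
  utils::write.csv(m, path, row.names = FALSE)
  sidecar <- list(baseline_s = mat$baseline_s,
                  event_durations = mat$event_durations,
                  animal_ids = mat$animal_ids, n_dropped = mat$n_dropped)
  writeLines(as.character(jsonlite::toJSON(sidecar, auto_unbox = TRUE, digits = NA)),
             paste0(path, ".json"))
  invisible(path)
}
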
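#' Two-photon movie container
#'
#' A registered single-plane movie as a `T x H x W` array of non-negative
#' fluorescence values. Registration (e.g. suite2p) is assumed done
#' upstream; [movie_drift_qc()] provides a residual-motion check.
#'
#' @param frames numeric array `T x H x W`, finite and >= 0, `T >= 2`.
#' @param frame_rate per-plane acquisition rate, samples/s (protocol:
#'   2.33 Hz).
#' @param plane_id integer plane index.
#' @return a `Movie` list.
#' @export
movie <- function(frames, frame_rate = 2.33, plane_id = 1L) {
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  if (dim(frames)[1L] < 2L) stop("movie needs at least 2 frames")
  if (anyNA(frames) || any(!is.finite(frames)) || any(frames < 0))
    stop("movie values must be finite and >= 0")
  if (frame_rate <= 0) stop("frame_rate must be > 0")
  structure(list(frames = frames, frame_rate = frame_rate,
                 plane_id = as.integer(plane_id)), class = "Movie")
}

#' Read a movie from a multi-page TIFF
#' @param path TIFF path, one page per frame.
#' @param frame_rate,plane_id see [movie()].
#' @return a `Movie`.
#' @export
read_movie_tiff <- function(path, frame_rate = 2.33, plane_id = 1L) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- aperm(simplify2array(pages), c(3L, 1L, 2L))
  movie(frames, frame_rate = frame_rate, plane_id = plane_id)
}

#' Write a movie to a multi-page TIFF
#' @param m a [movie()]; values are rescaled to `[0, 1]` 32-bit float pages.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(m, path) {
  mx <- max(m$frames)
  sc <- if (mx > 0) mx else 1
  pages <- lapply(seq_len(dim(m$frames)[1L]),
                  function(t) m$frames[t, , ] / sc)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' Residual-motion quality check
#'
#' Mean correlation of each frame with the temporal-mean image. Recordings
#' whose score falls below `floor` are flagged for exclusion, mirroring the
#' practice of discarding recordings with remaining motion artifacts or
#' Z-drift after registration.
#'
#' @param m a [movie()].
#' @param floor minimum acceptable mean frame-to-mean correlation.
#' @return list `score`, `per_frame`, `pass`.
#' @export
movie_drift_qc <- function(m, floor = 0.8) {
  mean_img <- apply(m$frames, c(2L, 3L), mean)
  v <- as.numeric(mean_img)
  per <- apply(m$frames, 1L, function(f) stats::cor(as.numeric(f), v))
  list(score = mean(per), per_frame = per, pass = mean(per) >= floor)
}

#' Detect swim bouts from a tail-angle trace
#'
#' Maximal runs where the absolute tail angle exceeds `angle_threshold`
#' (strictly), kept when the run lasts strictly longer than
#' `min_duration_s` — both thresholds are exclusive, so a run of exactly the
#' minimum duration is rejected.
#'
#' @param tail a [time_trace()] of tail angle in radians (protocol: 120 Hz).
#' @param angle_threshold radians (default 0.65).
#' @param min_duration_s seconds (default 1).
#' @return a `TailBouts` list: `intervals` (data.frame `start`, `end`,
#'   `duration`), `angle_threshold`, `min_duration_s`.
#' @export
detect_tail_bouts <- function(tail, angle_threshold = 0.65, min_duration_s = 1) {
  stopifnot(inherits(tail, "TimeTrace"))
  if (length(tail$values) == 0L) stop("empty trace")
  dt <- 1 / tail$rate
  r <- rle(abs(tail$values) > angle_threshold)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths
  keep <- which(r$values & r$lengths * dt > min_duration_s + 1e-9)
  iv <- data.frame(start = tail$t0 + starts_i[keep] * dt,
                   end = tail$t0 + ends_i[keep] * dt)
  iv$duration <- iv$end - iv$start
  ct_log("detect_tail_bouts: %d bouts", nrow(iv))
  structure(list(intervals = iv, angle_threshold = angle_threshold,
                 min_duration_s = min_duration_s), class = "TailBouts")
}

#' Astroglial pixel mask by intensity thresholding
#'
#' Thresholds the movie's temporal-mean image to isolate bright (indicator-
#' expressing) pixels. The default threshold is Otsu's method on the mean
#' image — deterministic and parameter-free; a manual override is available.
#'
#' @param mean_image `H x W` matrix (e.g. `apply(m$frames, c(2,3), mean)`).
#' @param threshold manual intensity threshold; pixels strictly above it are
#'   kept. `NULL` (default) uses Otsu.
#' @return logical `H x W` mask (nonempty, or an error).
#' @export
threshold_pixel_mask <- function(mean_image, threshold = NULL) {
  stopifnot(is.matrix(mean_image), all(is.finite(mean_image)))
  rg <- range(mean_image)
  if (is.null(threshold)) {
    if (diff(rg) == 0) stop("constant image: no separable intensity classes")
    threshold <- EBImage::otsu(mean_image, range = rg, levels = 256L)
  }
  mask <- mean_image > threshold
  if (!any(mask)) stop("empty pixel mask at threshold ", format(threshold))
  attr(mask, "threshold") <- threshold
  mask
}

#' Bin a movie into blocks and compute per-bin dF/F
#'
#' Divides the field of view into `bin_px x bin_px` blocks, averages the
#' masked pixels of each block per frame, and converts each bin trace to a
#' fractional change in fluorescence: `dFF(t) = (F(t) - F0) / F0` with `F0`
#' the bin's `f0_quantile` quantile over the whole recording (default 10th
#' percentile — robust to transients, deterministic). Blocks containing no
#' masked pixel are excluded and logged.
#'
#' @param m a [movie()].
#' @param mask logical `H x W` mask from [threshold_pixel_mask()].
#' @param bin_px block edge in pixels (protocol: 10).
#' @param f0_quantile baseline quantile in `(0, 1)`.
#' @return a `BinGrid` list: `bin_traces` (`B x T` dF/F), `bin_coords`
#'   (`B x 2` block row/col), `frame_rate`, `responsive_mask` and `p_values`
#'   (filled by [identify_responsive_bins()]).
#' @export
bin_and_dff <- function(m, mask, bin_px = 10L, f0_quantile = 0.10) {
  stopifnot(inherits(m, "Movie"), bin_px >= 1L)
  d <- dim(m$frames)
  if (!all(dim(mask) == d[2:3])) stop("mask must match the movie frame size")
  nbr <- floor(d[2L] / bin_px)
  nbc <- floor(d[3L] / bin_px)
  flat <- matrix(m$frames, nrow = d[1L])    # T x (H*W), column-major pixels
  traces <- NULL; coords <- NULL
  for (bc in seq_len(nbc)) {
    for (br in seq_len(nbr)) {
      rows_px <- ((br - 1L) * bin_px + 1L):(br * bin_px)
      cols_px <- ((bc - 1L) * bin_px + 1L):(bc * bin_px)
      sel <- as.matrix(expand.grid(rows_px, cols_px))
      inmask <- mask[sel]
      if (!any(inmask)) next
      px_idx <- (sel[inmask, 2L] - 1L) * d[2L] + sel[inmask, 1L]
      tr <- rowMeans(flat[, px_idx, drop = FALSE])
      traces <- rbind(traces, tr)
      coords <- rbind(coords, c(br, bc))
    }
  }
  if (is.null(traces)) stop("no bin contains masked pixels")
  f0 <- apply(traces, 1L, stats::quantile, probs = f0_quantile, names = FALSE)
  if (any(f0 <= 0)) stop("non-positive baseline fluorescence F0 in some bins")
  dff <- sweep(sweep(traces, 1L, f0, "-"), 1L, f0, "/")
  rownames(dff) <- NULL
  ct_log("bin_and_dff: %d bins x %d frames (%d empty blocks excluded)",
         nrow(dff), ncol(dff), nbr * nbc - nrow(dff))
  structure(list(bin_traces = dff, bin_coords = coords,
                 frame_rate = m$frame_rate,
                 responsive_mask = rep(NA, nrow(dff)),
                 p_values = rep(NA_real_, nrow(dff))),
            class = "BinGrid")
}

#' Identify motor-responsive bins
#'
#' For each bin, pairs the mean dF/F in a baseline window (`baseline_s`
#' before each bout onset) with the mean in a response window (`response_s`
#' after the onset) and applies a one-tailed (response > baseline) Wilcoxon
#' signed-rank test across bouts; a bin is responsive iff `p < alpha`.
#' No multiple-comparison correction is applied: the test selects bins for
#' downstream averaging, it is not inference on individual bins.
#'
#' Bouts whose baseline or response window leaves the recording are dropped
#' for all bins; a response window is truncated at the next bout onset when
#' bouts are closer together than `response_s`. Fewer than 5 usable bouts is
#' an error (the test is unstable below that).
#'
#' @param grid a [bin_and_dff()] result.
#' @param bouts a [detect_tail_bouts()] result (or data.frame of intervals).
#' @param baseline_s,response_s window lengths, s (protocol: 5 and 10).
#' @param alpha selection level (default 0.05, one-tailed).
#' @return the `BinGrid` with `responsive_mask`, `p_values`, and a
#'   `usable_bouts` attribute filled.
#' @export
identify_responsive_bins <- function(grid, bouts, baseline_s = 5,
                                     response_s = 10, alpha = 0.05) {
  stopifnot(inherits(grid, "BinGrid"))
  iv <- if (inherits(bouts, "TailBouts")) bouts$intervals else bouts
  nt <- ncol(grid$bin_traces)
  rate <- grid$frame_rate
  dur <- nt / rate
  onsets <- sort(iv$start)
  next_onset <- c(onsets[-1L], Inf)
  win <- list()
  for (k in seq_along(onsets)) {
    on <- onsets[k]
    resp_end <- min(on + response_s, next_onset[k])
    ib <- as.integer(floor((on - baseline_s) * rate + 1e-9)) + 1L
    ie <- as.integer(floor(on * rate + 1e-9))
    jb <- ie + 1L
    je <- as.integer(floor(resp_end * rate + 1e-9))
    if (ib < 1L || on + response_s > dur + 1e-9 || je > nt || je < jb) {
      ct_log("identify_responsive_bins: bout at %.3g s dropped (window out of range)", on)
      next
    }
    win[[length(win) + 1L]] <- list(base = ib:ie, resp = jb:je)
  }
  if (length(win) < 5L)
    stop("fewer than 5 bouts with full baseline and response windows")
  p <- apply(grid$bin_traces, 1L, function(tr) {
    base <- vapply(win, function(w) mean(tr[w$base]), numeric(1))
    resp <- vapply(win, function(w) mean(tr[w$resp]), numeric(1))
    signed_rank_test(resp, base, alternative = "greater")$p.value
  })
  grid$p_values <- unname(p)
  grid$responsive_mask <- grid$p_values < alpha
  attr(grid, "usable_bouts") <- length(win)
  ct_log("identify_responsive_bins: %d/%d bins responsive (%d bouts)",
         sum(grid$responsive_mask), length(p), length(win))
  grid
}

#' Mean trace over responsive bins
#'
#' Unweighted mean of the dF/F traces of bins flagged responsive; the signal
#' carried into all downstream quantification.
#'
#' @param grid a `BinGrid` after [identify_responsive_bins()].
#' @return a [time_trace()] at the movie frame rate.
#' @export
mean_responsive_trace <- function(grid) {
  stopifnot(inherits(grid, "BinGrid"))
  sel <- which(grid$responsive_mask)
  if (!length(sel))
    stop(sprintf("no responsive bins (smallest bin p = %.3g)",
                 suppressWarnings(min(grid$p_values, na.rm = TRUE))))
  time_trace(colMeans(grid$bin_traces[sel, , drop = FALSE]),
             rate = grid$frame_rate, t0 = 0, label = "mean_responsive_dff")
}

#' Mean activity inside vs outside swim bouts
#'
#' Mean dF/F over all bout (active-coping) intervals versus all inter-bout
#' (passive) periods of one session. Across sessions, pairs are compared by
#' [compare_sessions_ac_pc()].
#'
#' @param mean_trace a [time_trace()] (e.g. [mean_responsive_trace()]).
#' @param bouts a [detect_tail_bouts()] result.
#' @return list `ac_mean`, `pc_mean`.
#' @export
compare_ac_pc_activity <- function(mean_trace, bouts) {
  iv <- if (inherits(bouts, "TailBouts")) bouts$intervals else bouts
  n <- length(mean_trace$values)
  tt <- trace_times(mean_trace)
  in_bout <- rep(FALSE, n)
  for (k in seq_len(nrow(iv)))
    in_bout <- in_bout | (tt >= iv$start[k] & tt < iv$end[k])
  if (all(in_bout)) stop("no passive period in the recording")
  if (!any(in_bout)) stop("no bout samples in the recording")
  list(ac_mean = mean(mean_trace$values[in_bout]),
       pc_mean = mean(mean_trace$values[!in_bout]))
}

#' Paired AC vs PC comparison across sessions
#' @param pairs data.frame with columns `ac_mean`, `pc_mean` (one row per
#'   fish/session), e.g. rows of [compare_ac_pc_activity()] results.
#' @return list `pairs`, `test` (two-tailed [signed_rank_test()]).
#' @export
compare_sessions_ac_pc <- function(pairs) {
  list(pairs = pairs,
       test = signed_rank_test(pairs$ac_mean, pairs$pc_mean,
                               alternative = "two.sided"))
}

#' Stimulus-evoked response amplitudes
#'
#' Per-trial evoked amplitude: mean dF/F in the response window minus mean
#' in the baseline window around each stimulus time.
#'
#' @param mean_trace a [time_trace()] of dF/F.
#' @param stim_times stimulus onset times, s; trials whose windows leave the
#'   recording are dropped and logged.
#' @param baseline_s,response_s window lengths, s.
#' @return numeric vector of evoked amplitudes, one per usable trial.
#' @export
stimulus_evoked_response <- function(mean_trace, stim_times, baseline_s = 5,
                                     response_s = 10) {
  amps <- numeric(0)
  dur_end <- mean_trace$t0 + trace_duration(mean_trace)
  for (s in stim_times) {
    if (s - baseline_s < mean_trace$t0 - 1e-9 || s + response_s > dur_end + 1e-9) {
      ct_log("stimulus_evoked_response: trial at %.3g s dropped", s)
      next
    }
    base <- trace_window(mean_trace, s - baseline_s, s)
    resp <- trace_window(mean_trace, s, s + response_s)
    amps <- c(amps, mean(resp) - mean(base))
  }
  amps
}

#' Compare evoked amplitudes between two stimulus classes
#'
#' Paired Wilcoxon signed-rank when the trial counts match (trial k of one
#' class paired with trial k of the other); with unmatched counts it falls
#' back to the unpaired rank-sum test and says so.
#'
#' @param amps_a,amps_b evoked amplitudes ([stimulus_evoked_response()]) for
#'   the two classes (e.g. neutral light vs aversive vibration).
#' @param alternative passed to the underlying test (default two-sided).
#' @return list `test`, `paired` (logical).
#' @export
compare_stimulus_classes <- function(amps_a, amps_b,
                                     alternative = "two.sided") {
  if (length(amps_a) == length(amps_b)) {
    list(test = signed_rank_test(amps_a, amps_b, alternative = alternative),
         paired = TRUE)
  } else {
    ct_log("compare_stimulus_classes: unmatched trial counts (%d vs %d); unpaired fallback",
           length(amps_a), length(amps_b))
    w <- stats::wilcox.test(amps_a, amps_b, alternative = alternative,
                            exact = FALSE, correct = TRUE)
    list(test = list(statistic = unname(w$statistic), p.value = w$p.value,
                     n = length(amps_a) + length(amps_b), method = "rank-sum"),
         paired = FALSE)
  }
}
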
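#' Synthetic-data generator configuration
#'
#' Seeded configuration for the generators that emulate the statistical
#' structure of the coping assays: AC/PC-structured motion traces,
#' bout-locked photometry transients whose time-to-peak tracks bout length,
#' shared motion artifacts in signal and isosbestic channels, two-photon
#' movies with a compact responsive region, and alternating saline/CNO
#' session tables. Defaults encode the study conditions: six-minute
#' head-fixed sessions sampled at 10 Hz, right-skewed (log-normal) AC
#' durations, and a 12-minute zebrafish recording at 2.33 Hz per plane.
#'
#' A single root `seed` fans out deterministically to per-component child
#' seeds (`seed * 48271 + component offset, mod 2^31 - 1`), so each
#' generator is reproducible in isolation and jointly.
#'
#' @param seed integer root seed.
#' @param ... named overrides of any default; sub-lists (`motion`,
#'   `photometry`, `movie`, `dreadd`) are merged element-wise.
#' @return a `GeneratorConfig` nested list.
#' @export
generator_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    motion = list(
      session_s = 360, rate_hz = 10,
      ac_median_s = 3, ac_sigma = 0.6, ac_floor_s = 2.5,
      pc_median_s = 20, pc_sigma = 0.6, pc_floor_s = 2,
      start_margin_s = 8, end_margin_s = 12,
      amp = 1.0, amp_jitter_sd = 0.1, amp_floor = 0.7,
      baseline = 0, noise_sd = 0.2
    ),
    photometry = list(
      rate_hz = 20, f0_signal = 100, f0_iso = 50,
      peak_dff_per_s = 0.025, peak_jitter_sd = 0.02, peak_floor = 0.02,
      rise_frac = 0.8, rise_jitter_s = 0.3, decay_tau_s = 2,
      artifact_sd = 2, artifact_cutoff_hz = 0.5, iso_artifact_gain = 1,
      noise_sd = 0.2
    ),
    movie = list(
      h = 60, w = 60, bin_px = 10L, frame_rate_hz = 2.33, duration_s = 720,
      background = 20, bright = 150,
      bright_bins = list(rows = 2:5, cols = 2:5),
      responsive_bins = list(rows = 3:4, cols = 3:5),
      amp_dff = 0.3, decay_tau_s = 2, rise_s = 1, noise_scale = 0.05,
      tail_rate_hz = 120, tail_angle = 1.0, tail_noise_sd = 0.03,
      bout_median_s = 2, bout_sigma = 0.4, bout_floor_s = 1.2,
      gap_median_s = 30, gap_sigma = 0.3, gap_floor_s = 18,
      start_margin_s = 10, end_margin_s = 15
    ),
    dreadd = list(
      n_animals = 8, n_sessions = 6, first_label = "Saline",
      baseline_mean = 150, baseline_sd = 20,
      cno_effect = -60, carryover_frac = 0.5, noise_sd = 7
    )
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(overrides[[nm]]))
      modifyList(cfg[[nm]], overrides[[nm]]) else overrides[[nm]]
  }
  structure(cfg, class = "GeneratorConfig")
}

# deterministic child-seed derivation from the root seed
child_seed <- function(seed, component) {
  offsets <- c(motion = 101L, photometry = 202L, movie = 303L, dreadd = 404L,
               tail = 505L)
  as.integer((as.numeric(seed) * 48271 + offsets[[component]]) %% 2147483646) + 1L
}

# run code under a given seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# log-normal draw with a hard floor, by rejection (seeded, deterministic)
rlnorm_floor <- function(n, median, sigma, floor) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- stats::rlnorm(1, meanlog = log(median), sdlog = sigma)
      if (v >= floor) break
    }
    out[i] <- v
  }
  out
}

#' Generate a motion-index session with known AC/PC structure
#'
#' Baseline noise below the detection threshold, with supra-threshold AC
#' epochs (square pulses with per-bout amplitude jitter, edges aligned to
#' the sample grid) whose durations follow the configured log-normal. The
#' ground-truth segmentation is returned alongside the trace.
#'
#' @param cfg a [generator_config()].
#' @return list `trace` ([time_trace()]), `truth` (list with `segmentation`,
#'   a [bout_segmentation()], and `bouts`, a data.frame `onset`, `duration`,
#'   `amp`).
#' @export
gen_motion_session <- function(cfg = generator_config()) {
  m <- cfg$motion
  with_seed(child_seed(cfg$seed, "motion"), {
    dt <- 1 / m$rate_hz
    snap <- function(t) round(t / dt) * dt
    onsets <- durs <- amps <- numeric(0)
    t <- m$start_margin_s + rlnorm_floor(1, m$pc_median_s / 2, m$pc_sigma, 0)
    repeat {
      d <- snap(rlnorm_floor(1, m$ac_median_s, m$ac_sigma, m$ac_floor_s))
      t <- snap(t)
      if (t + d > m$session_s - m$end_margin_s) break
      onsets <- c(onsets, t); durs <- c(durs, d)
      amps <- c(amps, max(m$amp_floor, m$amp + stats::rnorm(1, 0, m$amp_jitter_sd)))
      t <- t + d + rlnorm_floor(1, m$pc_median_s, m$pc_sigma, m$pc_floor_s)
    }
    n <- as.integer(round(m$session_s * m$rate_hz))
    x <- m$baseline + stats::rnorm(n, 0, m$noise_sd)
    tt <- (seq_len(n) - 1L) * dt
    for (k in seq_along(onsets)) {
      sel <- tt >= onsets[k] - 1e-9 & tt < onsets[k] + durs[k] - 1e-9
      x[sel] <- x[sel] + amps[k]
    }
    truth_seg <- truth_segmentation(onsets, durs, m$session_s)
    list(trace = time_trace(x, rate = m$rate_hz, t0 = 0, label = "motion_index"),
         truth = list(segmentation = truth_seg,
                      bouts = data.frame(onset = onsets, duration = durs, amp = amps)))
  })
}

# alternating partition from AC onsets/durations over [0, session_s]
truth_segmentation <- function(onsets, durs, session_s) {
  if (!length(onsets))
    return(bout_segmentation("PC", 0, session_s, 0, session_s))
  states <- starts <- ends <- NULL
  cur <- 0
  for (k in seq_along(onsets)) {
    if (onsets[k] > cur + 1e-12) {
      states <- c(states, "PC"); starts <- c(starts, cur); ends <- c(ends, onsets[k])
    }
    states <- c(states, "AC"); starts <- c(starts, onsets[k])
    ends <- c(ends, onsets[k] + durs[k])
    cur <- onsets[k] + durs[k]
  }
  if (cur < session_s - 1e-12) {
    states <- c(states, "PC"); starts <- c(starts, cur); ends <- c(ends, session_s)
  }
  bout_segmentation(states, starts, ends, 0, session_s)
}

#' Generate a two-channel photometry session locked to known bouts
#'
#' Per AC bout, a calcium transient with time-to-peak
#' `rise_frac x bout duration` plus additive Gaussian jitter
#' (`rise_jitter_s`) and exponential decay is written into the signal
#' channel only;
#' a shared low-frequency motion artifact is injected into both the signal
#' and isosbestic channels; white measurement noise is added to each.
#'
#' @param cfg a [generator_config()].
#' @param truth the `truth` element from [gen_motion_session()].
#' @return list `session` ([photometry_session()]), `truth` (data.frame per
#'   bout: `onset`, `duration`, `time_to_peak`, `peak_dff`), `clean_dff`
#'   (the programmed transient sum, as a [time_trace()]), `artifact`.
#' @export
gen_photometry_session <- function(cfg = generator_config(), truth) {
  p <- cfg$photometry
  session_s <- cfg$motion$session_s
  with_seed(child_seed(cfg$seed, "photometry"), {
    n <- as.integer(round(session_s * p$rate_hz))
    tt <- (seq_len(n) - 1L) / p$rate_hz
    bouts <- truth$bouts
    g <- numeric(n)
    ttp <- peak <- numeric(nrow(bouts))
    for (k in seq_len(nrow(bouts))) {
      # additive homoscedastic jitter on the time-to-peak, truncated to stay
      # inside [0.2 s, duration + 1 s] (a transient may peak just after offset)
      ttp[k] <- min(bouts$duration[k] + 1,
                    max(0.2, p$rise_frac * bouts$duration[k] +
                          stats::rnorm(1, 0, p$rise_jitter_s)))
      # peak amplitude grows with bout length, mirroring the positive
      # rise-and-amplitude vs duration relationship the traces emulate
      peak[k] <- max(p$peak_floor,
                     p$peak_dff_per_s * bouts$duration[k] +
                       stats::rnorm(1, 0, p$peak_jitter_sd))
      rel <- tt - bouts$onset[k]
      ris <- rel >= 0 & rel < ttp[k]
      dec <- rel >= ttp[k]
      g[ris] <- g[ris] + peak[k] * rel[ris] / ttp[k]
      g[dec] <- g[dec] + peak[k] * exp(-(rel[dec] - ttp[k]) / p$decay_tau_s)
    }
    # shared slow artifact: low-passed white noise rescaled to artifact_sd
    art <- stats::rnorm(n)
    if (p$artifact_sd > 0) {
      art <- lowpass_butterworth(time_trace(art, p$rate_hz), p$artifact_cutoff_hz,
                                 order = 2L)$values
      art <- art / stats::sd(art) * p$artifact_sd
    } else art <- numeric(n)
    sig <- p$f0_signal * (1 + g) + art + stats::rnorm(n, 0, p$noise_sd)
    iso <- p$f0_iso + p$iso_artifact_gain * art + stats::rnorm(n, 0, p$noise_sd)
    session <- photometry_session(
      time_trace(sig, p$rate_hz, label = "ch465"),
      time_trace(iso, p$rate_hz, label = "ch405"),
      animal_id = "synthetic", sensor = "GCaMP6f")
    list(session = session,
         truth = data.frame(onset = bouts$onset, duration = bouts$duration,
                            time_to_peak = ttp, peak_dff = peak),
         clean_dff = time_trace(g, p$rate_hz, label = "programmed_dff"),
         artifact = art)
  })
}

#' Generate a two-photon movie and tail trace with a known responsive region
#'
#' A dim background with a bright astroglial rectangle; a programmed subset
#' of bins inside the bright region carries bout-locked dF/F transients
#' (linear rise over `rise_s`, exponential decay). Photon-like noise with
#' SD proportional to the square root of intensity is added per pixel and
#' frame. The tail-angle trace (120 Hz) holds supra-threshold plateaus at
#' exactly the programmed bout times.
#'
#' @param cfg a [generator_config()]; `cfg$movie$amp_dff = 0` gives a null
#'   movie (no responsive region) for type-I-error studies.
#' @return list `movie` ([movie()]), `tail` ([time_trace()]), `truth` (list
#'   `bouts` data.frame, `responsive_bins` B-length logical over the bins of
#'   the bright region in [bin_and_dff()] order, `bin_coords`).
#' @export
gen_twophoton_movie <- function(cfg = generator_config()) {
  mv <- cfg$movie
  with_seed(child_seed(cfg$seed, "movie"), {
    nfr <- as.integer(round(mv$duration_s * mv$frame_rate_hz))
    ftt <- (seq_len(nfr) - 1L) / mv$frame_rate_hz
    # bout times (drawn once; shared by movie and tail trace)
    onsets <- durs <- numeric(0)
    t <- mv$start_margin_s
    repeat {
      d <- rlnorm_floor(1, mv$bout_median_s, mv$bout_sigma, mv$bout_floor_s)
      if (t + d > mv$duration_s - mv$end_margin_s) break
      onsets <- c(onsets, t); durs <- c(durs, d)
      t <- t + d + rlnorm_floor(1, mv$gap_median_s, mv$gap_sigma, mv$gap_floor_s)
    }
    # transient time course shared by all responsive bins
    dff <- numeric(nfr)
    for (k in seq_along(onsets)) {
      rel <- ftt - onsets[k]
      ris <- rel >= 0 & rel < mv$rise_s
      dec <- rel >= mv$rise_s
      dff[ris] <- dff[ris] + mv$amp_dff * rel[ris] / mv$rise_s
      dff[dec] <- dff[dec] + mv$amp_dff * exp(-(rel[dec] - mv$rise_s) / mv$decay_tau_s)
    }
    bp <- mv$bin_px
    base_img <- matrix(mv$background, mv$h, mv$w)
    for (br in mv$bright_bins$rows) for (bc in mv$bright_bins$cols)
      base_img[((br - 1) * bp + 1):(br * bp), ((bc - 1) * bp + 1):(bc * bp)] <- mv$bright
    resp_img <- matrix(FALSE, mv$h, mv$w)
    for (br in mv$responsive_bins$rows) for (bc in mv$responsive_bins$cols)
      resp_img[((br - 1) * bp + 1):(br * bp), ((bc - 1) * bp + 1):(bc * bp)] <- TRUE
    if (mv$amp_dff > 0 && any(resp_img & base_img <= mv$background))
      stop("responsive region must lie inside the bright (masked) region")
    frames <- array(0, dim = c(nfr, mv$h, mv$w))
    npx <- mv$h * mv$w
    for (f in seq_len(nfr)) {
      img <- base_img
      img[resp_img] <- img[resp_img] * (1 + dff[f])
      img <- img + mv$noise_scale * sqrt(img) * stats::rnorm(npx)
      frames[f, , ] <- pmax(img, 0)
    }
    # tail trace: plateaus of tail_angle radians at the programmed bouts
    ntl <- as.integer(round(mv$duration_s * mv$tail_rate_hz))
    tlt <- (seq_len(ntl) - 1L) / mv$tail_rate_hz
    ang <- stats::rnorm(ntl, 0, mv$tail_noise_sd)
    for (k in seq_along(onsets)) {
      sel <- tlt >= onsets[k] & tlt < onsets[k] + durs[k]
      ang[sel] <- mv$tail_angle + stats::rnorm(sum(sel), 0, mv$tail_noise_sd)
    }
    # truth for bins, in bin_and_dff order (column-major over blocks)
    coords <- NULL; resp <- logical(0)
    for (bc in seq_len(floor(mv$w / bp))) for (br in seq_len(floor(mv$h / bp))) {
      if (br %in% mv$bright_bins$rows && bc %in% mv$bright_bins$cols) {
        coords <- rbind(coords, c(br, bc))
        resp <- c(resp, mv$amp_dff > 0 &&
                    br %in% mv$responsive_bins$rows && bc %in% mv$responsive_bins$cols)
      }
    }
    list(movie = movie(frames, frame_rate = mv$frame_rate_hz),
         tail = time_trace(ang, mv$tail_rate_hz, label = "tail_angle"),
         truth = list(bouts = data.frame(onset = onsets, duration = durs),
                      responsive_bins = resp, bin_coords = coords,
                      programmed_dff = time_trace(pmax(dff, 0) + 1e-12, mv$frame_rate_hz)))
  })
}

#' Generate an alternating saline/CNO session table with a known effect
#'
#' Per-animal alternating sessions: total AC time is an animal-specific
#' baseline plus session noise; CNO sessions are shifted by `cno_effect`
#' (negative: chemogenetic astrocyte activation suppresses AC), and the
#' saline session following a CNO session retains `carryover_frac` of the
#' effect (incomplete washout), which is what gives the two transition
#' types different magnitudes and makes the sign-inversion RM-ANOVA
#' sensitive to the drug effect.
#'
#' @param cfg a [generator_config()]; `cfg$dreadd$cno_effect = 0` gives the
#'   null scenario.
#' @return list `sessions` (data.frame for
#'   [dreadd_inversion_rm_anova()]), `true_effect`.
#' @export
gen_dreadd_scenario <- function(cfg = generator_config()) {
  d <- cfg$dreadd
  with_seed(child_seed(cfg$seed, "dreadd"), {
    labels <- rep(c(d$first_label, setdiff(c("Saline", "CNO"), d$first_label)),
                  length.out = d$n_sessions)
    out <- NULL
    for (a in seq_len(d$n_animals)) {
      base <- stats::rnorm(1, d$baseline_mean, d$baseline_sd)
      eff <- numeric(d$n_sessions)
      for (k in seq_len(d$n_sessions)) {
        eff[k] <- if (labels[k] == "CNO") d$cno_effect
        else if (k > 1L && labels[k - 1L] == "CNO") d$carryover_frac * d$cno_effect
        else 0
      }
      val <- pmax(0, base + eff + stats::rnorm(d$n_sessions, 0, d$noise_sd))
      out <- rbind(out, data.frame(animal = sprintf("m%02d", a),
                                   order = seq_len(d$n_sessions),
                                   label = labels, value = val))
    }
    list(sessions = out, true_effect = d$cno_effect)
  })
}

#' Bout-level recovery statistics against a ground truth
#'
#' Matches detected AC bouts to true AC bouts by temporal overlap (a true
#' bout is recovered when a detected bout overlaps more than half of it) and
#' reports precision, recall, F1, and onset/offset errors (in samples) over
#' the matched pairs.
#'
#' @param truth_seg,detected_seg [bout_segmentation()] objects.
#' @param rate trace sampling rate, samples/s (to express errors in samples).
#' @return list `f1`, `precision`, `recall`, `onset_err_samples`,
#'   `offset_err_samples` (vectors over matches), `n_true`, `n_detected`.
#' @export
bout_match_stats <- function(truth_seg, detected_seg, rate) {
  tb <- truth_seg[truth_seg$state == "AC", , drop = FALSE]
  db <- detected_seg[detected_seg$state == "AC", , drop = FALSE]
  if (nrow(tb) == 0L || nrow(db) == 0L)
    return(list(f1 = if (nrow(tb) == nrow(db)) 1 else 0, precision = NA, recall = NA,
                onset_err_samples = numeric(0), offset_err_samples = numeric(0),
                n_true = nrow(tb), n_detected = nrow(db)))
  matched_d <- rep(FALSE, nrow(db))
  on_err <- off_err <- numeric(0)
  tp <- 0L
  for (i in seq_len(nrow(tb))) {
    ov <- pmin(tb$end[i], db$end) - pmax(tb$start[i], db$start)
    j <- which.max(ov)
    if (ov[j] > tb$duration[i] / 2 && !matched_d[j]) {
      matched_d[j] <- TRUE
      tp <- tp + 1L
      on_err <- c(on_err, abs(db$start[j] - tb$start[i]) * rate)
      off_err <- c(off_err, abs(db$end[j] - tb$end[i]) * rate)
    }
  }
  precision <- tp / nrow(db)
  recall <- tp / nrow(tb)
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(f1 = f1, precision = precision, recall = recall,
       onset_err_samples = on_err, offset_err_samples = off_err,
       n_true = nrow(tb), n_detected = nrow(db))
}
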
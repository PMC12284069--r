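# Photometry preprocessing, alignment, and bout-locked quantification.

mk_session <- function(sig, iso = NULL, rate = 20) {
  photometry_session(time_trace(sig, rate),
                     if (!is.null(iso)) time_trace(iso, rate),
                     animal_id = "m1")
}

test_that("isosbestic correction cancels shared structure up to an affine map", {
  set.seed(21)
  base <- 50 + cumsum(rnorm(2000, 0, 0.05))
  expect_equal(isosbestic_correct(mk_session(base, base))$values,
               rep(0, 2000), tolerance = 1e-9)
  # pure gain difference between channels is absorbed by the affine fit
  expect_equal(isosbestic_correct(mk_session(base * 1.5, base))$values,
               rep(0, 2000), tolerance = 1e-9)
  # and the output is invariant to affine rescaling of the isosbestic channel
  g <- c(rep(0, 800), seq(0, 3, length.out = 400), rep(0, 800))
  s1 <- isosbestic_correct(mk_session(base + g, base))
  s2 <- isosbestic_correct(mk_session(base + g, 0.2 * base + 7))
  expect_equal(s1$values, s2$values, tolerance = 1e-6)
})

test_that("correction recovers a programmed transient and rejects the shared artifact", {
  cfg <- generator_config(314)
  g <- gen_motion_session(cfg)
  ph <- gen_photometry_session(cfg, g$truth)
  corr <- isosbestic_correct(ph$session)
  expect_gt(cor(corr$values, ph$clean_dff$values), 0.95)
  expect_lt(abs(cor(corr$values, ph$artifact)), 0.1)
  # a missing isosbestic channel passes through with a warning
  expect_warning(pt <- isosbestic_correct(
    photometry_session(ph$session$signal)), "unchanged")
  expect_equal(pt$values, ph$session$signal$values)
})

test_that("per-trial z-scoring uses the baseline's population moments", {
  set.seed(22)
  base <- rnorm(50, 10, 2)
  post <- rep(14, 100)
  tr <- time_trace(c(base, post), rate = 10)   # onset at t = 5
  z <- zscore_trial(tr, onset = 5, baseline_s = 5, post_s = 10)
  mu <- mean(base); sg <- sqrt(mean((base - mu)^2))
  expect_equal(mean(z$z[z$time < 0]), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z$z[z$time < 0]^2)), 1, tolerance = 1e-12)
  expect_equal(z$z[z$time >= 0][1L], (14 - mu) / sg, tolerance = 1e-12)
  expect_equal((14 - mu) / sg, 2.0, tolerance = 0.5)   # sampling error at n = 50
  expect_true(0 %in% z$time)

  expect_error(zscore_trial(time_trace(rep(1, 200), 10), 5, 3, 2), "zero variance")
  expect_null(zscore_trial(tr, onset = 2, baseline_s = 5, post_s = 1))
})

test_that("aligned matrices drop bad trials, sort by duration, and keep 0/1 baselines", {
  set.seed(23)
  tr <- time_trace(rnorm(1200) + 10, rate = 10)
  ev <- data.frame(onset = c(2, 40, 80), duration = c(3, 5, 4))
  mat <- build_aligned_matrix(tr, ev, baseline_s = 5, post_s = 10)
  expect_equal(nrow(mat$z), 2L)          # first trial's baseline out of range
  expect_equal(mat$n_dropped, 1L)
  srt <- sort_by_duration(mat)
  expect_equal(srt$event_durations, sort(mat$event_durations))
  base_cols <- mat$time_axis < 0
  for (i in seq_len(nrow(mat$z))) {
    expect_equal(mean(mat$z[i, base_cols]), 0, tolerance = 1e-9)
    expect_equal(sqrt(mean(mat$z[i, base_cols]^2)), 1, tolerance = 1e-9)
  }
  expect_error(build_aligned_matrix(tr, data.frame(onset = 1, duration = 2),
                                    baseline_s = 5), "dropped")
})

test_that("bout-locked synthetic transients produce a post-onset population peak", {
  cfg <- generator_config(271)
  g <- gen_motion_session(cfg)
  ph <- gen_photometry_session(cfg, g$truth)
  corr <- photometry_preprocess(ph$session)
  mat <- build_aligned_matrix(corr, ac_events(g$truth$segmentation), baseline_s = 5)
  avg <- colMeans(mat$z, na.rm = TRUE)
  expect_gt(mat$time_axis[which.max(avg)], 0)
})

test_that("per-animal normalization yields unit maxima, independently and idempotently", {
  z <- rbind(c(0, 2, 4), c(1, 0.5, 2), c(0, 8, 1), c(2, 1, 0.1))
  mat <- structure(list(z = z, time_axis = c(-1, 0, 1) / 10, baseline_s = 0.1,
                        event_durations = rep(1, 4),
                        animal_ids = c("a", "a", "b", "b"), n_dropped = 0L),
                   class = "EventAlignedMatrix")
  nm <- normalize_per_animal(mat)
  expect_equal(max(nm$z[1:2, ]), 1)
  expect_equal(max(nm$z[3:4, ]), 1)
  expect_equal(nm$z[1:2, ], z[1:2, ] / 4)
  expect_equal(nm$z[3:4, ], z[3:4, ] / 8)
  expect_equal(normalize_per_animal(nm)$z, nm$z)   # idempotent
  mat$z[1:2, ] <- -abs(mat$z[1:2, ])
  expect_error(normalize_per_animal(mat), "non-positive")
})

test_that("last-second AC vs PC comparison separates a programmed state difference", {
  # constructed trace: baseline N(0,1)-scaled, AC plateau z ~ 2, PC back to 0
  rate <- 10
  set.seed(24)
  n <- 3000
  x <- rnorm(n)                 # baseline sd 1 everywhere
  states <- starts <- ends <- NULL
  t <- 20
  for (k in 1:10) {
    tt <- (0:(n - 1)) / rate
    x[tt >= t & tt < t + 4] <- x[tt >= t & tt < t + 4] + 2
    states <- c(states, "PC", "AC"); starts <- c(starts, t - 10, t)
    ends <- c(ends, t, t + 4)
    t <- t + 14
  }
  seg <- bout_segmentation(c(states, "PC"), c(starts, t - 10), c(ends, n / rate),
                           10, n / rate)
  res <- state_amplitude_comparison(time_trace(x, rate), seg)
  expect_equal(nrow(res$pairs), 10L)
  expect_true(all(res$pairs$ac_last > res$pairs$pc_last))
  # all ten signs positive: the exact two-sided signed-rank floor at n = 10
  expect_equal(res$test$p.value, 2^-9, tolerance = 1e-12)
  expect_gt(mean(res$pairs$ac_last), 1)
  expect_lt(abs(mean(res$pairs$pc_last)), 1)
})

test_that("rise-time extraction handles ramps, steps, and programmed kinetics", {
  tax <- seq(-5, 15, by = 0.05)
  dur <- 6
  ramp <- ifelse(tax >= 0 & tax <= dur, tax / dur, ifelse(tax > dur, 0, 0))
  r1 <- rise_time(ramp, tax, dur)
  expect_equal(r1$rise_time_s, dur, tolerance = 0.05 + 1e-9)

  step <- ifelse(tax >= 0, 1, 0)
  r2 <- rise_time(step, tax, dur)
  expect_lte(r2$rise_time_s, 0.05 + 1e-9)
  expect_true(r2$reliable)

  flat <- rep(0, length(tax))
  expect_false(rise_time(flat, tax, dur)$reliable)

  # programmed time-to-peak at 0.8 x duration recovered within 2 samples
  cfg <- generator_config(99, photometry = list(rise_jitter_s = 0, noise_sd = 0.01,
                                                artifact_sd = 0))
  g <- gen_motion_session(generator_config(99, motion = list(noise_sd = 0,
                                                             amp_jitter_sd = 0)))
  ph <- gen_photometry_session(cfg, g$truth)
  corr <- isosbestic_correct(ph$session)
  mat <- build_aligned_matrix(corr, ac_events(g$truth$segmentation), baseline_s = 5)
  rp <- rise_points(mat, post_margin_s = 1)
  err <- abs(rp$rise_time_s - ph$truth$time_to_peak)
  expect_true(all(err <= 2 / corr$rate + 1e-9))
})

test_that("rise/duration regression matches closed-form and null expectations", {
  d <- seq(2, 10, length.out = 20)
  perfect <- data.frame(rise_time_s = 0.5 * d + 1, bout_duration_s = d)
  fit <- suppressWarnings(rise_duration_regression(perfect))
  expect_equal(fit$slope, 0.5, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # independence: E[R^2] under the null is 1/(n-1)
  set.seed(25)
  n <- 40
  r2s <- replicate(400, {
    pts <- data.frame(rise_time_s = sample(0.5 * d + rnorm(20)),
                      bout_duration_s = d)
    rise_duration_regression(pts)$r_squared
  })
  expect_lt(abs(mean(r2s) - 1 / (20 - 1)), 0.012)   # ~3.5 SE of the Beta null

  # the stated generator model at the pooled trial count (n = 256)
  set.seed(26)
  d256 <- rlnorm(256, log(3), 0.6)
  pts <- data.frame(rise_time_s = 0.8 * d256 + rnorm(256, 0, 0.3),
                    bout_duration_s = d256)
  f2 <- rise_duration_regression(pts)
  expect_true(f2$slope_ci[1] <= 0.8 && 0.8 <= f2$slope_ci[2])
  expect_error(rise_duration_regression(
    data.frame(rise_time_s = 1:3, bout_duration_s = rep(2, 3))), "variance")
})

test_that("onset latency recovers constructed shifts", {
  tax <- seq(-2, 8, by = 0.05)
  mkmat <- function(shift) {
    z <- t(vapply(1:12, function(i)
      ifelse(tax >= shift, 3, 0) + rnorm(length(tax), 0, 0.05), numeric(length(tax))))
    structure(list(z = z, time_axis = tax, baseline_s = 2,
                   event_durations = rep(4, 12), animal_ids = rep("a", 12),
                   n_dropped = 0L), class = "EventAlignedMatrix")
  }
  set.seed(27)
  a <- mkmat(0.5)
  res0 <- onset_latency(a, a)
  expect_true(all(res0$latency_diff_s == 0))

  b <- mkmat(1.0)   # b delayed 0.5 s relative to a
  res <- onset_latency(a, b)
  expect_equal(median(res$latency_diff_s), 0.5, tolerance = 0.05 + 1e-9)
  expect_lt(res$test$p.value, 0.01)
})

test_that("calcium-kinematic correlograms localize constructed lags", {
  set.seed(28)
  n <- 12000; rate <- 20
  k <- as.numeric(stats::filter(rnorm(n), rep(1, 40) / 40, sides = 1))
  k[is.na(k)] <- 0
  ca_lagged <- c(rep(0, 3 * rate), k[1:(n - 3 * rate)])
  cg <- ca_velocity_correlogram(time_trace(ca_lagged, rate), time_trace(k, rate),
                                bin_hz = 1, max_lag_s = 10)
  expect_equal(cg$lag_s[which.max(cg$r)], 3)

  ident <- ca_velocity_correlogram(time_trace(k, rate), time_trace(k, rate))
  expect_equal(ident$r[ident$lag_s == 0], 1, tolerance = 1e-9)

  # independent white noise, 600 bins: all |r| below the n = 600 null bound
  x <- time_trace(rnorm(600 * rate), rate)
  y <- time_trace(rnorm(600 * rate), rate)
  nullcg <- ca_velocity_correlogram(x, y, max_lag_s = 10)
  expect_true(all(abs(nullcg$r) < 0.13))
  expect_error(ca_velocity_correlogram(time_trace(rnorm(40), 20),
                                       time_trace(rnorm(40), 20)), "10 bins")
})

test_that("aligned matrices export to wide CSV with a JSON sidecar", {
  set.seed(29)
  tr <- time_trace(rnorm(600) + 5, rate = 10)
  mat <- build_aligned_matrix(tr, data.frame(onset = c(20, 40), duration = c(3, 2)),
                              baseline_s = 5, post_s = 8, animal_id = "m7")
  f <- tempfile(fileext = ".csv")
  write_aligned_csv(mat, f)
  back <- utils::read.csv(f, check.names = FALSE)
  expect_equal(dim(back), dim(mat$z))
  side <- jsonlite::fromJSON(paste0(f, ".json"))
  expect_equal(side$event_durations, mat$event_durations)
  expect_equal(side$animal_ids, rep("m7", 2))
})
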
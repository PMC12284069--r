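# Independent brute-force references and fixture builders shared across the
# suite. The oracles are deliberately literal (per-run loops over explicit
# run lists), independent of the package's rle-based implementations.

# Literal merge-then-prune bout segmentation: enumerate maximal
# supra-threshold runs, absorb short interior gaps, drop short active runs,
# emit the alternating partition. Works in sample indices.
oracle_detect_bouts <- function(values, rate, amp, min_ac, min_pc, t0 = 0) {
  n <- length(values)
  dt <- 1 / rate
  active <- values >= amp
  runs <- function(flag) {
    out <- list()
    i <- 1L
    while (i <= n) {
      if (flag[i]) {
        j <- i
        while (j < n && flag[j + 1L]) j <- j + 1L
        out[[length(out) + 1L]] <- c(i, j)
        i <- j + 1L
      } else i <- i + 1L
    }
    out
  }
  # merge: interior gaps shorter than min_pc become active
  act_runs <- runs(active)
  if (length(act_runs) >= 2L) {
    for (k in seq_len(length(act_runs) - 1L)) {
      gap_start <- act_runs[[k]][2L] + 1L
      gap_end <- act_runs[[k + 1L]][1L] - 1L
      if ((gap_end - gap_start + 1L) * dt < min_pc - 1e-9)
        active[gap_start:gap_end] <- TRUE
    }
  }
  # prune: active runs shorter than min_ac become passive
  for (r in runs(active)) {
    if ((r[2L] - r[1L] + 1L) * dt < min_ac - 1e-9)
      active[r[1L]:r[2L]] <- FALSE
  }
  # emit alternating partition
  states <- starts <- ends <- NULL
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && active[j + 1L] == active[i]) j <- j + 1L
    states <- c(states, if (active[i]) "AC" else "PC")
    starts <- c(starts, t0 + (i - 1L) * dt)
    ends <- c(ends, t0 + j * dt)
    i <- j + 1L
  }
  bout_segmentation(states, starts, ends, t0, t0 + n * dt)
}

# Literal run-length tail-bout oracle (strict > on both thresholds).
oracle_tail_bouts <- function(values, rate, thr, min_dur, t0 = 0) {
  n <- length(values)
  dt <- 1 / rate
  out <- NULL
  i <- 1L
  while (i <= n) {
    if (abs(values[i]) > thr) {
      j <- i
      while (j < n && abs(values[j + 1L]) > thr) j <- j + 1L
      if ((j - i + 1L) * dt > min_dur + 1e-9)
        out <- rbind(out, data.frame(start = t0 + (i - 1L) * dt,
                                     end = t0 + j * dt))
      i <- j + 1L
    } else i <- i + 1L
  }
  if (is.null(out)) out <- data.frame(start = numeric(0), end = numeric(0))
  out$duration <- out$end - out$start
  out
}

# Exact Pratt signed-rank p-value by enumerating all sign assignments of the
# non-zero differences (feasible for m <= 12).
oracle_signed_rank_p <- function(d, alternative = "two.sided") {
  ad <- abs(d)
  rk <- rank(ad)
  nz <- which(d != 0)
  m <- length(nz)
  stopifnot(m <= 12L)
  v_obs <- sum(rk[d > 0])
  vs <- vapply(0:(2^m - 1), function(mask) {
    signs <- bitwAnd(bitwShiftR(mask, seq_len(m) - 1L), 1L) == 1L
    sum(rk[nz[signs]])
  }, numeric(1))
  pg <- mean(vs >= v_obs)
  pl <- mean(vs <= v_obs)
  switch(alternative,
         greater = pg, less = pl,
         two.sided = min(1, 2 * min(pg, pl)))
}

# Random trace mixing a reflected random walk with square pulses — the
# stress input for segmentation oracle equivalence.
random_motion_trace <- function(n = 600, rate = 10) {
  walk <- abs(cumsum(rnorm(n, 0, 0.1)))
  walk <- walk / max(walk, 1) * runif(1, 0.3, 1.2)
  x <- walk
  for (k in seq_len(rpois(1, 3))) {
    len <- sample.int(80, 1)
    at <- sample.int(n - len, 1)
    x[at:(at + len - 1L)] <- x[at:(at + len - 1L)] + runif(1, 0.3, 1.5)
  }
  time_trace(x, rate = rate)
}

# Structural invariants every segmentation must satisfy.
expect_valid_segmentation <- function(seg, params) {
  span <- attr(seg, "session_span")
  expect_true(all(seg$duration > 0))
  expect_equal(seg$start[1L], span[1L])
  expect_equal(seg$end[nrow(seg)], span[2L])
  if (nrow(seg) > 1L) {
    expect_equal(seg$start[-1L], seg$end[-nrow(seg)])
    expect_true(all(seg$state[-1L] != seg$state[-nrow(seg)]))
  }
  ac <- seg$duration[seg$state == "AC"]
  expect_true(all(ac >= params$min_active_s - 1e-9))
  pc_int <- which(seg$state == "PC")
  pc_int <- pc_int[pc_int > 1L & pc_int < nrow(seg)]   # interior PC only
  expect_true(all(seg$duration[pc_int] >= params$min_passive_s - 1e-9))
  invisible(seg)
}
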
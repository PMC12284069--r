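#' Zero-phase Butterworth low-pass filter
#'
#' Low-pass filters a trace with a digital Butterworth filter of the given
#' design order. By default the filter is applied forward and backward
#' (zero-phase), so bout onsets and offsets are not shifted in time — the
#' property that matters for onset-aligned photometry. Forward-backward
#' application squares the magnitude response, i.e. the effective attenuation
#' is that of a filter of twice the design order; `order` always refers to
#' the one-way design.
#'
#' Edge handling: the trace is demeaned and odd-reflection padded by several
#' times the filter's settle time before filtering, so a constant trace
#' passes through unchanged (DC gain 1) and edges are not pulled toward zero.
#' Traces shorter than three times the filter's 99% impulse-response width
#' are rejected rather than silently padded.
#'
#' @param trace a [time_trace()].
#' @param cutoff_hz -3 dB cutoff of the one-way design, in Hz; must be below
#'   the Nyquist frequency `rate/2`.
#' @param order filter design order, >= 1. Default 1.
#' @param zero_phase apply forward-backward (default `TRUE`); `FALSE` gives
#'   the causal one-way filter, which delays features by roughly the filter
#'   time constant.
#' @return a filtered [time_trace()] of identical length and rate.
#' @export
lowpass_butterworth <- function(trace, cutoff_hz, order = 1L, zero_phase = TRUE) {
  stopifnot(inherits(trace, "TimeTrace"))
  if (!is.finite(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= trace$rate / 2)
    stop("cutoff_hz must lie in (0, rate/2)")
  if (order < 1) stop("order must be >= 1")
  # 99% settle width of the (cascaded) impulse response, in samples:
  # one first-order analog stage has tau = 1/(2*pi*fc); ~4.6 tau to 99%.
  tau_samp <- trace$rate / (2 * pi * cutoff_hz)
  ir99 <- 4.6 * order * tau_samp
  n <- length(trace$values)
  if (n < 3 * ir99)
    stop(sprintf(
      "trace too short for filter warm-up: %d samples < 3 x %.0f-sample impulse response",
      n, ir99))
  bf <- signal::butter(order, cutoff_hz / (trace$rate / 2), type = "low")
  mu <- mean(trace$values)
  x <- trace$values - mu
  npad <- min(n - 1L, ceiling(15 * order * tau_samp))
  # odd reflection about the endpoints (continuity of value and slope)
  head_pad <- 2 * x[1L] - x[(npad + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - npad)]
  xp <- c(head_pad, x, tail_pad)
  yp <- as.numeric(signal::filter(bf, xp))
  if (zero_phase) yp <- rev(as.numeric(signal::filter(bf, rev(yp))))
  y <- yp[(npad + 1L):(npad + n)] + mu
  ct_log("lowpass_butterworth: fc=%.3g Hz order=%d zero_phase=%s n=%d",
         cutoff_hz, order, zero_phase, n)
  time_trace(y, rate = trace$rate, t0 = trace$t0, label = trace$label)
}

#' Causal exponential smoothing
#'
#' First-order exponential (RC-style) smoothing with time constant `tau_s`:
#' the step response reaches `1 - exp(-1)` of the step amplitude `tau_s`
#' after the step. The recursion uses the exact discretization
#' `alpha = 1 - exp(-dt/tau)`, so the continuous-time step response is
#' matched at the sample points. Causal: output at time t depends only on
#' samples up to t.
#'
#' @param trace a [time_trace()].
#' @param tau_s smoothing time constant in seconds, > 0.
#' @return a smoothed [time_trace()] of identical length and rate.
#' @export
smooth_time_constant <- function(trace, tau_s) {
  stopifnot(inherits(trace, "TimeTrace"))
  if (!is.finite(tau_s) || tau_s <= 0) stop("tau_s must be > 0")
  alpha <- 1 - exp(-1 / (trace$rate * tau_s))
  # y[i] = alpha x[i] + (1-alpha) y[i-1], initialized at the first sample
  y <- as.numeric(signal::filter(
    signal::Arma(b = alpha, a = c(1, -(1 - alpha))), trace$values))
  # initialize at x[1] instead of 0 so a constant trace is a fixed point
  y <- y + trace$values[1L] * (1 - alpha)^seq_along(y)
  ct_log("smooth_time_constant: tau=%.3g s n=%d", tau_s, length(y))
  time_trace(y, rate = trace$rate, t0 = trace$t0, label = trace$label)
}

#' Band-limited resampling to a target rate
#'
#' Fourier-domain (band-limited) resampling: the trace's discrete spectrum
#' is truncated or zero-padded to the output length and inverse-transformed,
#' so any signal band-limited below the lower of the two Nyquist frequencies
#' is reconstructed rather than linearly interpolated. The output covers the
#' same time span; the sample count is `round(n * target_rate / rate)`. Like
#' all Fourier methods it assumes implicit periodicity, so roughly the first
#' and last second are edge-unreliable and should be excluded from event
#' detection.
#'
#' @param trace a [time_trace()].
#' @param target_rate output rate, samples/s, > 0. Upsampling is allowed but
#'   logged, since it adds no information.
#' @return a [time_trace()] at `target_rate`. Identity (bitwise) when
#'   `target_rate == rate`.
#' @export
resample_to_rate <- function(trace, target_rate) {
  stopifnot(inherits(trace, "TimeTrace"))
  if (!is.finite(target_rate) || target_rate <= 0) stop("target_rate must be > 0")
  if (target_rate == trace$rate) return(trace)
  if (target_rate > trace$rate)
    ct_log("resample_to_rate: upsampling %.4g -> %.4g Hz", trace$rate, target_rate)
  n <- length(trace$values)
  m <- max(1L, as.integer(round(n * target_rate / trace$rate)))
  y <- fft_resample(trace$values, m)
  ct_log("resample_to_rate: %d samples @ %.4g Hz -> %d @ %.4g Hz",
         n, trace$rate, m, target_rate)
  time_trace(y, rate = target_rate, t0 = trace$t0, label = trace$label)
}

# Fourier resampling of a real vector to length m (spectrum truncation /
# zero padding, with the shared-Nyquist bin split or folded so the output
# stays real and amplitude-faithful).
fft_resample <- function(x, m) {
  n <- length(x)
  if (m == n) return(x)
  X <- stats::fft(x)
  Y <- complex(m)
  N <- min(m, n)
  nyq <- N %/% 2L + 1L                    # positive-frequency bins incl. DC
  Y[1:nyq] <- X[1:nyq]
  if (N > 2L) {
    k <- N - nyq                          # negative-frequency bins
    Y[(m - k + 1L):m] <- X[(n - k + 1L):n]
  }
  if (N %% 2L == 0L) {
    if (m < n) {                          # downsample: fold aliased bin in
      Y[N %/% 2L + 1L] <- Y[N %/% 2L + 1L] + X[n - N %/% 2L + 1L]
    } else {                              # upsample: split shared bin
      Y[N %/% 2L + 1L] <- Y[N %/% 2L + 1L] / 2
      Y[m - N %/% 2L + 1L] <- Y[N %/% 2L + 1L]
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) * (1 / n)
}
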
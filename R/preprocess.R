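#' Resample a recording to a lower sampling rate
#'
#' Anti-aliased polyphase resampling. Upsampling is refused: screening and
#' cycle analysis only ever need a common lower rate.
#'
#' @param rec A [recording()].
#' @param target_fs Target sampling rate in Hz; must be <= `rec$fs`.
#' @return The resampled [recording()], with length
#'   `round(length(samples) * target_fs / fs)`.
#' @export
resample_to <- function(rec, target_fs) {
  assert_recording(rec)
  if (!is.finite(target_fs) || target_fs <= 0) stop_invalid("target_fs must be positive")
  if (target_fs > rec$fs) {
    stop_invalid("upsampling refused: target_fs must be <= the recording fs")
  }
  if (target_fs == rec$fs) return(rec)
  gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)
  ai <- round(target_fs * 1e6); bi <- round(rec$fs * 1e6)
  g <- gcd(ai, bi)
  p <- ai / g; q <- bi / g
  y <- signal::resample(rec$samples, p, q)
  n_out <- round(length(rec$samples) * target_fs / rec$fs)
  if (length(y) > n_out) y <- y[seq_len(n_out)]
  if (length(y) < n_out) y <- c(y, rep(y[length(y)], n_out - length(y)))
  rec_update(rec, y, fs = target_fs)
}

#' Bipolar re-reference an ordered set of contacts
#'
#' Subtracts adjacent electrode contacts along one shaft to isolate local
#' activity and cancel far-field signals: n contacts yield n - 1 derived
#' channels, derived channel i = contact i - contact i + 1.
#'
#' @param channels List of neural [recording()]s in contact order, sharing
#'   `fs` and length.
#' @return List of n - 1 derived [recording()]s; each `channel_id`
#'   concatenates the contributing pair.
#' @export
bipolar_rereference <- function(channels) {
  if (!is.list(channels) || length(channels) < 2L) {
    stop_invalid("need >= 2 contacts for bipolar re-referencing")
  }
  lapply(channels, assert_recording)
  ns <- vapply(channels, function(r) length(r$samples), integer(1))
  fss <- vapply(channels, function(r) r$fs, numeric(1))
  if (length(unique(ns)) != 1L || length(unique(fss)) != 1L) {
    stop_invalid("contacts must share sampling rate and length")
  }
  lapply(seq_len(length(channels) - 1L), function(i) {
    a <- channels[[i]]; b <- channels[[i + 1L]]
    out <- rec_update(a, a$samples - b$samples)
    out$channel_id <- paste(a$channel_id, b$channel_id, sep = "-")
    out
  })
}

#' Low-pass filter a respiration trace at 2 Hz
#'
#' Linear-phase windowed-sinc FIR filter (Hamming window, 1 Hz transition
#' band), applied with full group-delay compensation so the output has zero
#' net delay. Gain is within 1 percent of unity below 0.5 Hz and the 0 Hz
#' (DC) gain is exactly 1.
#'
#' @param rec An `"airflow"` or `"belt"` [recording()].
#' @param cutoff_hz Cutoff frequency, default 2 Hz.
#' @param transition_hz Transition-band width used to size the filter.
#' @return The filtered [recording()].
#' @export
lowpass_respiration <- function(rec, cutoff_hz = 2, transition_hz = 1) {
  assert_recording(rec, modalities = c("airflow", "belt"))
  ntaps <- ceiling(3.3 * rec$fs / transition_hz)
  if (ntaps %% 2L == 0L) ntaps <- ntaps + 1L
  b <- signal::fir1(ntaps - 1L, cutoff_hz / (rec$fs / 2), type = "low")
  b <- b / sum(b)   # exact unit gain at DC
  y <- fir_zerophase(rec$samples, b)
  out <- rec_update(rec, y)
  attr(out, "edge_exclude_s") <- max(attr(rec, "edge_exclude_s") %||% 0,
                                     ceiling((ntaps - 1) / 2 / rec$fs))
  out
}

# Apply an odd-length linear-phase FIR with edge padding and group-delay
# compensation (net delay zero).
fir_zerophase <- function(x, b) {
  n <- length(x)
  gd <- (length(b) - 1L) %/% 2L
  xp <- c(rep(x[1L], gd), x, rep(x[n], gd))
  y <- stats::filter(c(xp, rep(x[n], gd)), b, method = "convolution",
                     sides = 1L)
  as.numeric(y[(2L * gd + 1L):(2L * gd + n)])
}

# --- fifth-order Bessel band-pass, applied forward-backward -----------------

# Analog low-pass Bessel prototype of order 5, normalized so the magnitude
# response is -3 dB at omega = 1. Poles are the roots of the reverse Bessel
# polynomial s^5 + 15 s^4 + 105 s^3 + 420 s^2 + 945 s + 945.
bessel5_prototype <- function() {
  p <- polyroot(c(945, 945, 420, 105, 15, 1))
  magsq <- function(w) abs(prod(1i * w - p))^2
  w3 <- stats::uniroot(function(w) magsq(w) - 2 * 945^2, c(0.1, 10),
                       tol = 1e-12)$root
  list(pole = p / w3, gain = 945 / w3^5)
}

# Digital band-pass as second-order sections via the analog prototype,
# low-pass -> band-pass transformation, and the bilinear transform.
bessel_bandpass_sos <- function(lo_hz, hi_hz, fs) {
  proto <- bessel5_prototype()
  T <- 2
  w <- 2 / T * tan(pi * c(lo_hz, hi_hz) / fs)   # prewarped rad/s
  st <- signal::sftrans(Sz = numeric(0), Sp = proto$pole, Sg = proto$gain,
                        W = w, stop = FALSE)
  # bilinear transform applied pole-wise; the 5 zeros at s=0 map to z=+1 and
  # the degree deficit contributes 5 zeros at z=-1, giving b = [1, 0, -1]
  # per section below
  pd <- (2 / T + st$pole) / (2 / T - st$pole)
  # pair conjugate poles into biquads; give each section one zero at +1 and
  # one at -1 (b = [1, 0, -1])
  pu <- pd[Im(pd) > 1e-12]
  pr <- Re(pd[abs(Im(pd)) <= 1e-12])
  sos <- list()
  for (p in pu) {
    sos[[length(sos) + 1L]] <- list(b = c(1, 0, -1),
                                    a = c(1, -2 * Re(p), Mod(p)^2))
  }
  while (length(pr) >= 2L) {
    sos[[length(sos) + 1L]] <- list(b = c(1, 0, -1),
                                    a = c(1, -(pr[1] + pr[2]), pr[1] * pr[2]))
    pr <- pr[-(1:2)]
  }
  if (length(pr) == 1L) {
    sos[[length(sos) + 1L]] <- list(b = c(1, -1, 0), a = c(1, -pr[1], 0))
  }
  # normalize to unity gain at the band's geometric center frequency
  zc <- exp(2i * pi * sqrt(lo_hz * hi_hz) / fs)
  h <- prod(vapply(sos, function(s) {
    Mod(sum(s$b * zc^(0:-2)) / sum(s$a * zc^(0:-2)))
  }, numeric(1)))
  g_sec <- (1 / h)^(1 / length(sos))
  for (i in seq_along(sos)) sos[[i]]$b <- sos[[i]]$b * g_sec
  sos
}

# Complex frequency response of a second-order-section cascade at the
# given frequencies (Hz).
sos_response <- function(sos, f, fs) {
  zc <- exp(2i * pi * f / fs)
  h <- rep(1 + 0i, length(f))
  for (s in sos) {
    h <- h * (s$b[1L] + s$b[2L] / zc + s$b[3L] / zc^2) /
      (s$a[1L] + s$a[2L] / zc + s$a[3L] / zc^2)
  }
  h
}

# Forward-backward (zero-phase) application of a second-order-section
# cascade, realized spectrally: the signal's spectrum is multiplied by
# |H(f)|^2, the exact steady-state response of forward-backward filtering.
# The near-unit-circle poles of the 0.01 Hz corner make a time-domain
# recursion ring for minutes; the spectral realization has no transient.
# Odd-reflection padding suppresses circular wrap-around at the edges.
filtfilt_sos <- function(x, sos, pad_s, fs) {
  n <- length(x)
  np <- min(n - 1L, round(pad_s * fs))
  # grow the pad to the next 2-3-5-smooth length: keeps the FFT fast
  m <- stats::nextn(n + 2L * np, c(2, 3, 5))
  while ((m - n) %% 2L == 1L) m <- stats::nextn(m + 1L, c(2, 3, 5))
  np <- min(n - 1L, (m - n) %/% 2L)
  m <- n + 2L * np
  xp <- c(2 * x[1L] - x[(np + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - np)])
  # taper the pads to zero so the circular wrap seen by the FFT is smooth;
  # the slow envelope only creates sidebands local to each signal component
  ramp <- (1 - cos(pi * seq_len(np) / np)) / 2
  xp[seq_len(np)] <- xp[seq_len(np)] * ramp
  xp[m - np + seq_len(np)] <- xp[m - np + seq_len(np)] * rev(ramp)
  k <- seq_len(m) - 1L
  f <- pmin(k, m - k) * fs / m
  h2 <- Mod(sos_response(sos, f, fs))^2
  y <- Re(stats::fft(stats::fft(xp) * h2, inverse = TRUE)) / m
  y[(np + 1L):(np + n)]
}

#' Band-pass filter a recording for time-domain screening
#'
#' Fifth-order Bessel IIR band-pass (default 0.01 to 2 Hz) applied
#' forward-backward for zero phase shift, preserving waveform timing. The
#' forward-backward pass is realized spectrally (the spectrum is multiplied
#' by the squared magnitude response of the second-order-section cascade),
#' which is its exact steady state and avoids the minutes-long ringing a
#' time-domain recursion exhibits at the 0.01 Hz corner. The first and last
#' 10 s are flagged for exclusion from cycle extraction (edge effects).
#'
#' @param rec A [recording()] longer than six time constants of the low
#'   corner (about 95 s at 0.01 Hz).
#' @param band Two-element band in Hz.
#' @return The filtered [recording()], with `attr(x, "edge_exclude_s") = 10`.
#' @export
bandpass_for_timedomain <- function(rec, band = c(0.01, 2)) {
  assert_recording(rec)
  tc <- 1 / (2 * pi * band[1L])
  if (rec_duration(rec) <= 6 * tc) {
    stop_invalid(sprintf(
      "recording must be longer than 6 filter time constants (%.0f s) of the %g Hz corner",
      6 * tc, band[1L]))
  }
  sos <- bessel_bandpass_sos(band[1L], band[2L], rec$fs)
  y <- filtfilt_sos(rec$samples, sos, pad_s = 30, fs = rec$fs)
  out <- rec_update(rec, y)
  attr(out, "edge_exclude_s") <- max(attr(rec, "edge_exclude_s") %||% 0, 10)
  out
}

#' z-score a recording over its full duration
#'
#' Centering and scaling use the whole-recording mean and SD (not per-epoch
#' statistics), so later epoching does not change the normalization.
#'
#' @param rec A [recording()].
#' @return The standardized [recording()].
#' @export
zscore_recording <- function(rec) {
  assert_recording(rec)
  s <- stats::sd(rec$samples)
  if (!is.finite(s) || s < 1e-12 * max(1, abs(mean(rec$samples)))) {
    stop_rs("cannot z-score a (near-)constant signal", "rs_degenerate_signal")
  }
  rec_update(rec, (rec$samples - mean(rec$samples)) / s)
}
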
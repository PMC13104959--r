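# Time-domain screening: respiration-peak-locked cross-correlation with a
# permutation null, and the phase monotonicity index with a circular-shift
# null. Both operate on band-passed, z-scored signals.

#' Epoch paired signals on respiration peaks
#'
#' Cuts matching neural and respiration windows centered on each respiration
#' peak (peak inhalation). Windows are sized to the participant's breath
#' cycle so each epoch contains both the inhale peak and the exhale trough.
#' Epochs truncated by the recording edges are dropped.
#'
#' @param neural,resp Band-passed, z-scored [recording()]s sharing fs and
#'   length.
#' @param resp_peaks Respiration peak times in seconds, sorted.
#' @param window_s Epoch length in seconds; each epoch spans peak +/-
#'   `window_s / 2`. Use the participant's mean breath period (`band$tau`).
#' @return An object of class `"resp_epochs"`: matrices `neural` and `resp`
#'   (samples x epochs), `starts` (sample index of each epoch), `peak_times`,
#'   `fs`, `window_s`.
#' @export
epoch_on_respiration_peaks <- function(neural, resp, resp_peaks, window_s) {
  assert_recording(neural); assert_recording(resp)
  if (neural$fs != resp$fs || length(neural$samples) != length(resp$samples)) {
    stop_invalid("neural and resp must share sampling rate and length")
  }
  if (is.unsorted(resp_peaks)) stop_invalid("resp_peaks must be sorted")
  fs <- neural$fs
  n <- length(neural$samples)
  L <- round(window_s * fs)
  starts <- round((resp_peaks - window_s / 2) * fs) + 1L
  ok <- starts >= 1L & (starts + L - 1L) <= n
  if (!any(ok)) stop_rs("no usable respiration-peak epochs", "rs_empty_epochs")
  starts <- starts[ok]
  cut <- function(x) vapply(starts, function(s) x[s:(s + L - 1L)], numeric(L))
  structure(list(neural = cut(neural$samples), resp = cut(resp$samples),
                 starts = starts, peak_times = resp_peaks[ok],
                 fs = fs, window_s = window_s),
            class = "resp_epochs")
}

#' @export
print.resp_epochs <- function(x, ...) {
  cat(sprintf("<resp_epochs> %d epochs of %.2f s @ %g Hz\n",
              ncol(x$neural), x$window_s, x$fs))
  invisible(x)
}

# Normalized cross-correlation of paired epoch matrices at lags
# -max_lag..max_lag (positive lag = neural delayed relative to respiration),
# averaged over epochs. Each epoch's CCF is normalized by the product of the
# epoch-wise norms, so single-epoch values lie in [-1, 1].
mean_ccf_epochs <- function(respM, neuralM, fs, max_lag) {
  L <- nrow(respM)
  nfft <- next_pow2(L + max_lag)
  Fr <- stats::mvfft(rbind(respM, matrix(0, nfft - L, ncol(respM))))
  Fn <- stats::mvfft(rbind(neuralM, matrix(0, nfft - L, ncol(neuralM))))
  cc <- Re(stats::mvfft(Conj(Fr) * Fn, inverse = TRUE)) / nfft
  norms <- sqrt(colSums(respM^2) * colSums(neuralM^2))
  norms[norms == 0] <- Inf
  lags <- -max_lag:max_lag
  rows <- ifelse(lags >= 0, lags + 1L, nfft + lags + 1L)
  m <- cc[rows, , drop = FALSE] / rep(norms, each = length(rows))
  rowMeans(m)
}

#' Epoch-averaged cross-correlation between neural and respiration signals
#'
#' Computes the normalized cross-correlation function per respiration-peak
#' epoch, averages across epochs, and restricts lags to half a respiration
#' cycle to avoid spurious cyclic associations. Positive lags mean the
#' neural signal follows respiration.
#'
#' @param epochs A [epoch_on_respiration_peaks()] result with >= 5 epochs.
#' @param tau Respiration period in seconds; lags span `[-tau/2, tau/2]`.
#' @return An object of class `"ccf_result"`: `lags_s`, `mean_ccf`,
#'   `max_abs`, `lag_at_max_s`, `polarity` (-1 when the extreme mean CCF
#'   value is negative).
#' @export
mean_ccf <- function(epochs, tau) {
  if (!inherits(epochs, "resp_epochs")) stop_invalid("epochs must be resp_epochs")
  K <- ncol(epochs$neural)
  if (K < 5L) stop_rs("need at least 5 epochs for a mean CCF", "rs_insufficient_data")
  max_lag <- min(floor(tau / 2 * epochs$fs), nrow(epochs$neural) - 1L)
  m <- mean_ccf_epochs(epochs$resp, epochs$neural, epochs$fs, max_lag)
  i <- which.max(abs(m))
  structure(list(lags_s = (-max_lag:max_lag) / epochs$fs, mean_ccf = m,
                 max_abs = abs(m[i]), lag_at_max_s = (i - max_lag - 1L) / epochs$fs,
                 polarity = if (m[i] < 0) -1 else 1,
                 n_epochs = K, tau = tau),
            class = "ccf_result")
}

#' @export
print.ccf_result <- function(x, ...) {
  cat(sprintf("<ccf_result> max |mean CCF| %.3f at lag %+.3f s (%d epochs, polarity %+d)\n",
              x$max_abs, x$lag_at_max_s, x$n_epochs, x$polarity))
  if (!is.null(x$null_threshold)) {
    cat(sprintf("  null threshold %.3f (%d permutations)  ->  %s\n",
                x$null_threshold, x$n_perm, if (x$passes) "PASS" else "fail"))
  }
  invisible(x)
}

#' Cross-correlation screen with a permutation null
#'
#' Recomputes the epoch-averaged CCF `n_perm` times after replacing every
#' neural epoch with a randomly placed neural segment of equal length drawn
#' outside a `margin_s` exclusion zone around that epoch's original window;
#' the respiration epochs stay in place. The screen threshold is the
#' `1 - alpha` percentile of the permutation maxima. Channel polarity is
#' flipped (reported as `polarity = -1`) when the extreme of the real mean
#' CCF is negative, absorbing the arbitrary sign of bipolar derivations.
#'
#' @param neural Band-passed, z-scored neural [recording()] (the same one
#'   the epochs were cut from).
#' @param epochs A [epoch_on_respiration_peaks()] result.
#' @param tau Respiration period in seconds.
#' @param n_perm Number of permutations (default 500).
#' @param margin_s Exclusion margin around each original window (default 10).
#' @param alpha Significance level (default 0.01).
#' @param seed Integer seed.
#' @return A `"ccf_result"` augmented with `null_threshold`, `null_max`,
#'   `n_perm`, `passes`.
#' @export
ccf_permutation_null <- function(neural, epochs, tau, n_perm = 500,
                                 margin_s = 10, alpha = 0.01, seed = 1) {
  assert_recording(neural)
  real <- mean_ccf(epochs, tau)
  fs <- epochs$fs
  x <- neural$samples
  n <- length(x)
  L <- nrow(epochs$neural)
  max_lag <- min(floor(tau / 2 * fs), L - 1L)
  marg <- round(margin_s * fs)
  K <- ncol(epochs$neural)

  # legal start positions per epoch: the segment [s, s+L-1] must avoid
  # [start - marg, end + marg] around the original window
  allowed <- lapply(seq_len(K), function(k) {
    a <- epochs$starts[k] - marg          # forbidden zone begins
    b <- epochs$starts[k] + L - 1L + marg # forbidden zone ends
    left <- if (a - L >= 1L) c(1L, a - L) else NULL
    right <- if (b + 1L <= n - L + 1L) c(b + 1L, n - L + 1L) else NULL
    rbind(left, right)
  })
  if (any(vapply(allowed, is.null, logical(1)))) {
    stop_rs("margin too large: no legal sampling region for some epochs",
            "rs_margin_too_large")
  }

  null_max <- with_seed(substream_seed(seed, "ccf_permutation"), {
    vapply(seq_len(n_perm), function(p) {
      starts <- vapply(allowed, function(iv) {
        tot <- sum(iv[, 2L] - iv[, 1L] + 1)
        u <- sample.int(tot, 1L)
        for (r in seq_len(nrow(iv))) {
          w <- iv[r, 2L] - iv[r, 1L] + 1
          if (u <= w) return(as.numeric(iv[r, 1L] + u - 1))
          u <- u - w
        }
        as.numeric(iv[1L, 1L])
      }, numeric(1))
      neuM <- vapply(starts, function(s) x[s:(s + L - 1L)], numeric(L))
      max(abs(mean_ccf_epochs(epochs$resp, neuM, fs, max_lag)))
    }, numeric(1))
  })
  real$null_threshold <- percentile(null_max, 1 - alpha)
  real$null_max <- null_max
  real$n_perm <- n_perm
  real$alpha <- alpha
  real$passes <- real$max_abs > real$null_threshold
  real
}

# Per-cycle monotonicity fractions for a sample vector, given rising and
# falling windows as sample index pairs. Ties (zero differences) count as
# inconsistent in both directions.
pmi_cycles <- function(x, rise_win, fall_win) {
  d <- diff(x)
  P <- c(0, cumsum(d > 0))
  N <- c(0, cumsum(d < 0))
  rise <- (P[rise_win[, 2L]] - P[rise_win[, 1L]]) / (rise_win[, 2L] - rise_win[, 1L])
  fall <- (N[fall_win[, 2L]] - N[fall_win[, 1L]]) / (fall_win[, 2L] - fall_win[, 1L])
  cbind(rise = rise, fall = fall)
}

#' Phase monotonicity index with a circular-shift null
#'
#' For every respiration cycle, the neural signal is split at the
#' respiration extrema into a rising phase (trough to peak) and a falling
#' phase (peak to next trough). The cycle's rising consistency is the
#' fraction of consecutive neural sample differences that are positive; the
#' falling consistency the fraction that are negative; the cycle PMI is
#' their unweighted mean, and the channel PMI the median over cycles. A
#' perfectly monotone channel scores 1; an unrelated signal about 0.5. The
#' null circularly shifts the neural signal by at least `min_shift_s`
#' (preserving its autocorrelation while destroying alignment) and the
#' channel passes when its PMI exceeds the `1 - alpha` percentile of the
#' shifted statistics.
#'
#' @param neural A band-passed, z-scored neural [recording()].
#' @param resp_extrema An [detect_extrema()] result for the respiration
#'   trace (alternating troughs and peaks) covering >= 10 complete cycles.
#' @param n_perm Number of circular shifts (default 500).
#' @param min_shift_s Minimum shift in seconds (default 10).
#' @param alpha Significance level (default 0.01).
#' @param seed Integer seed.
#' @return An object of class `"pmi_screen"`: `per_cycle_pmi`,
#'   `rising_consistency`, `falling_consistency`, `channel_pmi`,
#'   `null_threshold`, `null_pmi`, `passes`.
#' @export
phase_monotonicity_index <- function(neural, resp_extrema, n_perm = 500,
                                     min_shift_s = 10, alpha = 0.01, seed = 1) {
  assert_recording(neural)
  if (!inherits(resp_extrema, "extrema")) stop_invalid("resp_extrema must be an extrema object")
  x <- neural$samples
  n <- length(x)
  fs <- neural$fs
  cyc <- extrema_cycles(resp_extrema)
  if (nrow(cyc) < 10L) {
    stop_rs("need >= 10 complete respiration cycles for the PMI", "rs_insufficient_data")
  }
  idx <- function(t) pmin(pmax(round(t * fs) + 1L, 1L), n)
  rise_win <- cbind(idx(cyc$trough_t), idx(cyc$peak_t))
  fall_win <- cbind(idx(cyc$peak_t), idx(cyc$end_t))
  ok <- (rise_win[, 2L] - rise_win[, 1L] + 1L) >= 3L &
    (fall_win[, 2L] - fall_win[, 1L] + 1L) >= 3L
  if (!any(ok)) stop_rs("all cycles shorter than 3 samples per phase", "rs_insufficient_data")
  rise_win <- rise_win[ok, , drop = FALSE]
  fall_win <- fall_win[ok, , drop = FALSE]

  channel_pmi_of <- function(v) {
    fr <- pmi_cycles(v, rise_win, fall_win)
    stats::median((fr[, 1L] + fr[, 2L]) / 2)
  }
  fr <- pmi_cycles(x, rise_win, fall_win)
  per_cycle <- (fr[, 1L] + fr[, 2L]) / 2
  channel_pmi <- stats::median(per_cycle)

  min_shift <- round(min_shift_s * fs)
  if (2L * min_shift >= n) {
    stop_rs("recording too short for the minimum circular shift", "rs_insufficient_data")
  }
  null_pmi <- with_seed(substream_seed(seed, "pmi_shift"), {
    shifts <- sample(min_shift:(n - min_shift), n_perm, replace = TRUE)
    vapply(shifts, function(m) {
      channel_pmi_of(x[c((m + 1L):n, 1L:m)])
    }, numeric(1))
  })
  threshold <- percentile(null_pmi, 1 - alpha)
  structure(list(subject_id = neural$subject_id, channel_id = neural$channel_id,
                 per_cycle_pmi = unname(per_cycle),
                 rising_consistency = unname(fr[, 1L]),
                 falling_consistency = unname(fr[, 2L]),
                 channel_pmi = channel_pmi,
                 null_threshold = threshold, null_pmi = null_pmi,
                 n_cycles = nrow(rise_win), n_perm = n_perm, alpha = alpha,
                 passes = channel_pmi > threshold),
            class = "pmi_screen")
}

#' @export
print.pmi_screen <- function(x, ...) {
  cat(sprintf("<pmi_screen> %s/%s: channel PMI %.3f over %d cycles vs null threshold %.3f  ->  %s\n",
              x$subject_id, x$channel_id, x$channel_pmi, x$n_cycles,
              x$null_threshold, if (x$passes) "PASS" else "fail"))
  invisible(x)
}
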
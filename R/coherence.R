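# Surrogate-based coherence screening of respiration-locked channels.

# Phase randomization of a real vector: uniform random phases with Hermitian
# symmetry preserved, amplitude spectrum untouched. Assumes an active RNG.
phase_randomize <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  half <- seq(2L, floor((n - 1) / 2) + 1L)
  ph <- stats::runif(length(half), 0, 2 * pi)
  X[half] <- Mod(X[half]) * exp(1i * ph)
  X[n + 2L - half] <- Conj(X[half])
  # DC (and Nyquist for even n) stay untouched so the output is real
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Phase-randomized surrogate of a recording
#'
#' Transforms the signal to the frequency domain, replaces all phases with
#' uniform random draws (Hermitian symmetry preserved), and inverts. The
#' surrogate has the identical amplitude spectrum — hence identical power
#' and autocorrelation — but no waveform timing, which is exactly what the
#' coherence null requires.
#'
#' @param rec A [recording()].
#' @param seed Integer seed.
#' @return A surrogate [recording()].
#' @export
phase_randomized_surrogate <- function(rec, seed) {
  assert_recording(rec)
  rec_update(rec, with_seed(seed, phase_randomize(rec$samples)))
}

#' Coherence screen of one neural channel against respiration
#'
#' A channel passes when (i) its maximum coherence with respiration inside
#' the breathing band exceeds the 99th percentile of the max-in-band
#' coherence of `n_surrogates` phase-randomized neural surrogates, and
#' (ii) its own power spectrum contains a spectral-parameterization peak
#' centered inside the same band (coherence driven purely by harmonics of a
#' nonsinusoidal breath, with no fundamental neural peak, fails this second
#' criterion).
#'
#' @param neural,resp [recording()]s with equal fs and length.
#' @param band A [find_breathing_band()] result for this participant.
#' @param n_surrogates Number of phase-randomized surrogates (default 1000).
#' @param alpha Significance level; the threshold is the `1 - alpha`
#'   percentile of the surrogate distribution (default 0.01).
#' @param seed Integer seed for the surrogate draws.
#' @param seg_s,overlap_s Coherence segmentation (see [coherence()]).
#' @return An object of class `"coherence_screen"`: the real coherence
#'   spectrum plus `max_coh_in_band`, `surrogate_threshold`,
#'   `has_psd_peak_in_band`, `passes`, and the surrogate maxima.
#' @export
coherence_screen <- function(neural, resp, band, n_surrogates = 1000,
                             alpha = 0.01, seed = 1, seg_s = 32,
                             overlap_s = 27) {
  assert_recording(neural); assert_recording(resp)
  if (!inherits(band, "breathing_band")) stop_invalid("band must be a breathing_band")
  if (neural$fs != resp$fs || length(neural$samples) != length(resp$samples)) {
    stop_invalid("neural and resp must share sampling rate and length")
  }
  fs <- neural$fs
  nper <- round(seg_s * fs)
  step <- nper - round(overlap_s * fs)
  if (length(resp$samples) < nper + step) {
    stop_invalid("need at least 2 coherence segments")
  }
  fr <- segment_ffts(resp$samples, fs, nper, step)
  in_band <- fr$freq >= band$band_lo - 1e-9 & fr$freq <= band$band_hi + 1e-9
  if (!any(in_band)) stop_invalid("breathing band lies outside the coherence grid")

  fx <- segment_ffts(neural$samples, fs, nper, step)
  coh <- coherence_from_ffts(fx$F, fr$F)
  max_real <- max(coh[in_band])

  Fr_band <- fr$F[in_band, , drop = FALSE]
  Syy_band <- rowMeans(Mod(Fr_band)^2)
  surr_max <- with_seed(substream_seed(seed, "coherence_surrogates"), {
    vapply(seq_len(n_surrogates), function(i) {
      xs <- phase_randomize(neural$samples)
      fsur <- segment_ffts(xs, fs, nper, step)
      Fb <- fsur$F[in_band, , drop = FALSE]
      c_band <- Mod(rowMeans(Fb * Conj(Fr_band)))^2 /
        (rowMeans(Mod(Fb)^2) * Syy_band)
      max(pmin(c_band, 1))
    }, numeric(1))
  })
  threshold <- percentile(surr_max, 1 - alpha)

  npsd <- welch_psd(neural)
  sm <- tryCatch(spectrum_model(npsd), error = function(e) NULL)
  has_peak <- !is.null(sm) && nrow(sm$peaks) > 0 &&
    any(sm$peaks$center_hz >= band$band_lo & sm$peaks$center_hz <= band$band_hi)

  structure(list(subject_id = neural$subject_id, channel_id = neural$channel_id,
                 freq = fx$freq, coh = coh, band = band,
                 max_coh_in_band = max_real,
                 surrogate_threshold = threshold,
                 surrogate_max = surr_max,
                 has_psd_peak_in_band = has_peak,
                 neural_spectrum = sm,
                 passes = max_real > threshold && has_peak,
                 n_surrogates = n_surrogates, alpha = alpha),
            class = "coherence_screen")
}

#' @export
print.coherence_screen <- function(x, ...) {
  cat(sprintf("<coherence_screen> %s/%s: max C in band %.3f vs threshold %.3f (p<%g, %d surrogates)\n",
              x$subject_id, x$channel_id, x$max_coh_in_band,
              x$surrogate_threshold, x$alpha, x$n_surrogates))
  cat(sprintf("  PSD peak in [%.3f, %.3f] Hz: %s  ->  %s\n",
              x$band$band_lo, x$band$band_hi,
              if (x$has_psd_peak_in_band) "yes" else "no",
              if (x$passes) "PASS" else "fail"))
  invisible(x)
}
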
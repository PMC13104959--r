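# Welch spectral estimation and spectral parameterization.

# Segment a signal, detrend (constant), taper (periodic Hann), and FFT.
# Returns the one-sided complex spectra (bins x segments) plus the density
# scale factor such that rowMeans(|F|^2) * scale, with interior bins
# doubled, is a one-sided PSD in units^2/Hz.
segment_ffts <- function(x, fs, nper, step) {
  n <- length(x)
  starts <- seq(1L, n - nper + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nper) - 1L) / nper)
  seg <- vapply(starts, function(s) {
    v <- x[s:(s + nper - 1L)]
    (v - mean(v)) * w
  }, numeric(nper))
  Fm <- stats::mvfft(seg)
  nb <- floor(nper / 2) + 1L
  list(F = Fm[seq_len(nb), , drop = FALSE],
       freq = (seq_len(nb) - 1L) * fs / nper,
       scale = 1 / (fs * sum(w^2)),
       nper = nper, n_segments = length(starts))
}

one_sided_psd <- function(sf) {
  p <- rowMeans(Mod(sf$F)^2) * sf$scale
  nb <- length(p)
  dbl <- 2:(nb - if (sf$nper %% 2L == 0L) 1L else 0L)
  p[dbl] <- 2 * p[dbl]
  p
}

#' Welch power spectral density
#'
#' Hann-tapered, constant-detrended, averaged periodogram. The default 40 s
#' window with 20 s overlap gives a frequency grid spacing of 0.025 Hz,
#' fine enough to resolve the slow respiration rhythm.
#'
#' @param rec A [recording()] at least one window long.
#' @param window_s Segment length in seconds (default 40).
#' @param overlap_s Segment overlap in seconds (default 20).
#' @return An object of class `"welch_psd"`: list with `freq` (Hz), `psd`
#'   (power density, units^2/Hz), `fs`, `window_s`, `n_segments`.
#' @export
welch_psd <- function(rec, window_s = 40, overlap_s = 20) {
  assert_recording(rec)
  nper <- round(window_s * rec$fs)
  if (length(rec$samples) < nper) {
    stop_invalid("recording shorter than one Welch window")
  }
  if (overlap_s >= window_s) stop_invalid("overlap must be shorter than the window")
  step <- nper - round(overlap_s * rec$fs)
  sf <- segment_ffts(rec$samples, rec$fs, nper, step)
  structure(list(freq = sf$freq, psd = one_sided_psd(sf), fs = rec$fs,
                 window_s = window_s, n_segments = sf$n_segments),
            class = "welch_psd")
}

#' @export
print.welch_psd <- function(x, ...) {
  cat(sprintf("<welch_psd> %d bins, df = %g Hz, %d segments\n",
              length(x$freq), x$freq[2] - x$freq[1], x$n_segments))
  invisible(x)
}

#' Magnitude-squared coherence between two recordings
#'
#' `C(f) = |Pxy(f)|^2 / (Pxx(f) Pyy(f))` on Welch cross- and auto-spectra.
#' The default 32 s segments with 27 s overlap give a frequency resolution
#' of 1/32 = 0.03125 Hz. Coherence of a single segment is identically 1, so
#' at least two segments are required.
#'
#' @param x,y [recording()]s with equal sampling rate and length.
#' @param seg_s Segment length in seconds (default 32).
#' @param overlap_s Segment overlap in seconds (default 27).
#' @return An object of class `"coherence_result"`: `freq` (Hz), `coh`
#'   (values in `[0, 1]`), `n_segments`.
#' @export
coherence <- function(x, y, seg_s = 32, overlap_s = 27) {
  assert_recording(x); assert_recording(y)
  if (x$fs != y$fs || length(x$samples) != length(y$samples)) {
    stop_invalid("x and y must share sampling rate and length")
  }
  nper <- round(seg_s * x$fs)
  step <- nper - round(overlap_s * x$fs)
  if (step < 1L) stop_invalid("overlap must be shorter than the segment")
  if (length(x$samples) < nper + step) {
    stop_invalid("need at least 2 segments for coherence")
  }
  fx <- segment_ffts(x$samples, x$fs, nper, step)
  fy <- segment_ffts(y$samples, y$fs, nper, step)
  coh <- coherence_from_ffts(fx$F, fy$F)
  structure(list(freq = fx$freq, coh = coh, n_segments = fx$n_segments),
            class = "coherence_result")
}

coherence_from_ffts <- function(Fx, Fy) {
  Sxy <- rowMeans(Fx * Conj(Fy))
  Sxx <- rowMeans(Mod(Fx)^2)
  Syy <- rowMeans(Mod(Fy)^2)
  pmin(pmax(Mod(Sxy)^2 / (Sxx * Syy), 0), 1)
}

#' @export
print.coherence_result <- function(x, ...) {
  cat(sprintf("<coherence> %d bins, df = %g Hz, %d segments, max %.3f @ %.3f Hz\n",
              length(x$freq), x$freq[2] - x$freq[1], x$n_segments,
              max(x$coh), x$freq[which.max(x$coh)]))
  invisible(x)
}

# --- spectral parameterization ---------------------------------------------

gauss_shape <- function(f, center, height, sd) height * exp(-(f - center)^2 / (2 * sd^2))

# Aperiodic fit (offset - exponent * log10 f) robust to periodic peaks:
# ordinary fit, then refit on the points that do not bulge above it.
aperiodic_fit <- function(lf, lp) {
  fit <- stats::lm.fit(cbind(1, lf), lp)$coefficients
  resid <- lp - (fit[1L] + fit[2L] * lf)
  thr <- percentile(pmax(resid, 0), 0.025)
  keep <- resid <= thr + 1e-12
  if (sum(keep) >= 5L) fit <- stats::lm.fit(cbind(1, lf[keep]), lp[keep])$coefficients
  c(offset = unname(fit[1L]), slope = unname(fit[2L]))
}

#' Parameterize a power spectrum into aperiodic and periodic components
#'
#' Models `log10 PSD` as an aperiodic `offset - exponent * log10(f)`
#' component plus Gaussian periodic peaks, in the spirit of spectral
#' parameterization practice: a robust aperiodic fit, iterative extraction
#' of up to `max_n_peaks` Gaussians from the flattened spectrum (largest
#' first, stopping when the next candidate falls below both the relative
#' and absolute height thresholds), then an aperiodic refit on the
#' peak-subtracted spectrum.
#'
#' @param x A `"welch_psd"` object, or a numeric frequency vector (then
#'   supply `power`).
#' @param power Power values when `x` is a frequency vector.
#' @param freq_range Fit range in Hz (default 0.05 to 2).
#' @param max_n_peaks Maximum number of Gaussian peaks (default 4).
#' @param peak_width_limits Allowed peak FWHM range in Hz (default 0.02-0.5).
#' @param min_peak_height Absolute height floor in log10 power units (default 0.55,
#'   calibrated so a pure aperiodic Welch spectrum at the default
#'   segmentation almost never yields a spurious peak).
#' @param peak_threshold Relative height floor, in SDs of the flattened
#'   spectrum.
#' @return An object of class `"spectrum_model"`: `offset`, `exponent`
#'   (positive for 1/f-like decay), `peaks` (data frame: `center_hz`,
#'   `height_log10`, `fwhm_hz`), `freq`, `power_log10`, `fitted_log10`,
#'   `r_squared`.
#' @export
spectrum_model <- function(x, power = NULL, freq_range = c(0.05, 2),
                           max_n_peaks = 4, peak_width_limits = c(0.02, 0.5),
                           min_peak_height = 0.55, peak_threshold = 2) {
  if (inherits(x, "welch_psd")) { freq <- x$freq; power <- x$psd } else freq <- x
  keep <- freq >= freq_range[1L] & freq <= freq_range[2L] & power > 0
  if (sum(keep) < 10L) stop_invalid("too few frequency bins in the fit range")
  f <- freq[keep]
  lf <- log10(f)
  lp <- log10(power[keep])

  ap <- aperiodic_fit(lf, lp)
  flat <- lp - (ap[1L] + ap[2L] * lf)
  sd_lim <- peak_width_limits / (2 * sqrt(2 * log(2)))

  peaks <- list()
  resid <- flat
  for (it in seq_len(max_n_peaks)) {
    i <- which.max(resid)
    h <- resid[i]
    if (h < max(peak_threshold * stats::sd(resid), min_peak_height)) break
    # local fit window: walk outward while the flattened spectrum keeps
    # falling and stays above half height, so neighboring peaks (e.g.
    # harmonics of a nonsinusoidal rhythm) are not swallowed
    l <- i
    while (l > 1L && resid[l - 1L] <= resid[l] && resid[l - 1L] >= h / 2) l <- l - 1L
    r <- i
    nr <- length(resid)
    while (r < nr && resid[r + 1L] <= resid[r] && resid[r + 1L] >= h / 2) r <- r + 1L
    win <- l:r
    sd0 <- min(max((f[r] - f[l] + 1e-3) / 2.355, sd_lim[1L]), sd_lim[2L])
    par0 <- c(f[i], h, sd0)
    if (length(win) >= 4L) {
      obj <- function(p) sum((resid[win] - gauss_shape(f[win], p[1L], p[2L], p[3L]))^2)
      opt <- tryCatch(
        stats::optim(par0, obj, method = "L-BFGS-B",
                     lower = c(f[l], 0.5 * h, sd_lim[1L]),
                     upper = c(f[r], 1.5 * h, sd_lim[2L])),
        error = function(e) list(par = par0))
      peaks[[it]] <- opt$par
    } else {
      peaks[[it]] <- par0
    }
    pk_it <- peaks[[it]]
    resid <- resid - gauss_shape(f, pk_it[1L], pk_it[2L], pk_it[3L])
  }

  peak_sum <- flat - resid
  ap <- stats::lm.fit(cbind(1, lf), lp - peak_sum)$coefficients
  fitted <- ap[1L] + ap[2L] * lf + peak_sum
  pk <- if (length(peaks)) {
    m <- do.call(rbind, peaks)
    data.frame(center_hz = m[, 1L], height_log10 = m[, 2L],
               fwhm_hz = m[, 3L] * 2.355)[order(-m[, 2L]), , drop = FALSE]
  } else {
    data.frame(center_hz = numeric(0), height_log10 = numeric(0),
               fwhm_hz = numeric(0))
  }
  structure(list(offset = unname(ap[1L]), exponent = -unname(ap[2L]),
                 peaks = pk, freq = f, power_log10 = lp,
                 fitted_log10 = unname(fitted),
                 r_squared = 1 - stats::var(lp - fitted) / stats::var(lp)),
            class = "spectrum_model")
}

#' @export
print.spectrum_model <- function(x, ...) {
  cat(sprintf("<spectrum_model> exponent %.2f, offset %.2f, R2 %.3f, %d peak(s)\n",
              x$exponent, x$offset, x$r_squared, nrow(x$peaks)))
  if (nrow(x$peaks)) {
    for (i in seq_len(nrow(x$peaks))) {
      cat(sprintf("  peak %.3f Hz, height %.2f, FWHM %.3f Hz\n",
                  x$peaks$center_hz[i], x$peaks$height_log10[i], x$peaks$fwhm_hz[i]))
    }
  }
  invisible(x)
}

#' Identify the breathing frequency band from a respiration spectrum
#'
#' Parameterizes the respiration PSD into aperiodic and periodic components
#' and takes the center frequency of the highest-amplitude periodic peak
#' (within 0.05-1 Hz) as the breathing frequency. The analysis band is the
#' fixed 0.2 Hz bandwidth centered there, and tau = 1/f_resp is one
#' respiration period.
#'
#' @param x A respiration [recording()] (a Welch PSD is computed with
#'   [welch_psd()] defaults) or a precomputed `"welch_psd"`.
#' @param f_limits Allowed breathing-frequency range, default `c(0.05, 1)`.
#' @param ... Passed to [spectrum_model()].
#' @return An object of class `"breathing_band"`: `f_resp`, `band_lo`,
#'   `band_hi` (`f_resp` +/- 0.1 Hz), `tau` (s), and the underlying
#'   `spectrum_model`.
#' @export
find_breathing_band <- function(x, f_limits = c(0.05, 1), ...) {
  psd <- if (is_recording(x)) {
    assert_recording(x, modalities = c("airflow", "belt"))
    welch_psd(x)
  } else x
  sm <- spectrum_model(psd, ...)
  pk <- sm$peaks[sm$peaks$center_hz >= f_limits[1L] &
                   sm$peaks$center_hz <= f_limits[2L], , drop = FALSE]
  if (!nrow(pk)) {
    stop_rs(sprintf("no periodic breathing peak found in %.2f-%.2f Hz; participant excluded",
                    f_limits[1L], f_limits[2L]), "rs_no_breathing_peak")
  }
  f_resp <- pk$center_hz[1L]   # peaks are sorted by height
  structure(list(f_resp = f_resp, band_lo = f_resp - 0.1,
                 band_hi = f_resp + 0.1, tau = 1 / f_resp,
                 spectrum = sm),
            class = "breathing_band")
}

#' @export
print.breathing_band <- function(x, ...) {
  cat(sprintf("<breathing_band> f_resp %.3f Hz, band [%.3f, %.3f] Hz, tau %.2f s\n",
              x$f_resp, x$band_lo, x$band_hi, x$tau))
  invisible(x)
}
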
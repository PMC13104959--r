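# Extrema detection, artifact rejection, greedy matching, and the waveform
# shape features.

test_that("a 0.25 Hz sine yields 15 alternating peak/trough pairs in 60 s", {
  r <- sine_recording(0.25, 60, 500)
  ext <- detect_extrema(r, base_height = 0, relative_amplitude_frac = 0.3)
  expect_equal(sum(ext$kinds == "peak"), 15)
  expect_equal(sum(ext$kinds == "trough"), 15)
  expect_alternating(ext)
  expect_error(detect_extrema(recording(rep(1, 5000), 100, "neural")),
               class = "rs_empty_extrema")
})

test_that("small fast ripple does not displace the detected extrema", {
  fs <- 500
  t <- (0:(60 * fs - 1)) / fs
  clean <- sine_recording(0.25, 60, fs)
  noisy <- recording(clean$samples + 0.05 * sin(2 * pi * 5 * t), fs, "neural")
  e1 <- detect_extrema(clean, base_height = 0)
  e2 <- detect_extrema(noisy, base_height = 0)
  expect_equal(length(e1$idx), length(e2$idx))
  expect_identical(e1$kinds, e2$kinds)
  # the winning candidate can sit on a ripple crest, but never farther than
  # half a ripple period from the clean extremum
  expect_true(all(abs(e1$idx - e2$idx) <= 0.1 * fs + 1))
})

test_that("the relative amplitude stage removes runt peaks", {
  fs <- 100
  t <- (0:(120 * fs - 1)) / fs
  # strong breathing-rate rhythm plus tiny bumps between cycles
  x <- sin(2 * pi * 0.25 * t) + 0.05 * sin(2 * pi * 0.5 * t + 1)
  ext <- detect_extrema(recording(x, fs, "neural"), base_height = -2,
                        min_distance_factor = 0.5, relative_amplitude_frac = 0.3)
  # without the relative threshold the 0.5 Hz modulation creates extra
  # candidates below base height -2; surviving peaks must be near amplitude 1
  expect_true(all(ext$values[ext$kinds == "peak"] > 0.5))
  expect_alternating(ext)
})

test_that("MAD artifact rejection drops exactly the planted outlier", {
  fs <- 100
  t_cycle <- seq(0, 4, by = 1 / fs)[-1]
  cycle <- sin(2 * pi * t_cycle / 4 - pi / 2)
  # one cycle with a grossly inflated peak; troughs stay normal so only the
  # outlier's own trough-to-trough window is abnormal
  big_cycle <- pmin(cycle, 0) + 50 * pmax(cycle, 0)
  x <- c(rep(cycle, 10), big_cycle, rep(cycle, 10))
  r <- recording(x, fs, "neural")
  ext <- detect_extrema(r, base_height = NULL)
  n_peaks_before <- sum(ext$kinds == "peak")
  kept <- reject_artifact_cycles(ext, r, mad_k = 5)
  expect_equal(sum(kept$kinds == "peak"), n_peaks_before - 1)
  expect_lt(max(kept$values), 2)   # the amplitude-50 peak is gone
  expect_alternating(kept)
})

test_that("homogeneous cycles survive rejection even with MAD = 0", {
  fs <- 100
  cycle <- sin(2 * pi * seq(0, 4, by = 1 / fs)[-1] / 4 - pi / 2)
  r <- recording(rep(cycle, 12), fs, "neural")
  ext <- detect_extrema(r)
  kept <- reject_artifact_cycles(ext, r, mad_k = 5)
  expect_equal(length(kept$idx), length(ext$idx))
})

test_that("rejection count is non-increasing in the MAD multiplier", {
  sim <- simulate_respiration(duration_s = 200, fs = 100, seed = 17)
  z <- zscore_recording(bandpass_for_timedomain(sim$recording))
  ext <- detect_extrema(z)
  n_kept <- vapply(c(1, 2, 5, 10), function(k) {
    length(reject_artifact_cycles(ext, z, mad_k = k)$idx)
  }, numeric(1))
  expect_true(all(diff(n_kept) >= 0))
})

test_that("greedy matching reproduces the documented examples", {
  mk <- function(peaks) {
    times <- as.vector(rbind(peaks - 1.5, peaks, peaks + 1.5))
    extrema_from_times(times, rep(c("trough", "peak", "trough"), length(peaks)))
  }
  res <- match_peaks(mk(c(10, 20, 30)), mk(c(10.4, 20.3, 30.1)), tau = 4)
  expect_equal(nrow(res), 3)
  expect_equal(res$delay_s, c(0.4, 0.3, 0.1))
  # a neural peak more than tau away is never matched
  expect_equal(nrow(match_peaks(mk(10), mk(10 + 4.5), tau = 4)), 0)
  # greedy order: the first respiration peak claims the shared neural peak
  res2 <- match_peaks(mk(c(10, 11)), mk(10.6), tau = 4)
  expect_equal(nrow(res2), 1)
  expect_equal(res2$resp_peak_t, 10)
  expect_equal(res2$delay_s, 0.6, tolerance = 1e-12)
})

test_that("greedy matching agrees with an independent oracle on random instances", {
  set.seed(123)
  mk <- function(peaks) {
    times <- as.vector(rbind(peaks - 0.4, peaks, peaks + 0.4))
    extrema_from_times(times, rep(c("trough", "peak", "trough"), length(peaks)))
  }
  for (case in 1:100) {
    nr <- sample(1:5, 1); nn <- sample(1:5, 1)
    rp <- sort(runif(nr, 0, 30)); np <- sort(runif(nn, 0, 30))
    # keep peaks separated so the synthetic troughs stay alternating
    rp <- rp[c(TRUE, diff(rp) > 1)]; np <- np[c(TRUE, diff(np) > 1)]
    tau <- runif(1, 1, 5)
    got <- match_peaks(mk(rp), mk(np), tau = tau)
    want <- greedy_match_oracle(rp, np, tau)
    expect_equal(nrow(got), if (is.null(want)) 0 else nrow(want))
    if (!is.null(want)) {
      expect_equal(got$resp_peak_t, rp[want[, 1]])
      expect_equal(got$neural_peak_t, np[want[, 2]])
      expect_equal(got$delay_s, want[, 3], tolerance = 1e-12)
    }
  }
})

test_that("matching is injective and cycles are correctly ordered", {
  ds <- generate_dataset(list(duration_s = 200, fs = 100, beta = 0.3), seed = 19)
  rz <- zscore_recording(bandpass_for_timedomain(
    lowpass_respiration(ds$recordings[["s01/resp_airflow"]])))
  nz <- zscore_recording(bandpass_for_timedomain(ds$recordings[["s01/lfp01"]]))
  pairs <- match_peaks(detect_extrema(rz), detect_extrema(nz), tau = 4)
  expect_gt(nrow(pairs), 20)
  expect_false(any(duplicated(pairs$neural_peak_t)))
  expect_true(all(pairs$resp_trough_t < pairs$resp_peak_t &
                    pairs$resp_peak_t < pairs$resp_end_t))
  expect_true(all(pairs$neural_trough_t < pairs$neural_peak_t &
                    pairs$neural_peak_t < pairs$neural_end_t))
  expect_true(all(abs(pairs$delay_s) < 4))
})

test_that("waveform features match analytic values on a pure sine cycle", {
  fs <- 500
  r <- sine_recording(0.25, 60, fs)
  ext <- detect_extrema(r, base_height = 0)
  pairs <- match_peaks(ext, ext, tau = 4)
  f <- cycle_features(pairs, r, r)
  mid <- 5   # interior cycle, away from edges
  expect_equal(f$resp_amplitude[mid], 2, tolerance = 1e-3)
  expect_equal(f$resp_rise_decay_symmetry[mid], 0.5, tolerance = 1e-2)
  # odd symmetry: area above the median around the peak equals the area
  # below it around the trough
  expect_equal(f$resp_peak_auc[mid], f$resp_trough_auc[mid], tolerance = 1e-2)
  # sharpness oracle: numerical quadrature of the definition on the
  # analytic sine. The window holds the samples within half the
  # peak-to-trough amplitude (2) of the extremum, i.e. sin(wt) >= 0 for the
  # peak: |t| <= 1 s; sharpness = mean |dx/dt| there / amplitude
  w <- 2 * pi * 0.25
  tt <- seq(-1, 1, by = 1 / fs)
  expected <- mean(abs(w * cos(w * tt))) / 2
  expect_equal(f$resp_peak_sharpness[mid], expected, tolerance = 0.02)
  expect_equal(f$resp_trough_sharpness[mid], expected, tolerance = 0.02)
})

test_that("degenerate cycles are skipped with a warning", {
  fs <- 100
  r <- recording(rep(sin(2 * pi * seq(0, 4, by = 1 / fs)[-1] / 4), 10), fs, "neural")
  pairs <- data.frame(resp_trough_t = 5, resp_peak_t = 6, resp_end_t = 7,
                      neural_trough_t = 5, neural_peak_t = 6, neural_end_t = 7,
                      delay_s = 0)
  class(pairs) <- c("matched_cycles", "data.frame")
  # peak time chosen where the signal is NOT above both troughs
  expect_warning(out <- cycle_features(pairs, r, r), "degenerate")
  expect_equal(nrow(out), 0)
})

test_that("feature outlier exclusion is one-sided and row-wise", {
  base <- data.frame(subject_id = "s01", channel_id = "ch1", modality = "airflow",
                     delay_s = 0)
  cols <- c(paste0("resp_", respshape:::shape_feature_names),
            paste0("neural_", respshape:::shape_feature_names))
  mk <- function(n, val) {
    df <- base[rep(1, n), ]
    for (cl in cols) df[[cl]] <- val
    df
  }
  # homogeneous: nothing dropped (zero spread)
  hom <- mk(30, 1)
  expect_equal(nrow(exclude_feature_outliers(hom)), 30)
  # 99 rows with bounded jitter and one wild rise time: only that row is
  # dropped (uniform jitter never reaches median + 3 SD on its own)
  tb <- mk(100, 1)
  set.seed(4)
  for (cl in cols) tb[[cl]] <- 1 + runif(100, -0.01, 0.01)
  tb$resp_rise_time_s[100] <- 100
  out <- exclude_feature_outliers(tb)
  expect_equal(nrow(out), 99)
  # values far BELOW the median are never excluded
  tb2 <- mk(100, 1)
  for (cl in cols) tb2[[cl]] <- 1 + runif(100, -0.01, 0.01)
  tb2$resp_rise_time_s[100] <- -100
  expect_equal(nrow(exclude_feature_outliers(tb2)), 100)
  # amplitude is not filtered
  tb3 <- mk(100, 1)
  for (cl in cols) tb3[[cl]] <- 1 + runif(100, -0.01, 0.01)
  tb3$resp_amplitude[100] <- 1000
  expect_equal(nrow(exclude_feature_outliers(tb3)), 100)
})

test_that("noiseless extraction recovers generator truth within 2 samples", {
  fs <- 500
  sim <- simulate_respiration(duration_s = 120, fs = fs, seed = 23)
  ext <- detect_extrema(sim$recording)
  cyc_pk <- ext$times[ext$kinds == "peak"]
  # align detected cycles to truth rows by nearest peak
  for (i in seq_len(nrow(sim$truth))) {
    j <- which.min(abs(cyc_pk - sim$truth$peak_t[i]))
    expect_lt(abs(cyc_pk[j] - sim$truth$peak_t[i]), 2.5 / fs)
  }
})
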
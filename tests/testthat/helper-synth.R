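# Shared fixtures, built in code at test time.

sine_recording <- function(freq_hz = 0.25, duration_s = 60, fs = 500,
                           amplitude = 1, modality = "neural", phase = 0) {
  t <- (0:(round(duration_s * fs) - 1)) / fs
  recording(amplitude * sin(2 * pi * freq_hz * t + phase), fs, modality)
}

# A feature-level synthetic table with a known standardized within-subject
# slope, for coupling-model tests that do not need rendered signals.
feature_table <- function(beta, n_subjects = 4, n_channels = 2, n_cycles = 60,
                          seed = 1, noise_sd = 0.7, subject_shift = 0.5) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    do.call(rbind, lapply(seq_len(n_subjects), function(s) {
      do.call(rbind, lapply(seq_len(n_channels), function(ch) {
        x <- stats::rnorm(n_cycles, mean = s * subject_shift, sd = 1)
        y <- beta * (x - s * subject_shift) + stats::rnorm(n_cycles, 0, noise_sd) +
          0.2 * s
        data.frame(subject_id = sprintf("s%02d", s),
                   channel_id = sprintf("ch%d", ch), modality = "airflow",
                   resp_rise_time_s = x, neural_rise_time_s = y,
                   stringsAsFactors = FALSE)
      }))
    }))
  })
}

# Independent re-implementation of the greedy peak-matching contract, used
# as an oracle: visit respiration peaks in order, assign the closest
# unmatched neural peak (earlier peak wins ties), keep if |delay| < tau.
greedy_match_oracle <- function(rp, np, tau) {
  taken <- logical(length(np))
  out <- NULL
  for (i in seq_along(rp)) {
    cand <- which(!taken)
    if (!length(cand)) break
    d <- abs(np[cand] - rp[i])
    j <- cand[order(d, np[cand])][1]
    if (abs(np[j] - rp[i]) < tau) {
      taken[j] <- TRUE
      out <- rbind(out, c(i, j, np[j] - rp[i]))
    }
  }
  out
}

# Build an extrema object directly from alternating trough/peak times, for
# oracle tests that bypass signal-level detection.
extrema_from_times <- function(times, kinds, fs = 100, values = NULL) {
  if (is.null(values)) values <- ifelse(kinds == "peak", 1, -1)
  structure(list(idx = round(times * fs) + 1L, times = times, kinds = kinds,
                 values = values, fs = fs),
            class = "extrema")
}

expect_alternating <- function(ext) {
  k <- ext$kinds
  if (length(k) > 1) {
    testthat::expect_true(all(k[-1] != k[-length(k)]))
  }
  testthat::expect_true(!is.unsorted(ext$times, strictly = TRUE))
}
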
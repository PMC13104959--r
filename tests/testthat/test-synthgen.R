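# The synthetic generator: rendering correctness, determinism, and the
# ground-truth contract that downstream stages rely on.

test_that("a symmetric zero-jitter template renders exactly symmetric cycles", {
  sim <- simulate_respiration(
    breath_template(mean_rise_s = 2, mean_decay_s = 2, rise_jitter_sd = 0,
                    decay_jitter_sd = 0, pause_mean_s = 0, pause_jitter_sd = 0,
                    amplitude_jitter_sd = 0),
    duration_s = 60, fs = 500, seed = 1)
  expect_true(all(sim$truth$rise_s == 2))
  expect_true(all(sim$truth$decay_s == 2))
  ext <- detect_extrema(sim$recording)
  pairs <- match_peaks(ext, ext, tau = 4)
  feats <- cycle_features(pairs, sim$recording, sim$recording)
  expect_equal(unique(feats$resp_rise_decay_symmetry), 0.5)
  expect_equal(unique(feats$resp_cycle_duration_s), 4)
})

test_that("the same seed reproduces signals and datasets sample-exactly", {
  a <- simulate_respiration(duration_s = 40, fs = 100, seed = 7)
  b <- simulate_respiration(duration_s = 40, fs = 100, seed = 7)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$truth, b$truth)
  d1 <- generate_dataset(list(duration_s = 60, fs = 100), seed = 5)
  d2 <- generate_dataset(list(duration_s = 60, fs = 100), seed = 5)
  expect_identical(d1$manifest, d2$manifest)
  expect_identical(d1$recordings[["s01/lfp01"]]$samples,
                   d2$recordings[["s01/lfp01"]]$samples)
  expect_false(identical(
    d1$recordings[["s01/lfp01"]]$samples,
    generate_dataset(list(duration_s = 60, fs = 100), seed = 6)$recordings[["s01/lfp01"]]$samples))
})

test_that("extracted rise and decay track the template means under jitter", {
  tmpl <- breath_template(mean_rise_s = 1.5, mean_decay_s = 2.5,
                          rise_jitter_sd = 0.2, decay_jitter_sd = 0.2)
  sim <- simulate_respiration(tmpl, duration_s = 300, fs = 100, seed = 7)
  z <- zscore_recording(bandpass_for_timedomain(sim$recording))
  ext <- detect_extrema(z)
  pairs <- match_peaks(ext, ext, tau = 4)
  feats <- cycle_features(pairs, z, z)
  expect_lt(abs(median(feats$resp_rise_time_s) - 1.5), 0.15)
  expect_lt(abs(median(feats$resp_decay_time_s) - 2.5), 0.15)
})

test_that("each rendered respiration cycle has exactly one detected peak", {
  sim <- simulate_respiration(duration_s = 120, fs = 100, seed = 11)
  ext <- detect_extrema(sim$recording)
  expect_alternating(ext)
  pk_t <- ext$times[ext$kinds == "peak"]
  per_cycle <- vapply(seq_len(nrow(sim$truth)), function(i) {
    sum(pk_t > sim$truth$trough_t[i] & pk_t < sim$truth$end_t[i])
  }, numeric(1))
  expect_true(all(per_cycle == 1))
})

test_that("truth-table durations tile the rendered breath train", {
  sim <- simulate_respiration(duration_s = 120, fs = 100, seed = 3)
  tt <- sim$truth
  expect_equal(tt$end_t[nrow(tt)] - tt$trough_t[1],
               sum(tt$rise_s + tt$decay_s), tolerance = 1 / 100)
  expect_equal(tt$trough_t[-1], tt$end_t[-nrow(tt)])
  expect_true(all(tt$pause_s <= tt$decay_s))
})

test_that("identity coupling with zero noise copies respiration durations", {
  sim <- simulate_respiration(duration_s = 90, fs = 100, seed = 2)
  lfp <- simulate_coupled_lfp(sim$truth,
                              coupling_truth(beta_true = 1, noise_scale = 0),
                              fs = 100, seed = 9, background_rms = 0)
  tn <- attr(lfp, "truth")
  expect_equal(tn$rise_s, sim$truth$rise_s[tn$cycle], tolerance = 1e-12)
  expect_equal(tn$rise_s + tn$decay_s,
               sim$truth$rise_s[tn$cycle] + sim$truth$decay_s[tn$cycle],
               tolerance = 1e-12)
  expect_equal(tn$peak_t - tn$resp_peak_t, rep(0.3, nrow(tn)), tolerance = 1e-9)
})

test_that("uncoupled rendering leaves no rise-time association (20 replicates)", {
  slopes <- vapply(1:20, function(k) {
    sim <- simulate_respiration(duration_s = 2200, fs = 100, seed = k)
    lfp <- simulate_coupled_lfp(sim$truth, coupling_truth(beta_true = 0),
                                fs = 100, seed = 1000 + k)
    tn <- attr(lfp, "truth")
    stats::coef(stats::lm(scale(tn$rise_s) ~ scale(sim$truth$rise_s[tn$cycle])))[2]
  }, numeric(1))
  expect_lt(abs(mean(slopes)), 0.05)
  expect_lt(max(abs(slopes)), 0.15)
})

test_that("feature noise dilutes the recovered posterior toward chance", {
  p_at_scale <- function(noise_scale) {
    mean(vapply(1:10, function(k) {
      sim <- simulate_respiration(duration_s = 300, fs = 100, seed = 40 + k)
      lfp <- simulate_coupled_lfp(
        sim$truth, coupling_truth(beta_true = 0.15, noise_scale = noise_scale),
        fs = 100, seed = 140 + k)
      tn <- attr(lfp, "truth")
      rows <- data.frame(subject_id = "s01", channel_id = "c1",
                         modality = "airflow",
                         resp_rise_time_s = sim$truth$rise_s[tn$cycle],
                         neural_rise_time_s = tn$rise_s)
      fit <- suppressWarnings(shape_coupling(rows, "rise_time", chains = 2,
                                             iter = 700, warmup = 350,
                                             seed = 240 + k))
      fit$p_positive
    }, numeric(1)))
  }
  p <- vapply(c(0.3, 0.74, 1.5), p_at_scale, numeric(1))
  expect_true(all(diff(p) < 0))
  expect_gt(p[1], 0.9)          # tight noise: coupling nearly certain
  expect_lt(p[3], p[1] - 0.1)   # heavy noise: evidence decays toward 0.5
  expect_gt(p[3], 0.5)          # but never flips sign systematically
})

test_that("configuration and argument errors are raised", {
  expect_error(simulate_respiration(duration_s = -1), class = "rs_invalid_argument")
  expect_error(simulate_respiration(fs = -5), class = "rs_invalid_argument")
  expect_error(breath_template(mean_rise_s = 0), class = "rs_invalid_argument")
  expect_error(coupling_truth(noise_df = 2), class = "rs_invalid_argument")
  sim <- simulate_respiration(duration_s = 60, fs = 100, seed = 1)
  expect_error(simulate_coupled_lfp(sim$truth, coupling_truth(lag_s = 30),
                                    fs = 100, seed = 1),
               class = "rs_config_error")
  expect_error(generate_dataset(list(n_coupled = 0), seed = 1),
               class = "rs_config_error")
})

test_that("the dataset manifest records every channel with its role", {
  ds <- generate_dataset(list(duration_s = 60, fs = 100, n_coupled = 1,
                              n_uncoupled = 1), seed = 4)
  expect_equal(nrow(ds$manifest), 3)
  expect_setequal(ds$manifest$role, c("respiration", "coupled", "uncoupled"))
  expect_equal(length(ds$recordings), 3)
  ds2 <- generate_dataset(list(duration_s = 60, fs = 100, n_subjects = 2,
                               modalities = c("airflow", "belt"),
                               n_coupled = 2, n_uncoupled = 1), seed = 4)
  expect_equal(nrow(ds2$manifest), 2 * (2 + 2 + 1))
  # adding channels must not perturb existing streams (named substreams)
  expect_identical(ds$recordings[["s01/lfp01"]]$samples,
                   ds2$recordings[["s01/lfp01"]]$samples)
})

test_that("datasets round-trip through the delimited format with manifest", {
  ds <- generate_dataset(list(duration_s = 60, fs = 100), seed = 8)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  expect_equal(nrow(man), nrow(ds$manifest))
  rec <- read_recording(file.path(dir, man$file[man$role == "coupled"][1]))
  orig <- ds$recordings[["s01/lfp01"]]
  expect_equal(rec$samples, orig$samples, tolerance = 1e-6)
  expect_equal(rec$fs, orig$fs)
  expect_equal(rec$modality, "neural")
})
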
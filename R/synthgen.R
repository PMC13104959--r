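#' Breath template parameters
#'
#' Describes the average morphology of one breath for the synthetic
#' generator. A breath is rendered as smooth half-cosine limbs: a monotone
#' rise from the (negative) onset trough to the inhale peak, and a monotone
#' decay back down through baseline, holding at baseline for the
#' post-expiratory pause before descending into the next trough. The decay
#' duration is the full peak-to-trough interval and therefore contains the
#' pause, mirroring how the trough-to-trough analysis segments real breaths.
#'
#' @param mean_rise_s,mean_decay_s Mean rise (trough to peak) and decay
#'   (peak to next trough, pause included) durations in seconds. Must be > 0.
#' @param rise_jitter_sd,decay_jitter_sd Cycle-to-cycle SD of the durations,
#'   seconds. Drawn durations are truncated below at 0.2 s (rise) / 0.3 s
#'   (decay).
#' @param pause_mean_s,pause_jitter_sd Post-expiratory pause mean and SD,
#'   seconds. The pause is held at baseline (above the trough), inside the
#'   decay limb.
#' @param amplitude_mean,amplitude_jitter_sd Peak-to-trough amplitude mean
#'   and SD, arbitrary units.
#' @param modality `"airflow"` or `"belt"`. Belt traces are rendered from the
#'   same template but with the pause damped (x 0.3) and the waveform
#'   low-pass smoothed (~1 Hz), emulating the blunter chest-displacement
#'   morphology; cycle durations are unchanged.
#' @return An object of class `"breath_template"`.
#' @export
breath_template <- function(mean_rise_s = 1.6, mean_decay_s = 2.2,
                            rise_jitter_sd = 0.25, decay_jitter_sd = 0.3,
                            pause_mean_s = 0.5, pause_jitter_sd = 0.2,
                            amplitude_mean = 1, amplitude_jitter_sd = 0.15,
                            modality = c("airflow", "belt")) {
  modality <- match.arg(modality)
  means <- c(mean_rise_s, mean_decay_s, pause_mean_s, amplitude_mean)
  sds <- c(rise_jitter_sd, decay_jitter_sd, pause_jitter_sd, amplitude_jitter_sd)
  if (any(!is.finite(means)) || any(means[c(1, 2, 4)] <= 0) || pause_mean_s < 0) {
    stop_invalid("template means must be positive (pause mean >= 0)")
  }
  if (any(!is.finite(sds)) || any(sds < 0)) {
    stop_invalid("jitter SDs must be >= 0")
  }
  structure(list(mean_rise_s = mean_rise_s, mean_decay_s = mean_decay_s,
                 rise_jitter_sd = rise_jitter_sd, decay_jitter_sd = decay_jitter_sd,
                 pause_mean_s = pause_mean_s, pause_jitter_sd = pause_jitter_sd,
                 amplitude_mean = amplitude_mean,
                 amplitude_jitter_sd = amplitude_jitter_sd,
                 modality = modality),
            class = "breath_template")
}

#' Ground-truth coupling parameters for the synthetic LFP renderer
#'
#' @param beta_true Standardized slope linking respiration cycle features to
#'   neural cycle features (dimensionless).
#' @param noise_df Degrees of freedom of the Student-t feature noise; must be
#'   > 2 so the noise variance is finite.
#' @param noise_scale Scale of the Student-t feature noise, in pooled-SD
#'   units of the respiration feature. The default 0.74 puts the total
#'   standardized feature variance near 1 at moderate coupling
#'   (df = 5: 0.3^2 + 0.74^2 * 5/3 ~ 1).
#' @param coupled_channel_ids Optional identifiers of coupled channels.
#' @param lag_s Mean delay of the neural peak after the matched respiration
#'   peak, seconds; must be non-negative and shorter than one breath.
#' @return An object of class `"coupling_truth"`.
#' @export
coupling_truth <- function(beta_true = 0.3, noise_df = 5, noise_scale = 0.74,
                           coupled_channel_ids = character(), lag_s = 0.3) {
  if (!is.finite(noise_df) || noise_df <= 2) stop_invalid("noise_df must be > 2")
  if (!is.finite(noise_scale) || noise_scale < 0) stop_invalid("noise_scale must be >= 0")
  if (!is.finite(lag_s) || lag_s < 0) stop_invalid("lag_s must be >= 0")
  structure(list(beta_true = beta_true, noise_df = noise_df,
                 noise_scale = noise_scale,
                 coupled_channel_ids = coupled_channel_ids, lag_s = lag_s),
            class = "coupling_truth")
}

# Render a chain of trough->peak->trough cycles into a sample buffer.
# Cycle k spans [T_k, T_k + rise_k + decay_k]; consecutive cycles share
# troughs at level -b; the pause sits at baseline 0 inside the decay limb.
render_cycle_chain <- function(n_samples, fs, start_t, rise, decay, pause,
                               peak_h, trough_d, pause_noise_sd = 0) {
  x <- numeric(n_samples)
  seg_idx <- function(t0, t1) {
    i0 <- max(floor(t0 * fs) + 1, 1)
    i1 <- min(floor(t1 * fs), n_samples)
    if (i1 < i0) return(integer())
    i0:i1
  }
  half_cos <- function(idx, t0, dur, from, to) {
    tt <- (idx - 1) / fs - t0
    from + (to - from) * (1 - cos(pi * tt / dur)) / 2
  }
  b <- trough_d
  # lead-in: baseline down to the first trough
  lead <- 0.4
  i <- seg_idx(start_t - lead, start_t)
  if (length(i)) x[i] <- half_cos(i, start_t - lead, lead, 0, -b)
  t <- start_t
  n_cyc <- length(rise)
  for (k in seq_len(n_cyc)) {
    c_total <- decay[k] - pause[k]
    c1 <- 0.55 * c_total
    c2 <- c_total - c1
    i <- seg_idx(t, t + rise[k])
    x[i] <- half_cos(i, t, rise[k], -b, peak_h[k])
    t1 <- t + rise[k]
    i <- seg_idx(t1, t1 + c1)
    x[i] <- half_cos(i, t1, c1, peak_h[k], 0)
    t2 <- t1 + c1
    i <- seg_idx(t2, t2 + pause[k])
    if (length(i)) {
      x[i] <- if (pause_noise_sd > 0) stats::rnorm(length(i), 0, pause_noise_sd) else 0
    }
    t3 <- t2 + pause[k]
    i <- seg_idx(t3, t3 + c2)
    x[i] <- half_cos(i, t3, c2, 0, -b)
    t <- t + rise[k] + decay[k]
  }
  # tail: return from the final trough to baseline
  i <- seg_idx(t, t + lead)
  if (length(i)) x[i] <- half_cos(i, t, lead, -b, 0)
  x
}

# Two-pass centered moving average (triangular kernel overall), edge-padded.
smooth_belt <- function(x, fs, width_s = 0.3) {
  w <- max(3L, round(width_s * fs))
  if (w %% 2L == 0L) w <- w + 1L
  k <- rep(1 / w, w)
  pad <- (w - 1L) %/% 2L
  for (pass in 1:2) {
    xp <- c(rep(x[1L], pad), x, rep(x[length(x)], pad))
    x <- as.numeric(stats::filter(xp, k, sides = 2L))[(pad + 1L):(pad + length(x))]
  }
  x
}

#' Simulate a respiration recording with a per-cycle truth table
#'
#' Concatenates smooth asymmetric breath cycles (half-cosine rise and decay
#' limbs with a baseline pause; see [breath_template()]) with independently
#' jittered per-cycle durations, pauses and amplitudes. The same seed
#' reproduces the signal sample-exactly.
#'
#' @param params A [breath_template()].
#' @param duration_s Recording length in seconds (>= 30).
#' @param fs Sampling rate in Hz (>= 100).
#' @param seed Integer seed.
#' @param subject_id,channel_id Identity labels for the [recording()].
#' @return A list with elements `recording` (a [recording()]) and `truth`
#'   (data frame, one row per rendered cycle: `trough_t`, `peak_t`, `end_t`,
#'   `rise_s`, `decay_s`, `pause_s`, `amplitude`).
#' @export
simulate_respiration <- function(params = breath_template(), duration_s = 300,
                                 fs = 500, seed = 1,
                                 subject_id = "s01", channel_id = NULL) {
  if (!inherits(params, "breath_template")) stop_invalid("params must be a breath_template")
  if (!is.finite(duration_s) || duration_s <= 0 || !is.finite(fs) || fs <= 0) {
    stop_invalid("duration_s and fs must be positive")
  }
  if (duration_s < 30) stop_invalid("duration_s must be >= 30 s for downstream screening")
  if (fs < 100) stop_invalid("fs must be >= 100 Hz")
  channel_id <- channel_id %||% paste0("resp_", params$modality)

  with_seed(seed, {
    mean_cycle <- params$mean_rise_s + params$mean_decay_s
    n_est <- ceiling(duration_s / max(0.5, mean_cycle)) + 20L
    rise <- pmax(stats::rnorm(n_est, params$mean_rise_s, params$rise_jitter_sd), 0.2)
    decay <- pmax(stats::rnorm(n_est, params$mean_decay_s, params$decay_jitter_sd), 0.3)
    pause <- pmax(stats::rnorm(n_est, params$pause_mean_s, params$pause_jitter_sd), 0)
    if (params$modality == "belt") pause <- 0.3 * pause
    pause <- pmin(pause, pmax(decay - 0.2, 0))
    amp <- pmax(stats::rnorm(n_est, params$amplitude_mean, params$amplitude_jitter_sd),
                0.2 * params$amplitude_mean)
    b <- 0.4 / 1.4 * params$amplitude_mean   # constant trough depth
    a <- pmax(amp - b, 0.1 * params$amplitude_mean)

    start_t <- 1.0
    ends <- start_t + cumsum(rise + decay)
    keep <- which(ends <= duration_s - 0.5)
    if (!length(keep)) stop_invalid("duration too short to render a single cycle")
    n_cyc <- max(keep)
    idx <- seq_len(n_cyc)
    n_samples <- round(duration_s * fs)
    x <- render_cycle_chain(n_samples, fs, start_t, rise[idx], decay[idx],
                            pause[idx], a[idx], b,
                            pause_noise_sd = 0.01 * params$amplitude_mean)
    if (params$modality == "belt") x <- smooth_belt(x, fs)

    trough_t <- start_t + c(0, cumsum(rise[idx] + decay[idx]))[idx]
    truth <- data.frame(
      cycle = idx,
      trough_t = trough_t,
      peak_t = trough_t + rise[idx],
      end_t = trough_t + rise[idx] + decay[idx],
      rise_s = rise[idx],
      decay_s = decay[idx],
      pause_s = pause[idx],
      amplitude = a[idx] + b
    )
    rec <- recording(x, fs, modality = params$modality,
                     subject_id = subject_id, channel_id = channel_id)
    list(recording = rec, truth = truth)
  })
}

zcol <- function(v) {
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) return(rep(0, length(v)))
  (v - mean(v)) / s
}

# 1/f^exponent Gaussian noise, unit SD, via spectral shaping.
sim_powerlaw <- function(n, fs, exponent) {
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  k <- seq_len(n) - 1L
  f <- pmin(k, n - k) * fs / n
  sc <- c(0, f[-1L]^(-exponent / 2))
  x <- Re(stats::fft(X * sc, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Simulate an LFP channel whose cycle shapes track respiration
#'
#' For every breath in `resp_truth`, renders one neural oscillation cycle
#' whose standardized rise time, decay time and amplitude equal
#' `beta_true` x (standardized respiration feature) plus Student-t noise,
#' with the neural peak delayed by `lag_s` relative to the respiration peak.
#' Neural cycles chain through shared troughs; a proportional drift
#' correction (gain `anchor_gain`) acting on the neural pause keeps the peak
#' lag bounded without constraining the current cycle's rendered durations.
#' The oscillation is summed with `1/f^background_exponent` background
#' activity. With `beta_true = 0` the channel is still respiration-locked in
#' time but its shape fluctuations are independent of the breath's.
#'
#' @param resp_truth Truth table from [simulate_respiration()].
#' @param truth A [coupling_truth()].
#' @param background_exponent Aperiodic background exponent (1/f^x), default 2.
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed.
#' @param duration_s Output length; defaults to covering the whole breath train.
#' @param background_rms Background SD as a fraction of the mean cycle
#'   amplitude (default 0.1, a strongly entrained channel).
#' @param anchor_gain Drift-correction gain in (0, 1]; 0.25 keeps the lag SD
#'   near half a second without biasing rise-time coupling.
#' @param subject_id,channel_id Identity labels.
#' @return A [recording()] (modality `"neural"`). The per-cycle neural truth
#'   table is attached as `attr(x, "truth")` and the generating
#'   [coupling_truth()] as `attr(x, "ground_truth")`.
#' @export
simulate_coupled_lfp <- function(resp_truth, truth = coupling_truth(),
                                 background_exponent = 2, fs = 500, seed = 1,
                                 duration_s = NULL, background_rms = 0.1,
                                 anchor_gain = 0.25,
                                 subject_id = "s01", channel_id = "lfp01") {
  if (!is.data.frame(resp_truth) || nrow(resp_truth) == 0L) {
    stop_invalid("resp_truth must be a non-empty truth table")
  }
  if (!inherits(truth, "coupling_truth")) stop_invalid("truth must be a coupling_truth")
  periods <- resp_truth$rise_s + resp_truth$decay_s
  if (truth$lag_s >= min(periods)) {
    stop_rs("lag_s must be shorter than the shortest respiration period",
            "rs_config_error")
  }
  duration_s <- duration_s %||% (max(resp_truth$end_t) + 1.5)

  with_seed(seed, {
    n <- nrow(resp_truth)
    zr <- cbind(rise = zcol(resp_truth$rise_s),
                decay = zcol(resp_truth$decay_s),
                amp = zcol(resp_truth$amplitude))
    eps <- matrix(stats::rt(3L * n, truth$noise_df) * truth$noise_scale, n, 3L)
    zn <- truth$beta_true * zr + eps

    m_r <- mean(resp_truth$rise_s);   s_r <- stats::sd(resp_truth$rise_s)
    m_d <- mean(resp_truth$decay_s);  s_d <- stats::sd(resp_truth$decay_s)
    m_a <- mean(resp_truth$amplitude); s_a <- stats::sd(resp_truth$amplitude)
    if (n < 2L) { s_r <- s_d <- s_a <- 0 }

    rise_n <- pmax(m_r + zn[, 1L] * s_r, 0.2)
    dn <- pmax(m_d + zn[, 2L] * s_d, 0.3)
    amp_n <- pmax(m_a + zn[, 3L] * s_a, 0.2 * m_a)
    b_n <- 0.4 / 1.4 * m_a
    a_n <- pmax(amp_n - b_n, 0.1 * m_a)

    # chain peaks with soft anchoring to resp peaks + lag; the correction is
    # absorbed entirely by the flat mid-decay pause so the trough-adjacent
    # limb shapes (which set where extrema are detected) never carry it
    peak_t <- numeric(n)
    D <- numeric(n)
    pause_n <- 0.3 * dn
    peak_t[1L] <- resp_truth$peak_t[1L] + truth$lag_s
    if (n > 1L) {
      for (k in 1:(n - 1L)) {
        pred <- peak_t[k] + dn[k] + rise_n[k + 1L]
        target <- resp_truth$peak_t[k + 1L] + truth$lag_s
        adj <- -anchor_gain * (pred - target)
        pause_n[k] <- max(0.05, 0.3 * dn[k] + adj)
        D[k] <- 0.7 * dn[k] + pause_n[k]
        peak_t[k + 1L] <- peak_t[k] + D[k] + rise_n[k + 1L]
      }
    }
    D[n] <- dn[n]

    n_samples <- round(duration_s * fs)
    # drop cycles that would run off either end of the buffer
    ok_start <- which(peak_t - rise_n >= 0.45)
    ok_end <- which(peak_t + D <= duration_s - 0.5)
    if (!length(ok_start) || !length(ok_end) || min(ok_start) > max(ok_end)) {
      stop_invalid("duration too short for any neural cycle")
    }
    idx <- min(ok_start):max(ok_end)
    start_t <- peak_t[idx[1L]] - rise_n[idx[1L]]
    x <- render_cycle_chain(n_samples, fs, start_t, rise_n[idx], D[idx],
                            pause_n[idx], a_n[idx], b_n)
    x <- x + background_rms * m_a * sim_powerlaw(n_samples, fs, background_exponent)

    truth_n <- data.frame(
      cycle = idx,
      resp_peak_t = resp_truth$peak_t[idx],
      trough_t = peak_t[idx] - rise_n[idx],
      peak_t = peak_t[idx],
      end_t = peak_t[idx] + D[idx],
      rise_s = rise_n[idx],
      decay_s = D[idx],
      amplitude = a_n[idx] + b_n
    )
    rec <- recording(x, fs, modality = "neural",
                     subject_id = subject_id, channel_id = channel_id)
    attr(rec, "truth") <- truth_n
    attr(rec, "ground_truth") <- truth
    rec
  })
}

#' Simulate an uncoupled aperiodic (1/f) channel
#'
#' A pure aperiodic-background channel with no respiration-locked activity;
#' the negative control for the screening stages.
#'
#' @param duration_s,fs Length (s) and sampling rate (Hz).
#' @param seed Integer seed.
#' @param exponent Spectral exponent of the 1/f^x background.
#' @param sd Sample standard deviation of the output.
#' @param subject_id,channel_id Identity labels.
#' @return A [recording()] (modality `"neural"`).
#' @export
simulate_aperiodic_channel <- function(duration_s, fs, seed, exponent = 2,
                                       sd = 1, subject_id = "s01",
                                       channel_id = "noise01") {
  if (!is.finite(duration_s) || duration_s <= 0 || !is.finite(fs) || fs <= 0) {
    stop_invalid("duration_s and fs must be positive")
  }
  x <- with_seed(seed, sim_powerlaw(round(duration_s * fs), fs, exponent)) * sd
  recording(x, fs, modality = "neural", subject_id = subject_id,
            channel_id = channel_id)
}

#' Generate a full synthetic dataset with a ground-truth manifest
#'
#' Builds, for each subject, one respiration recording per modality, a set
#' of shape-coupled LFP channels (driven by the first listed modality's
#' breath train) and a set of uncoupled aperiodic control channels. One
#' global seed drives named per-stream substreams, so adding channels or
#' subjects never perturbs existing recordings.
#'
#' @param config Named list overriding any of: `n_subjects`, `duration_s`,
#'   `fs`, `modalities` (subset of `"airflow"`, `"belt"`), `n_coupled`,
#'   `n_uncoupled`, `beta`, `noise_df`, `noise_scale`, `lag_s`,
#'   `background_exponent`, `background_rms`, `template_airflow`,
#'   `template_belt`.
#' @param seed Integer seed.
#' @return An object of class `"synth_dataset"`: list with `recordings`
#'   (named list of [recording()]s), `manifest` (data frame: one row per
#'   recording with its ground-truth role and `beta_true`), `truth` (per
#'   subject: respiration and neural truth tables), and `config`.
#' @export
generate_dataset <- function(config = list(), seed = 1) {
  cfg <- utils::modifyList(list(
    n_subjects = 1L, duration_s = 300, fs = 500,
    modalities = "airflow", n_coupled = 1L, n_uncoupled = 1L,
    beta = 0.3, noise_df = 5, noise_scale = 0.74, lag_s = 0.3,
    background_exponent = 2, background_rms = 0.1,
    template_airflow = breath_template(modality = "airflow"),
    template_belt = breath_template(modality = "belt")
  ), config)
  if (cfg$n_subjects < 1L || length(cfg$modalities) < 1L ||
      cfg$n_coupled < 1L || cfg$n_uncoupled < 1L) {
    stop_rs(paste("config must name >= 1 subject, >= 1 respiration modality,",
                  ">= 1 coupled and >= 1 uncoupled channel"), "rs_config_error")
  }
  if (!all(cfg$modalities %in% c("airflow", "belt"))) {
    stop_rs("modalities must be 'airflow' and/or 'belt'", "rs_config_error")
  }
  recordings <- list()
  truth <- list()
  manifest <- list()
  add_row <- function(rec, role, beta_true) {
    key <- paste(rec$subject_id, rec$channel_id, sep = "/")
    recordings[[key]] <<- rec
    manifest[[length(manifest) + 1L]] <<- data.frame(
      subject_id = rec$subject_id, channel_id = rec$channel_id,
      modality = rec$modality, role = role, beta_true = beta_true,
      fs = rec$fs, duration_s = rec_duration(rec))
  }
  for (s in seq_len(cfg$n_subjects)) {
    sid <- sprintf("s%02d", s)
    truth[[sid]] <- list()
    primary_truth <- NULL
    for (mod in cfg$modalities) {
      tmpl <- if (mod == "airflow") cfg$template_airflow else cfg$template_belt
      sim <- simulate_respiration(
        tmpl, duration_s = cfg$duration_s, fs = cfg$fs,
        seed = substream_seed(seed, paste0("resp/", sid, "/", mod)),
        subject_id = sid)
      truth[[sid]][[paste0("resp_", mod)]] <- sim$truth
      if (is.null(primary_truth)) primary_truth <- sim$truth
      add_row(sim$recording, "respiration", NA_real_)
    }
    ct <- coupling_truth(beta_true = cfg$beta, noise_df = cfg$noise_df,
                         noise_scale = cfg$noise_scale, lag_s = cfg$lag_s)
    for (j in seq_len(cfg$n_coupled)) {
      cid <- sprintf("lfp%02d", j)
      rec <- simulate_coupled_lfp(
        primary_truth, ct, background_exponent = cfg$background_exponent,
        fs = cfg$fs, seed = substream_seed(seed, paste0("lfp/", sid, "/", cid)),
        duration_s = cfg$duration_s, background_rms = cfg$background_rms,
        subject_id = sid, channel_id = cid)
      truth[[sid]][[cid]] <- attr(rec, "truth")
      add_row(rec, "coupled", cfg$beta)
    }
    for (j in seq_len(cfg$n_uncoupled)) {
      cid <- sprintf("noise%02d", j)
      rec <- simulate_aperiodic_channel(
        cfg$duration_s, cfg$fs,
        seed = substream_seed(seed, paste0("noise/", sid, "/", cid)),
        exponent = cfg$background_exponent, subject_id = sid, channel_id = cid)
      add_row(rec, "uncoupled", 0)
    }
  }
  structure(list(recordings = recordings,
                 manifest = do.call(rbind, manifest),
                 truth = truth, config = cfg, seed = seed),
            class = "synth_dataset")
}

#' @export
print.synth_dataset <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<synth_dataset> %d subjects, %d recordings (%s)\n",
              length(unique(m$subject_id)), nrow(m),
              paste(sprintf("%d %s", table(m$role), names(table(m$role))),
                    collapse = ", ")))
  cat(sprintf("  fs %g Hz, %g s, beta_true %g, seed %d\n",
              x$config$fs, x$config$duration_s, x$config$beta, x$seed))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' One delimited time-series file per recording (see [write_recording()])
#' plus a JSON manifest recording every channel's ground-truth role.
#'
#' @param dataset A [generate_dataset()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!inherits(dataset, "synth_dataset")) stop_invalid("dataset must be a synth_dataset")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- dataset$manifest
  m$file <- sprintf("%s_%s.tsv", m$subject_id, m$channel_id)
  for (i in seq_len(nrow(m))) {
    key <- paste(m$subject_id[i], m$channel_id[i], sep = "/")
    write_recording(dataset$recordings[[key]], file.path(dir, m$file[i]),
                    provenance = sprintf("role=%s", m$role[i]))
  }
  jsonlite::write_json(m, file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
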
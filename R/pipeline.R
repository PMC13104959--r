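# End-to-end conveniences tying the screening and cycle-shape stages
# together, mirroring how a full analysis proceeds: coherence screen on the
# (low-passed) respiration, then time-domain screens and feature extraction
# on band-passed, z-scored signals.

#' Screen one neural channel against respiration
#'
#' Runs the three sequential screening criteria for a channel: (1) the
#' surrogate-thresholded coherence screen with the spectral-peak criterion,
#' (2) the respiration-peak-locked cross-correlation screen with its
#' permutation null, and (3) the phase monotonicity index with its
#' circular-shift null. The respiration trace is low-pass filtered before
#' the coherence stage; both signals are band-passed (0.01-2 Hz, zero
#' phase) and z-scored for the time-domain stages. A channel is retained
#' only when all three criteria pass.
#'
#' @param neural Raw neural [recording()].
#' @param resp Raw respiration [recording()] (airflow or belt).
#' @param band Optional precomputed [find_breathing_band()]; derived from
#'   `resp` when missing.
#' @param n_surrogates Phase-randomized surrogates for the coherence null.
#' @param n_perm Permutations for the CCF and PMI nulls.
#' @param alpha Significance level for all three nulls.
#' @param seed Integer seed.
#' @return An object of class `"channel_screen"`: the three stage results
#'   (`coherence`, `ccf`, `pmi`), the `band`, and the overall `passes`.
#' @export
screen_channel <- function(neural, resp, band = NULL, n_surrogates = 1000,
                           n_perm = 500, alpha = 0.01, seed = 1) {
  assert_recording(neural, modalities = "neural")
  assert_recording(resp, modalities = c("airflow", "belt"))
  resp_lp <- lowpass_respiration(resp)
  band <- band %||% find_breathing_band(resp_lp)

  coh <- coherence_screen(neural, resp_lp, band, n_surrogates = n_surrogates,
                          alpha = alpha, seed = substream_seed(seed, "coh"))

  neural_z <- zscore_recording(bandpass_for_timedomain(neural))
  resp_z <- zscore_recording(bandpass_for_timedomain(resp_lp))
  resp_ext <- detect_extrema(resp_z)
  resp_peaks <- resp_ext$times[resp_ext$kinds == "peak"]
  epochs <- epoch_on_respiration_peaks(neural_z, resp_z, resp_peaks,
                                       window_s = band$tau)
  ccf_res <- ccf_permutation_null(neural_z, epochs, tau = band$tau,
                                  n_perm = n_perm, alpha = alpha,
                                  seed = substream_seed(seed, "ccf"))
  pmi_res <- phase_monotonicity_index(neural_z, resp_ext, n_perm = n_perm,
                                      alpha = alpha,
                                      seed = substream_seed(seed, "pmi"))
  structure(list(subject_id = neural$subject_id, channel_id = neural$channel_id,
                 band = band, coherence = coh, ccf = ccf_res, pmi = pmi_res,
                 polarity = ccf_res$polarity,
                 passes = coh$passes && ccf_res$passes && pmi_res$passes),
            class = "channel_screen")
}

#' @export
print.channel_screen <- function(x, ...) {
  cat(sprintf("<channel_screen> %s/%s @ %.3f Hz breathing\n",
              x$subject_id, x$channel_id, x$band$f_resp))
  cat(sprintf("  coherence: %-4s  CCF: %-4s  PMI: %-4s  ->  %s (polarity %+d)\n",
              if (x$coherence$passes) "pass" else "FAIL",
              if (x$ccf$passes) "pass" else "FAIL",
              if (x$pmi$passes) "pass" else "FAIL",
              if (x$passes) "RETAINED" else "excluded", x$polarity))
  invisible(x)
}

#' Extract matched-cycle shape features for one channel
#'
#' The feature-extraction arm of the pipeline: band-pass and z-score both
#' signals, flip the neural polarity if requested, detect extrema in each,
#' reject artifact cycles, match respiration to neural peaks greedily
#' within one respiration period, and compute the waveform shape features
#' per matched pair.
#'
#' @param neural,resp Raw [recording()]s.
#' @param tau Respiration period in seconds (from [find_breathing_band()]).
#' @param polarity `+1` or `-1`; `-1` negates the neural signal first (as
#'   determined by the CCF screen for bipolar derivations).
#' @param mad_k MAD multiplier for artifact-cycle rejection.
#' @param exclude_outliers Apply [exclude_feature_outliers()] (default TRUE).
#' @param lowpass_resp Low-pass the respiration trace first (default TRUE).
#' @return A [cycle_features()] table.
#' @export
extract_matched_features <- function(neural, resp, tau, polarity = 1,
                                     mad_k = 5, exclude_outliers = TRUE,
                                     lowpass_resp = TRUE) {
  assert_recording(neural, modalities = "neural")
  assert_recording(resp, modalities = c("airflow", "belt"))
  if (lowpass_resp) resp <- lowpass_respiration(resp)
  resp_z <- zscore_recording(bandpass_for_timedomain(resp))
  neural_z <- zscore_recording(bandpass_for_timedomain(neural))
  if (polarity < 0) neural_z <- rec_update(neural_z, -neural_z$samples)
  resp_ext <- detect_extrema(resp_z)
  neural_ext <- detect_extrema(neural_z)
  resp_ext <- reject_artifact_cycles(resp_ext, resp_z, mad_k = mad_k)
  neural_ext <- reject_artifact_cycles(neural_ext, neural_z, mad_k = mad_k)
  pairs <- match_peaks(resp_ext, neural_ext, tau = tau)
  feats <- cycle_features(pairs, resp_z, neural_z)
  if (exclude_outliers && nrow(feats) >= 10L) {
    feats <- exclude_feature_outliers(feats)
  }
  feats
}
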
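# Extrema detection, respiration-neural cycle matching, and per-cycle
# waveform shape features.

# Candidate local maxima above `height`, pruned so surviving peaks are at
# least `distance` samples apart (larger peaks win, as in the standard
# find-peaks algorithm).
find_peaks_1d <- function(x, height, distance) {
  n <- length(x)
  if (n < 3L) return(integer())
  i <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  i <- i[x[i] >= height]
  if (length(i) < 2L) return(i)
  ord <- i[order(x[i], decreasing = TRUE)]
  keep <- logical(n)
  blocked <- logical(n)
  for (p in ord) {
    if (blocked[p]) next
    keep[p] <- TRUE
    blocked[max(1L, p - distance + 1L):min(n, p + distance - 1L)] <- TRUE
  }
  sort(which(keep))
}

new_extrema <- function(idx, kinds, values, fs) {
  structure(list(idx = idx, times = (idx - 1) / fs, kinds = kinds,
                 values = values, fs = fs),
            class = "extrema")
}

#' @export
print.extrema <- function(x, ...) {
  cat(sprintf("<extrema> %d peaks, %d troughs over %.1f s\n",
              sum(x$kinds == "peak"), sum(x$kinds == "trough"),
              if (length(x$times)) diff(range(x$times)) else 0))
  invisible(x)
}

# Enforce strict peak/trough alternation: runs of same-kind extrema are
# collapsed to the single most extreme member.
enforce_alternation <- function(idx, kinds, values) {
  if (!length(idx)) return(list(idx = idx, kinds = kinds, values = values))
  o <- order(idx)
  idx <- idx[o]; kinds <- kinds[o]; values <- values[o]
  run <- cumsum(c(TRUE, kinds[-1L] != kinds[-length(kinds)]))
  pick <- vapply(split(seq_along(idx), run), function(j) {
    if (kinds[j[1L]] == "peak") j[which.max(values[j])] else j[which.min(values[j])]
  }, integer(1))
  pick <- sort(pick)
  list(idx = idx[pick], kinds = kinds[pick], values = values[pick])
}

#' Detect alternating peaks and troughs in a recording
#'
#' Two-stage adaptive procedure. Stage one finds candidate peaks above
#' `base_height` separated by at least `min_distance_factor` seconds
#' (troughs identically, on the negated signal). Stage two removes peaks
#' whose height above `base_height` falls below `relative_amplitude_frac`
#' times the median peak height (again mirrored for troughs), then enforces
#' strict alternation by keeping the higher of consecutive peaks and the
#' deeper of consecutive troughs. Extrema inside a filter edge-exclusion
#' zone (`attr(rec, "edge_exclude_s")`) are discarded first.
#'
#' @param rec A [recording()] of at least 10 s.
#' @param base_height Candidate threshold in signal units; defaults to the
#'   signal median (0 for z-scored input).
#' @param min_distance_factor Minimum inter-peak distance in seconds
#'   (default 1.5; the candidate spacing is `1.5 * fs` samples).
#' @param relative_amplitude_frac Relative amplitude threshold (default 0.3).
#' @return An object of class `"extrema"`: sorted `times` (s), strictly
#'   alternating `kinds` (`"peak"`/`"trough"`), `idx`, `values`, `fs`.
#' @export
detect_extrema <- function(rec, base_height = NULL, min_distance_factor = 1.5,
                           relative_amplitude_frac = 0.3) {
  assert_recording(rec)
  if (rec_duration(rec) < 10) stop_invalid("recording must be at least 10 s")
  x <- rec$samples
  base <- base_height %||% stats::median(x)
  dist <- max(1L, round(min_distance_factor * rec$fs))

  pk <- find_peaks_1d(x, base, dist)
  tr <- find_peaks_1d(-x, -base, dist)
  # stage 2: relative amplitude threshold against the median extremum
  if (length(pk)) {
    amp <- x[pk] - base
    pk <- pk[amp >= relative_amplitude_frac * stats::median(amp)]
  }
  if (length(tr)) {
    dep <- base - x[tr]
    tr <- tr[dep >= relative_amplitude_frac * stats::median(dep)]
  }
  idx <- c(pk, tr)
  kinds <- c(rep("peak", length(pk)), rep("trough", length(tr)))
  values <- x[idx]

  edge <- attr(rec, "edge_exclude_s") %||% 0
  if (edge > 0 && length(idx)) {
    t <- (idx - 1) / rec$fs
    keep <- t >= edge & t <= rec_duration(rec) - edge
    idx <- idx[keep]; kinds <- kinds[keep]; values <- values[keep]
  }
  alt <- enforce_alternation(idx, kinds, values)
  if (!length(alt$idx)) {
    stop_rs("no extrema survive detection", "rs_empty_extrema")
  }
  new_extrema(alt$idx, alt$kinds, alt$values, rec$fs)
}

# Complete trough->peak->trough cycles from an alternating extrema sequence.
extrema_cycles <- function(ext) {
  k <- ext$kinds
  pk <- which(k == "peak")
  pk <- pk[pk > 1L & pk < length(k)]
  pk <- pk[k[pk - 1L] == "trough" & k[pk + 1L] == "trough"]
  data.frame(trough_i = pk - 1L, peak_i = pk, end_i = pk + 1L,
             trough_t = ext$times[pk - 1L], peak_t = ext$times[pk],
             end_t = ext$times[pk + 1L])
}

#' Reject artifact cycles by robust amplitude and RMS thresholds
#'
#' Computes, for every trough-to-trough cycle, its within-cycle amplitude
#' (max minus min) and RMS, and drops cycles where either exceeds
#' `median + mad_k * MAD` (strict inequality, so a homogeneous set with
#' MAD = 0 loses nothing). Alternation is re-enforced after removal.
#'
#' @param ext An [detect_extrema()] result with >= 5 cycles.
#' @param rec The [recording()] the extrema came from.
#' @param mad_k MAD multiplier (default 5).
#' @return A filtered `"extrema"` object.
#' @export
reject_artifact_cycles <- function(ext, rec, mad_k = 5) {
  assert_recording(rec)
  if (!inherits(ext, "extrema")) stop_invalid("ext must be an extrema object")
  cyc <- extrema_cycles(ext)
  if (nrow(cyc) < 5L) stop_rs("need >= 5 cycles for artifact rejection", "rs_empty_extrema")
  x <- rec$samples
  stats_m <- t(vapply(seq_len(nrow(cyc)), function(i) {
    seg <- x[ext$idx[cyc$trough_i[i]]:ext$idx[cyc$end_i[i]]]
    c(amp = max(seg) - min(seg), rms = sqrt(mean(seg^2)))
  }, numeric(2)))
  bad <- stats_m[, 1L] > stats::median(stats_m[, 1L]) + mad_k * stats::mad(stats_m[, 1L]) |
    stats_m[, 2L] > stats::median(stats_m[, 2L]) + mad_k * stats::mad(stats_m[, 2L])
  if (all(bad)) stop_rs("all cycles rejected as artifacts", "rs_empty_extrema")
  drop <- cyc$peak_i[bad]
  keep <- setdiff(seq_along(ext$idx), drop)
  alt <- enforce_alternation(ext$idx[keep], ext$kinds[keep], ext$values[keep])
  new_extrema(alt$idx, alt$kinds, alt$values, ext$fs)
}

#' Greedy one-to-one matching of respiration and neural peaks
#'
#' Iterates through the respiration peaks in time order, assigning each the
#' temporally closest unmatched neural peak. A pair is kept only when the
#' delay is shorter than one respiration period `tau` and both cycles have
#' both bounding troughs. The greedy order — not global optimality — is the
#' contract: an earlier respiration peak may claim a neural peak that a
#' later one is closer to. Equidistant candidates resolve to the earlier
#' neural peak.
#'
#' @param resp_ext,neural_ext [detect_extrema()] results (alternating).
#' @param tau Respiration period in seconds (> 0).
#' @param match_direction `"absolute"` matches on `|delay|`;
#'   `"neural_after_resp"` restricts candidates to neural peaks at or after
#'   the respiration peak.
#' @return An object of class `c("matched_cycles", "data.frame")`, one row
#'   per matched pair: respiration and neural trough/peak/trough times and
#'   the signed `delay_s` (positive = neural later).
#' @export
match_peaks <- function(resp_ext, neural_ext, tau,
                        match_direction = c("absolute", "neural_after_resp")) {
  match_direction <- match.arg(match_direction)
  if (!inherits(resp_ext, "extrema") || !inherits(neural_ext, "extrema")) {
    stop_invalid("resp_ext and neural_ext must be extrema objects")
  }
  if (!is.finite(tau) || tau <= 0) stop_invalid("tau must be > 0")
  rc <- extrema_cycles(resp_ext)
  nc <- extrema_cycles(neural_ext)
  out <- list()
  if (nrow(rc) && nrow(nc)) {
    taken <- logical(nrow(nc))
    for (i in seq_len(nrow(rc))) {
      delay <- nc$peak_t - rc$peak_t[i]
      cand <- which(!taken & (if (match_direction == "absolute") TRUE else delay >= 0))
      if (!length(cand)) next
      # earlier neural peak wins ties: order() is stable on peak time
      j <- cand[order(abs(delay[cand]), nc$peak_t[cand])][1L]
      if (abs(delay[j]) < tau) {
        taken[j] <- TRUE
        out[[length(out) + 1L]] <- data.frame(
          resp_trough_t = rc$trough_t[i], resp_peak_t = rc$peak_t[i],
          resp_end_t = rc$end_t[i],
          neural_trough_t = nc$trough_t[j], neural_peak_t = nc$peak_t[j],
          neural_end_t = nc$end_t[j],
          delay_s = delay[j])
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else data.frame(
    resp_trough_t = numeric(0), resp_peak_t = numeric(0), resp_end_t = numeric(0),
    neural_trough_t = numeric(0), neural_peak_t = numeric(0),
    neural_end_t = numeric(0), delay_s = numeric(0))
  class(res) <- c("matched_cycles", "data.frame")
  res
}

# The eight waveform shape features (plus amplitude) for one
# trough->peak->trough cycle of a sample vector.
cycle_shape_features <- function(x, fs, t0, t1, t2) {
  n <- length(x)
  i0 <- min(max(round(t0 * fs) + 1L, 1L), n)
  i1 <- min(max(round(t1 * fs) + 1L, 1L), n)
  i2 <- min(max(round(t2 * fs) + 1L, 1L), n)
  peak_v <- x[i1]
  trough_v <- (x[i0] + x[i2]) / 2      # mean of the two bounding troughs
  amp <- peak_v - trough_v
  if (!(peak_v > x[i0] && peak_v > x[i2]) || amp <= 0) return(NULL)
  rise <- t1 - t0
  decay <- t2 - t1

  # sharpness: mean |first derivative| inside the contiguous window around
  # the extremum where the signal is within half the local amplitude of it,
  # normalized by the local amplitude
  fwhm_window <- function(center, lo, hi, cond) {
    l <- center; while (l > lo && cond(x[l - 1L])) l <- l - 1L
    r <- center; while (r < hi && cond(x[r + 1L])) r <- r + 1L
    l:r
  }
  sharp <- function(w) {
    if (length(w) < 2L) return(NA_real_)
    mean(abs(diff(x[w]))) * fs / amp
  }
  half_pk <- peak_v - amp / 2
  w_pk <- fwhm_window(i1, i0, i2, function(v) v >= half_pk)
  # the exhale trough window may extend past the cycle end, up to one cycle
  cap <- min(n, i2 + (i2 - i0))
  half_tr <- x[i2] + amp / 2
  w_tr <- fwhm_window(i2, i1, cap, function(v) v <= half_tr)

  # AUC: trapezoidal integral of (signal - cycle median) over the contiguous
  # region around the extremum on the extremum's side of the median
  med <- stats::median(x[i0:i2])
  w_auc_pk <- fwhm_window(i1, i0, i2, function(v) v > med)
  w_auc_tr <- fwhm_window(i2, i1, cap, function(v) v < med)
  auc_pk <- trapz_int(x[w_auc_pk] - med, fs)
  auc_tr <- trapz_int(med - x[w_auc_tr], fs)

  c(rise_time_s = rise, decay_time_s = decay, cycle_duration_s = rise + decay,
    amplitude = amp, rise_decay_symmetry = rise / (rise + decay),
    peak_sharpness = sharp(w_pk), trough_sharpness = sharp(w_tr),
    peak_auc = max(auc_pk, 0), trough_auc = max(auc_tr, 0))
}

shape_feature_names <- c("rise_time_s", "decay_time_s", "cycle_duration_s",
                         "amplitude", "rise_decay_symmetry", "peak_sharpness",
                         "trough_sharpness", "peak_auc", "trough_auc")

#' Extract waveform shape features for matched cycle pairs
#'
#' Computes, for every matched respiration-neural cycle pair, the eight
#' waveform shape features — rise time, decay time, cycle duration,
#' rise-decay symmetry, inhale-peak and exhale-trough sharpness, and
#' inhale-peak and exhale-trough AUC — plus the peak-to-trough amplitude,
#' identically for both signals. Degenerate cycles (peak not above both
#' troughs) are skipped with a warning.
#'
#' @param pairs A [match_peaks()] result.
#' @param resp_rec,neural_rec The [recording()]s the extrema came from.
#' @return A data frame of class `c("cycle_features", "data.frame")`, one
#'   row per matched cycle, with columns `subject_id`, `channel_id`,
#'   `modality`, `delay_s`, and `resp_*` / `neural_*` for each feature.
#' @export
cycle_features <- function(pairs, resp_rec, neural_rec) {
  if (!inherits(pairs, "matched_cycles")) stop_invalid("pairs must come from match_peaks()")
  assert_recording(resp_rec); assert_recording(neural_rec)
  rows <- list()
  skipped <- 0L
  for (i in seq_len(nrow(pairs))) {
    fr <- cycle_shape_features(resp_rec$samples, resp_rec$fs,
                               pairs$resp_trough_t[i], pairs$resp_peak_t[i],
                               pairs$resp_end_t[i])
    fn <- cycle_shape_features(neural_rec$samples, neural_rec$fs,
                               pairs$neural_trough_t[i], pairs$neural_peak_t[i],
                               pairs$neural_end_t[i])
    if (is.null(fr) || is.null(fn)) { skipped <- skipped + 1L; next }
    names(fr) <- paste0("resp_", names(fr))
    names(fn) <- paste0("neural_", names(fn))
    rows[[length(rows) + 1L]] <-
      c(delay_s = pairs$delay_s[i], fr, fn)
  }
  if (skipped > 0L) {
    warning(sprintf("%d degenerate cycle pair(s) skipped", skipped), call. = FALSE)
  }
  out <- if (length(rows)) as.data.frame(do.call(rbind, rows)) else
    stats::setNames(as.data.frame(matrix(numeric(0), 0, 1 + 18)),
                    c("delay_s", paste0("resp_", shape_feature_names),
                      paste0("neural_", shape_feature_names)))
  out <- cbind(data.frame(subject_id = rep(neural_rec$subject_id, nrow(out)),
                          channel_id = rep(neural_rec$channel_id, nrow(out)),
                          modality = rep(resp_rec$modality, nrow(out)),
                          stringsAsFactors = FALSE),
               out)
  class(out) <- c("cycle_features", "data.frame")
  out
}

#' Exclude extreme cycles feature-wise
#'
#' For each channel and each waveform metric (rise time, decay time,
#' rise-decay symmetry, cycle duration, sharpness and AUC — amplitude is
#' not filtered), cycles whose value exceeds `median + n_sd * SD` are
#' flagged; a row is dropped when any of its features is flagged, keeping
#' respiration and neural features paired. The rule is one-sided: values
#' far *below* the median are never excluded.
#'
#' @param rows A [cycle_features()] table with >= 10 rows per channel.
#' @param n_sd SD multiplier (default 3).
#' @return The filtered table; the logical flag matrix is attached as
#'   `attr(x, "outlier_flags")`.
#' @export
exclude_feature_outliers <- function(rows, n_sd = 3) {
  if (!is.data.frame(rows)) stop_invalid("rows must be a cycle feature table")
  filt_feats <- setdiff(shape_feature_names, "amplitude")
  cols <- c(paste0("resp_", filt_feats), paste0("neural_", filt_feats))
  cols <- intersect(cols, names(rows))
  flags <- matrix(FALSE, nrow(rows), length(cols),
                  dimnames = list(NULL, cols))
  for (ch in unique(rows$channel_id)) {
    sel <- which(rows$channel_id == ch)
    if (length(sel) < 10L) {
      warning(sprintf("channel %s has fewer than 10 cycles; outlier filter skipped", ch),
              call. = FALSE)
      next
    }
    for (cl in cols) {
      v <- rows[[cl]][sel]
      thr <- stats::median(v, na.rm = TRUE) + n_sd * stats::sd(v)
      flags[sel, cl] <- !is.na(v) & v > thr
    }
  }
  keep <- rowSums(flags) == 0L
  out <- rows[keep, , drop = FALSE]
  attr(out, "outlier_flags") <- flags
  class(out) <- class(rows)
  out
}

#' @export
print.cycle_features <- function(x, ...) {
  cat(sprintf("<cycle_features> %d matched cycles, %d channel(s), %d subject(s)\n",
              nrow(x), length(unique(x$channel_id)), length(unique(x$subject_id))))
  if (nrow(x)) {
    cat(sprintf("  median resp rise/decay %.2f/%.2f s, neural rise/decay %.2f/%.2f s\n",
                stats::median(x$resp_rise_time_s), stats::median(x$resp_decay_time_s),
                stats::median(x$neural_rise_time_s), stats::median(x$neural_decay_time_s)))
  }
  invisible(x)
}
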
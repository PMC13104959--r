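#' Construct a labeled single-channel recording
#'
#' The basic container used throughout the package: one time series (a neural
#' LFP channel, a nasal airflow trace, or a respiration belt trace) with its
#' sampling rate and identity. Neural samples are in microvolts by convention;
#' respiration traces are in arbitrary transducer units.
#'
#' @param samples Numeric vector of samples. Must be finite.
#' @param fs Sampling rate in Hz (> 0).
#' @param modality One of `"neural"`, `"airflow"`, `"belt"`.
#' @param subject_id,channel_id Identifiers carried through the pipeline.
#' @param region_label Optional anatomical label (free text).
#' @return An object of class `"recording"`: a list with fields `samples`,
#'   `fs`, `modality`, `subject_id`, `channel_id`, `region_label`.
#' @export
recording <- function(samples, fs, modality = c("neural", "airflow", "belt"),
                      subject_id = "s01", channel_id = "ch01",
                      region_label = NA_character_) {
  modality <- match.arg(modality)
  if (length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop_invalid("fs must be a single positive number")
  }
  samples <- as.numeric(samples)
  if (length(samples) == 0L || anyNA(samples) || any(!is.finite(samples))) {
    stop_invalid("samples must be a non-empty finite numeric vector")
  }
  structure(
    list(samples = samples, fs = fs, modality = modality,
         subject_id = as.character(subject_id),
         channel_id = as.character(channel_id),
         region_label = region_label),
    class = "recording"
  )
}

is_recording <- function(x) inherits(x, "recording")

assert_recording <- function(x, modalities = NULL) {
  if (!is_recording(x)) stop_invalid("expected a 'recording' object")
  if (!is.null(modalities) && !(x$modality %in% modalities)) {
    stop_rs(sprintf("recording modality '%s' not allowed here (need %s)",
                    x$modality, paste(modalities, collapse = "/")),
            "rs_modality_error")
  }
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec A [recording()].
#' @return Length in seconds.
#' @export
rec_duration <- function(rec) {
  assert_recording(rec)
  length(rec$samples) / rec$fs
}

# Replace the sample vector, keeping labels and carrying over attributes
# such as the filter edge-exclusion flag.
rec_update <- function(rec, samples, fs = rec$fs) {
  out <- rec
  out$samples <- as.numeric(samples)
  out$fs <- fs
  attr(out, "edge_exclude_s") <- attr(rec, "edge_exclude_s")
  out
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s/%s (%s): %.1f s @ %g Hz\n",
              x$subject_id, x$channel_id, x$modality,
              rec_duration(x), x$fs))
  edge <- attr(x, "edge_exclude_s")
  if (!is.null(edge)) cat(sprintf("  filter edge exclusion: %g s\n", edge))
  invisible(x)
}

#' Write a recording to the package's delimited time-series format
#'
#' Plain text: `#`-prefixed header lines (`fs`, `modality`, `subject`,
#' `channel`, plus free-form provenance), then two tab-separated columns
#' `time_s` and `value`.
#'
#' @param rec A [recording()].
#' @param path Output file path.
#' @param provenance Optional character vector appended as header comments.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, provenance = character()) {
  assert_recording(rec)
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(sprintf("# fs=%.10g", rec$fs),
           sprintf("# modality=%s", rec$modality),
           sprintf("# subject=%s", rec$subject_id),
           sprintf("# channel=%s", rec$channel_id))
  if (!is.na(rec$region_label)) hdr <- c(hdr, sprintf("# region=%s", rec$region_label))
  if (length(provenance)) hdr <- c(hdr, paste("#", provenance))
  writeLines(c(hdr, "time_s\tvalue"), con)
  t <- (seq_along(rec$samples) - 1) / rec$fs
  utils::write.table(data.frame(time_s = t, value = rec$samples),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a recording from the delimited time-series format
#'
#' @param path File written by [write_recording()] (or any file with the same
#'   layout: `# key=value` headers including `fs`, then `time_s`/`value`
#'   columns).
#' @return A [recording()].
#' @export
read_recording <- function(path) {
  lines <- readLines(path, n = 50L)
  hdr_n <- sum(startsWith(lines, "#"))
  hdr <- lines[startsWith(lines, "#")]
  get_field <- function(key, default = NA_character_) {
    m <- grep(sprintf("^# %s=", key), hdr, value = TRUE)
    if (!length(m)) return(default)
    sub(sprintf("^# %s=", key), "", m[1L])
  }
  fs <- as.numeric(get_field("fs"))
  if (!is.finite(fs)) stop_invalid(sprintf("no '# fs=' header found in %s", path))
  dat <- utils::read.table(path, sep = "\t", skip = hdr_n + 1L,
                           col.names = c("time_s", "value"))
  recording(dat$value, fs,
            modality = get_field("modality", "neural"),
            subject_id = get_field("subject", "s01"),
            channel_id = get_field("channel", "ch01"),
            region_label = get_field("region"))
}
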
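#' Labeled EEG trial set
#'
#' The canonical container for segmented, labeled EEG trials: a numeric tensor
#' of `n` trials by `E` electrodes by `T` time samples (microvolts), an
#' integer class label per trial, the sampling rate, and channel/class names.
#' Labels are 0-based (values in `[0, M)` where `M = length(class_names)`),
#' matching the usual event-code arithmetic of cue-based MI paradigms.
#'
#' @param signals numeric array, `n x E x T`, in microvolts. All values must
#'   be finite.
#' @param labels integer vector of length `n` with values in `[0, M)`.
#' @param sampling_rate sampling frequency in Hz (positive scalar).
#' @param channel_names character vector of length `E`; defaults to
#'   `"ch01"..."chE"`.
#' @param class_names character vector of length `M`. `M` is taken from this
#'   argument; defaults to one name per observed label
#'   (`"class0"..."class<max>"`).
#'
#' @return An object of class `eeg_trialset`.
#' @examples
#' x <- eeg_trialset(array(rnorm(2 * 3 * 4), c(2, 3, 4)), c(0L, 1L), 250,
#'                   class_names = c("left", "right"))
#' dim(x$signals)
#' @export
eeg_trialset <- function(signals, labels, sampling_rate,
                         channel_names = NULL, class_names = NULL) {
  if (!is.array(signals) || length(dim(signals)) != 3L)
    stopf("`signals` must be a 3-d array (trials x electrodes x samples)")
  labels <- as.integer(labels)
  if (is.null(channel_names))
    channel_names <- sprintf("ch%02d", seq_len(dim(signals)[2]))
  if (is.null(class_names)) {
    m <- max(labels, 0L) + 1L
    class_names <- paste0("class", seq_len(m) - 1L)
  }
  x <- structure(
    list(signals = signals, labels = labels,
         sampling_rate = as.numeric(sampling_rate),
         channel_names = as.character(channel_names),
         class_names = as.character(class_names)),
    class = "eeg_trialset")
  validate_trialset(x)
}

#' Validate an EEG trial set
#'
#' Checks the container invariants: matching trial counts, labels in range,
#' positive sampling rate, finite signal values, and name lengths consistent
#' with the tensor dimensions.
#'
#' @param x an `eeg_trialset`.
#' @return `x`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_trialset <- function(x) {
  d <- dim(x$signals)
  if (length(x$labels) != d[1])
    stopf("validation error: %d trials but %d labels", d[1], length(x$labels))
  m <- length(x$class_names)
  if (length(x$labels) && (min(x$labels) < 0L || max(x$labels) >= m))
    stopf("validation error: labels must lie in [0, %d); found %d",
          m, if (min(x$labels) < 0L) min(x$labels) else max(x$labels))
  if (!is.finite(x$sampling_rate) || x$sampling_rate <= 0)
    stopf("validation error: sampling_rate must be a positive number")
  if (length(x$channel_names) != d[2])
    stopf("validation error: %d channel names for %d electrodes",
          length(x$channel_names), d[2])
  if (!all(is.finite(x$signals)))
    stopf("validation error: signals contain non-finite values")
  x
}

#' @export
print.eeg_trialset <- function(x, ...) {
  d <- dim(x$signals)
  cat(sprintf("<eeg_trialset> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$sampling_rate))
  tab <- table(factor(x$labels, levels = seq_along(x$class_names) - 1L,
                      labels = x$class_names))
  cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

.archive_keys <- c("signals", "labels", "sampling_rate", "channel_names",
                   "class_names")

#' Save a trial set archive
#'
#' Writes the trial set as a named-entry archive (R serialization, `.rds`)
#' with entries `signals`, `labels`, `sampling_rate`, `channel_names` and
#' `class_names`. Signal values round-trip bit-identically through
#' [load_trialset()].
#'
#' @param trialset a validated [eeg_trialset].
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
save_trialset <- function(trialset, path) {
  validate_trialset(trialset)
  payload <- unclass(trialset)[.archive_keys]
  tryCatch(saveRDS(payload, path),
           error = function(e) stopf("I/O error writing '%s': %s", path,
                                     conditionMessage(e)))
  invisible(path)
}

#' Load a trial set archive
#'
#' Reads an archive written by [save_trialset()] and returns a validated
#' [eeg_trialset]. A missing entry raises a format error naming the entry;
#' out-of-range labels raise a validation error.
#'
#' @param path file path of the archive.
#' @return An [eeg_trialset].
#' @export
load_trialset <- function(path) {
  if (!file.exists(path)) stopf("I/O error: no such file '%s'", path)
  payload <- readRDS(path)
  if (!is.list(payload)) stopf("format error: '%s' is not a trial-set archive", path)
  missing <- setdiff(.archive_keys, names(payload))
  if (length(missing))
    stopf("format error: archive is missing entry \"%s\"", missing[1])
  eeg_trialset(payload$signals, payload$labels, payload$sampling_rate,
               payload$channel_names, payload$class_names)
}

#' Crop the cue-aligned analysis window
#'
#' Extracts, from continuous per-trial recordings, the fixed-length window
#' starting at the cue: samples `[cue_onset, cue_onset + round(duration_s *
#' sampling_rate))`, 0-based and half-open. With the conventional 4-s MI
#' window at 250 Hz this yields exactly 1000 samples per trial.
#'
#' @param continuous numeric array `n x E x S` of continuous segments.
#' @param cue_onset 0-based sample index of the cue within each segment.
#' @param duration_s window length in seconds.
#' @param sampling_rate sampling frequency in Hz.
#' @return Array `n x E x round(duration_s * sampling_rate)`.
#' @export
crop_cue_window <- function(continuous, cue_onset, duration_s, sampling_rate) {
  if (!is.array(continuous) || length(dim(continuous)) != 3L)
    stopf("`continuous` must be a 3-d array (trials x electrodes x samples)")
  if (!is_count(cue_onset, min = 0L)) stopf("`cue_onset` must be a non-negative integer")
  if (duration_s < 0) stopf("`duration_s` must be non-negative")
  len <- as.integer(round(duration_s * sampling_rate))
  avail <- dim(continuous)[3]
  if (cue_onset + len > avail)
    stopf("bounds error: window [%d, %d) exceeds the %d available samples",
          cue_onset, cue_onset + len, avail)
  idx <- if (len > 0) (cue_onset + 1L):(cue_onset + len) else integer(0)
  continuous[, , idx, drop = FALSE]
}

#' Select and reorder channels
#'
#' Restricts a trial set to the named channels, in the order given — e.g.
#' dropping EOG channels from a 25-channel montage, or keeping only
#' C3/Cz/C4.
#'
#' @param trialset an [eeg_trialset].
#' @param keep character vector of channel names to retain (order preserved).
#' @return An [eeg_trialset] with `E = length(keep)`.
#' @export
select_channels <- function(trialset, keep) {
  validate_trialset(trialset)
  idx <- match(keep, trialset$channel_names)
  if (anyNA(idx))
    stopf("lookup error: unknown channel \"%s\"", keep[which(is.na(idx))[1]])
  eeg_trialset(trialset$signals[, idx, , drop = FALSE], trialset$labels,
               trialset$sampling_rate, trialset$channel_names[idx],
               trialset$class_names)
}

#' Epoch a continuous recording at cue events
#'
#' Generic event-table epoching: cuts a fixed-duration window after each cue
#' onset out of one continuous multichannel recording, producing a labeled
#' trial set. This is the step a competition-format event table drives
#' (session splits, event-code-to-class maps) once the recording is in
#' memory.
#'
#' @param continuous numeric matrix `E x S` (channels by samples).
#' @param onsets integer vector of 0-based cue-onset sample indices.
#' @param labels integer class labels (0-based), one per onset.
#' @param duration_s window length in seconds.
#' @param sampling_rate sampling frequency in Hz.
#' @param channel_names,class_names passed to [eeg_trialset()].
#' @return An [eeg_trialset] with one trial per onset.
#' @export
epoch_trials <- function(continuous, onsets, labels, duration_s, sampling_rate,
                         channel_names = NULL, class_names = NULL) {
  if (!is.matrix(continuous)) stopf("`continuous` must be an E x S matrix")
  if (length(onsets) != length(labels))
    stopf("`onsets` and `labels` must have the same length")
  len <- as.integer(round(duration_s * sampling_rate))
  ne <- nrow(continuous)
  out <- array(0, c(length(onsets), ne, len))
  for (i in seq_along(onsets)) {
    o <- as.integer(onsets[i])
    if (o < 0 || o + len > ncol(continuous))
      stopf("bounds error: window [%d, %d) exceeds the %d available samples",
            o, o + len, ncol(continuous))
    out[i, , ] <- continuous[, (o + 1L):(o + len), drop = FALSE]
  }
  eeg_trialset(out, labels, sampling_rate, channel_names, class_names)
}
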
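#' Construct an EEG trial
#'
#' An `eeg_trial` is one labeled multi-channel EEG recording: a numeric
#' matrix of `channels x samples`, its sampling rate, channel names and
#' optional class label / identifiers. It is the unit every pipeline stage
#' consumes and produces.
#'
#' @param samples Numeric matrix, channels in rows, time samples in columns.
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector of channel labels, one per row of
#'   `samples`. Defaults to `"ch1"`, `"ch2"`, ...
#' @param label Integer class index (0-based) or `NA` when unlabeled.
#' @param subject_id,trial_id Identifier strings carried through the pipeline.
#'
#' @details A trial must have at least one channel and at least `2 * fs`
#'   samples (two seconds), the minimum for a meaningful spectrogram.
#'
#' @return An object of class `eeg_trial`.
#' @export
#' @examples
#' x <- matrix(rnorm(8 * 400), nrow = 8)
#' tr <- eeg_trial(x, fs = 100, label = 0L)
#' n_channels(tr)
eeg_trial <- function(samples, fs, channel_names = NULL, label = NA_integer_,
                      subject_id = "s00", trial_id = "t00") {
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop("`samples` must be a numeric matrix (channels x time)")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive sampling rate in Hz")
  }
  if (nrow(samples) < 1L) stop("an EEG trial needs at least one channel")
  if (ncol(samples) < 2 * fs) {
    stop(sprintf("an EEG trial needs at least 2*fs = %d samples, got %d",
                 ceiling(2 * fs), ncol(samples)))
  }
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nrow(samples)))
  if (length(channel_names) != nrow(samples)) {
    stop("`channel_names` length must equal the number of channels")
  }
  storage.mode(samples) <- "double"
  rownames(samples) <- channel_names
  structure(
    list(samples = samples, fs = as.numeric(fs),
         channel_names = as.character(channel_names),
         label = if (is.na(label)) NA_integer_ else as.integer(label),
         subject_id = as.character(subject_id),
         trial_id = as.character(trial_id),
         meta = list()),
    class = "eeg_trial"
  )
}

#' @export
print.eeg_trial <- function(x, ...) {
  cat(sprintf("<eeg_trial %s> %d channels x %d samples @ %g Hz (%.1f s), label = %s\n",
              x$trial_id, nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs,
              if (is.na(x$label)) "none" else x$label))
  invisible(x)
}

#' Number of channels / samples of a trial
#' @param trial An `eeg_trial`.
#' @return Integer count.
#' @export
n_channels <- function(trial) nrow(trial$samples)

#' @rdname n_channels
#' @export
n_samples <- function(trial) ncol(trial$samples)

is_eeg_trial <- function(x) inherits(x, "eeg_trial")

stopifnot_trial <- function(trial) {
  if (!is_eeg_trial(trial)) stop("expected an `eeg_trial` object")
  invisible(trial)
}
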
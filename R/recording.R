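#' Construct a multichannel EEG recording
#'
#' The basic container used throughout the package: a channels-by-samples
#' matrix in microvolts plus its sampling rate and channel labels.
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param fs sampling rate in samples per second.
#' @param channel_labels character vector, one label per row of `data`;
#'   defaults to the standard 19-channel 10-20 montage when the channel
#'   count matches.
#' @param state_label optional name of the behavioural/sleep state
#'   (e.g. `"EO"`, `"EC"`, `"REM_stim"`, `"REM_nostim"`).
#' @param true_label_sequence optional integer vector of per-sample
#'   ground-truth microstate indices (synthetic data only).
#' @param seed optional integer recording the seed the data came from.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels = NULL, state_label = NULL,
                          true_label_sequence = NULL, seed = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(channel_labels)) {
    if (nrow(data) == 19L) channel_labels <- montage_10_20()
    else channel_labels <- paste0("ch", seq_len(nrow(data)))
  }
  if (nrow(data) != length(channel_labels))
    stop("data has ", nrow(data), " channels but ", length(channel_labels),
         " channel labels were given")
  if (ncol(data) < 1L) stop("recording must contain at least one sample")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  if (!is.null(true_label_sequence) &&
      length(true_label_sequence) != ncol(data))
    stop("true_label_sequence length must equal the sample count")
  rownames(data) <- channel_labels
  structure(
    list(data = data, fs = fs, channel_labels = as.character(channel_labels),
         state_label = state_label,
         true_label_sequence = true_label_sequence, seed = seed),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  if (!is.null(x$state_label)) cat("  state:", x$state_label, "\n")
  cat("  channels:", paste(utils::head(x$channel_labels, 8), collapse = ", "),
      if (length(x$channel_labels) > 8) "...", "\n")
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

#' Standard 19-channel 10-20 montage labels
#'
#' @return Character vector of the 19 scalp positions of the international
#'   10-20 system (mastoid references A1/A2 excluded).
#' @export
montage_10_20 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

n_samples <- function(rec) ncol(rec$data)
n_channels <- function(rec) nrow(rec$data)

#' Replace the data matrix of a recording, keeping metadata
#' @keywords internal
#' @noRd
with_data <- function(rec, data) {
  rec$data <- data
  rownames(rec$data) <- rec$channel_labels
  rec
}
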
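#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth filtering of every channel,
#' with odd-reflection padding to suppress edge transients. The default
#' 0.5-70 Hz band is the broadband conditioning applied before any other
#' analysis; zero-phase filtering is used so microstate timing is not
#' shifted.
#'
#' @param rec an `eeg_recording`.
#' @param low_hz,high_hz band corners; `0 < low_hz < high_hz < fs/2`.
#' @param order Butterworth order per pass (default 4).
#' @return A filtered `eeg_recording`.
#' @export
bandpass <- function(rec, low_hz = 0.5, high_hz = 70, order = 4L) {
  stopifnot(inherits(rec, "eeg_recording"))
  filt <- design_bandpass(low_hz, high_hz, rec$fs, order)
  # DC lies in the stopband: removing it up front avoids exciting the
  # slow high-pass transient with the channel offset
  centred <- rec$data - rowMeans(rec$data)
  with_data(rec, zerophase_mat(centred, filt, default_pad(filt)))
}

#' Zero-phase notch filter
#'
#' Narrowband rejection (second-order Butterworth band-stop, applied
#' forward-backward) at the mains frequency. The rejection bandwidth is
#' `freq_hz / quality`.
#'
#' @param rec an `eeg_recording`.
#' @param freq_hz notch centre (default 50 Hz mains).
#' @param quality quality factor (default 30).
#' @return A filtered `eeg_recording`.
#' @export
notch <- function(rec, freq_hz = 50, quality = 30) {
  stopifnot(inherits(rec, "eeg_recording"))
  filt <- design_notch(freq_hz, rec$fs, quality)
  with_data(rec, zerophase_mat(rec$data, filt, default_pad(filt)))
}

#' Re-reference a recording
#'
#' `linked_mastoids` subtracts the mean of the A1 and A2 channels from
#' every channel; `common_average` subtracts the per-sample mean over all
#' channels.
#'
#' @param rec an `eeg_recording`.
#' @param scheme `"common_average"` or `"linked_mastoids"`.
#' @param mastoid_labels labels of the two mastoid reference channels.
#' @return A re-referenced `eeg_recording`.
#' @export
rereference <- function(rec, scheme = c("common_average", "linked_mastoids"),
                        mastoid_labels = c("A1", "A2")) {
  stopifnot(inherits(rec, "eeg_recording"))
  scheme <- match.arg(scheme)
  if (scheme == "common_average") {
    ref <- colMeans(rec$data)
  } else {
    present <- mastoid_labels %in% rec$channel_labels
    if (!all(present))
      stop("missing reference channel(s) ",
           paste(mastoid_labels[!present], collapse = ", "),
           "; available: ", paste(rec$channel_labels, collapse = ", "))
    ref <- colMeans(rec$data[mastoid_labels, , drop = FALSE])
  }
  with_data(rec, sweep(rec$data, 2L, ref, "-"))
}

#' Cut a recording into fixed-length epochs
#'
#' Produces contiguous (optionally overlapping) epochs; trailing samples
#' that do not fill a whole epoch are dropped. The recording's state label
#' is propagated to every epoch.
#'
#' @param rec an `eeg_recording`.
#' @param length_s epoch length in seconds (default 2 s, non-overlapping).
#' @param overlap_s overlap between successive epochs in seconds.
#' @return An `epoch_set`: list with `epochs` (E x C x L array), `fs`,
#'   `epoch_length_s`, `labels` (per-epoch state label), `channel_labels`.
#' @export
epoch <- function(rec, length_s = 2, overlap_s = 0) {
  stopifnot(inherits(rec, "eeg_recording"))
  len <- as.integer(round(length_s * rec$fs))
  if (len < 2) stop("epoch length must cover at least 2 samples")
  if (overlap_s >= length_s) stop("overlap_s must be smaller than length_s")
  step <- len - as.integer(round(overlap_s * rec$fs))
  n <- n_samples(rec)
  if (n < len)
    stop("recording (", n, " samples) is shorter than one epoch (",
         len, " samples)")
  starts <- seq(1L, n - len + 1L, by = step)
  e <- length(starts)
  arr <- array(0, dim = c(e, n_channels(rec), len))
  for (i in seq_len(e))
    arr[i, , ] <- rec$data[, starts[i]:(starts[i] + len - 1L)]
  structure(list(epochs = arr, fs = rec$fs, epoch_length_s = length_s,
                 overlap_s = overlap_s,
                 labels = rep(rec$state_label %||% NA_character_, e),
                 starts = starts,
                 channel_labels = rec$channel_labels),
            class = "epoch_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples (%g s @ %g Hz)\n",
              d[1], d[2], d[3], x$epoch_length_s, x$fs))
  invisible(x)
}

#' Extract one canonical frequency band from a recording
#'
#' Band-pass delegation with the band's corners (see [band_definition()]).
#'
#' @param rec an `eeg_recording`.
#' @param band a `band_definition` or a band name such as `"delta"`.
#' @param order Butterworth order per pass.
#' @return A band-limited `eeg_recording`.
#' @export
extract_band <- function(rec, band, order = 4L) {
  if (is.character(band)) band <- band_definition(band)
  stopifnot(inherits(band, "band_definition"))
  bandpass(rec, band$low_hz, band$high_hz, order)
}

#' One-call signal conditioning
#'
#' Broadband band-pass, notch, and re-reference in the conventional order.
#'
#' @param rec an `eeg_recording`.
#' @param low_hz,high_hz broadband corners.
#' @param notch_hz mains frequency (`NULL` to skip).
#' @param reref re-reference scheme passed to [rereference()], or `NULL`
#'   to skip (simulated montages carry no mastoid channels, so the default
#'   is the common average).
#' @return A conditioned `eeg_recording`.
#' @export
preprocess <- function(rec, low_hz = 0.5, high_hz = 70, notch_hz = 50,
                       reref = "common_average") {
  out <- bandpass(rec, low_hz, high_hz)
  if (!is.null(notch_hz)) out <- notch(out, notch_hz)
  if (!is.null(reref)) out <- rereference(out, reref)
  out
}
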
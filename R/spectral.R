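#' Welch estimator configuration
#'
#' @param segment_length segment length M in samples (>= 8).
#' @param window taper name; `"hamming"` (default) or `"rectangular"`.
#' @param overlap overlap between segments in samples (< M); the default 0
#'   matches per-window computation on non-overlapping epochs.
#' @return A `spectral_config`.
#' @export
spectral_config <- function(segment_length, window = "hamming", overlap = 0L) {
  if (segment_length < 8) stop("segment_length must be >= 8")
  if (overlap >= segment_length) stop("overlap must be smaller than M")
  window <- match.arg(window, c("hamming", "rectangular"))
  structure(list(segment_length = as.integer(segment_length),
                 window = window, overlap = as.integer(overlap)),
            class = "spectral_config")
}

taper_values <- function(config) {
  m <- config$segment_length
  switch(config$window,
         hamming = 0.54 - 0.46 * cos(2 * pi * (0:(m - 1)) / (m - 1)),
         rectangular = rep(1, m))
}

#' Welch power spectral density
#'
#' Averaged modified periodograms: the signal is split into (optionally
#' overlapping) segments of length M, each segment is tapered by the window
#' w(n), and its periodogram |FFT|^2 / (fs * M * U) is computed, where
#' U = mean(w^2) normalizes the window power. Segment periodograms are
#' averaged and returned as a one-sided density (factor 2 off DC/Nyquist),
#' in signal-units^2 per Hz.
#'
#' @param x numeric vector, or channels x samples matrix.
#' @param fs sampling rate (Hz).
#' @param config a `spectral_config`; defaults to one segment spanning the
#'   whole input with a Hamming taper and no overlap.
#' @return A `psd_result`: `freqs` (Hz, 0..fs/2), `power`
#'   (channels x frequencies), `config`.
#' @export
welch_psd <- function(x, fs, config = NULL) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  l <- ncol(x)
  if (is.null(config)) config <- spectral_config(l)
  m <- config$segment_length
  if (l < m)
    stop("input length (", l, ") is shorter than segment length M (", m, ")")
  w <- taper_values(config)
  u <- mean(w^2)
  step <- m - config$overlap
  starts <- seq(1L, l - m + 1L, by = step)
  n_freq <- m %/% 2L + 1L
  freqs <- (0:(n_freq - 1L)) * fs / m
  power <- matrix(0, nrow(x), n_freq)
  for (s in starts) {
    seg <- x[, s:(s + m - 1L), drop = FALSE] *
      matrix(w, nrow(x), m, byrow = TRUE)
    ft <- t(apply(seg, 1L, stats::fft))
    if (nrow(seg) == 1L) ft <- matrix(stats::fft(seg[1L, ]), nrow = 1L)
    pg <- (Mod(ft[, seq_len(n_freq), drop = FALSE])^2) / (fs * m * u)
    # one-sided correction: double everything except DC (and Nyquist if M even)
    dbl <- rep(2, n_freq)
    dbl[1L] <- 1
    if (m %% 2L == 0L) dbl[n_freq] <- 1
    pg <- sweep(pg, 2L, dbl, "*")
    power <- power + pg
  }
  power <- power / length(starts)
  rownames(power) <- rownames(x)
  structure(list(freqs = freqs, power = power, config = config, fs = fs,
                 n_segments = length(starts)),
            class = "psd_result")
}

#' @export
print.psd_result <- function(x, ...) {
  cat(sprintf("<psd_result> %d channels x %d frequencies (0-%g Hz), %d segment(s)\n",
              nrow(x$power), length(x$freqs), max(x$freqs), x$n_segments))
  invisible(x)
}

#' Band power from a PSD
#'
#' Trapezoidal integral of the one-sided density over the band, per channel.
#'
#' @param psd a `psd_result`.
#' @param band a `band_definition` or band name.
#' @return Named numeric vector, one value per channel (signal-units^2).
#' @export
band_power <- function(psd, band) {
  if (is.character(band)) band <- band_definition(band)
  stopifnot(inherits(psd, "psd_result"), inherits(band, "band_definition"))
  idx <- which(psd$freqs >= band$low_hz & psd$freqs <= band$high_hz)
  if (length(idx) < 2)
    stop("band ", band$name, " (", band$low_hz, "-", band$high_hz,
         " Hz) covers fewer than 2 frequency bins at resolution ",
         psd$freqs[2] - psd$freqs[1], " Hz")
  f <- psd$freqs[idx]
  p <- psd$power[, idx, drop = FALSE]
  dt <- diff(f)
  as.numeric(p[, -length(idx), drop = FALSE] %*% dt / 2 +
               p[, -1L, drop = FALSE] %*% dt / 2) |>
    stats::setNames(rownames(psd$power))
}

#' Average several PSDs on a common frequency grid
#'
#' @param psds list of `psd_result` objects with identical `freqs`.
#' @return A `psd_result` holding the element-wise mean power.
#' @export
average_psd <- function(psds) {
  stopifnot(length(psds) >= 1L)
  f0 <- psds[[1]]$freqs
  for (p in psds)
    if (length(p$freqs) != length(f0) || any(abs(p$freqs - f0) > 1e-9))
      stop("all PSDs must share the same frequency grid")
  pow <- Reduce(`+`, lapply(psds, function(p) p$power)) / length(psds)
  out <- psds[[1]]
  out$power <- pow
  out
}
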
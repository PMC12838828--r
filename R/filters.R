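# Internal zero-phase IIR filtering helpers shared by the preprocessing and
# synthetic-data code. Band-pass filters are designed analytically as
# cascaded second-order sections (biquads): the expanded polynomial form of
# a high-order Butterworth band-pass with corners far below Nyquist is
# numerically unusable (pole clustering near z = 1 destroys stop-band
# attenuation), while biquads are exact. The notch is a low-degree
# band-stop from signal::butter, which is well conditioned. The
# forward-backward pass and odd-reflection edge padding live here because
# signal::filtfilt applies no padding and distorts epoch edges.

# Butterworth band-pass as second-order sections, via the analog lowpass
# prototype, the band transform, and the bilinear mapping with frequency
# prewarping. Returns sections (list of list(b, a)), overall gain (applied
# in the first section), and the largest pole modulus (for padding).
butter_bp_sos <- function(order, low_hz, high_hz, fs) {
  nyq <- fs / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop("band-pass corners must satisfy 0 < low (", low_hz, ") < high (",
         high_hz, ") < Nyquist (", nyq, " Hz)")
  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * low_hz / fs)             # prewarped rad/s
  w2 <- fs2 * tan(pi * high_hz / fs)
  w0 <- sqrt(w1 * w2)
  bw <- w2 - w1
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  q <- proto * bw / 2
  s_poles <- c(q + sqrt(q^2 - w0^2), q - sqrt(q^2 - w0^2))
  z_poles <- (fs2 + s_poles) / (fs2 - s_poles)
  gain <- Re(bw^order * fs2^order / prod(fs2 - s_poles))
  # group poles into conjugate (or real) pairs
  cplx <- z_poles[Im(z_poles) > 1e-10]
  real_p <- Re(z_poles[abs(Im(z_poles)) <= 1e-10])
  sections <- vector("list", order)
  si <- 0L
  for (p in cplx) {
    si <- si + 1L
    sections[[si]] <- list(b = c(1, 0, -1),
                           a = c(1, -2 * Re(p), Mod(p)^2))
  }
  if (length(real_p) > 0) {
    real_p <- sort(real_p)
    for (j in seq(1, length(real_p), by = 2)) {
      si <- si + 1L
      sections[[si]] <- list(
        b = c(1, 0, -1),
        a = c(1, -(real_p[j] + real_p[j + 1]), real_p[j] * real_p[j + 1]))
    }
  }
  sections <- sections[seq_len(si)]
  sections[[1]]$b <- sections[[1]]$b * gain
  structure(list(sections = sections,
                 max_pole = max(Mod(z_poles))),
            class = "sos_filter")
}

design_bandpass <- function(low_hz, high_hz, fs, order = 4L) {
  butter_bp_sos(order, low_hz, high_hz, fs)
}

design_notch <- function(freq_hz, fs, quality = 30) {
  nyq <- fs / 2
  if (!(freq_hz > 0 && freq_hz < nyq))
    stop("notch frequency must lie in (0, Nyquist = ", nyq, " Hz)")
  bw <- freq_hz / quality
  lo <- max(freq_hz - bw / 2, 1e-6)
  hi <- min(freq_hz + bw / 2, nyq * (1 - 1e-9))
  signal::butter(2L, c(lo, hi) / nyq, type = "stop")
}

# Single forward pass of a filter (Arma or sos_filter) over a vector.
# Each stage starts from the steady state for a constant input x[1], so
# the slow-pole startup transient is not excited by the signal offset.
filter_steady <- function(b, a, x) {
  hdc <- sum(b) / sum(a)
  nx <- length(b) - 1L
  ny <- length(a) - 1L
  as.numeric(signal::filter(b, a, x,
                            init.x = rep(x[1], nx),
                            init.y = rep(x[1] * hdc, ny)))
}

apply_filter_fwd <- function(filt, x) {
  if (inherits(filt, "sos_filter")) {
    for (s in filt$sections) x <- filter_steady(s$b, s$a, x)
    x
  } else {
    filter_steady(filt$b, filt$a, x)
  }
}

# Odd (point-symmetric) reflection padding of a numeric vector. When the
# requested pad exceeds the signal length, the reflection is continued by
# a constant level so that slow poles can fully settle before the signal
# starts (the constant start matches the steady-state filter
# initialization exactly).
reflect_pad <- function(x, pad) {
  n <- length(x)
  if (pad <= 0L) return(list(x = x, pad = 0L))
  refl <- min(pad, n - 1L)
  head_pad <- 2 * x[1] - x[seq(refl + 1L, 2L, by = -1L)]
  tail_pad <- 2 * x[n] - x[seq(n - 1L, n - refl, by = -1L)]
  extra <- pad - refl
  if (extra > 0L) {
    head_pad <- c(rep(head_pad[1], extra), head_pad)
    tail_pad <- c(tail_pad, rep(tail_pad[length(tail_pad)], extra))
  }
  list(x = c(head_pad, x, tail_pad), pad = pad)
}

# Zero-phase (forward-backward) filtering of one series.
zerophase_vec <- function(x, filt, pad) {
  p <- reflect_pad(x, pad)
  y <- apply_filter_fwd(filt, p$x)
  y <- rev(apply_filter_fwd(filt, rev(y)))
  if (p$pad > 0L) y <- y[(p$pad + 1L):(p$pad + length(x))]
  y
}

# Apply zero-phase filter to every row of a channels x samples matrix.
zerophase_mat <- function(data, filt, pad) {
  out <- t(apply(data, 1L, zerophase_vec, filt = filt, pad = pad))
  if (nrow(data) == 1L) out <- matrix(out, 1L)
  out
}

# Padding length from the slowest pole's settling time (decay to 1e-6),
# capped by the signal length inside zerophase_vec.
default_pad <- function(filt) {
  r <- if (inherits(filt, "sos_filter")) filt$max_pole
       else max(Mod(polyroot(rev(filt$a))))
  if (!is.finite(r) || r >= 1) return(10000L)
  max(24L, as.integer(ceiling(log(1e-6) / log(r))))
}

# Band-limit a white-noise vector; used by the synthetic generator.
bandlimited_noise <- function(n, low_hz, high_hz, fs) {
  x <- stats::rnorm(n)
  filt <- design_bandpass(low_hz, min(high_hz, fs / 2 * 0.99), fs)
  zerophase_vec(x, filt, default_pad(filt))
}
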
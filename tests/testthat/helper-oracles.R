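# Independent oracles used across the suite. These deliberately take
# different computational routes from the package implementations.

# Naive LZ76 exhaustive-history parser working on the string itself:
# each component is the shortest extension that is not a substring of the
# preceding text; a reproducible final word still counts.
lz76_naive <- function(bits) {
  s <- paste(bits, collapse = "")
  n <- nchar(s)
  n_components <- 0L
  pos <- 1L
  while (pos <= n) {
    len <- 1L
    while (pos + len - 1L <= n) {
      word <- substr(s, pos, pos + len - 1L)
      hist <- substr(s, 1L, pos + len - 2L)
      if (!grepl(word, hist, fixed = TRUE)) break
      len <- len + 1L
    }
    if (pos + len - 1L > n) len <- n - pos + 1L
    n_components <- n_components + 1L
    pos <- pos + len
  }
  n_components
}

# Brute-force GEV: explicit loop over maps, assigning each to its best
# prototype by squared Pearson correlation on demeaned vectors.
gev_brute <- function(prototypes, maps, gfp_at_maps) {
  num <- 0
  den <- 0
  for (i in seq_len(nrow(maps))) {
    m <- maps[i, ] - mean(maps[i, ])
    best <- 0
    for (j in seq_len(nrow(prototypes))) {
      p <- prototypes[j, ] - mean(prototypes[j, ])
      r <- sum(m * p) / sqrt(sum(m^2) * sum(p^2))
      best <- max(best, r^2)
    }
    num <- num + gfp_at_maps[i]^2 * best
    den <- den + gfp_at_maps[i]^2
  }
  num / den
}

# Brute-force segment-level transition probabilities by bigram counting.
transition_brute <- function(labels, k) {
  segs <- rle(labels)$values
  out <- matrix(0, k, k)
  if (length(segs) < 2) return(out)
  for (i in seq_len(length(segs) - 1))
    out[segs[i], segs[i + 1]] <- out[segs[i], segs[i + 1]] + 1
  for (r in seq_len(k)) if (sum(out[r, ]) > 0) out[r, ] <- out[r, ] / sum(out[r, ])
  out
}

# Exact Mann-Whitney p by enumerating group assignments, with U computed
# by direct pairwise comparison (not the rank-sum identity).
mwu_exact_brute <- function(a, b) {
  u_pairwise <- function(x, y) {
    u <- 0
    for (xi in x) for (yi in y) u <- u + (xi > yi) + 0.5 * (xi == yi)
    u
  }
  pooled <- c(a, b)
  n1 <- length(a)
  u_obs <- u_pairwise(a, b)
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(idx)
    u_pairwise(pooled[idx], pooled[-idx]))
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# Small orthogonal zero-mean unit-norm prototype set (K maps, C channels).
orthogonal_prototypes <- function(k, c, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(c * k), c, k)
    m <- sweep(m, 2, colMeans(m))     # zero-mean columns
    q <- qr.Q(qr(m))                  # orthonormal, still zero-mean
    t(q)
  })
}

# RMS amplitude of the middle half of a sinusoidal signal.
mid_amplitude <- function(x) {
  n <- length(x)
  mid <- x[floor(n / 4):ceiling(3 * n / 4)]
  sqrt(2) * sqrt(mean(mid^2))
}

# 12 s default so that narrow-band edge transients have decayed in the
# middle half where mid_amplitude measures
make_sine_recording <- function(freq, fs = 250, dur = 12, n_ch = 4,
                                amp = 1) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  data <- matrix(rep(amp * sin(2 * pi * freq * t), n_ch), n_ch,
                 byrow = TRUE)
  eeg_recording(data, fs, paste0("ch", seq_len(n_ch)))
}
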
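#' Analytic signal via the Hilbert transform
#'
#' Complex series whose real part is the input (exactly) and whose
#' imaginary part is the Hilbert transform, computed by the frequency-
#' domain method (positive frequencies doubled, negative zeroed). The
#' modulus is the instantaneous amplitude envelope.
#'
#' @param x real numeric vector, length >= 4.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 4) stop("analytic signal requires at least 4 samples")
  if (stats::sd(x) == 0)
    warning("constant input: analytic amplitude degenerates to |x - mean|")
  ft <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::fft(ft * h, inverse = TRUE) / n
  complex(real = x, imaginary = Im(z))
}

#' Binarize a series at its median
#'
#' `bit_t = 1` if the value strictly exceeds the window median, else 0.
#' Ties map to 0, and values within square-root machine precision
#' (relative to the signal scale) of the median count as ties, so a
#' numerically constant envelope binarizes to all zeros rather than to
#' floating-point noise.
#'
#' @param amplitude numeric vector (typically an analytic amplitude).
#' @return A `binary_sequence`: integer 0/1 vector with the source length.
#' @export
binarize_median <- function(amplitude) {
  if (length(amplitude) < 1) stop("empty input")
  med <- stats::median(amplitude)
  tol <- sqrt(.Machine$double.eps) * max(abs(amplitude), 1)
  bits <- as.integer(amplitude > med + tol)
  structure(list(bits = bits, n = length(bits)), class = "binary_sequence")
}

#' @export
print.binary_sequence <- function(x, ...) {
  s <- paste(utils::head(x$bits, 40), collapse = "")
  cat(sprintf("<binary_sequence> n = %d: %s%s\n", x$n, s,
              if (x$n > 40) "..." else ""))
  invisible(x)
}

as_bits <- function(b) {
  if (inherits(b, "binary_sequence")) return(b$bits)
  if (is.character(b) && length(b) == 1L) {
    bits <- as.integer(strsplit(b, "")[[1]])
  } else {
    bits <- as.integer(b)
  }
  if (length(bits) < 1 || any(is.na(bits)) || any(!bits %in% c(0L, 1L)))
    stop("input must be a non-empty binary (0/1) sequence")
  bits
}

#' Lempel-Ziv (1976) complexity
#'
#' Number of components in the exhaustive production history of a binary
#' sequence; a final word that is reproducible from the history still
#' counts as one component. The classic sequence "0001101001000101"
#' parses into 6 components.
#'
#' @param b a `binary_sequence`, a 0/1 vector, or a string such as "0011".
#' @return Integer complexity count.
#' @export
lzc <- function(b) {
  .lz76_count(as_bits(b))
}

#' Length-normalized Lempel-Ziv complexity
#'
#' `lzc(b) * log2(n) / n`, which tends to 1 for maximally irregular
#' sequences and to 0 for trivial ones as n grows, making values
#' comparable across window lengths.
#'
#' @inheritParams lzc
#' @return Scalar normalized complexity.
#' @export
lzc_normalized <- function(b) {
  bits <- as_bits(b)
  n <- length(bits)
  if (n < 2) stop("normalized LZC requires n >= 2")
  .lz76_count(bits) * log2(n) / n
}

#' Per-channel complexity of an epoch
#'
#' For every channel: analytic signal, amplitude envelope, median
#' binarization, normalized Lempel-Ziv complexity. Optionally band-filters
#' the epoch first (the clinical pipeline uses the delta band; pass
#' `band = NULL` to analyse the broadband signal).
#'
#' @param x channels x samples matrix (one epoch) or `eeg_recording`.
#' @param fs sampling rate, required when filtering a bare matrix.
#' @param band `NULL`, a band name, or a `band_definition`.
#' @return Named numeric vector of normalized LZC, one value per channel.
#' @export
epoch_lzc <- function(x, fs = NULL, band = NULL) {
  if (inherits(x, "eeg_recording")) {
    if (!is.null(band)) x <- extract_band(x, band)
    m <- x$data
  } else {
    m <- as.matrix(x)
    if (!is.null(band)) {
      if (is.null(fs)) stop("fs is required to band-filter a matrix")
      if (is.character(band)) band <- band_definition(band)
      filt <- design_bandpass(band$low_hz, band$high_hz, fs)
      m <- zerophase_mat(m, filt, default_pad(filt))
    }
  }
  out <- apply(m, 1L, function(ch)
    lzc_normalized(binarize_median(Mod(analytic_signal(ch)))))
  stats::setNames(as.numeric(out), rownames(m))
}

#' Assemble a classification feature vector
#'
#' Concatenates one microstate temporal parameter (per state) with,
#' optionally, the per-channel LZC values, in a fixed documented order:
#' first the K microstate values (by state index), then the C channel LZC
#' values (by channel order).
#'
#' @param ms a `microstate_features` object.
#' @param lzc_values named per-channel LZC vector (required for `"+lzc"`
#'   sets).
#' @param set_id one of `"duration"`, `"occurrence"`, `"coverage"`,
#'   `"mean_gfp"`, optionally suffixed `"+lzc"`, e.g. `"mean_gfp+lzc"`.
#' @param epoch_id optional identifier carried through for bookkeeping;
#'   when both `ms` and `lzc_values` carry an `epoch_id` attribute they
#'   must agree.
#' @return A named numeric `feature_vector` with attributes `set_id` and
#'   `epoch_id`.
#' @export
build_features <- function(ms, lzc_values = NULL,
                           set_id = "mean_gfp+lzc", epoch_id = NULL) {
  stopifnot(inherits(ms, "microstate_features"))
  parts <- strsplit(set_id, "+", fixed = TRUE)[[1]]
  base <- parts[1]
  with_lzc <- length(parts) == 2 && parts[2] == "lzc"
  col <- switch(base,
                duration = "duration_ms", occurrence = "occurrence_per_s",
                coverage = "coverage", mean_gfp = "mean_gfp",
                stop("unknown feature set '", set_id, "'"))
  v <- ms$per_state[[col]]
  names(v) <- paste0(base, "_state", ms$per_state$state)
  if (with_lzc) {
    if (is.null(lzc_values))
      stop("feature set '", set_id, "' requires lzc_values")
    id_ms <- attr(ms, "epoch_id"); id_lz <- attr(lzc_values, "epoch_id")
    if (!is.null(id_ms) && !is.null(id_lz) && !identical(id_ms, id_lz))
      stop("epoch id mismatch: microstate features from '", id_ms,
           "', LZC from '", id_lz, "'")
    lz <- as.numeric(lzc_values)
    names(lz) <- paste0("lzc_", names(lzc_values) %||%
                          paste0("ch", seq_along(lz)))
    v <- c(v, lz)
  }
  if (any(!is.finite(v)))
    stop("non-finite feature values")
  structure(v, set_id = set_id, epoch_id = epoch_id, class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> set '%s', length %d\n",
              attr(x, "set_id"), length(x)))
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}
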
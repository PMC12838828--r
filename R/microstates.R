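#' Global field power
#'
#' Per-sample spatial standard deviation across electrodes:
#' `GFP_t = sqrt( sum_i (x_it - xbar_t)^2 / N )`. GFP peaks mark moments of
#' maximal topographic signal-to-noise and supply the candidate maps for
#' microstate clustering.
#'
#' @param x channels x samples numeric matrix, or an `eeg_recording`.
#' @param fs sampling rate (Hz); taken from the recording when available.
#' @return A `gfp_series`: list with `values` (length-T, non-negative) and
#'   `fs`.
#' @export
gfp <- function(x, fs = NULL) {
  if (inherits(x, "eeg_recording")) {
    fs <- x$fs
    x <- x$data
  }
  x <- as.matrix(x)
  if (nrow(x) < 2)
    stop("GFP is undefined for fewer than 2 channels")
  centred <- sweep(x, 2L, colMeans(x), "-")
  structure(list(values = sqrt(colMeans(centred^2)), fs = fs),
            class = "gfp_series")
}

#' @export
print.gfp_series <- function(x, ...) {
  cat(sprintf("<gfp_series> %d samples, mean %.3g\n",
              length(x$values), mean(x$values)))
  invisible(x)
}

#' Locate GFP peaks
#'
#' Strict local maxima of the GFP curve, greedily thinned so that no two
#' retained peaks are closer than `min_separation_ms` (the larger peak
#' wins).
#'
#' @param series a `gfp_series` (or plain numeric vector).
#' @param min_separation_ms minimal separation between retained peaks (ms);
#'   0 disables thinning.
#' @param fs sampling rate, required if `series` is a bare vector.
#' @return Integer vector of peak sample indices (possibly empty).
#' @export
gfp_peaks <- function(series, min_separation_ms = 0, fs = NULL) {
  v <- if (inherits(series, "gfp_series")) series$values else as.numeric(series)
  if (is.null(fs) && inherits(series, "gfp_series")) fs <- series$fs
  n <- length(v)
  if (n < 3) stop("series must contain at least 3 samples")
  core <- v[2:(n - 1)]
  is_peak <- core > v[1:(n - 2)] & core > v[3:n]
  idx <- which(is_peak) + 1L
  if (min_separation_ms > 0 && length(idx) > 1L) {
    if (is.null(fs)) stop("fs is required when min_separation_ms > 0")
    min_sep <- min_separation_ms / 1000 * fs
    keep <- integer(0)
    for (i in idx[order(v[idx], decreasing = TRUE)]) {
      if (all(abs(keep - i) >= min_sep)) keep <- c(keep, i)
    }
    idx <- sort(keep)
  }
  idx
}

# Average-reference and unit-normalize map rows; drops all-zero maps' scale
# issues by leaving them zero.
normalize_maps <- function(maps) {
  maps <- sweep(maps, 1L, rowMeans(maps), "-")
  nrm <- sqrt(rowSums(maps^2))
  nz <- nrm > 0
  maps[nz, ] <- maps[nz, , drop = FALSE] / nrm[nz]
  maps
}

# Deterministic sign convention: the entry of largest magnitude is positive.
fix_sign <- function(map) {
  i <- which.max(abs(map))
  if (map[i] < 0) -map else map
}

# Row-wise argmax with lowest-index tie-break.
argmax_rows <- function(m) max.col(m, ties.method = "first")

#' Polarity-invariant modified k-means over topographic maps
#'
#' Clusters GFP-peak topographies into K prototype maps ignoring polarity:
#' assignment maximizes the squared spatial correlation, and each prototype
#' is updated as the dominant spatial eigenvector of its assigned maps.
#' The best of `n_init` seeded restarts by global explained variance (GEV)
#' is returned. Empty clusters are re-seeded from the worst-fitted map.
#'
#' @param maps P x C matrix of candidate topographies (rows).
#' @param k number of microstate classes (2 <= K <= P).
#' @param n_init number of random restarts (default 10).
#' @param max_iter iteration cap per restart (default 500).
#' @param seed integer seed for the restarts.
#' @param gfp_values optional length-P GFP value per map, used for the GEV
#'   weighting; computed from the raw maps when omitted.
#' @return A `microstate_model`: `prototypes` (K x C, zero-mean unit-norm
#'   rows), `k`, `gev`, `labels` (assignment of the training maps),
#'   `n_init`, `max_iter`, `seed`, `history` (per-restart GEV).
#' @export
fit_microstates <- function(maps, k, n_init = 10L, max_iter = 500L, seed = 1L,
                            gfp_values = NULL) {
  maps <- as.matrix(maps)
  p <- nrow(maps)
  if (!(p >= k && k >= 2)) stop("need P >= K >= 2 (P = ", p, ", K = ", k, ")")
  if (is.null(gfp_values))
    gfp_values <- sqrt(rowMeans(sweep(maps, 1L, rowMeans(maps), "-")^2))
  if (length(gfp_values) != p)
    stop("gfp_values must have one entry per map")
  x <- normalize_maps(maps)
  restart_seeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max %/% 2L, n_init))
  best <- NULL
  history <- numeric(n_init)
  for (r in seq_len(n_init)) {
    fit <- withr::with_seed(restart_seeds[r],
                            ms_kmeans_once(x, k, max_iter, gfp_values))
    history[r] <- fit$gev
    if (is.null(best) || fit$gev > best$gev) best <- fit
  }
  structure(list(prototypes = best$prototypes, k = as.integer(k),
                 gev = best$gev, labels = best$labels,
                 n_init = n_init, max_iter = max_iter, seed = seed,
                 n_iter = best$n_iter, history = history),
            class = "microstate_model")
}

# One seeded restart of the polarity-invariant k-means.
ms_kmeans_once <- function(x, k, max_iter, gfp_values) {
  p <- nrow(x)
  protos <- x[sample.int(p, k), , drop = FALSE]
  labels <- rep(0L, p)
  gev_prev <- -Inf
  w <- gfp_values^2
  tw <- sum(w)
  for (it in seq_len(max_iter)) {
    corr <- x %*% t(protos)             # spatial correlation (unit rows)
    new_labels <- argmax_rows(corr^2)
    for (ki in seq_len(k)) {
      assigned <- which(new_labels == ki)
      if (length(assigned) == 0L) {
        # re-seed an empty cluster from the worst-fitted map
        fit_q <- corr[cbind(seq_len(p), new_labels)]^2
        worst <- which.min(fit_q)
        protos[ki, ] <- x[worst, ]
        new_labels[worst] <- ki
        assigned <- worst
      }
      xa <- x[assigned, , drop = FALSE]
      if (length(assigned) == 1L) {
        v <- as.numeric(xa)
      } else {
        v <- svd(xa, nu = 0L, nv = 1L)$v[, 1L]
      }
      v <- v - mean(v)
      v <- v / sqrt(sum(v^2))
      protos[ki, ] <- fix_sign(v)
    }
    corr <- x %*% t(protos)
    new_labels <- argmax_rows(corr^2)
    gev_now <- sum(w * corr[cbind(seq_len(p), new_labels)]^2) / tw
    converged <- identical(new_labels, labels) ||
      abs(gev_now - gev_prev) < 1e-6 * max(gev_prev, 1e-12)
    labels <- new_labels
    gev_prev <- gev_now
    if (converged) break
  }
  list(prototypes = protos, labels = labels, gev = gev_prev, n_iter = it)
}

#' @export
print.microstate_model <- function(x, ...) {
  cat(sprintf("<microstate_model> K = %d, GEV = %.4f (%d restarts, seed %d)\n",
              x$k, x$gev, x$n_init, x$seed))
  invisible(x)
}

#' Global explained variance of a fitted model
#'
#' GFP^2-weighted mean squared spatial correlation between each map and its
#' assigned (best-matching, polarity-ignored) prototype. Lies in [0, 1];
#' 1 means every map is (anti-)proportional to a prototype.
#'
#' @param model a `microstate_model`.
#' @param maps P x C matrix of topographies.
#' @param gfp_at_maps length-P vector of GFP values at those maps.
#' @return Scalar GEV in [0, 1].
#' @export
gev <- function(model, maps, gfp_at_maps) {
  stopifnot(inherits(model, "microstate_model"))
  maps <- as.matrix(maps)
  if (length(gfp_at_maps) != nrow(maps))
    stop("gfp_at_maps must have one entry per map")
  if (sum(gfp_at_maps^2) <= 0)
    stop("total GFP is zero; GEV is undefined")
  x <- normalize_maps(maps)
  corr <- x %*% t(model$prototypes)
  best <- apply(corr^2, 1L, max)
  sum(gfp_at_maps^2 * best) / sum(gfp_at_maps^2)
}

#' Select the number of microstate classes by maximal GEV
#'
#' Fits the modified k-means for every K in `k_range` and returns the model
#' with the largest GEV; the full GEV-versus-K table is attached as
#' `gev_table`.
#'
#' @inheritParams fit_microstates
#' @param k_range candidate class counts (default 4:10).
#' @return The winning `microstate_model` with a `gev_table` data frame
#'   (`k`, `gev`) attached.
#' @export
select_n_states <- function(maps, k_range = 4:10, n_init = 10L,
                            max_iter = 500L, seed = 1L, gfp_values = NULL) {
  maps <- as.matrix(maps)
  if (any(k_range < 2) || any(k_range > min(10L, nrow(maps))))
    stop("k_range must lie within [2, min(10, P)]")
  fits <- lapply(k_range, function(k)
    fit_microstates(maps, k, n_init, max_iter, seed, gfp_values))
  gevs <- vapply(fits, function(f) f$gev, numeric(1))
  best <- fits[[which.max(gevs)]]
  best$gev_table <- data.frame(k = as.integer(k_range), gev = gevs)
  best
}

#' Backfit a microstate model to continuous data
#'
#' Assigns every sample to the prototype with maximal squared spatial
#' correlation (polarity ignored), then absorbs segments shorter than
#' `min_duration_ms` into whichever neighbouring state correlates better
#' with the segment's samples.
#'
#' @param model a `microstate_model`.
#' @param x channels x samples matrix or `eeg_recording`.
#' @param min_duration_ms smoothing threshold (default 20 ms; 0 disables).
#' @param fs sampling rate, required for smoothing when `x` is a matrix.
#' @return A `label_sequence`: `labels` (1..K per sample), `fs`, `k`.
#' @export
backfit <- function(model, x, min_duration_ms = 20, fs = NULL) {
  stopifnot(inherits(model, "microstate_model"))
  if (inherits(x, "eeg_recording")) {
    fs <- x$fs
    x <- x$data
  }
  x <- as.matrix(x)
  if (ncol(model$prototypes) != nrow(x))
    stop("channel count mismatch between model and data")
  xt <- normalize_maps(t(x))
  corr2 <- (xt %*% t(model$prototypes))^2
  labels <- argmax_rows(corr2)
  if (min_duration_ms > 0) {
    if (is.null(fs)) stop("fs is required for duration smoothing")
    min_len <- min_duration_ms / 1000 * fs
    labels <- absorb_short_segments(labels, corr2, min_len)
  }
  structure(list(labels = as.integer(labels), fs = fs,
                 k = model$k),
            class = "label_sequence")
}

# Merge segments shorter than min_len samples into the better-correlated
# neighbouring state, shortest segments first, until none remain (or a
# segment has no distinct neighbour).
absorb_short_segments <- function(labels, corr2, min_len) {
  repeat {
    segs <- segment_table(labels)
    short <- segs[segs$length < min_len, , drop = FALSE]
    if (nrow(short) == 0L || nrow(segs) == 1L) break
    s <- short[which.min(short$length), ]
    i <- which(segs$start == s$start)
    left <- if (i > 1L) segs$state[i - 1L] else NA_integer_
    right <- if (i < nrow(segs)) segs$state[i + 1L] else NA_integer_
    idx <- s$start:s$end
    score <- function(st) if (is.na(st)) -Inf else mean(corr2[idx, st])
    target <- if (score(left) >= score(right)) left else right
    if (is.na(target)) break
    labels[idx] <- target
  }
  labels
}

# Run-length segment table for an integer label vector.
segment_table <- function(labels) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  data.frame(state = r$values, start = ends - r$lengths + 1L,
             end = ends, length = r$lengths)
}

#' Segment-level microstate transition matrix
#'
#' `T[i, j]` is the probability that a segment of state `i` is followed by
#' a segment of state `j`. Self-transitions are structurally zero at the
#' segment level. Rows for states with no outgoing transition are left as
#' zeros.
#'
#' @param labels a `label_sequence` or integer vector.
#' @param k number of states (taken from the `label_sequence` if available).
#' @return K x K matrix with non-negative entries; occupied rows sum to 1.
#' @export
transition_matrix <- function(labels, k = NULL) {
  if (inherits(labels, "label_sequence")) {
    k <- k %||% labels$k
    labels <- labels$labels
  }
  k <- k %||% max(labels)
  segs <- segment_table(labels)$state
  if (length(segs) < 2L)
    stop("transition matrix requires at least 2 segments")
  counts <- matrix(0, k, k)
  for (i in seq_len(length(segs) - 1L))
    counts[segs[i], segs[i + 1L]] <- counts[segs[i], segs[i + 1L]] + 1
  rs <- rowSums(counts)
  occ <- rs > 0
  counts[occ, ] <- counts[occ, , drop = FALSE] / rs[occ]
  counts
}

#' Microstate temporal parameters
#'
#' Per-state summaries of a backfitted label sequence: mean segment
#' duration (ms), occurrence (segments per second), coverage (fraction of
#' samples), and mean GFP while the state is active, plus the segment-level
#' transition matrix. States that never occur get all-zero parameters (a
#' message notes them).
#'
#' @param labels a `label_sequence` (or integer vector plus `fs`/`k`).
#' @param gfp_series a `gfp_series` (or numeric vector) aligned with
#'   `labels`.
#' @param fs,k used when `labels` is a bare vector.
#' @return A `microstate_features` object: data frame `per_state` with
#'   columns `state`, `duration_ms`, `occurrence_per_s`, `coverage`,
#'   `mean_gfp`, and the `transition` matrix.
#' @export
temporal_parameters <- function(labels, gfp_series, fs = NULL, k = NULL) {
  if (inherits(labels, "label_sequence")) {
    fs <- fs %||% labels$fs
    k <- k %||% labels$k
    labels <- labels$labels
  }
  g <- if (inherits(gfp_series, "gfp_series")) gfp_series$values
       else as.numeric(gfp_series)
  if (length(g) != length(labels))
    stop("labels and GFP series must have equal length")
  if (is.null(fs)) stop("fs is required")
  k <- k %||% max(labels)
  segs <- segment_table(labels)
  total_s <- length(labels) / fs
  per_state <- data.frame(state = seq_len(k), duration_ms = 0,
                          occurrence_per_s = 0, coverage = 0,
                          mean_gfp = 0)
  absent <- setdiff(seq_len(k), unique(labels))
  if (length(absent) > 0L)
    message("state(s) ", paste(absent, collapse = ", "),
            " never occur; their parameters are zero")
  for (st in seq_len(k)) {
    sl <- segs$length[segs$state == st]
    if (length(sl) > 0L) {
      per_state$duration_ms[st] <- mean(sl) / fs * 1000
      per_state$occurrence_per_s[st] <- length(sl) / total_s
      per_state$coverage[st] <- sum(sl) / length(labels)
      per_state$mean_gfp[st] <- mean(g[labels == st])
    }
  }
  trans <- if (nrow(segs) >= 2L) transition_matrix(labels, k = k)
           else matrix(NA_real_, k, k)
  structure(list(per_state = per_state, transition = trans, fs = fs, k = k),
            class = "microstate_features")
}

#' @export
print.microstate_features <- function(x, ...) {
  cat("<microstate_features>\n")
  print(x$per_state, row.names = FALSE)
  invisible(x)
}
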
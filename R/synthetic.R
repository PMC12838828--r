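#' Generate prototype microstate topographies
#'
#' Draws `n_states` random scalp topographies (zero-mean across channels,
#' unit Euclidean norm) by rejection sampling so that no pair exceeds the
#' requested absolute spatial correlation. These play the role of the
#' quasi-stable microstate prototype maps that the segmentation stage is
#' expected to recover.
#'
#' @param n_states number of prototype maps (2..10).
#' @param channel_labels electrode labels (at least 4 channels).
#' @param corr_cap maximum allowed absolute pairwise spatial correlation.
#' @param seed integer seed; the output is a pure function of the arguments.
#' @return A `topography_set`: list with `maps` (n_states x channels),
#'   `channel_labels`, `corr_cap`, `seed`.
#' @export
make_topographies <- function(n_states, channel_labels, corr_cap = 0.5,
                              seed = 1L) {
  if (n_states < 2 || n_states > 10)
    stop("n_states must be between 2 and 10")
  n_ch <- length(channel_labels)
  if (n_ch < 4) stop("at least 4 channels are required")
  maps <- withr::with_seed(seed, {
    out <- matrix(0, n_states, n_ch)
    accepted <- 0L
    max_draws <- 500L * n_states
    draws <- 0L
    while (accepted < n_states) {
      draws <- draws + 1L
      if (draws > max_draws)
        stop("could not sample ", n_states, " topographies with pairwise ",
             "|correlation| <= corr_cap = ", corr_cap,
             " after ", max_draws, " draws; raise corr_cap")
      cand <- stats::rnorm(n_ch)
      cand <- cand - mean(cand)
      cand <- cand / sqrt(sum(cand^2))
      ok <- accepted == 0L ||
        all(abs(out[seq_len(accepted), , drop = FALSE] %*% cand) <= corr_cap)
      if (ok) {
        accepted <- accepted + 1L
        out[accepted, ] <- cand
      }
    }
    out
  })
  colnames(maps) <- channel_labels
  structure(list(maps = maps, channel_labels = as.character(channel_labels),
                 corr_cap = corr_cap, seed = seed),
            class = "topography_set")
}

#' Describe one simulated brain state
#'
#' A `state_spec` bundles everything that makes a simulated condition
#' distinct: per-band amplitude gains (the spectral signature), microstate
#' dwell-time distribution, microstate transition matrix, sensor noise, and
#' a complexity knob giving monotone control over broadband irregularity
#' (implemented as the fraction of unfiltered noise mixed into each
#' microstate source signal).
#'
#' @param state_name condition name, e.g. `"EO"`.
#' @param band_gains named non-negative numeric vector with entries
#'   `delta`, `theta`, `alpha`, `beta`, `gamma`.
#' @param ms_duration_ms length-2 vector: mean and jitter (SD) of the
#'   microstate dwell time in ms; the mean must lie in [20, 500].
#' @param ms_transition K x K row-stochastic matrix of segment-level
#'   microstate transition probabilities.
#' @param noise_sd additive white sensor noise SD (microvolts).
#' @param complexity_knob in [0, 1]; fraction of broadband noise in the
#'   source mixture.
#' @return A `state_spec` object.
#' @export
state_spec <- function(state_name, band_gains, ms_duration_ms, ms_transition,
                       noise_sd = 0.1, complexity_knob = 0.2) {
  bands <- names(band_table())
  if (!all(bands %in% names(band_gains)))
    stop("band_gains must name all of: ", paste(bands, collapse = ", "))
  band_gains <- band_gains[bands]
  if (any(band_gains < 0)) stop("all band gains must be >= 0")
  if (sum(band_gains) == 0) stop("at least one band gain must be positive")
  if (length(ms_duration_ms) != 2 || ms_duration_ms[1] < 20 ||
      ms_duration_ms[1] > 500 || ms_duration_ms[2] < 0)
    stop("ms_duration_ms must be c(mean, jitter) with mean in [20, 500] ms")
  ms_transition <- as.matrix(ms_transition)
  if (nrow(ms_transition) != ncol(ms_transition))
    stop("ms_transition must be square")
  if (any(ms_transition < 0) ||
      any(abs(rowSums(ms_transition) - 1) > 1e-9))
    stop("ms_transition rows must be non-negative and sum to 1 (+/- 1e-9)")
  if (complexity_knob < 0 || complexity_knob > 1)
    stop("complexity_knob must lie in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(state_name = state_name, band_gains = band_gains,
                 ms_duration_ms = as.numeric(ms_duration_ms),
                 ms_transition = ms_transition, noise_sd = noise_sd,
                 complexity_knob = complexity_knob),
            class = "state_spec")
}

uniform_offdiag_transition <- function(k) {
  m <- matrix(1 / (k - 1), k, k)
  diag(m) <- 0
  m
}

#' Default specifications of the four study conditions
#'
#' Eyes-open wakefulness (EO), eyes-closed/NREM onset (EC), REM sleep with
#' auditory stimuli (REM_stim) and REM sleep without stimuli (REM_nostim).
#' Spectral signatures follow the qualitative contrasts the analysis
#' expects: alpha power maximal during EO, delta dominant during EC, delta
#' and alpha elevated again under REM-with-stimuli and reduced once stimuli
#' stop. Broadband complexity is ordered EC < EO < REM_nostim < REM_stim.
#' Microstate dwell is 90 +/- 20 ms for every state, the middle of the
#' 60-120 ms quasi-stability range. Gains are contrasted strongly enough
#' that each state's nominally dominant band stays dominant after the
#' spectral smearing that microstate gating necessarily introduces.
#'
#' @param n_microstates number of microstate classes shared by all states.
#' @param noise_sd sensor noise SD applied to every state (microvolts).
#' @return Named list of four `state_spec` objects.
#' @export
default_state_specs <- function(n_microstates = 4L, noise_sd = 0.1) {
  tm <- uniform_offdiag_transition(n_microstates)
  g <- function(d, t, a, b, gm)
    c(delta = d, theta = t, alpha = a, beta = b, gamma = gm)
  dwell <- c(90, 20)
  list(
    EO = state_spec("EO", g(0.5, 0.35, 3.0, 0.45, 0.2), dwell, tm,
                    noise_sd, complexity_knob = 0.10),
    EC = state_spec("EC", g(1.8, 0.9, 0.7, 0.35, 0.18), dwell, tm,
                    noise_sd, complexity_knob = 0.05),
    REM_stim = state_spec("REM_stim", g(2.0, 1.0, 0.9, 0.5, 0.3), dwell,
                          tm, noise_sd, complexity_knob = 0.22),
    REM_nostim = state_spec("REM_nostim", g(0.6, 1.9, 0.45, 0.3, 0.18),
                            dwell, tm, noise_sd, complexity_knob = 0.15)
  )
}

#' Simulate a per-sample microstate label sequence
#'
#' Piecewise-constant sequence of microstate indices: dwell times are drawn
#' from a truncated normal (floor 20 ms), successors from the state's
#' transition matrix.
#'
#' @param spec a `state_spec`.
#' @param n_samples length of the sequence to produce.
#' @param fs sampling rate (Hz).
#' @param seed integer seed.
#' @return Integer vector of length `n_samples` with values in 1..K.
#' @export
simulate_label_sequence <- function(spec, n_samples, fs, seed = 1L) {
  stopifnot(inherits(spec, "state_spec"))
  if (n_samples < 1) stop("n_samples must be >= 1")
  k <- nrow(spec$ms_transition)
  mu <- spec$ms_duration_ms[1]; jit <- spec$ms_duration_ms[2]
  withr::with_seed(seed, {
    labels <- integer(n_samples)
    pos <- 1L
    state <- sample.int(k, 1L)
    while (pos <= n_samples) {
      d_ms <- max(20, stats::rnorm(1L, mu, jit))
      len <- max(1L, as.integer(round(d_ms / 1000 * fs)))
      end <- min(pos + len - 1L, n_samples)
      labels[pos:end] <- state
      pos <- end + 1L
      state <- sample.int(k, 1L, prob = spec$ms_transition[state, ])
    }
    labels
  })
}

#' Simulate one multichannel EEG recording
#'
#' Each microstate source is a standardized mixture of band-limited noise
#' components (weighted by the state's band gains) blended with broadband
#' noise according to the complexity knob; the recording is the sum over
#' microstates of prototype map x source, gated by the simulated label
#' sequence, with per-segment amplitude modulation and additive white
#' sensor noise. Ground-truth labels are carried on the result.
#'
#' @param topo a `topography_set`.
#' @param spec a `state_spec`; its transition matrix must match the number
#'   of maps in `topo`.
#' @param duration_s recording length in seconds (at least 2 s).
#' @param fs sampling rate (Hz).
#' @param seed integer seed.
#' @param amplitude_uv nominal source amplitude in microvolts.
#' @return An `eeg_recording` with `true_label_sequence` and `state_label`.
#' @export
simulate_recording <- function(topo, spec, duration_s, fs = 250, seed = 1L,
                               amplitude_uv = 10) {
  stopifnot(inherits(topo, "topography_set"), inherits(spec, "state_spec"))
  n <- as.integer(round(duration_s * fs))
  if (n < 2 * fs) stop("duration_s * fs must be at least 2 * fs samples")
  k <- nrow(topo$maps)
  if (nrow(spec$ms_transition) != k)
    stop("spec has ", nrow(spec$ms_transition), " microstates but topo has ",
         k, " maps")
  labels <- simulate_label_sequence(spec, n, fs, seed = seed)
  bands <- band_table()
  gains <- spec$band_gains
  knob <- spec$complexity_knob
  data <- withr::with_seed(seed + 1L, {
    out <- matrix(0, length(topo$channel_labels), n)
    for (ki in seq_len(k)) {
      mix <- numeric(n)
      for (b in names(bands)) {
        if (gains[[b]] <= 0) next
        comp <- bandlimited_noise(n, bands[[b]][1],
                                  min(bands[[b]][2], fs / 2 * 0.95), fs)
        mix <- mix + gains[[b]] * comp / stats::sd(comp)
      }
      mix <- mix / stats::sd(mix)
      src <- (1 - knob) * mix + knob * stats::rnorm(n)
      # per-segment amplitude modulation (mild lognormal)
      seg_id <- cumsum(c(1L, diff(labels) != 0L))
      n_seg <- seg_id[n]
      amp <- exp(stats::rnorm(n_seg, 0, 0.2))[seg_id]
      active <- labels == ki
      env <- src * amp
      env[!active] <- 0
      out <- out + outer(as.numeric(topo$maps[ki, ]), env)
    }
    out <- out * amplitude_uv
    if (spec$noise_sd > 0)
      out <- out + matrix(stats::rnorm(length(out), 0, spec$noise_sd),
                          nrow(out), ncol(out))
    out
  })
  eeg_recording(data, fs, topo$channel_labels, state_label = spec$state_name,
                true_label_sequence = labels, seed = seed)
}

#' Generator configuration for a synthetic dataset
#'
#' @param specs named list of `state_spec` objects (one per condition).
#' @param channel_labels electrode montage.
#' @param n_microstates number of prototype maps.
#' @param corr_cap topography sampling correlation cap.
#' @param duration_s per-recording length (s).
#' @param fs sampling rate (Hz).
#' @param amplitude_uv nominal source amplitude (microvolts).
#' @return A `synth_config` list.
#' @export
synth_config <- function(specs = default_state_specs(),
                         channel_labels = montage_10_20(),
                         n_microstates = 4L, corr_cap = 0.5,
                         duration_s = 60, fs = 250, amplitude_uv = 10) {
  structure(list(specs = specs, channel_labels = channel_labels,
                 n_microstates = n_microstates, corr_cap = corr_cap,
                 duration_s = duration_s, fs = fs,
                 amplitude_uv = amplitude_uv),
            class = "synth_config")
}

#' Simulate a balanced labeled dataset
#'
#' One shared topography set; `n_recordings_per_state` recordings per
#' condition, each with a sub-seed derived reproducibly from the master
#' seed.
#'
#' @param n_recordings_per_state recordings per condition (>= 1).
#' @param config a `synth_config`.
#' @param seed master integer seed.
#' @return List with `recordings` (list of `eeg_recording`), `topographies`,
#'   and `config`.
#' @export
make_dataset <- function(n_recordings_per_state, config = synth_config(),
                         seed = 1L) {
  if (n_recordings_per_state < 1)
    stop("n_recordings_per_state must be >= 1")
  topo <- make_topographies(config$n_microstates, config$channel_labels,
                            config$corr_cap, seed = seed)
  n_total <- n_recordings_per_state * length(config$specs)
  sub_seeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max %/% 2L, n_total))
  recs <- vector("list", n_total)
  i <- 0L
  for (spec in config$specs) {
    for (r in seq_len(n_recordings_per_state)) {
      i <- i + 1L
      recs[[i]] <- simulate_recording(topo, spec, config$duration_s,
                                      config$fs, seed = sub_seeds[i],
                                      amplitude_uv = config$amplitude_uv)
    }
  }
  list(recordings = recs, topographies = topo, config = config)
}
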
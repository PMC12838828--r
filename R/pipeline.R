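#' Feature-extraction pipeline: recordings to agent dataset
#'
#' For every recording: optional channel subsetting, signal conditioning
#' (broadband band-pass, notch, common-average reference), GFP-peak
#' extraction and per-recording microstate fitting, epoching, per-epoch
#' backfitting with temporal parameters, per-channel Lempel-Ziv
#' complexity, and assembly into agent observations: the epoch's GFP
#' amplitude sequence plus the chosen static feature vector.
#'
#' @param recordings list of labeled `eeg_recording` objects (all states
#'   must be represented for training).
#' @param epoch_s epoch length in seconds (default 2 s, non-overlapping).
#' @param feature_set static feature set id passed to [build_features()].
#' @param k number of microstate classes; `NULL` selects K in
#'   `k_range` by maximal GEV per recording.
#' @param k_range candidate K values when `k` is `NULL`.
#' @param n_init,max_iter clustering restarts and iteration cap.
#' @param min_duration_ms backfit smoothing threshold.
#' @param peak_separation_ms minimal GFP-peak separation.
#' @param lzc_band band for the complexity features (`NULL` = broadband;
#'   the clinical convention is `"delta"`).
#' @param channels optional channel-label subset to analyse.
#' @param bandpass_hz broadband conditioning corners.
#' @param notch_hz mains frequency (`NULL` to skip).
#' @param standardize z-score the static features across the dataset
#'   (recommended; the scaling is stored on the result as
#'   `feature_scaling`).
#' @param seed seed for the clustering restarts.
#' @return An `agent_dataset`; each example's `x` is the epoch GFP series
#'   and `static` the feature vector.
#' @export
build_agent_dataset <- function(recordings, epoch_s = 2,
                                feature_set = "mean_gfp+lzc",
                                k = 4L, k_range = 4:10,
                                n_init = 5L, max_iter = 100L,
                                min_duration_ms = 20,
                                peak_separation_ms = 10,
                                lzc_band = NULL, channels = NULL,
                                bandpass_hz = c(0.5, 70), notch_hz = 50,
                                standardize = TRUE, seed = 1L) {
  states <- vapply(recordings, function(r) r$state_label %||% NA_character_,
                   character(1))
  if (anyNA(states)) stop("all recordings must carry a state label")
  class_names <- sort(unique(states))
  xs <- list(); statics <- list(); labels <- integer(0)
  needs_lzc <- grepl("\\+lzc$", feature_set)
  for (ri in seq_along(recordings)) {
    rec <- recordings[[ri]]
    if (!is.null(channels)) {
      missing_ch <- setdiff(channels, rec$channel_labels)
      if (length(missing_ch) > 0)
        stop("unknown channel(s): ", paste(missing_ch, collapse = ", "))
      rec <- eeg_recording(rec$data[channels, , drop = FALSE], rec$fs,
                           channels, rec$state_label,
                           rec$true_label_sequence, rec$seed)
    }
    rec <- preprocess(rec, bandpass_hz[1], bandpass_hz[2], notch_hz,
                      reref = "common_average")
    g_all <- gfp(rec)
    peaks <- gfp_peaks(g_all, peak_separation_ms)
    peak_maps <- t(rec$data[, peaks, drop = FALSE])
    model <- if (is.null(k)) {
      select_n_states(peak_maps, k_range, n_init, max_iter,
                      seed = seed + ri, gfp_values = g_all$values[peaks])
    } else {
      fit_microstates(peak_maps, k, n_init, max_iter, seed = seed + ri,
                      gfp_values = g_all$values[peaks])
    }
    eps <- epoch(rec, epoch_s)
    lzc_ch <- NULL
    for (ei in seq_len(dim(eps$epochs)[1])) {
      em <- eps$epochs[ei, , ]
      g_e <- gfp(em, fs = rec$fs)
      lab <- backfit(model, em, min_duration_ms, fs = rec$fs)
      feats <- suppressMessages(temporal_parameters(lab, g_e))
      if (needs_lzc)
        lzc_ch <- epoch_lzc(em, fs = rec$fs, band = lzc_band)
      fv <- build_features(feats, lzc_ch, feature_set)
      xs[[length(xs) + 1L]] <- g_e$values
      statics[[length(statics) + 1L]] <- as.numeric(fv)
      labels <- c(labels, match(rec$state_label, class_names))
    }
  }
  scaling <- NULL
  if (standardize && length(statics) > 0) {
    st <- do.call(rbind, statics)
    mu <- colMeans(st)
    sdv <- apply(st, 2L, stats::sd)
    sdv[sdv == 0 | is.na(sdv)] <- 1
    statics <- lapply(statics, function(v) as.numeric((v - mu) / sdv))
    scaling <- list(mean = mu, sd = sdv)
  }
  out <- agent_dataset(xs, labels, statics, class_names)
  out$feature_scaling <- scaling
  out
}

#' Default channel subsets for the montage-reduction study
#'
#' Nested subsets of the 10-20 montage with sizes 19, 13, 12, 10, 7, and
#' 2, emphasising frontal and central electrodes at intermediate sizes.
#'
#' @return Named list of character vectors.
#' @export
default_channel_subsets <- function() {
  list(
    ch19 = montage_10_20(),
    ch13 = c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz",
             "C4", "T4", "Pz"),
    ch12 = c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz",
             "C4", "T4"),
    ch10 = c("Fp1", "Fp2", "F3", "Fz", "F4", "C3", "Cz", "C4", "P3", "P4"),
    ch7 = c("Fp1", "Fp2", "Fz", "C3", "Cz", "C4", "Pz"),
    ch2 = c("C3", "C4")
  )
}

#' Channel-subset ablation experiment
#'
#' Re-extracts features, retrains, and evaluates the agent for each channel
#' subset.
#'
#' @param recordings labeled recordings.
#' @param subsets named list of channel-label vectors.
#' @param cfg a `train_config`.
#' @param architecture agent architecture.
#' @param ... further arguments to [build_agent_dataset()].
#' @return List with `grid` (data frame: subset, n_channels, accuracy) and
#'   `reports` (per-subset `eval_report`s on the held-out split).
#' @export
channel_subset_experiment <- function(recordings,
                                      subsets = default_channel_subsets(),
                                      cfg = train_config(),
                                      architecture = "cnn_gru_rl", ...) {
  reports <- list()
  rows <- list()
  for (nm in names(subsets)) {
    ds <- build_agent_dataset(recordings, channels = subsets[[nm]],
                              seed = cfg$seed, ...)
    fit <- train(ds, cfg, architecture)
    rep_ <- evaluate(fit$policy, ds, cfg, idx = fit$val_idx)
    reports[[nm]] <- rep_
    rows[[nm]] <- data.frame(subset = nm,
                             n_channels = length(subsets[[nm]]),
                             accuracy = rep_$accuracy,
                             mean_reward = rep_$mean_reward)
  }
  list(grid = do.call(rbind, rows), reports = reports)
}

#' Window-length experiment
#'
#' Re-extracts features at several epoch lengths, retraining and
#' evaluating per length.
#'
#' @param recordings labeled recordings.
#' @param lengths_s epoch lengths in seconds (default
#'   `c(1, 5, 10, 20, 30, 40)`).
#' @inheritParams channel_subset_experiment
#' @return List with `grid` (length_s, n_epochs, accuracy) and `reports`.
#' @export
window_length_experiment <- function(recordings,
                                     lengths_s = c(1, 5, 10, 20, 30, 40),
                                     cfg = train_config(),
                                     architecture = "cnn_gru_rl", ...) {
  min_dur <- min(vapply(recordings, function(r) ncol(r$data) / r$fs,
                        numeric(1)))
  bad <- lengths_s[lengths_s > min_dur]
  if (length(bad) > 0)
    stop("window length(s) ", paste(bad, collapse = ", "),
         " s exceed the shortest recording (", min_dur, " s)")
  reports <- list()
  rows <- list()
  for (len in lengths_s) {
    ds <- build_agent_dataset(recordings, epoch_s = len, seed = cfg$seed,
                              ...)
    fit <- train(ds, cfg, architecture)
    rep_ <- evaluate(fit$policy, ds, cfg, idx = fit$val_idx)
    nm <- paste0("w", len)
    reports[[nm]] <- rep_
    rows[[nm]] <- data.frame(length_s = len,
                             n_epochs = length(ds$examples),
                             accuracy = rep_$accuracy,
                             mean_reward = rep_$mean_reward)
  }
  list(grid = do.call(rbind, rows), reports = reports)
}

#' End-to-end synthetic study
#'
#' Simulate a balanced four-state dataset, run the full feature pipeline,
#' train the agent, and evaluate on the held-out split.
#'
#' @param n_per_state recordings per condition.
#' @param duration_s recording length (s).
#' @param cfg a `train_config`.
#' @param synth a `synth_config`.
#' @param architecture agent architecture.
#' @param seed master seed (drives simulation, pipeline, and training).
#' @param ... further arguments to [build_agent_dataset()].
#' @return List with `report` (held-out `eval_report`), `fit`, `dataset`.
#' @export
run_end_to_end <- function(n_per_state = 5L, duration_s = 60,
                           cfg = train_config(), synth = synth_config(),
                           architecture = "cnn_gru_rl", seed = 1L, ...) {
  synth$duration_s <- duration_s
  sim <- make_dataset(n_per_state, synth, seed = seed)
  ds <- build_agent_dataset(sim$recordings, seed = seed, ...)
  cfg$seed <- seed
  fit <- train(ds, cfg, architecture)
  report <- evaluate(fit$policy, ds, cfg, idx = fit$val_idx)
  list(report = report, fit = fit, dataset = ds)
}
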
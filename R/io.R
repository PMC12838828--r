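#' Write a recording as delimited text with a JSON sidecar
#'
#' Samples are rows, channels are columns (tab-separated with a header);
#' the sidecar `<path>.json` carries the sampling rate, channel labels,
#' state label, and seed.
#'
#' @param rec an `eeg_recording`.
#' @param path output file path (e.g. `"rec.tsv"`).
#' @return `path`, invisibly.
#' @export
write_recording_text <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  m <- t(rec$data)
  colnames(m) <- rec$channel_labels
  utils::write.table(m, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  meta <- list(fs = rec$fs, channel_labels = rec$channel_labels,
               state_label = rec$state_label, seed = rec$seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a recording from delimited text + JSON sidecar
#'
#' @param path path given to [write_recording_text()].
#' @return An `eeg_recording`.
#' @export
read_recording_text <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         check.names = FALSE)
  eeg_recording(t(as.matrix(m)), meta$fs, meta$channel_labels,
                state_label = meta$state_label, seed = meta$seed)
}

pad_ascii <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write a recording in European Data Format (EDF)
#'
#' Minimal EDF writer: one-second data records, 16-bit samples scaled to
#' each channel's physical range. The sampling rate must be an integer;
#' trailing samples that do not fill a whole record are dropped (with a
#' warning). The state label, when present, is stored in the recording
#' identification field.
#'
#' @param rec an `eeg_recording`.
#' @param path output `.edf` path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF export requires an integer sampling rate")
  fs <- as.integer(round(fs))
  nc <- n_channels(rec)
  n_rec <- n_samples(rec) %/% fs
  if (n_rec < 1) stop("recording shorter than one 1-second data record")
  used <- n_rec * fs
  if (used < n_samples(rec))
    warning("dropping ", n_samples(rec) - used,
            " trailing samples that do not fill a whole data record")
  data <- rec$data[, seq_len(used), drop = FALSE]
  pmin_ <- apply(data, 1L, min); pmax_ <- apply(data, 1L, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(pad_ascii(x, width), con, width,
                                     eos = NULL)
  wr("0", 8)
  wr("X X X X", 80)
  wr(if (is.null(rec$state_label)) "Startdate X X X X"
     else paste("Startdate X X X X state:", rec$state_label), 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256L * (nc + 1L), 8)
  wr("", 44)
  wr(n_rec, 8)
  wr(1, 8)
  wr(nc, 4)
  for (lab in rec$channel_labels) wr(lab, 16)
  for (i in seq_len(nc)) wr("", 80)
  for (i in seq_len(nc)) wr("uV", 8)
  for (i in seq_len(nc)) wr(format(pmin_[i], digits = 6), 8)
  for (i in seq_len(nc)) wr(format(pmax_[i], digits = 6), 8)
  for (i in seq_len(nc)) wr(-32768L, 8)
  for (i in seq_len(nc)) wr(32767L, 8)
  for (i in seq_len(nc)) wr("", 80)
  for (i in seq_len(nc)) wr(fs, 8)
  for (i in seq_len(nc)) wr("", 32)
  scale <- 65535 / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(nc)) {
      dig <- round((data[ch, idx] - pmin_[ch]) * scale[ch]) - 32768
      dig <- pmin(32767, pmax(-32768, dig))
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read a European Data Format (EDF) file
#'
#' Reads 16-bit continuous EDF as written by [write_edf()] (and standard
#' single-rate EDF recordings generally; EDF+ annotation channels are not
#' supported).
#'
#' @param path `.edf` path.
#' @return An `eeg_recording`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)                                  # version
  rd(80)                                 # patient id
  rec_id <- rd(80)
  rd(8); rd(8)                           # date, time
  rd(8)                                  # header bytes
  rd(44)                                 # reserved
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  nc <- as.integer(rd(4))
  labels <- vapply(seq_len(nc), function(i) rd(16), character(1))
  for (i in seq_len(nc)) rd(80)          # transducer
  for (i in seq_len(nc)) rd(8)           # physical dimension
  pmin_ <- vapply(seq_len(nc), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(nc), function(i) as.numeric(rd(8)), numeric(1))
  dmin_ <- vapply(seq_len(nc), function(i) as.numeric(rd(8)), numeric(1))
  dmax_ <- vapply(seq_len(nc), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(nc)) rd(80)          # prefiltering
  spr <- vapply(seq_len(nc), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(nc)) rd(32)          # reserved
  if (length(unique(spr)) != 1L)
    stop("mixed per-channel sampling rates are not supported")
  fs <- spr[1] / dur
  data <- matrix(0, nc, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(nc)) {
      dig <- readBin(con, "integer", spr[ch], size = 2L, signed = TRUE,
                     endian = "little")
      phys <- (dig - dmin_[ch]) * (pmax_[ch] - pmin_[ch]) /
        (dmax_[ch] - dmin_[ch]) + pmin_[ch]
      data[ch, ((r - 1L) * spr[ch] + 1L):(r * spr[ch])] <- phys
    }
  }
  state <- if (grepl("state:", rec_id))
    trimws(sub(".*state:", "", rec_id)) else NULL
  eeg_recording(data, fs, labels, state_label = state)
}

#' Save a microstate model as JSON
#'
#' @param model a `microstate_model`.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_microstate_model <- function(model, path) {
  stopifnot(inherits(model, "microstate_model"))
  out <- list(prototypes = unclass(model$prototypes), k = model$k,
              gev = model$gev, n_init = model$n_init,
              max_iter = model$max_iter, seed = model$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a microstate model saved by [write_microstate_model()]
#'
#' @param path `.json` path.
#' @return A `microstate_model`.
#' @export
read_microstate_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(prototypes = as.matrix(x$prototypes), k = as.integer(x$k),
                 gev = x$gev, labels = NULL, n_init = x$n_init,
                 max_iter = x$max_iter, seed = x$seed,
                 n_iter = NA_integer_, history = NULL),
            class = "microstate_model")
}
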
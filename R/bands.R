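#' EEG frequency band definitions
#'
#' Conventional band corners used throughout the package: delta 0.5-4,
#' theta 4-7, alpha 8-12, beta 13-30, gamma 30-70 Hz. The gamma upper
#' edge matches the broadband filter's upper corner; its lower edge is a
#' package convention (the literature varies between 25 and 35 Hz).
#'
#' @param name one of `"delta"`, `"theta"`, `"alpha"`, `"beta"`, `"gamma"`.
#' @param low_hz,high_hz optional custom corners overriding the defaults.
#' @return A `band_definition` object with fields `name`, `low_hz`, `high_hz`.
#' @examples
#' band_definition("alpha")
#' band_definition("custom", 2, 30)
#' @export
band_definition <- function(name, low_hz = NULL, high_hz = NULL) {
  defaults <- band_table()
  if (is.null(low_hz) || is.null(high_hz)) {
    if (!name %in% names(defaults))
      stop("unknown band '", name, "'; known bands: ",
           paste(names(defaults), collapse = ", "),
           " (or give explicit corners)")
    corners <- defaults[[name]]
    low_hz <- corners[1]; high_hz <- corners[2]
  }
  if (!(low_hz >= 0 && low_hz < high_hz))
    stop("band corners must satisfy 0 <= low_hz < high_hz")
  structure(list(name = name, low_hz = low_hz, high_hz = high_hz),
            class = "band_definition")
}

band_table <- function() {
  list(delta = c(0.5, 4), theta = c(4, 7), alpha = c(8, 12),
       beta = c(13, 30), gamma = c(30, 70))
}

#' All default EEG bands
#' @return Named list of `band_definition` objects.
#' @export
default_bands <- function() {
  nm <- names(band_table())
  stats::setNames(lapply(nm, band_definition), nm)
}

#' @export
print.band_definition <- function(x, ...) {
  cat(sprintf("<band> %s: %g-%g Hz\n", x$name, x$low_hz, x$high_hz))
  invisible(x)
}
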
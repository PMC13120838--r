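#' Frequency band definition
#'
#' A named frequency band with its integer-bin membership convention: bins in
#' (f_low, f_high], except that a band flagged `closed_low` (by default the
#' lowest band of a set, theta) also includes f_low. This resolves edge
#' frequencies (8 Hz, 13 Hz) that are printed as belonging to two adjacent
#' bands.
#'
#' @param name band label.
#' @param f_low,f_high band edges in Hz, f_low < f_high.
#' @param closed_low include the integer bin at f_low?
#' @return object of class `band_def`.
#' @export
band_def <- function(name, f_low, f_high, closed_low = FALSE) {
  if (f_low >= f_high) stop_config("band_def: need f_low < f_high")
  structure(list(name = name, f_low = f_low, f_high = f_high,
                 closed_low = closed_low),
            class = "band_def")
}

#' Canonical band sets
#'
#' `mode = "broadband"` returns the three bands whose averages form the
#' 60 x 3 broadband decoding feature set (theta 4-8, alpha 8-13, beta 13-30);
#' `mode = "bands"` splits beta into low (13-20) and high (20-30) for the
#' band-specific analyses.
#'
#' @param mode "broadband" or "bands".
#' @return named list of `band_def`.
#' @export
default_band_defs <- function(mode = c("bands", "broadband")) {
  mode <- match.arg(mode)
  theta <- band_def("theta", 4, 8, closed_low = TRUE)
  alpha <- band_def("alpha", 8, 13)
  if (mode == "broadband") {
    list(theta = theta, alpha = alpha, beta = band_def("beta", 13, 30))
  } else {
    list(theta = theta, alpha = alpha,
         low_beta = band_def("low_beta", 13, 20),
         high_beta = band_def("high_beta", 20, 30))
  }
}

# Integer frequency bins belonging to a band under its edge convention.
band_bins <- function(band, freqs) {
  lo <- if (isTRUE(band$closed_low)) band$f_low else band$f_low + 1L
  freqs[freqs >= lo & freqs <= band$f_high]
}

# Midpoint frequency used to convert oscillatory cycles to window lengths
# (theta 6, alpha 10.5, low beta 16.5, high beta 25 Hz).
band_center <- function(band) (band$f_low + band$f_high) / 2

# Candidate cycle counts for adaptive window selection, by band.
band_cycle_range <- function(band) {
  if (band$f_high <= 13) 2:4 else 3:6
}
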
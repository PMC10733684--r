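#' Preprocessing parameters
#'
#' Parameters of the Savitzky-Golay derivative applied to every spectrum
#' before analysis: a local least-squares polynomial fit in a sliding window
#' whose analytic derivative at the window centre gives a smoothed spectral
#' derivative. Defaults follow the study protocol: window of 13 channels,
#' second-order polynomial, first derivative.
#'
#' @param window_length odd integer window width in channels (default 13).
#' @param poly_order polynomial order of the local fit (default 2).
#' @param derivative_order derivative order evaluated (default 1).
#' @return a list of class `preprocess_params`.
#' @export
preprocess_params <- function(window_length = 13L, poly_order = 2L,
                              derivative_order = 1L) {
  window_length <- as.integer(window_length)
  poly_order <- as.integer(poly_order)
  derivative_order <- as.integer(derivative_order)
  if (window_length < 3L || window_length %% 2L == 0L) {
    abort("window_length must be an odd integer >= 3, got %d", window_length)
  }
  if (poly_order >= window_length) abort("poly_order must be < window_length")
  if (derivative_order > poly_order) abort("derivative_order must be <= poly_order")
  structure(list(window_length = window_length, poly_order = poly_order,
                 derivative_order = derivative_order),
            class = "preprocess_params")
}

#' Savitzky-Golay derivative of a spectrum
#'
#' Applies Savitzky-Golay smoothing coupled with differentiation to a
#' spectrum (or to each row of a matrix of spectra). At the edges the
#' polynomial fitted to the first/last full window is evaluated at the edge
#' positions, so the output has the same length as the input and stays
#' aligned with the wavelength grid. The derivative is taken per channel
#' index (the grid is treated as evenly indexed), not per nm.
#'
#' @param x numeric vector (one spectrum) or matrix (spectra in rows).
#' @param params a [preprocess_params()] object.
#' @return object of the same shape as `x`.
#' @export
sg_first_derivative <- function(x, params = preprocess_params()) {
  stopifnot(inherits(params, "preprocess_params"))
  n_chan <- if (is.matrix(x)) ncol(x) else length(x)
  if (n_chan < params$window_length) {
    abort("spectrum has %d channels, shorter than the %d-point window",
          n_chan, params$window_length)
  }
  sg <- function(v) {
    signal::sgolayfilt(v, p = params$poly_order, n = params$window_length,
                       m = params$derivative_order)
  }
  if (is.matrix(x)) t(apply(x, 1, sg)) else sg(x)
}

#' Preprocess every spectrum of an inventory
#'
#' Applies [sg_first_derivative()] to all replicate spectra. Preprocessing
#' precedes any replicate averaging (the two commute for a linear filter,
#' but the pipeline fixes this order).
#'
#' @inheritParams drop_zero_variance_channels
#' @param params a [preprocess_params()] object.
#' @return the preprocessed inventory.
#' @export
preprocess_inventory <- function(inv, params = preprocess_params()) {
  if (nrow(inv$spectra) == 0) return(inv)
  out <- inv
  out$spectra <- sg_first_derivative(inv$spectra, params)
  out
}
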
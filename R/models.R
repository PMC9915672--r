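#' Sigmoid response-level function
#'
#' Four-parameter sigmoid used for monotonic response-level curves:
#' `y = y0 + yrange / (1 + exp((x0 - level) / dx))`.
#'
#' @param level Sound pressure level(s) in dB SPL.
#' @param y0 Offset response (dF/F units).
#' @param yrange Response range in amplitude (dF/F units).
#' @param x0 Sigmoid midpoint (dB SPL).
#' @param dx Sigmoid width (dB); must be positive.
#' @return Numeric vector of responses, one per level.
#' @seealso [gaussian_response()], [evaluate_model()]
#' @export
#' @examples
#' sigmoid_response(55, y0 = -0.12, yrange = 0.88, x0 = 55, dx = 11) # y0 + yrange/2
sigmoid_response <- function(level, y0, yrange, x0, dx) {
  stopifnot(dx > 0)
  y0 + yrange / (1 + exp((x0 - level) / dx))
}

#' Gaussian response-level function
#'
#' Four-parameter Gaussian used for nonmonotonic response-level curves:
#' `y = y0 + yrange * exp(-(level - xmean)^2 / (2 * sigma^2))`.
#'
#' @param level Sound pressure level(s) in dB SPL.
#' @param y0 Offset response (dF/F units).
#' @param yrange Peak amplitude above offset (dF/F units).
#' @param xmean Preferred sound level (dB SPL).
#' @param sigma Tuning width (dB); must be positive.
#' @return Numeric vector of responses, one per level.
#' @export
#' @examples
#' gaussian_response(50, y0 = -0.04, yrange = 0.54, xmean = 50, sigma = 13) # peak: y0 + yrange
gaussian_response <- function(level, y0, yrange, xmean, sigma) {
  stopifnot(sigma > 0)
  y0 + yrange * exp(-(level - xmean)^2 / (2 * sigma^2))
}

#' Evaluate a response-level model at given sound levels
#'
#' @param params Numeric vector of length 4. For `kind = "sigmoid"`:
#'   `(y0, yrange, x0, dx)`; for `kind = "gaussian"`:
#'   `(y0, yrange, xmean, sigma)`.
#' @param levels Sound pressure levels in dB SPL.
#' @param kind `"sigmoid"` or `"gaussian"`.
#' @return Numeric vector of model responses at `levels`.
#' @export
evaluate_model <- function(params, levels, kind = c("sigmoid", "gaussian")) {
  kind <- match.arg(kind)
  stopifnot(length(params) == 4, all(is.finite(params)))
  if (kind == "sigmoid") {
    sigmoid_response(levels, params[[1]], params[[2]], params[[3]], params[[4]])
  } else {
    gaussian_response(levels, params[[1]], params[[2]], params[[3]], params[[4]])
  }
}
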
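#' Pi-periodic Gaussian profile
#'
#' The wrapped (pi-periodic) Gaussian used throughout the hypercolumn model
#' for LGN input tuning, recurrent projection profiles and tuning-curve fits:
#' \deqn{G(\theta;\sigma) = \sum_k \exp\{-(\theta + k\pi)^2 / (2\sigma^2)\}.}
#' The sum is truncated at \eqn{|k| \le \lceil 6\sigma/\pi \rceil + 1}, which
#' keeps the neglected terms below machine precision for the widths used in
#' practice. The profile is even, pi-periodic and peak-normalized so that
#' \eqn{G(0;\sigma) = 1} up to the (tiny) wrap-around contribution.
#'
#' @param theta Orientation offset(s) in radians.
#' @param sigma Width in radians; must be positive.
#' @return Numeric vector of weights, same length as `theta`.
#' @examples
#' periodic_gaussian(0, 0.3)
#' periodic_gaussian(c(-0.5, 0.5), 0.3) # even symmetry
#' @export
periodic_gaussian <- function(theta, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    abort("`sigma` must be a single positive number (radians).", class = "ringcrf_parameter_error")
  }
  kmax <- ceiling(6 * sigma / pi) + 1
  out <- numeric(length(theta))
  for (k in seq(-kmax, kmax)) {
    out <- out + exp(-(theta + k * pi)^2 / (2 * sigma^2))
  }
  out
}

# Peak value of the circular convolution (over the half-circle, density 1/pi)
# of a projection profile G(.; sigma_ab) with an activity profile
# nu0 * G(.; sigma_b): the result is
#   nu0 * Keff * G(.; sqrt(sigma_ab^2 + sigma_b^2)),
# with Keff = sqrt(2*pi) * sigma_ab * sigma_b / (pi * sqrt(sigma_ab^2 + sigma_b^2)).
# Used to reduce the ring feedback to effective scalar couplings.
conv_peak_factor <- function(sigma_ab, sigma_b) {
  sqrt(2 * pi) * sigma_ab * sigma_b / (pi * sqrt(sigma_ab^2 + sigma_b^2))
}
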
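#' Exponential-power pollen dispersal kernel
#'
#' The two-dimensional dispersal density used throughout the package:
#' \deqn{p(x, y; a, b) = \frac{b}{2 \pi a^2 \Gamma(2/b)}
#'       \exp\{-(r/a)^b\}, \quad r = \sqrt{x^2+y^2},}
#' where `a` (meters) is the scale and `b` the shape. `b = 1` is the
#' exponential kernel, `b = 2` Gaussian, and `b < 1` fat-tailed (excess
#' long-distance dispersal). The density integrates to 1 over the plane;
#' the implied distance density is `2 pi r p(r)`.
#'
#' @param r distance(s) from the source, meters (non-negative).
#' @param a scale parameter, meters (> 0).
#' @param b shape parameter, dimensionless (> 0).
#' @return `kernel_pdf`: the 2D density at distance `r` (per square meter).
#' @export
kernel_pdf <- function(r, a, b) {
  if (any(a <= 0) || any(b <= 0)) stop("kernel parameters must be positive")
  b / (2 * pi * a^2 * gamma(2 / b)) * exp(-(r / a)^b)
}

#' @rdname kernel_pdf
#' @return `kernel_rdensity`: the density of the dispersal *distance*
#'   (per meter), `2 pi r` times the 2D density.
#' @export
kernel_rdensity <- function(r, a, b) 2 * pi * r * kernel_pdf(r, a, b)

#' @rdname kernel_pdf
#' @return `kernel_mean`: mean dispersal distance
#'   \eqn{\delta = a \Gamma(3/b) / \Gamma(2/b)}.
#' @export
kernel_mean <- function(a, b) {
  if (any(a <= 0) || any(b <= 0)) stop("kernel parameters must be positive")
  a * gamma(3 / b) / gamma(2 / b)
}

#' @rdname kernel_pdf
#' @param n number of random distances to draw.
#' @return `kernel_rdistance`: `n` random dispersal distances. Uses the fact
#'   that \eqn{(r/a)^b \sim} Gamma(2/b) under the distance density.
#' @export
kernel_rdistance <- function(n, a, b) {
  if (a <= 0 || b <= 0) stop("kernel parameters must be positive")
  a * stats::rgamma(n, shape = 2 / b, rate = 1)^(1 / b)
}
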
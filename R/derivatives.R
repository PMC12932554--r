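#' Centred finite-difference first derivative
#'
#' Estimates \eqn{f'(t_i) = [x(t_i + \theta/2) - x(t_i - \theta/2)] /
#' \theta} on a uniform grid. The half-step \eqn{\theta/2} must land
#' exactly on the sample grid, i.e. \eqn{\theta} must correspond to an even
#' number (>= 2) of sample intervals. Boundary points where the stencil
#' leaves the record are returned as `NA`. The operator is exact for affine
#' signals and second-order accurate (error \eqn{O(\theta^2)}) otherwise.
#'
#' @param x Numeric signal values on a uniform time grid (typically the
#'   smoothed signal).
#' @param dt Sample interval in seconds (1 / sample rate).
#' @param theta Derivative step \eqn{\theta} in seconds (the "time
#'   threshold").
#' @return Numeric vector of the same length; `NA` where unavailable.
#' @examples
#' t <- seq(0, 1, by = 0.01)
#' d <- first_derivative(3 * t, dt = 0.01, theta = 0.02)
#' range(d, na.rm = TRUE)  # 3 3
#' @export
first_derivative <- function(x, dt, theta) {
  m <- theta_half_steps(dt, theta)
  n <- length(x)
  if (n < 2L * m + 1L)
    stop("record too short for derivative step theta = ", theta, " s")
  d <- rep(NA_real_, n)
  i <- (m + 1L):(n - m)
  d[i] <- (x[i + m] - x[i - m]) / theta
  d
}

#' Second derivative as a composition of two centred stencils
#'
#' Applies the centred first-difference stencil to already-computed
#' first-derivative values, \eqn{f''(t_i) = [f'(t_i + \theta/2) -
#' f'(t_i - \theta/2)] / \theta}, rather than the direct three-point
#' second difference of the original signal. The composition is somewhat
#' more noise-sensitive than the classical scheme but emphasises changes
#' in curvature, which is what the peak detector keys on; it is exact for
#' quadratic signals.
#'
#' @param first_deriv Output of [first_derivative()] (may contain boundary
#'   `NA`s, which propagate).
#' @inheritParams first_derivative
#' @return Numeric vector of the same length; `NA` where unavailable.
#' @export
second_derivative <- function(first_deriv, dt, theta) {
  m <- theta_half_steps(dt, theta)
  n <- length(first_deriv)
  if (n < 2L * m + 1L)
    stop("record too short for derivative step theta = ", theta, " s")
  d <- rep(NA_real_, n)
  i <- (m + 1L):(n - m)
  d[i] <- (first_deriv[i + m] - first_deriv[i - m]) / theta
  d
}

# number of sample intervals in theta/2; validates grid alignment
theta_half_steps <- function(dt, theta) {
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0)
    stop("'theta' must be a single positive number")
  steps <- theta / (2 * dt)
  m <- round(steps)
  if (m < 1L || abs(steps - m) > 1e-6 * max(1, m))
    stop(
      "'theta' (", theta, " s) must equal an even number >= 2 of sample ",
      "intervals (dt = ", dt, " s) so the half-step lands on the grid"
    )
  as.integer(m)
}
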
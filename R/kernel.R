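#' Calibrate a seed-size-dependent exponential dispersal kernel
#'
#' Seeds of shoreline plants float downstream and are deposited on the bank
#' with a constant per-cell retention probability \eqn{\lambda}, so the
#' fraction still afloat after `d` cells is \eqn{\lambda^d}. Field data show
#' that larger seeds travel farther, with \eqn{\lambda} a sigmoidal function
#' of seed size `S` (in mm):
#' \deqn{\lambda(S) = 1 - \frac{1}{1 + e^{\alpha + \beta (S - S_{min})}}}
#' Because \eqn{\alpha} and \eqn{\beta} are not ecologically interpretable,
#' the kernel is parameterized by the median dispersal distances of the
#' smallest and largest seeds, `d05` and `d30` (in cells). The calibration
#' solves \eqn{\lambda(S_{min})^{d05} = 0.5} and
#' \eqn{\lambda(S_{max})^{d30} = 0.5}, which has the closed form
#' \eqn{\alpha = \mathrm{logit}(0.5^{1/d05})} and
#' \eqn{\beta = [\mathrm{logit}(0.5^{1/d30}) - \alpha] / (S_{max} - S_{min})}.
#'
#' @param d05 Median dispersal distance of the smallest seeds (cells); > 0.
#' @param d30 Median dispersal distance of the largest seeds (cells); > 0.
#' @param s_min,s_max Seed-size bounds in mm. Helophyte seed lengths span
#'   roughly 0.5--30 mm, the defaults.
#'
#' @return An object of class `dispersal_kernel`: a list with elements
#'   `alpha`, `beta`, `d05`, `d30`, `s_min`, `s_max`.
#' @seealso [lambda_of_size()], [median_distance()], [deposition_pmf()]
#' @examples
#' k <- dispersal_kernel(d05 = 60, d30 = 700)
#' median_distance(lambda_of_size(k, 0.5))  # 60, by construction
#' @export
dispersal_kernel <- function(d05, d30, s_min = 0.5, s_max = 30) {
  if (!is.numeric(d05) || length(d05) != 1L || !is.finite(d05) || d05 <= 0)
    abort("`d05` must be a single positive number (cells).")
  if (!is.numeric(d30) || length(d30) != 1L || !is.finite(d30) || d30 <= 0)
    abort("`d30` must be a single positive number (cells).")
  if (!(s_max > s_min)) abort("`s_max` must exceed `s_min`.")
  alpha <- logit_half_power(d05)
  beta <- (logit_half_power(d30) - alpha) / (s_max - s_min)
  structure(
    list(alpha = alpha, beta = beta, d05 = d05, d30 = d30,
         s_min = s_min, s_max = s_max),
    class = "dispersal_kernel"
  )
}

# logit(0.5^(1/d)), computed in log space so it stays accurate for large d
# (0.5^(1/d) -> 1): log(lam) = log(0.5)/d, log(1-lam) = log(-expm1(log(0.5)/d)).
logit_half_power <- function(d) {
  loglam <- log(0.5) / d
  loglam - log(-expm1(loglam))
}

#' @export
print.dispersal_kernel <- function(x, ...) {
  cat("Seed-size-dependent exponential dispersal kernel\n")
  cat(sprintf("  alpha = %.4f, beta = %.5f per mm\n", x$alpha, x$beta))
  cat(sprintf("  median distance: %.6g cells at S = %.3g mm, %.6g cells at S = %.3g mm\n",
              x$d05, x$s_min, x$d30, x$s_max))
  invisible(x)
}

#' @describeIn dispersal_kernel One-row tibble of the calibrated coefficients.
#' @param x A `dispersal_kernel`.
#' @param ... Unused.
#' @export
tidy.dispersal_kernel <- function(x, ...) {
  tibble(alpha = x$alpha, beta = x$beta, d05 = x$d05, d30 = x$d30,
         s_min = x$s_min, s_max = x$s_max)
}

#' Decay exponent for a given seed size
#'
#' Evaluates the sigmoid \eqn{\lambda(S)} of a calibrated kernel. `lambda` is
#' the per-cell retention probability of a floating seed and always lies in
#' (0, 1).
#'
#' @param kernel A [dispersal_kernel()].
#' @param size Seed size(s) in mm; must lie within `[s_min, s_max]`.
#' @return Numeric vector of decay exponents, same length as `size`.
#' @export
lambda_of_size <- function(kernel, size) {
  stopifnot(inherits(kernel, "dispersal_kernel"))
  if (any(!is.finite(size)) || any(size < kernel$s_min) || any(size > kernel$s_max))
    abort(sprintf("`size` must lie within [%g, %g] mm.", kernel$s_min, kernel$s_max))
  plogis(kernel$alpha + kernel$beta * (size - kernel$s_min))
}

# log(lambda(S)), stable for lambda near 1.
log_lambda_of_size <- function(kernel, size) {
  eta <- kernel$alpha + kernel$beta * (size - kernel$s_min)
  plogis(eta, log.p = TRUE)
}

#' Fraction of seeds still afloat after a given distance
#'
#' The water column retains a fraction \eqn{\lambda^d} of released seeds
#' beyond distance `d` (cells).
#'
#' @param lambda Decay exponent in (0, 1).
#' @param d Non-negative integer distance(s), in cells.
#' @return Retention fraction(s) in (0, 1].
#' @export
retention_fraction <- function(lambda, d) {
  check_lambda(lambda)
  if (any(d < 0)) abort("`d` must be non-negative.")
  exp(d * log(lambda))
}

#' Deposition probabilities over a bounded window
#'
#' Probability that a seed is deposited in the cell at distance `d` from its
#' parent, for `d = 0, ..., d_max - 1`, conditional on deposition within the
#' window: \eqn{(\lambda^d - \lambda^{d+1}) / (1 - \lambda^{d_{max}})}.
#' Entries are positive and sum to 1.
#'
#' @inheritParams retention_fraction
#' @param d_max Window length in cells (>= 1).
#' @return Numeric vector of length `d_max`.
#' @export
deposition_pmf <- function(lambda, d_max) {
  check_lambda(lambda)
  if (d_max < 1) abort("`d_max` must be at least 1.")
  loglam <- log(lambda)
  # lambda^d (1 - lambda) / (1 - lambda^d_max), in log space for large d
  exp(seq_len(d_max) * loglam - loglam) * (-expm1(loglam)) / (-expm1(d_max * loglam))
}

#' Median dispersal distance implied by a decay exponent
#'
#' The (real-valued) distance at which retention falls to one half:
#' \eqn{\ln 0.5 / \ln \lambda}.
#'
#' @inheritParams retention_fraction
#' @return Median distance(s) in cells.
#' @export
median_distance <- function(lambda) {
  check_lambda(lambda)
  log(0.5) / log(lambda)
}

#' Draw random dispersal distances
#'
#' Distances are geometric, \eqn{P(k) = \lambda^k (1 - \lambda)} for
#' `k = 0, 1, 2, ...` — the discretization of the exponential kernel in which
#' the probability of landing in cell `k` equals
#' `retention_fraction(lambda, k) - retention_fraction(lambda, k + 1)`.
#'
#' @inheritParams retention_fraction
#' @param n Number of draws.
#' @return Integer vector of `n` non-negative cell offsets.
#' @export
sample_dispersal_distance <- function(lambda, n = 1) {
  check_lambda(lambda)
  rgeom(n, prob = 1 - lambda)
}

check_lambda <- function(lambda) {
  if (any(!is.finite(lambda)) || any(lambda <= 0) || any(lambda >= 1))
    abort("`lambda` must lie strictly between 0 and 1.")
  invisible(lambda)
}

#' Tabulate a kernel over seed sizes
#'
#' Convenience view of a calibrated kernel: decay exponent and median
#' dispersal distance across a grid of seed sizes.
#'
#' @param kernel A [dispersal_kernel()].
#' @param sizes Seed sizes (mm); defaults to 60 points spanning the kernel's
#'   size range.
#' @return A tibble with columns `size`, `lambda`, `median_distance`.
#' @export
kernel_profile <- function(kernel, sizes = NULL) {
  if (is.null(sizes))
    sizes <- seq(kernel$s_min, kernel$s_max, length.out = 60)
  lam <- lambda_of_size(kernel, sizes)
  tibble(size = sizes, lambda = lam, median_distance = median_distance(lam))
}

#' @export
autoplot.dispersal_kernel <- function(object, ...) {
  prof <- kernel_profile(object)
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$size, y = .data$median_distance)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Seed size (mm)", y = "Median dispersal distance (cells)")
}
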
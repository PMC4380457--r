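# Model parameters and numerically stable scalar kernels.
#
# Every closed form in the package is expressed through three primitives that
# stay accurate across the critical case lambda == mu:
#   .em1r(x) = expm1(x)/x          (-> 1 as x -> 0)
#   .l1pr(x) = log1p(x)/x          (-> 1 as x -> 0)
#   growth integral G(tau) = (exp(r*tau)-1)/r = tau * .em1r(r*tau)
# so no expression ever divides by lambda - mu directly.

.em1r <- function(x) {
  out <- x
  small <- abs(x) < 1e-5
  out[!small] <- expm1(x[!small]) / x[!small]
  xs <- x[small]
  out[small] <- 1 + xs / 2 + xs^2 / 6 + xs^3 / 24
  out
}

.l1pr <- function(x) {
  out <- x
  small <- abs(x) < 1e-5
  out[!small] <- log1p(x[!small]) / x[!small]
  xs <- x[small]
  out[small] <- 1 - xs / 2 + xs^2 / 3 - xs^3 / 4
  out
}

# G(tau) for a parameter set: (e^{r tau} - 1)/r, vectorized over tau
.growth <- function(r, tau) tau * .em1r(r * tau)

#' Yule process parameters
#'
#' Bundle and validate the four parameters of a birth--death tree of fixed
#' height with Bernoulli leaf sampling: the per-lineage birth rate
#' \eqn{\lambda}, death rate \eqn{\mu}, sampling fraction \eqn{\sigma} and
#' tree height (age) \eqn{T}.  All rates are per unit time; time units are
#' arbitrary but must be consistent between rates and height.
#'
#' The object also records the net growth rate \eqn{r = \lambda - \mu} and a
#' \code{near_critical} flag, true when \eqn{|\lambda-\mu| T} is smaller than
#' \code{1e-8 * max(1, \lambda T)}.  The flag is informational: all density
#' and moment functions evaluate through limit-safe kernels and need no
#' branch switching near \eqn{\lambda = \mu}.
#'
#' @param lambda birth (speciation) rate, \eqn{\ge 0}.  Must be positive for
#'   any of the density functions to be meaningful.
#' @param mu death (extinction) rate, \eqn{\ge 0}.
#' @param sigma sampling fraction in \eqn{[0, 1]}: the probability that a
#'   leaf extant at height \eqn{T} is observed.
#' @param height tree height \eqn{T \ge 0}.
#' @return An object of class \code{"yule_params"}.
#' @examples
#' p <- yule_params(lambda = 6, mu = 3, sigma = 0.1, height = 1)
#' mean_leaves(p)
#' @export
yule_params <- function(lambda, mu = 0, sigma = 1, height) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L, is.finite(lambda),
            is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(sigma), length(sigma) == 1L, is.finite(sigma),
            is.numeric(height), length(height) == 1L, is.finite(height))
  if (lambda < 0) stop("'lambda' must be >= 0", call. = FALSE)
  if (mu < 0) stop("'mu' must be >= 0", call. = FALSE)
  if (sigma < 0 || sigma > 1) stop("'sigma' must be in [0, 1]", call. = FALSE)
  if (height < 0) stop("'height' must be >= 0", call. = FALSE)
  r <- lambda - mu
  structure(
    list(lambda = lambda, mu = mu, sigma = sigma, height = height,
         r = r,
         near_critical = abs(r) * height < 1e-8 * max(1, lambda * height)),
    class = "yule_params")
}

#' @export
print.yule_params <- function(x, ...) {
  cat(sprintf(
    "Yule parameters: lambda = %g, mu = %g, sigma = %g, height = %g (r = %g%s)\n",
    x$lambda, x$mu, x$sigma, x$height, x$r,
    if (x$near_critical) ", near-critical" else ""))
  invisible(x)
}

.check_params <- function(params, need_lambda = FALSE) {
  if (!inherits(params, "yule_params"))
    stop("'params' must be created by yule_params()", call. = FALSE)
  if (need_lambda && params$lambda <= 0)
    stop("density evaluation requires lambda > 0", call. = FALSE)
  invisible(params)
}

# same rates/sampling at a different height (used for subtree laws P(m | t/2))
.at_height <- function(params, height) {
  yule_params(params$lambda, params$mu, params$sigma, height)
}
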
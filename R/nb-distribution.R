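#' Negative binomial log-probability, mean/log-size convention
#'
#' The single place the package's NB parameterization is defined: a count
#' \eqn{y} has mean \eqn{\mu} and size (shape) \eqn{e^\sigma}, so
#' \deqn{\mathrm{Var}(y) = \mu + \mu^2 / e^{\sigma}.}
#' Larger \eqn{\sigma} means less extra-Poisson noise; \eqn{\sigma \to
#' +\infty} recovers the Poisson distribution.  Every module uses this
#' convention.
#'
#' @param y non-negative integer count(s).
#' @param mu positive mean(s).
#' @param sigma log-size parameter(s).
#' @return log-probability, vectorized over the arguments.
#' @export
nbLogPmf <- function(y, mu, sigma) {
  if (any(mu <= 0)) stop("mu must be positive")
  stats::dnbinom(y, size = exp(sigma), mu = mu, log = TRUE)
}

#' @rdname nbLogPmf
#' @param lower.tail,log.p as in [stats::pnbinom()].
#' @export
nbCdf <- function(y, mu, sigma, lower.tail = TRUE, log.p = FALSE) {
  if (any(mu <= 0)) stop("mu must be positive")
  stats::pnbinom(y, size = exp(sigma), mu = mu, lower.tail = lower.tail,
                 log.p = log.p)
}

#' @rdname nbLogPmf
#' @param p probability in `[0, 1]`.
#' @export
nbQuantile <- function(p, mu, sigma) {
  if (any(mu <= 0)) stop("mu must be positive")
  stats::qnbinom(p, size = exp(sigma), mu = mu)
}

#' Truncated negative binomial log-probability
#'
#' Renormalizes [nbLogPmf()] over the closed integer support
#' `[lower, upper]`: the log-probability is
#' `nbLogPmf(y) - log(CDF(upper) - CDF(lower - 1))`.  Bounds are
#' integer-inclusive because they come from discrete quantiles.
#'
#' @inheritParams nbLogPmf
#' @param lower,upper integer truncation bounds, `lower <= y <= upper`;
#'   `upper` may be `Inf`.
#' @return log-probability under the truncated distribution.
#' @export
truncatedNbLogPmf <- function(y, mu, sigma, lower, upper) {
  if (any(mu <= 0)) stop("mu must be positive")
  if (any(lower > upper)) stop("truncation bounds must satisfy lower <= upper")
  if (any(y < lower | y > upper)) {
    stop("y outside truncation bounds [lower, upper]")
  }
  nbLogPmf(y, mu, sigma) - .nbTruncLogZ(mu, sigma, lower, upper)
}

# log normalizing constant of the truncated support, vectorized
.nbTruncLogZ <- function(mu, sigma, lower, upper) {
  size <- exp(sigma)
  hi <- stats::pnbinom(upper, size = size, mu = mu)
  lo <- ifelse(lower > 0,
               stats::pnbinom(lower - 1, size = size, mu = mu), 0)
  # clamp: keeps log finite (and finite-difference gradients defined) when
  # an optimizer wanders into a region where the truncated mass underflows
  log(pmax(hi - lo, 1e-300))
}

# Maximum-likelihood NB fit (free mean), used by the truncation-bias study.
# Returns c(sigma, logmu); optim BFGS on the (log-size, log-mean) scale.
.nbFitMl <- function(y) {
  nll <- function(par) {
    -sum(stats::dnbinom(y, size = exp(par[1L]), mu = exp(par[2L]), log = TRUE))
  }
  init <- c(0, log(mean(y) + 0.1))
  o <- stats::optim(init, nll, method = "BFGS",
                    control = list(maxit = 500))
  list(sigma = o$par[1L], logmu = o$par[2L],
       converged = o$convergence == 0L)
}

# Right-truncated ML fit: the data were truncated at `upper` (inclusive) and
# the likelihood is renormalized accordingly.
.nbFitMlTruncated <- function(y, upper) {
  n <- length(y)
  nll <- function(par) {
    mu <- exp(par[2L])
    -sum(stats::dnbinom(y, size = exp(par[1L]), mu = mu, log = TRUE)) +
      n * .nbTruncLogZ(mu, par[1L], 0, upper)
  }
  init <- c(0, log(mean(y) + 0.1))
  o <- stats::optim(init, nll, method = "BFGS",
                    control = list(maxit = 500))
  list(sigma = o$par[1L], logmu = o$par[2L],
       converged = o$convergence == 0L)
}
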
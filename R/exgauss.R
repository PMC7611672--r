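#' The ex-Gaussian distribution
#'
#' Density, distribution function, survival function and random generation
#' for the ex-Gaussian distribution: the sum of a Gaussian with mean `mu` and
#' standard deviation `sigma` and an independent exponential with mean `tau`.
#' It is the standard positively skewed model for reaction-time data; its
#' mean is `mu + tau`.
#'
#' All functions are evaluated in log space internally so that they remain
#' numerically stable when `tau` is small relative to `sigma`.
#'
#' @param t vector of quantiles (seconds).
#' @param n number of draws.
#' @param mu,sigma,tau ex-Gaussian parameters; `sigma` and `tau` must be
#'   strictly positive. Recycled against `t`.
#' @param log,log.p logical; return log density / log probability.
#' @param lower.tail logical; if `FALSE`, `pexgauss()` returns the survival
#'   function `P(T > t)`.
#' @return numeric vector.
#' @examples
#' dexgauss(0.45, mu = 0.4, sigma = 0.05, tau = 0.1)
#' mean(rexgauss(1e4, 0.4, 0.05, 0.1))  # ~ 0.5
#' @export
dexgauss <- function(t, mu, sigma, tau, log = FALSE) {
  check_exg(sigma, tau)
  out <- exg_logpdf_cpp(as.numeric(t), as.numeric(mu),
                        as.numeric(sigma), as.numeric(tau))
  if (log) out else exp(out)
}

#' @rdname dexgauss
#' @export
pexgauss <- function(t, mu, sigma, tau, lower.tail = TRUE, log.p = FALSE) {
  check_exg(sigma, tau)
  out <- if (lower.tail) {
    exg_logcdf_cpp(as.numeric(t), as.numeric(mu),
                   as.numeric(sigma), as.numeric(tau))
  } else {
    exg_logsf_cpp(as.numeric(t), as.numeric(mu),
                  as.numeric(sigma), as.numeric(tau))
  }
  if (log.p) out else exp(out)
}

#' @rdname dexgauss
#' @export
sexgauss <- function(t, mu, sigma, tau) {
  pexgauss(t, mu, sigma, tau, lower.tail = FALSE)
}

#' @rdname dexgauss
#' @export
rexgauss <- function(n, mu, sigma, tau) {
  check_exg(sigma, tau)
  rnorm(n, mu, sigma) + rexp(n, rate = 1 / tau)
}

check_exg <- function(sigma, tau) {
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("`sigma` must be strictly positive", call. = FALSE)
  }
  if (any(!is.finite(tau)) || any(tau <= 0)) {
    stop("`tau` must be strictly positive", call. = FALSE)
  }
  invisible(TRUE)
}
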
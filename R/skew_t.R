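#' Skew-t distribution (Azzalini parameterization)
#'
#' Density and distribution function of the four-parameter skew-t family used
#' to smooth the resampled-statistic histogram into precise tail p-values:
#' location `xi`, scale `omega > 0`, slant (skewness) parameter, and degrees
#' of freedom `nu > 0`. With slant 0 this reduces to a scaled Student t, and
#' as `nu -> Inf` with slant 0 to the normal — so a normal-looking resampling
#' null is a regular point of the family, not a failure mode.
#'
#' @param x,q Quantile vector.
#' @param xi Location.
#' @param omega Scale, > 0.
#' @param slant Slant; 0 means symmetric.
#' @param nu Degrees of freedom, > 0.
#' @param log Return log density.
#' @return `dskt` the density, `pskt` the CDF (by adaptive quadrature of the
#'   density).
#' @export
dskt <- function(x, xi = 0, omega = 1, slant = 0, nu = 10, log = FALSE) {
  stopifnot(omega > 0, nu > 0)
  z <- (x - xi) / omega
  ld <- base::log(2) - base::log(omega) + dt(z, df = nu, log = TRUE) +
    pt(slant * z * sqrt((nu + 1) / (nu + z^2)), df = nu + 1, log.p = TRUE)
  if (log) ld else exp(ld)
}

#' @rdname dskt
#' @export
pskt <- function(q, xi = 0, omega = 1, slant = 0, nu = 10) {
  vapply(q, function(qq) {
    if (!is.finite(qq)) return(ifelse(qq > 0, 1, 0))
    v <- integrate(dskt, -Inf, qq, xi = xi, omega = omega, slant = slant,
                   nu = nu, rel.tol = 1e-9, abs.tol = 1e-13,
                   stop.on.error = FALSE)$value
    min(max(v, 0), 1)
  }, numeric(1))
}

#' Fit a skew-t distribution to resampled z-scores
#'
#' Maximum likelihood over (location, scale, slant, df) with moment-based
#' initialization and Nelder-Mead search on a transformed scale
#' (`log(omega)`, `log(nu - 0.5)`). Failure — degenerate input, optimizer
#' non-convergence, or non-finite parameters — is signaled via `fit_ok`
#' rather than an error, so callers can fall back to the empirical null.
#'
#' @param z_samples Numeric vector of resampled statistics (NAs dropped).
#' @param min_n Minimum number of usable samples required to attempt the fit.
#' @return List of class `skew_t_fit`: `xi`, `omega`, `slant`, `nu`,
#'   `fit_ok`, `n_used`.
#' @export
fit_skew_t <- function(z_samples, min_n = 50) {
  z <- z_samples[is.finite(z_samples)]
  n <- length(z)
  fail <- structure(list(xi = NA_real_, omega = NA_real_, slant = NA_real_,
                         nu = NA_real_, fit_ok = FALSE, n_used = n),
                    class = "skew_t_fit")
  if (n < min_n || sd(z) == 0) return(fail)
  m <- mean(z); s <- sd(z)
  g1 <- mean((z - m)^3) / s^3
  init <- c(m, base::log(s), sign(g1) * min(3 * abs(g1), 4), base::log(10 - 0.5))
  negll <- function(par) {
    omega <- exp(par[2]); nu <- 0.5 + exp(par[4])
    if (!is.finite(omega) || !is.finite(nu) || nu > 1e6) return(1e10)
    ll <- dskt(z, par[1], omega, par[3], nu, log = TRUE)
    if (any(!is.finite(ll))) return(1e10)
    -sum(ll)
  }
  opt <- tryCatch(
    optim(init, negll, method = "Nelder-Mead",
          control = list(maxit = 2000, reltol = 1e-10)),
    error = function(e) NULL)
  if (is.null(opt) || opt$convergence != 0 || any(!is.finite(opt$par))) return(fail)
  nu <- 0.5 + exp(opt$par[4])
  if (!is.finite(nu)) return(fail)
  structure(list(xi = opt$par[1], omega = exp(opt$par[2]), slant = opt$par[3],
                 nu = min(nu, 1e4), fit_ok = TRUE, n_used = n),
            class = "skew_t_fit")
}
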
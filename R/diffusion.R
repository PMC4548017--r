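#' Parameters of the large-time diffusion approximation
#'
#' The five summary statistics that determine the effective diffusion
#' constant: mean run time \eqn{\mu_\tau}, run-time variance
#' \eqn{\sigma_\tau^2}, mean rest time \eqn{\mu_\omega}, index of persistence
#' \eqn{\psi_d} and mean squared speed \eqn{S_T^2}. The rest-time variance is
#' deliberately absent: to first order the diffusion constant depends on the
#' waiting-time law only through its mean.
#'
#' @param mu_tau,mu_omega Mean run and rest durations (> 0).
#' @param sigma2_tau Run-duration variance (>= 0).
#' @param psi_d Index of persistence in `[0, 1)`.
#' @param S_T2 Mean squared speed.
#' @param n_dim Spatial dimension (default 2).
#' @return An object of class `diffusion_params`.
#' @export
diffusion_params <- function(mu_tau, sigma2_tau, mu_omega, psi_d, S_T2,
                             n_dim = 2L) {
  stopifnot(mu_tau > 0, mu_omega > 0, sigma2_tau >= 0, S_T2 >= 0, n_dim >= 1)
  if (psi_d >= 1) stop("psi_d must be < 1 for a diffusive limit to exist")
  if (psi_d < 0) stop("psi_d must be non-negative")
  structure(list(mu_tau = mu_tau, sigma2_tau = sigma2_tau,
                 mu_omega = mu_omega, psi_d = psi_d, S_T2 = S_T2,
                 n_dim = as.integer(n_dim)),
            class = "diffusion_params")
}

#' Effective diffusion constant of the velocity-jump process with rests
#'
#' Parabolic-limit diffusion constant
#' \deqn{D_{eff} = \frac{S_T^2}{n}\,\frac{\mu_\tau^2}{\mu_\tau + \mu_\omega}
#'   \left[\frac{1}{1-\psi_d}
#'   + \frac{1}{2}\left(\frac{\sigma_\tau^2}{\mu_\tau^2} - 1\right)\right].}
#' The bracketed second term is the non-Markovian correction: it vanishes for
#' exponentially distributed run times and grows with the run-time variance.
#'
#' @param p A [diffusion_params()] object.
#' @return Scalar `D_eff` (length^2/time).
#' @export
effective_diffusion <- function(p) {
  stopifnot(inherits(p, "diffusion_params"))
  (p$S_T2 / p$n_dim) * p$mu_tau^2 / (p$mu_tau + p$mu_omega) *
    (1 / (1 - p$psi_d) + 0.5 * (p$sigma2_tau / p$mu_tau^2 - 1))
}

#' Large-time MSD growth rate \eqn{2 n D_{eff}}
#'
#' The asymptotic slope of the mean squared displacement, the quantity that
#' is read off empirical MSD curves (e.g. 12.5 um^2/s for the E. coli data
#' set, 4.7e4 km^2/day predicted for the gull data set).
#'
#' @inheritParams effective_diffusion
#' @export
msd_slope <- function(p) {
  2 * p$n_dim * effective_diffusion(p)
}

#' Diffusion parameters from model ingredients
#'
#' Extracts \eqn{(\mu_\tau, \sigma_\tau^2, \mu_\omega, \psi_d, S_T^2)} from
#' duration laws plus either a [turning_kernel()] (from which the persistence
#' index and mean squared speed are computed) or explicitly supplied `psi_d`
#' and `S_T2` values (as when they come straight from data).
#'
#' @param run,rest [time_dist()] duration laws; the run law needs finite
#'   first and second moments, the rest law a finite mean.
#' @param turning Optional [turning_kernel()].
#' @param psi_d,S_T2 Explicit overrides (required if `turning` is absent).
#' @param n_dim Spatial dimension.
#' @return A [diffusion_params()] object.
#' @export
from_model <- function(run, rest, turning = NULL, psi_d = NULL, S_T2 = NULL,
                       n_dim = 2L) {
  stopifnot(inherits(run, "time_dist"), inherits(rest, "time_dist"))
  if (!is.null(turning)) {
    stopifnot(inherits(turning, "turning_kernel"))
    if (is.null(psi_d)) psi_d <- persistence_index(turning)
    if (is.null(S_T2)) S_T2 <- speed_msq(turning$speed)
  }
  if (is.null(psi_d) || is.null(S_T2)) {
    stop("supply either a turning kernel or explicit psi_d and S_T2")
  }
  mt <- dist_moments(run)
  mw <- dist_moments(rest)
  diffusion_params(mu_tau = mt$mean, sigma2_tau = mt$variance,
                   mu_omega = mw$mean, psi_d = psi_d, S_T2 = S_T2,
                   n_dim = n_dim)
}

#' @export
print.diffusion_params <- function(x, ...) {
  cat("<diffusion_params> mu_tau = ", format(x$mu_tau),
      ", sigma2_tau = ", format(x$sigma2_tau),
      ", mu_omega = ", format(x$mu_omega),
      ", psi_d = ", format(x$psi_d),
      ", S_T2 = ", format(x$S_T2), ", n = ", x$n_dim, "\n",
      "  D_eff = ", format(effective_diffusion(x)),
      "  (MSD slope 2nD = ", format(msd_slope(x)), ")\n", sep = "")
  invisible(x)
}

#' Planar heat-kernel reference density
#'
#' Fundamental solution of the effective diffusion equation on the plane for
#' a point mass of `N0` particles released at the origin:
#' \eqn{N_0 (4\pi D t)^{-1} \exp(-\|x\|^2 / 4Dt)}. Used as the reference for
#' cross-sections of long-time simulated position densities.
#'
#' @param x,y Coordinates (vectorised).
#' @param t Time (> 0).
#' @param D Diffusion constant (> 0).
#' @param N0 Total mass (default 1).
#' @return Density values.
#' @export
heat_kernel_2d <- function(x, y = 0, t, D, N0 = 1) {
  if (any(t <= 0)) stop("t must be positive")
  if (any(D <= 0)) stop("D must be positive")
  N0 / (4 * pi * D * t) * exp(-(x^2 + y^2) / (4 * D * t))
}
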
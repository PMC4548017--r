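#' Run- and rest-duration distributions
#'
#' Construct a duration law for running or resting phases of the velocity-jump
#' process. Three families are supported, each with a closed-form Laplace
#' transform: exponential (rate \eqn{\beta}, mean \eqn{1/\beta}), gamma
#' (shape \eqn{k}, scale \eqn{\theta}) and inverse Gaussian (mean \eqn{\mu},
#' shape \eqn{\lambda_s}).
#'
#' @param family One of `"exp"`, `"gamma"`, `"invgauss"` (aliases
#'   `"exponential"`, `"inverse_gaussian"` accepted).
#' @param ... Family parameters: `rate` for exponential; `shape` and `scale`
#'   for gamma; `mean` and `shape` for inverse Gaussian. All must be strictly
#'   positive. Unnamed arguments are taken in the order just given.
#' @return An object of class `time_dist`.
#' @examples
#' time_dist("exp", rate = 2.30)
#' time_dist("gamma", shape = 1/7, scale = 7)
#' time_dist("invgauss", mean = 1.26, shape = 1.22)
#' @export
time_dist <- function(family, ...) {
  family <- switch(tolower(family),
    exp = , exponential = "exp",
    gamma = "gamma",
    invgauss = , inverse_gaussian = , ig = "invgauss",
    stop("unknown duration family: ", family)
  )
  args <- list(...)
  expected <- switch(family,
    exp = "rate",
    gamma = c("shape", "scale"),
    invgauss = c("mean", "shape")
  )
  if (is.null(names(args)) || all(names(args) == "")) {
    names(args) <- expected[seq_along(args)]
  }
  if (!setequal(names(args), expected)) {
    stop(sprintf("family '%s' needs parameters: %s", family,
                 paste(expected, collapse = ", ")))
  }
  params <- vapply(args[expected], function(p) as.numeric(p)[1], numeric(1))
  if (any(!is.finite(params)) || any(params <= 0)) {
    stop("all distribution parameters must be strictly positive and finite")
  }
  structure(list(family = family, params = as.list(params)),
            class = "time_dist")
}

#' @export
print.time_dist <- function(x, ...) {
  cat("<time_dist> ", format(x), "\n", sep = "")
  m <- dist_moments(x)
  cat("  mean = ", format(m$mean), ", variance = ", format(m$variance),
      "\n", sep = "")
  invisible(x)
}

#' @export
format.time_dist <- function(x, ...) {
  paste0(x$family, ":", paste(vapply(x$params, format, character(1),
                                     digits = 17), collapse = ","))
}

#' Parse a `family:param1,param2` distribution specification
#'
#' Inverse of [format.time_dist()]; round trips are bit-exact because
#' formatting uses 17 significant digits.
#'
#' @param spec A string such as `"exp:2.30"`, `"gamma:0.2,2.5"` or
#'   `"invgauss:1.26,1.22"`.
#' @return A [time_dist()] object.
#' @export
parse_dist <- function(spec) {
  stopifnot(is.character(spec), length(spec) == 1)
  parts <- strsplit(trimws(spec), ":", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("distribution spec must look like 'family:p1,p2'")
  vals <- as.numeric(strsplit(parts[2], ",", fixed = TRUE)[[1]])
  if (any(is.na(vals))) stop("could not parse numeric parameters in: ", spec)
  do.call(time_dist, c(list(parts[1]), as.list(vals)))
}

# inverse-Gaussian density/cdf/sampler; no installed package provides these
dinvgauss <- function(t, mean, shape) {
  out <- numeric(length(t))
  ok <- t > 0
  tt <- t[ok]
  out[ok] <- sqrt(shape / (2 * pi * tt^3)) *
    exp(-shape * (tt - mean)^2 / (2 * mean^2 * tt))
  out
}

pinvgauss <- function(q, mean, shape) {
  out <- numeric(length(q))
  ok <- q > 0
  qq <- q[ok]
  a <- sqrt(shape / qq)
  out[ok] <- stats::pnorm(a * (qq / mean - 1)) +
    exp(2 * shape / mean) * stats::pnorm(-a * (qq / mean + 1))
  out
}

# Michael, Schucany & Haas transformation sampler
rinvgauss <- function(n, mean, shape) {
  y <- stats::rnorm(n)^2
  x <- mean + mean^2 * y / (2 * shape) -
    mean / (2 * shape) * sqrt(4 * mean * shape * y + mean^2 * y^2)
  u <- stats::runif(n)
  ifelse(u <= mean / (mean + x), x, mean^2 / x)
}

#' Probability density of a duration law
#'
#' @param dist A [time_dist()].
#' @param t Vector of times, all `>= 0`.
#' @return Density values `f(t)`.
#' @export
dist_pdf <- function(dist, t) {
  stopifnot(inherits(dist, "time_dist"))
  if (any(t < 0)) stop("t must be non-negative")
  p <- dist$params
  switch(dist$family,
    exp = stats::dexp(t, rate = p$rate),
    gamma = stats::dgamma(t, shape = p$shape, scale = p$scale),
    invgauss = dinvgauss(t, p$mean, p$shape)
  )
}

#' Cumulative distribution of a duration law
#'
#' @inheritParams dist_pdf
#' @param q Vector of times.
#' @return `P(T <= q)`.
#' @export
dist_cdf <- function(dist, q) {
  stopifnot(inherits(dist, "time_dist"))
  p <- dist$params
  switch(dist$family,
    exp = stats::pexp(q, rate = p$rate),
    gamma = stats::pgamma(q, shape = p$shape, scale = p$scale),
    invgauss = pinvgauss(q, p$mean, p$shape)
  )
}

#' Laplace transform of a duration pdf, with analytic derivatives
#'
#' Closed forms: exponential \eqn{\beta/(\beta+\lambda)}; gamma
#' \eqn{(1+\theta\lambda)^{-k}}; inverse Gaussian
#' \eqn{\exp\{(\lambda_s/\mu)(1 - \sqrt{1 + 2\mu^2\lambda/\lambda_s})\}}
#' with the principal square root. Derivatives up to second order are exact.
#'
#' @inheritParams dist_pdf
#' @param lam Real or complex Laplace variable(s); contour points with
#'   negative real part are allowed as long as the gamma/inverse-Gaussian
#'   branch point is not crossed on the negative real axis.
#' @param deriv Derivative order 0, 1 or 2 with respect to `lam`.
#' @return Complex (or real, for real non-negative `lam`) transform values.
#' @export
dist_laplace <- function(dist, lam, deriv = 0) {
  stopifnot(inherits(dist, "time_dist"), deriv %in% 0:2)
  p <- dist$params
  realin <- is.numeric(lam) && all(lam >= 0)
  lam <- as.complex(lam)
  out <- switch(dist$family,
    exp = {
      b <- p$rate
      switch(as.character(deriv),
        "0" = b / (b + lam),
        "1" = -b / (b + lam)^2,
        "2" = 2 * b / (b + lam)^3
      )
    },
    gamma = {
      k <- p$shape; th <- p$scale
      z <- 1 + th * lam
      bad <- Re(z) <= 0 & abs(Im(z)) < 1e-12 * (1 + abs(Re(z)))
      if (any(bad)) {
        stop("gamma Laplace transform evaluated on its branch cut (1 + scale*lambda on the negative real axis)")
      }
      switch(as.character(deriv),
        "0" = z^(-k),
        "1" = -k * th * z^(-k - 1),
        "2" = k * (k + 1) * th^2 * z^(-k - 2)
      )
    },
    invgauss = {
      mu <- p$mean; ls <- p$shape
      z <- 1 + 2 * mu^2 * lam / ls
      bad <- Re(z) <= 0 & abs(Im(z)) < 1e-12 * (1 + abs(Re(z)))
      if (any(bad)) {
        stop("inverse-Gaussian Laplace transform evaluated on its branch cut")
      }
      sq <- sqrt(z)
      f <- exp((ls / mu) * (1 - sq))
      g1 <- -mu / sq            # d/dlam of the exponent
      g2 <- mu * (mu^2 / ls) / sq^3
      switch(as.character(deriv),
        "0" = f,
        "1" = g1 * f,
        "2" = (g2 + g1^2) * f
      )
    }
  )
  if (realin) Re(out) else out
}

#' Mean and variance of a duration law
#'
#' Closed forms: exponential \eqn{(1/\beta, 1/\beta^2)}; gamma
#' \eqn{(k\theta, k\theta^2)}; inverse Gaussian \eqn{(\mu, \mu^3/\lambda_s)}.
#'
#' @inheritParams dist_pdf
#' @return A list with elements `mean` and `variance`.
#' @export
dist_moments <- function(dist) {
  stopifnot(inherits(dist, "time_dist"))
  p <- dist$params
  switch(dist$family,
    exp = list(mean = 1 / p$rate, variance = 1 / p$rate^2),
    gamma = list(mean = p$shape * p$scale, variance = p$shape * p$scale^2),
    invgauss = list(mean = p$mean, variance = p$mean^3 / p$shape)
  )
}

#' Draw i.i.d. durations
#'
#' Uses the current R random stream; seed management is the caller's
#' responsibility (simulation configs carry an explicit seed).
#'
#' @inheritParams dist_pdf
#' @param m Number of draws (`m = 0` gives an empty vector).
#' @return Numeric vector of `m` positive durations.
#' @export
dist_sample <- function(dist, m) {
  stopifnot(inherits(dist, "time_dist"), m >= 0)
  if (m == 0) return(numeric(0))
  p <- dist$params
  switch(dist$family,
    exp = stats::rexp(m, rate = p$rate),
    gamma = stats::rgamma(m, shape = p$shape, scale = p$scale),
    invgauss = rinvgauss(m, p$mean, p$shape)
  )
}

#' Delay kernel of a duration law in Laplace space
#'
#' The renewal-type memory kernel of the velocity-jump transport equations,
#' \deqn{\bar\Phi(\lambda) = \frac{\lambda \bar f(\lambda)}{1 - \bar f(\lambda)},}
#' where \eqn{\bar f} is the Laplace transform of the duration pdf. At
#' \eqn{\lambda = 0} the removable singularity is filled with the limit
#' \eqn{1/\mu}. Analytic first and second derivatives are available (needed by
#' the Laplace-space moment solver, where time-weighted convolutions become
#' kernel derivatives).
#'
#' @inheritParams dist_laplace
#' @return Kernel transform values (complex for complex input).
#' @export
kernel_laplace <- function(dist, lam, deriv = 0) {
  stopifnot(deriv %in% 0:2)
  realin <- is.numeric(lam) && all(lam >= 0)
  lam <- as.complex(lam)
  u <- dist_laplace(dist, lam, 0)
  d <- 1 - u
  out <- rep(NA_complex_, length(lam))
  at0 <- abs(lam) == 0
  if (any(!at0)) {
    small <- !at0 & abs(d) < 1e-13
    if (any(small)) {
      stop("kernel_laplace: 1 - fbar(lambda) within tolerance of zero away from the origin (numerical pole)")
    }
    l <- lam[!at0]; u0 <- u[!at0]; dd <- d[!at0]
    if (deriv == 0) {
      out[!at0] <- l * u0 / dd
    } else {
      u1 <- dist_laplace(dist, l, 1)
      if (deriv == 1) {
        out[!at0] <- (u0 + l * u1) / dd + l * u0 * u1 / dd^2
      } else {
        u2 <- dist_laplace(dist, l, 2)
        out[!at0] <- (2 * u1 + l * u2) / dd +
          (2 * u0 * u1 + 2 * l * u1^2 + l * u0 * u2) / dd^2 +
          2 * l * u0 * u1^2 / dd^3
      }
    }
  }
  if (any(at0)) {
    km <- kernel_moments(dist)
    out[at0] <- switch(as.character(deriv),
      "0" = km$phi0, "1" = km$phi_prime0,
      "2" = stop("second kernel derivative at 0 not provided"))
  }
  if (realin) Re(out) else out
}

#' Small-\eqn{\lambda} kernel moments
#'
#' \eqn{\bar\Phi(0) = 1/\mu} and
#' \eqn{\bar\Phi'(0) = (\sigma^2/\mu^2 - 1)/2}, the two constants that enter
#' the large-time effective diffusion approximation.
#'
#' @inheritParams dist_pdf
#' @return List with `phi0` (units 1/time) and `phi_prime0` (dimensionless).
#' @export
kernel_moments <- function(dist) {
  m <- dist_moments(dist)
  if (!is.finite(m$variance)) stop("kernel moments need a finite variance")
  list(phi0 = 1 / m$mean,
       phi_prime0 = 0.5 * (m$variance / m$mean^2 - 1))
}

#' Impulse weight of a delay kernel
#'
#' The delay kernel decomposes as \eqn{\Phi(t) = c\,\delta(t) + \Phi_{reg}(t)}
#' with \eqn{c = \lim_{\lambda\to\infty} \lambda \bar f(\lambda) = f(0^+)}:
#' the rate for exponential laws, zero for inverse Gaussian and for gamma with
#' shape > 1, and divergent for gamma shape < 1 (rejected).
#'
#' @inheritParams dist_pdf
#' @return Scalar impulse weight `c` (units 1/time).
#' @keywords internal
kernel_impulse <- function(dist) {
  p <- dist$params
  switch(dist$family,
    exp = p$rate,
    gamma = {
      if (p$shape < 1) {
        stop("gamma with shape < 1 has a divergent delay-kernel impulse; ",
             "the moment solver cannot handle it (use the sample-path simulator)")
      }
      if (p$shape == 1) 1 / p$scale else 0
    },
    invgauss = 0
  )
}

# regular part of the kernel at t = 0 (used by the trapezoidal endpoint)
kernel_reg0 <- function(dist) {
  p <- dist$params
  switch(dist$family,
    exp = 0,
    invgauss = 0,
    gamma = {
      if (p$shape >= 2 || p$shape == 1) {
        if (p$shape == 2) 1 / p$scale^2 else 0
      } else {
        NA_real_  # singular for shape in (1, 2); caller substitutes
      }
    }
  )
}

#' Delay kernel summary object
#'
#' Bundles the pieces of \eqn{\Phi} the moment machinery needs: the impulse
#' weight at \eqn{t = 0}, the small-\eqn{\lambda} moments, and the source law.
#' The regular part on a time grid comes from [kernel_on_grid()].
#'
#' @inheritParams dist_pdf
#' @return An object of class `delay_kernel` with fields `source`,
#'   `impulse_weight`, `phi0`, `phi_prime0`.
#' @export
delay_kernel <- function(dist) {
  km <- kernel_moments(dist)
  structure(list(source = dist,
                 impulse_weight = kernel_impulse(dist),
                 phi0 = km$phi0,
                 phi_prime0 = km$phi_prime0),
            class = "delay_kernel")
}

#' @export
print.delay_kernel <- function(x, ...) {
  cat("<delay_kernel> source ", format(x$source),
      "; impulse ", format(x$impulse_weight),
      "; Phi(0+) = ", format(x$phi0),
      ", Phi'(0+) = ", format(x$phi_prime0), "\n", sep = "")
  invisible(x)
}

#' Numerical inverse Laplace transform
#'
#' Fixed-contour Talbot inversion and Euler (alternating-series with binomial
#' averaging) inversion. Both evaluate the transform only at points
#' proportional to \eqn{1/t}, so the call is vectorised over `t`.
#'
#' @param transform A function taking a complex vector and returning the
#'   transform values.
#' @param t Positive times at which to invert.
#' @param method `"talbot"` (default) or `"euler"`.
#' @param nodes Number of Talbot contour nodes, or the number of pre-summation
#'   terms for Euler (which then averages `euler_m` further partial sums).
#' @param euler_m Binomial-averaging depth for the Euler method.
#' @return Numeric vector of inverse-transform values at `t`.
#' @export
invert_laplace <- function(transform, t, method = c("talbot", "euler"),
                           nodes = if (match.arg(method) == "talbot") 32L else 18L,
                           euler_m = 15L) {
  method <- match.arg(method)
  stopifnot(all(t > 0))
  if (method == "talbot") {
    M <- as.integer(nodes)
    # z_k = t * s_k is independent of t on the scaled Talbot contour
    acc <- 0.5 * exp(2 * M / 5) * Re(transform(as.complex(2 * M / (5 * t))))
    for (k in seq_len(M - 1)) {
      th <- k * pi / M
      ct <- cos(th) / sin(th)
      z <- (2 * M / 5) * th * complex(real = ct, imaginary = 1)
      sig <- th + (th * ct - 1) * ct
      acc <- acc + Re(exp(z) * transform(z / t) *
                        complex(real = 1, imaginary = sig))
    }
    (2 / (5 * t)) * acc
  } else {
    A <- 18.4
    n0 <- as.integer(nodes); m <- as.integer(euler_m)
    nmax <- n0 + m
    terms <- matrix(0, nrow = length(t), ncol = nmax + 1)
    terms[, 1] <- 0.5 * Re(transform(as.complex(A / (2 * t))))
    for (k in seq_len(nmax)) {
      lam <- complex(real = A, imaginary = 2 * k * pi) / (2 * t)
      terms[, k + 1] <- (-1)^k * Re(transform(lam))
    }
    csum <- t(apply(terms, 1, cumsum))
    if (length(t) == 1) csum <- matrix(csum, nrow = 1)
    w <- choose(m, 0:m) / 2^m
    partial <- csum[, (n0 + 1):(n0 + m + 1), drop = FALSE]
    est <- as.numeric(partial %*% w)
    if (any(!is.finite(est))) {
      stop("Euler inversion failed to converge (non-decaying terms)")
    }
    est * exp(A / 2) / t
  }
}

#' Tabulate a (time-weighted) delay-kernel regular part on a uniform grid
#'
#' Returns the impulse weight (which contributes only for `weight_power = 0`,
#' since \eqn{t^k \delta(t) = 0} for \eqn{k \ge 1}) and the grid values
#' \eqn{t^k \Phi_{reg}(t)} at \eqn{t = 0, dt, \dots, n\,dt}, where
#' \eqn{\Phi_{reg}} is recovered by numerically inverting
#' \eqn{\bar\Phi(\lambda) - c}.
#'
#' @inheritParams dist_pdf
#' @param dt Grid spacing (> 0).
#' @param n_steps Number of steps; the grid has `n_steps + 1` points from 0.
#' @param weight_power Integer 0, 1 or 2: the power of `t` multiplying the
#'   kernel, as needed by the time-weighted convolutions of the moment system.
#' @param method,nodes Passed to [invert_laplace()].
#' @return List with `impulse_weight` (0 unless `weight_power == 0`) and
#'   `values`, a numeric vector of length `n_steps + 1` starting at `t = 0`.
#' @export
kernel_on_grid <- function(dist, dt, n_steps, weight_power = 0,
                           method = "talbot", nodes = 32L) {
  stopifnot(dt > 0, n_steps >= 1, weight_power %in% 0:2)
  cc <- kernel_impulse(dist)
  tgrid <- dt * seq_len(n_steps)
  if (dist$family == "exp" || (dist$family == "gamma" && dist$params$shape == 1)) {
    vals <- rep(0, n_steps + 1)
  } else {
    reg <- invert_laplace(function(l) kernel_laplace(dist, l) - cc,
                          tgrid, method = method, nodes = nodes)
    v0 <- kernel_reg0(dist)
    if (is.na(v0)) {
      warning("delay-kernel regular part is singular at t = 0 ",
              "(gamma shape in (1,2)); using the first grid value")
      v0 <- reg[1]
    }
    vals <- c(v0, reg)
  }
  k <- weight_power
  if (k > 0) vals <- c(0, tgrid)^k * vals
  list(impulse_weight = if (k == 0) cc else 0, values = vals)
}
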
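#' Speed laws for run velocities
#'
#' The turning kernel factorises into an angular part and a speed part
#' `h(s)`; the speed of each new run is drawn independently of the previous
#' one (memoryless in speed). `speed_const()` is the degenerate law used in
#' the planar benchmark simulations (`s = 1`); `speed_lognormal()` is a
#' flexible positive law parameterised on the log scale.
#'
#' @param s,meanlog,sdlog Law parameters.
#' @return An object of class `speed_law`.
#' @export
speed_const <- function(s = 1) {
  stopifnot(s > 0)
  structure(list(type = "const", s = s), class = "speed_law")
}

#' @rdname speed_const
#' @export
speed_lognormal <- function(meanlog, sdlog) {
  stopifnot(sdlog >= 0)
  structure(list(type = "lognormal", meanlog = meanlog, sdlog = sdlog),
            class = "speed_law")
}

#' Lognormal speed law with a prescribed mean squared speed
#'
#' Convenience constructor: given a target \eqn{S_T^2 = E[s^2]} and a log-scale
#' spread, returns the lognormal law with exactly that second moment
#' (\eqn{E[s^2] = e^{2m + 2\sigma^2}}).
#'
#' @param S_T2 Target mean squared speed.
#' @param sdlog Log-scale standard deviation (default 0.25).
#' @export
speed_lognormal_msq <- function(S_T2, sdlog = 0.25) {
  speed_lognormal(meanlog = (log(S_T2) - 2 * sdlog^2) / 2, sdlog = sdlog)
}

#' @rdname speed_const
#' @param law A `speed_law`.
#' @param n Number of draws.
#' @export
speed_sample <- function(law, n) {
  stopifnot(inherits(law, "speed_law"))
  switch(law$type,
    const = rep(law$s, n),
    lognormal = stats::rlnorm(n, law$meanlog, law$sdlog)
  )
}

#' Mean squared speed \eqn{S_T^2 = E[s^2]} of a speed law
#' @param law A `speed_law`.
#' @export
speed_msq <- function(law) {
  stopifnot(inherits(law, "speed_law"))
  switch(law$type,
    const = law$s^2,
    lognormal = exp(2 * law$meanlog + 2 * law$sdlog^2)
  )
}

#' Von Mises reorientation kernel
#'
#' Planar turning kernel: the angle change between consecutive runs follows a
#' von Mises law centred on the previous heading,
#' \eqn{\Theta(\theta) = e^{\kappa\cos\theta} / (2\pi I_0(\kappa))},
#' and the new speed is drawn from `speed` independently of the old one.
#' The index of persistence is \eqn{\psi_d = I_1(\kappa)/I_0(\kappa)}.
#'
#' @param kappa Concentration (>= 0; 0 gives uniform reorientation).
#' @param mu_angle Mean turn in radians (default 0: symmetric turning).
#' @param speed A `speed_law` (default unit speed).
#' @return An object of class `turning_kernel`.
#' @export
turning_kernel <- function(kappa, mu_angle = 0, speed = speed_const(1)) {
  stopifnot(kappa >= 0, inherits(speed, "speed_law"))
  structure(list(kappa = kappa, mu_angle = mu_angle, speed = speed),
            class = "turning_kernel")
}

#' Index of persistence
#'
#' The Bessel-function ratio \eqn{I_1(\kappa)/I_0(\kappa)}, i.e. the mean
#' cosine of the turn angle, relating the mean post-turn velocity to the
#' pre-turn velocity. Uses exponentially scaled Bessel functions so large
#' concentrations do not overflow.
#'
#' @param x A `turning_kernel` or a numeric concentration \eqn{\kappa}.
#' @return A value in `[0, 1)`.
#' @export
persistence_index <- function(x) {
  kappa <- if (inherits(x, "turning_kernel")) x$kappa else x
  stopifnot(all(kappa >= 0))
  ifelse(kappa == 0, 0,
         besselI(kappa, 1, expon.scaled = TRUE) /
           besselI(kappa, 0, expon.scaled = TRUE))
}

#' Concentration with a prescribed persistence index
#'
#' Solves \eqn{I_1(\kappa)/I_0(\kappa) = \psi_d} by bracketed root finding.
#'
#' @param psi_d Target persistence in `[0, 1)`.
#' @export
kappa_for_psi <- function(psi_d) {
  stopifnot(psi_d >= 0, psi_d < 1)
  if (psi_d == 0) return(0)
  stats::uniroot(function(k) persistence_index(k) - psi_d,
                 c(1e-10, 1e4), tol = 1e-12)$root
}

# Best & Fisher (1979) von Mises sampler, vectorised with batch rejection
rvonmises <- function(n, kappa) {
  if (n == 0) return(numeric(0))
  if (kappa < 1e-10) return(stats::runif(n, -pi, pi))
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(n - length(out), 16L)
    m <- ceiling(m * 1.3)
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    keep <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3[keep] - 0.5) * acos(f[keep])
    out <- c(out, th)
  }
  out[seq_len(n)]
}

#' Draw post-rest headings
#'
#' New heading = previous heading + a von Mises turn, wrapped to
#' \eqn{[0, 2\pi)}.
#'
#' @param prev_angle Previous heading(s), radians.
#' @param kernel A [turning_kernel()].
#' @param n Number of draws (recycled against `prev_angle`).
#' @export
draw_turn <- function(prev_angle, kernel, n = length(prev_angle)) {
  stopifnot(inherits(kernel, "turning_kernel"))
  (prev_angle + kernel$mu_angle + rvonmises(n, kernel$kappa)) %% (2 * pi)
}

#' Simulation configuration
#'
#' @param run,rest [time_dist()] duration laws for running and resting phases.
#' @param turning A [turning_kernel()].
#' @param T_end Simulation horizon (> 0); the final phase is truncated there.
#' @param n_paths Ensemble size.
#' @param init_run_fraction Probability that a path starts in a run; the
#'   initial phase begins at `t = 0` (no stationary-age correction), matching
#'   the initial-condition convention of the moment equations.
#' @param seed Optional integer seed; fixed seeds make ensembles bit-for-bit
#'   reproducible.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(run, rest, turning = turning_kernel(0),
                       T_end, n_paths = 1L, init_run_fraction = 0.5,
                       seed = NULL) {
  stopifnot(inherits(run, "time_dist"), inherits(rest, "time_dist"),
            inherits(turning, "turning_kernel"),
            T_end > 0, n_paths >= 1,
            init_run_fraction >= 0, init_run_fraction <= 1)
  structure(list(run = run, rest = rest, turning = turning,
                 T_end = T_end, n_paths = as.integer(n_paths),
                 init_run_fraction = init_run_fraction, seed = seed,
                 n_dim = 2L),
            class = "sim_config")
}

# core path generator; assumes the RNG state is already positioned.
# Returns a data.frame of phases tiling [0, T_end].
generate_path <- function(cfg, init_state = NULL) {
  run <- cfg$run; rest <- cfg$rest; tk <- cfg$turning
  T_end <- cfg$T_end
  if (is.null(init_state)) {
    init_state <- if (stats::runif(1) < cfg$init_run_fraction) "run" else "rest"
  }
  mu_cycle <- dist_moments(run)$mean + dist_moments(rest)$mean
  block <- max(8L, ceiling(2.2 * T_end / mu_cycle))
  durs <- numeric(0); states <- character(0)
  first <- init_state
  repeat {
    nr <- block
    d_run <- dist_sample(run, nr)
    d_rest <- dist_sample(rest, nr)
    if (first == "run") {
      nd <- as.vector(rbind(d_run, d_rest))
      ns <- rep(c("run", "rest"), nr)
    } else {
      nd <- as.vector(rbind(d_rest, d_run))
      ns <- rep(c("rest", "run"), nr)
    }
    durs <- c(durs, nd); states <- c(states, ns)
    if (sum(durs) >= T_end) break
    first <- if (states[length(states)] == "run") "rest" else "run"
    block <- max(8L, block)
  }
  ends <- cumsum(durs)
  n_ph <- which(ends >= T_end)[1]
  durs <- durs[seq_len(n_ph)]; states <- states[seq_len(n_ph)]
  starts <- c(0, ends[seq_len(n_ph - 1)])
  durs[n_ph] <- T_end - starts[n_ph]

  is_run <- states == "run"
  n_runs <- sum(is_run)
  # headings: initial orientation uniform; each later run turns from the
  # orientation carried through the preceding rest
  theta0 <- stats::runif(1, 0, 2 * pi)
  if (n_runs > 0) {
    turns <- rvonmises(n_runs, tk$kappa) + tk$mu_angle
    if (init_state == "run") turns[1] <- 0  # first run uses theta0 itself
    run_angles <- (theta0 + cumsum(turns)) %% (2 * pi)
    run_speeds <- speed_sample(tk$speed, n_runs)
  } else {
    run_angles <- numeric(0); run_speeds <- numeric(0)
  }
  # rests carry the orientation of the preceding run (or theta0 initially)
  ridx <- cumsum(is_run)
  angle <- ifelse(ridx >= 1, run_angles[pmax(ridx, 1L)], theta0)
  speed <- numeric(n_ph)
  speed[is_run] <- run_speeds
  vx <- ifelse(is_run, speed * cos(angle), 0)
  vy <- ifelse(is_run, speed * sin(angle), 0)
  x_start <- c(0, cumsum(vx * durs))[seq_len(n_ph)]
  y_start <- c(0, cumsum(vy * durs))[seq_len(n_ph)]
  data.frame(state = states, t_start = starts, duration = durs,
             angle = angle, speed = ifelse(is_run, speed, 0),
             vx = vx, vy = vy, x_start = x_start, y_start = y_start)
}

#' Simulate one sample path of the velocity-jump process
#'
#' Gillespie-style generation: alternating run and rest phases with durations
#' drawn from the configured laws; each run starts with a fresh speed and a
#' heading turned from the orientation stored through the preceding rest; the
#' final phase is truncated at `T_end`. Positions start at the origin.
#'
#' @param cfg A [sim_config()].
#' @param init_state Optional `"run"`/`"rest"` override of the random initial
#'   phase.
#' @return An object of class `sample_path`: a list with `phases` (a data
#'   frame of state, start time, duration, heading, speed, velocity and start
#'   position) and `T_end`.
#' @export
simulate_path <- function(cfg, init_state = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  structure(list(phases = generate_path(cfg, init_state), T_end = cfg$T_end,
                 origin = c(0, 0)),
            class = "sample_path")
}

#' @export
print.sample_path <- function(x, ...) {
  cat("<sample_path> ", nrow(x$phases), " phases over [0, ",
      format(x$T_end), "]\n", sep = "")
  invisible(x)
}

#' Simulate an ensemble of sample paths
#'
#' @inheritParams simulate_path
#' @return List of `sample_path` objects of length `cfg$n_paths`.
#' @export
simulate_ensemble <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  lapply(seq_len(cfg$n_paths), function(i) {
    structure(list(phases = generate_path(cfg), T_end = cfg$T_end,
                   origin = c(0, 0)),
              class = "sample_path")
  })
}

# positions for a phase table at times tt (vectorised)
path_positions <- function(ph, tt, T_end) {
  if (any(tt < 0 | tt > T_end)) stop("t outside [0, T_end]")
  idx <- findInterval(tt, ph$t_start)
  idx[idx < 1] <- 1
  el <- tt - ph$t_start[idx]
  cbind(x = ph$x_start[idx] + ph$vx[idx] * el,
        y = ph$y_start[idx] + ph$vy[idx] * el)
}

#' Position along a sample path
#'
#' Piecewise-linear interpolation: constant-velocity motion during runs, no
#' displacement during rests.
#'
#' @param path A `sample_path`.
#' @param t Times in `[0, T_end]`.
#' @return A two-column matrix of positions.
#' @export
position_at <- function(path, t) {
  stopifnot(inherits(path, "sample_path"))
  path_positions(path$phases, t, path$T_end)
}

#' Empirical mean squared displacement of an ensemble
#'
#' Mean over paths of the squared displacement from each path's initial
#' position, evaluated on a time grid.
#'
#' @param paths List of `sample_path` objects.
#' @param grid Times within `[0, T_end]`.
#' @return Data frame with columns `t`, `msd`, `se` (Monte-Carlo standard
#'   error of the mean) and `n_paths`.
#' @export
empirical_msd <- function(paths, grid) {
  if (length(paths) == 0) stop("empty ensemble")
  n <- length(paths)
  s1 <- numeric(length(grid)); s2 <- numeric(length(grid))
  for (p in paths) {
    xy <- position_at(p, grid)
    d2 <- xy[, 1]^2 + xy[, 2]^2
    s1 <- s1 + d2; s2 <- s2 + d2^2
  }
  msd <- s1 / n
  se <- sqrt(pmax(s2 / n - msd^2, 0) / n)
  data.frame(t = grid, msd = msd, se = se, n_paths = n)
}

#' Streaming ensemble summary: MSD curve and final positions
#'
#' Simulates `cfg$n_paths` paths one at a time (so large ensembles never need
#' to be stored) and accumulates the empirical MSD on `grid` together with the
#' positions at `T_end`, which feed the heat-kernel cross-section comparison.
#'
#' @inheritParams simulate_path
#' @param grid Times within `[0, T_end]`.
#' @param keep_final Collect final positions?
#' @return List with `msd` (as in [empirical_msd()]) and `final` (matrix of
#'   positions at `T_end`, or NULL).
#' @export
ensemble_msd <- function(cfg, grid, keep_final = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_paths
  s1 <- numeric(length(grid)); s2 <- numeric(length(grid))
  fin <- if (keep_final) matrix(0, n, 2) else NULL
  for (i in seq_len(n)) {
    ph <- generate_path(cfg)
    xy <- path_positions(ph, grid, cfg$T_end)
    d2 <- xy[, 1]^2 + xy[, 2]^2
    s1 <- s1 + d2; s2 <- s2 + d2^2
    if (keep_final) {
      last <- nrow(ph)
      fin[i, ] <- c(ph$x_start[last] + ph$vx[last] * ph$duration[last],
                    ph$y_start[last] + ph$vy[last] * ph$duration[last])
    }
  }
  msd <- s1 / n
  se <- sqrt(pmax(s2 / n - msd^2, 0) / n)
  list(msd = data.frame(t = grid, msd = msd, se = se, n_paths = n),
       final = fin)
}

#' Export an ensemble's phases as a flat data frame
#'
#' One row per phase with the CSV layout used by the command-line tools:
#' `track_id, phase_index, state, t_start, duration, vx, vy, x_start, y_start`.
#'
#' @param paths List of `sample_path` objects.
#' @export
paths_to_df <- function(paths) {
  do.call(rbind, lapply(seq_along(paths), function(i) {
    ph <- paths[[i]]$phases
    data.frame(track_id = i, phase_index = seq_len(nrow(ph)),
               state = ph$state, t_start = ph$t_start,
               duration = ph$duration, vx = ph$vx, vy = ph$vy,
               x_start = ph$x_start, y_start = ph$y_start)
  }))
}
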
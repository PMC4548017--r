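# shared builders for the test suite; everything is generated in code

ecoli_moment_config <- function(dt = 1e-3, T = 4, V_p2_0 = NULL) {
  run <- time_dist("exp", 2.30)
  rest <- time_dist("exp", 11.98)
  if (is.null(V_p2_0)) V_p2_0 <- 9.26 * 66
  moment_config(run, rest, psi_d = 0.46, S_T2 = 9.26,
                N_p0 = 66, N_r0 = 1802, V_p2_0 = V_p2_0, dt = dt, T = T)
}

gull_moment_config <- function(dt = 1.26 / 100, T = 40) {
  moment_config(time_dist("invgauss", 1.26, 1.22),
                time_dist("invgauss", 10.79, 7.42),
                psi_d = 0.42, S_T2 = 1.03e5, N_p0 = 6, N_r0 = 56,
                dt = dt, T = T)
}

# Markovian reduction of the moment system for exponential kernels,
# solved with an independent stiff integrator (deSolve) as oracle
markov_oracle <- function(cfg, times) {
  bt <- cfg$run$params$rate
  bw <- cfg$rest$params$rate
  psi <- cfg$psi_d; S2 <- cfg$S_T2
  rhs <- function(t, y, p) {
    with(as.list(y), list(c(
      N_p = -bt * N_p + bw * N_r,
      N_r = bt * N_p - bw * N_r,
      V_p = -bt * V_p + S2 * bw * N_r,
      V_r = bt * V_p - bw * V_r,
      B_p = V_p - bt * B_p + psi * bw * B_r,
      B_r = bt * B_p - bw * B_r,
      D_p = 2 * B_p - bt * D_p + bw * D_r,
      D_r = bt * D_p - bw * D_r)))
  }
  y0 <- c(N_p = cfg$N_p0, N_r = cfg$N_r0, V_p = cfg$V_p2_0, V_r = 0,
          B_p = 0, B_r = 0, D_p = 0, D_r = 0)
  deSolve::ode(y0, c(0, times), rhs, NULL, rtol = 1e-12, atol = 1e-10)
}

# align requested times onto a moment_state grid
grid_idx <- function(state, times) {
  vapply(times, function(x) which.min(abs(state$t - x)), integer(1))
}

rel_err <- function(a, b) abs(a / b - 1)
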
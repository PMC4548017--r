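test_that("haversine distance: identities and an independent oracle", {
  expect_equal(haversine_km(48.1, 11.6, 48.1, 11.6), 0)
  expect_equal(haversine_km(0, 0, 0, 180), pi * 6371)
  expect_equal(haversine_km(0, 0, 0, 1), 6371 * pi / 180, tolerance = 1e-9)
  expect_error(haversine_km(91, 0, 0, 0), "invalid")
  set.seed(4)
  la1 <- runif(20, -80, 80); lo1 <- runif(20, -180, 180)
  la2 <- runif(20, -80, 80); lo2 <- runif(20, -180, 180)
  oracle <- geosphere::distHaversine(cbind(lo1, la1), cbind(lo2, la2),
                                     r = 6371)
  expect_equal(haversine_km(la1, lo1, la2, lo2), oracle, tolerance = 1e-9)
})

test_that("window diameter equals the brute-force maximum pairwise distance", {
  expect_equal(window_diameter(50, 3), 0)
  expect_equal(window_diameter(c(50, 51), c(3, 3)),
               haversine_km(50, 3, 51, 3))
  # collinear equatorial points: extremes dominate
  expect_equal(window_diameter(c(0, 0, 0), c(0, 1, 2)),
               haversine_km(0, 0, 0, 2))
  expect_error(window_diameter(numeric(0), numeric(0)), "empty")
  set.seed(8)
  la <- runif(12, 40, 60); lo <- runif(12, -10, 10)
  brute <- max(apply(expand.grid(1:12, 1:12), 1, function(ij)
    haversine_km(la[ij[1]], lo[ij[1]], la[ij[2]], lo[ij[2]])))
  expect_equal(window_diameter(la, lo), brute)
})

make_square_track <- function(segments, fix_dt = 0.1, lat0 = 52, lon0 = 4.5) {
  # segments: data.frame(days, speed_east_km_day)
  t <- seq(0, sum(segments$days), by = fix_dt)
  v <- approx(cumsum(c(0, segments$days)), c(segments$speed, 0),
              xout = t, method = "constant", rule = 2)$y
  x <- cumsum(c(0, diff(t)) * v)
  data.frame(t = t, lat = lat0,
             lon = lon0 + x / (111.195 * cos(lat0 * pi / 180)))
}

test_that("threshold segmentation recovers blocky rest/run/rest structure", {
  # purely stationary: one rest covering the record
  still <- data.frame(t = seq(0, 5, 0.1), lat = 52, lon = 4)
  ph <- segment_track(still)
  expect_equal(ph$state, "rest")
  expect_equal(c(ph$t_start, ph$t_end), c(0, 5))
  # 10 d rest, 3 d at 300 km/day, 10 d rest
  tr <- make_square_track(data.frame(days = c(10, 3, 10),
                                     speed = c(0, 300, 0)))
  ph <- segment_track(tr)
  expect_equal(ph$state, c("rest", "run", "rest"))
  expect_lt(abs(ph$t_end[1] - 10), 1)
  expect_lt(abs(ph$t_start[3] - 13), 1)
  # a 1-day pause inside a migration is not reported as rest
  tr2 <- make_square_track(data.frame(days = c(5, 1, 6),
                                      speed = c(300, 0, 300)))
  expect_equal(segment_track(tr2)$state, "run")
  expect_error(segment_track(still[1:5, ]), "shorter than")
})

test_that("segmentation labels are invariant to sub-threshold GPS jitter", {
  tr <- make_square_track(data.frame(days = c(8, 4, 8, 3, 9),
                                     speed = c(0, 250, 0, 350, 0)))
  ph0 <- segment_track(tr)
  set.seed(31)
  kpd <- 111.195
  trj <- tr
  trj$lat <- tr$lat + rnorm(nrow(tr), sd = 1) / kpd
  trj$lon <- tr$lon + rnorm(nrow(tr), sd = 1) / (kpd * cos(52 * pi / 180))
  phj <- segment_track(trj)
  expect_equal(phj$state, ph0$state)
  expect_equal(phj$t_start, ph0$t_start, tolerance = 0.2)
})

test_that("labelled-track phase statistics and first-phase censor flag", {
  # one pure run: a single duration, no angles
  tr <- data.frame(t = seq(0, 1, 0.01), x = seq(0, 2, length.out = 101),
                   y = 0, state = "run")
  st <- extract_phase_stats(tr)
  expect_length(st$rest_durations, 0)
  expect_length(st$turn_angles, 0)
  expect_equal(st$initial_state, "run")
  # alternating track with known durations
  states <- rep(c("rest", "run", "rest", "run", "rest"),
                times = c(20, 30, 20, 30, 10))
  tt <- seq_along(states) * 0.1
  xx <- cumsum(c(0, diff(tt)) * (states == "run"))
  tr2 <- data.frame(t = tt, x = xx, y = 0, state = states)
  st2 <- extract_phase_stats(tr2)
  expect_equal(st2$rest_durations, c(2, 2))     # final rest censored out
  expect_equal(st2$run_durations, c(3, 3))
  expect_equal(st2$initial_state, "rest")
  st3 <- extract_phase_stats(tr2, truncate_first_phase = TRUE)
  expect_equal(st3$rest_durations, 2)
  # straight runs: zero turn angle
  expect_equal(st2$turn_angles, 0)
})

test_that("von Mises concentration fitting: degenerate and recovery cases", {
  set.seed(3)
  u <- runif(1e5, -pi, pi)
  f0 <- suppressWarnings(fit_vonmises_kappa(u))
  expect_lt(f0$kappa, 0.02)
  expect_lt(abs(f0$psi_d), 0.02)
  expect_warning(fz <- fit_vonmises_kappa(rep(0, 50)), "capped")
  expect_equal(fz$kappa, 1e3)
  expect_warning(fn <- fit_vonmises_kappa(c(pi, pi, -pi)), "kappa set to 0")
  expect_equal(fn$kappa, 0)
  # parameter recovery at kappa = 2
  set.seed(9)
  th <- draw_turn(rep(0, 1e5), turning_kernel(2))
  th <- ((th + pi) %% (2 * pi)) - pi
  fit <- fit_vonmises_kappa(th)
  expect_lt(rel_err(fit$kappa, 2), 0.02)
  # psi estimate is unbiased to < 0.01 across concentrations
  for (kap in c(0.5, 1, 2, 5)) {
    set.seed(100 + kap * 10)
    ang <- draw_turn(rep(0, 1e5), turning_kernel(kap))
    expect_lt(abs(fit_vonmises_kappa(ang)$psi_d - persistence_index(kap)),
              0.01)
  }
})

test_that("duration-law fitting: closed forms, recovery, truncation, censoring", {
  expect_equal(fit_duration_dist(rep(2.5, 10), "exp")$params$rate, 1 / 2.5)
  set.seed(12)
  x <- dist_sample(time_dist("invgauss", 1.26, 1.22), 1e5)
  f <- fit_duration_dist(x, "invgauss")
  expect_lt(rel_err(f$params$mean, 1.26), 0.02)
  expect_lt(rel_err(f$params$shape, 1.22), 0.02)
  y <- dist_sample(time_dist("exp", 11.98), 1e5)
  expect_lt(rel_err(fit_duration_dist(y, "exp")$params$rate, 11.98), 0.02)
  g <- dist_sample(time_dist("gamma", 1.8, 0.6), 1e5)
  fg <- fit_duration_dist(g, "gamma")
  expect_lt(rel_err(fg$params$shape, 1.8), 0.03)
  expect_lt(rel_err(fg$params$scale, 0.6), 0.03)
  # left-truncated inverse-Gaussian likelihood undoes the truncation bias
  set.seed(13)
  w <- dist_sample(time_dist("invgauss", 10.79, 7.42), 4e4)
  wt <- w[w > 3]
  naive <- fit_duration_dist(wt, "invgauss")
  trunc <- fit_duration_dist(wt, "invgauss", truncation = 3)
  expect_gt(rel_err(naive$params$mean, 10.79), 0.05)  # the bias is real
  expect_lt(rel_err(trunc$params$mean, 10.79), 0.03)
  expect_lt(rel_err(trunc$params$shape, 7.42), 0.06)
  # right-censored observations keep long phases from being lost
  set.seed(14)
  full <- dist_sample(time_dist("exp", 0.2), 2e4)
  cens_at <- runif(2e4, 0, 15)
  obs <- pmin(full, cens_at)
  is_c <- full > cens_at
  fitc <- fit_duration_dist(obs[!is_c], "exp", censored = obs[is_c])
  expect_lt(rel_err(1 / fitc$params$rate, 5), 0.03)
  expect_error(fit_duration_dist(c(-1, 2), "exp"), "positive")
  expect_error(fit_duration_dist(c(0.5, 2), "exp", truncation = 1),
               "truncation")
})

test_that("mean squared speed is the plain second moment", {
  expect_equal(mean_squared_speed(rep(1, 5)), 1)
  expect_equal(mean_squared_speed(c(1, 3)), 5)
  set.seed(2)
  law <- speed_lognormal_msq(9.26)
  s <- speed_sample(law, 1e5)
  expect_lt(abs(mean_squared_speed(s) - 9.26) / 9.26, 0.02)
  expect_error(mean_squared_speed(numeric(0)), "at least one")
})

test_that("merged-run moment de-bias inverts the compound-geometric gluing", {
  rest <- time_dist("invgauss", 10.79, 7.42)
  cutoff <- 2.5
  set.seed(21)
  n <- 3e4
  tau <- dist_sample(time_dist("invgauss", 1.26, 1.22), 3 * n)
  om <- dist_sample(rest, 3 * n)
  runs <- numeric(0); cur <- 0; k <- 0; i <- 1; j <- 1
  while (k < n && i <= 3 * n && j <= 3 * n) {
    cur <- cur + tau[i]; i <- i + 1
    if (om[j] < cutoff) {
      cur <- cur + om[j]
    } else {
      runs <- c(runs, cur); cur <- 0; k <- k + 1
    }
    j <- j + 1
  }
  db <- debias_run_moments(mean(runs), var(runs), rest, cutoff)
  expect_lt(rel_err(db$mean, 1.26), 0.02)
  expect_lt(rel_err(db$variance, 1.26^3 / 1.22), 0.05)
  expect_equal(db$q, dist_cdf(rest, cutoff))
  # no truncation: identity
  id <- debias_run_moments(2, 3, rest, 0)
  expect_equal(id, list(mean = 2, variance = 3, q = 0))
})

test_that("28-day interval splitting rebases time within each interval", {
  tr <- data.frame(t = seq(0, 70, 0.5), lat = 52, lon = 4)
  sp <- split_track(tr, days = 28)
  expect_equal(sort(unique(sp$interval)), 1:3)
  expect_true(all(sp$t >= 0 & sp$t < 28))
  expect_equal(sum(sp$interval == 1), sum(tr$t < 28))
})
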
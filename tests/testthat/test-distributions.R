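test_that("duration pdfs match closed forms and normalise", {
  expect_equal(dist_pdf(time_dist("exp", 1), 0), 1)
  expect_equal(dist_pdf(time_dist("gamma", 1, 1), 2), exp(-2))
  ig <- time_dist("invgauss", 1.26, 1.22)
  expect_equal(stats::integrate(function(t) dist_pdf(ig, t), 0, Inf,
                                rel.tol = 1e-10)$value, 1, tolerance = 1e-8)
  for (d in list(time_dist("exp", 2.3), time_dist("gamma", 1.7, 0.4), ig)) {
    expect_equal(stats::integrate(function(t) dist_pdf(d, t), 0, Inf,
                                  rel.tol = 1e-9)$value, 1, tolerance = 1e-7)
    m <- dist_moments(d)
    expect_gt(m$mean, 0)
    expect_gte(m$variance, 0)
  }
  expect_error(dist_pdf(ig, -1), "non-negative")
  expect_error(time_dist("exp", rate = -1), "positive")
})

test_that("Laplace transforms evaluate their closed forms", {
  expect_equal(dist_laplace(time_dist("exp", 5), 0), 1)
  # direct-evaluation oracle: (1 + 7)^(-1/7)
  expect_equal(dist_laplace(time_dist("gamma", 1 / 7, 7), 1), 8^(-1 / 7))
  expect_equal(8^(-1 / 7), 0.7429971, tolerance = 1e-7)
  # small-lambda expansion 1 - mu*lam + O(lam^2)
  ig <- time_dist("invgauss", 1.26, 1.22)
  lam <- 1e-6
  expect_equal(dist_laplace(ig, lam), 1 - 1.26 * lam, tolerance = 1e-9)
  # branch-cut guards
  expect_error(dist_laplace(time_dist("gamma", 2, 1), -2), "branch")
  expect_error(dist_laplace(ig, -1), "branch")
  # analytic derivatives agree with central differences
  h <- 1e-5
  for (d in list(time_dist("exp", 2.3), time_dist("gamma", 0.6, 2), ig)) {
    for (lam in c(0.3, 2 + 1i)) {
      fd1 <- (dist_laplace(d, lam + h) - dist_laplace(d, lam - h)) / (2 * h)
      expect_equal(dist_laplace(d, lam, 1), fd1, tolerance = 1e-7)
    }
  }
})

test_that("closed-form moments include the printed worked values", {
  expect_equal(dist_moments(time_dist("gamma", 1 / 5, 5 / 2)),
               list(mean = 0.5, variance = 1.25))
  expect_equal(dist_moments(time_dist("gamma", 1 / 7, 7)),
               list(mean = 1, variance = 7))
  m <- dist_moments(time_dist("invgauss", 1.26, 1.22))
  expect_equal(m$mean, 1.26)
  expect_equal(m$variance, 1.26^3 / 1.22)
  expect_equal(dist_moments(time_dist("exp", 4)),
               list(mean = 0.25, variance = 0.0625))
})

test_that("sampling is deterministic under a seed and matches the mean", {
  expect_length(dist_sample(time_dist("exp", 1), 0), 0)
  d <- time_dist("exp", 2.30)
  set.seed(42); x1 <- dist_sample(d, 1e5)
  set.seed(42); x2 <- dist_sample(d, 1e5)
  expect_identical(x1, x2)
  expect_lt(abs(mean(x1) - 1 / 2.30), 3 * sd(x1) / sqrt(1e5))
  set.seed(7)
  ig <- time_dist("invgauss", 1.26, 1.22)
  y <- dist_sample(ig, 1e5)
  expect_lt(abs(mean(y) - 1.26), 3 * sd(y) / sqrt(1e5))
  expect_lt(abs(var(y) / (1.26^3 / 1.22) - 1), 0.05)
})

test_that("delay kernel transform and its small-lambda moments", {
  # exponential kernel is the constant rate
  d <- time_dist("exp", 3.7)
  expect_equal(kernel_laplace(d, 0.5), 3.7)
  expect_equal(kernel_laplace(d, 4 + 2i), 3.7 + 0i)
  # gamma(1/7,7): lambda*fbar/(1-fbar) at lambda = 1, via the transform value
  f1 <- 8^(-1 / 7)
  expect_equal(kernel_laplace(time_dist("gamma", 1 / 7, 7), 1),
               f1 / (1 - f1))
  # limit at 0 equals 1/mean for all families
  for (d in list(time_dist("exp", 2.3), time_dist("gamma", 1.4, 2),
                 time_dist("invgauss", 10.79, 7.42))) {
    mu <- dist_moments(d)$mean
    expect_equal(kernel_laplace(d, 0), 1 / mu)
    expect_equal(Re(kernel_laplace(d, 1e-8)), 1 / mu, tolerance = 1e-4)
    km <- kernel_moments(d)
    expect_equal(km$phi0, 1 / mu)
  }
  # phi_prime0 closed forms
  expect_equal(kernel_moments(time_dist("exp", 9))$phi_prime0, 0)
  expect_equal(kernel_moments(time_dist("gamma", 1 / 5, 5 / 2))$phi_prime0, 2)
  expect_equal(kernel_moments(time_dist("invgauss", 10.79, 7.42))$phi0,
               1 / 10.79)
  # central finite difference of the kernel transform across the origin
  # recovers phi_prime0
  for (d in list(time_dist("gamma", 1 / 5, 5 / 2),
                 time_dist("invgauss", 1.26, 1.22),
                 time_dist("exp", 2.3))) {
    h <- 1e-4
    fd <- Re(kernel_laplace(d, as.complex(h)) -
               kernel_laplace(d, as.complex(-h))) / (2 * h)
    target <- kernel_moments(d)$phi_prime0
    expect_equal(fd, target,
                 tolerance = if (target == 0) 1e-6 else 1e-4)
  }
})

test_that("numerical Laplace inversion: known pairs, cross-method, round trip", {
  expect_equal(invert_laplace(function(l) 1 / (l + 1), 1), exp(-1),
               tolerance = 1e-8)
  expect_equal(invert_laplace(function(l) 1 / l^2, 3), 3, tolerance = 1e-8)
  expect_equal(invert_laplace(function(l) 1 / (l + 1), 1, method = "euler"),
               exp(-1), tolerance = 1e-7)
  # talbot and euler agree on smooth transforms
  for (tt in c(0.5, 1, 4)) {
    a <- invert_laplace(function(l) 1 / (l^2 + l + 1), tt)
    b <- invert_laplace(function(l) 1 / (l^2 + l + 1), tt, method = "euler")
    expect_equal(a, b, tolerance = 1e-6)
  }
  # round trip through the analytic transform recovers the pdf
  for (d in list(time_dist("exp", 2.3), time_dist("gamma", 1.5, 0.8),
                 time_dist("invgauss", 1.26, 1.22))) {
    mu <- dist_moments(d)$mean
    ts <- c(0.1, 1, 5) * mu
    inv <- invert_laplace(function(l) dist_laplace(d, l), ts)
    expect_equal(inv, dist_pdf(d, ts), tolerance = 1e-6)
  }
})

test_that("kernel grids: impulse decomposition and the renewal oracle", {
  g <- kernel_on_grid(time_dist("exp", 2.3), 0.05, 20)
  expect_equal(g$impulse_weight, 2.3)
  expect_equal(g$values, rep(0, 21))
  # time weights kill the impulse
  g1 <- kernel_on_grid(time_dist("exp", 2.3), 0.05, 20, weight_power = 1)
  expect_equal(g1$impulse_weight, 0)
  gi <- kernel_on_grid(time_dist("invgauss", 1.26, 1.22), 0.05, 40)
  expect_equal(gi$impulse_weight, 0)
  expect_true(any(gi$values > 0))
  # gamma below shape 1 has a divergent impulse: reject, point to simulator
  expect_error(kernel_on_grid(time_dist("gamma", 1 / 7, 7), 0.1, 10),
               "simulator")
  # renewal-count oracle: double integral of the reconstructed kernel equals
  # the Monte-Carlo expected number of renewals in [0, T]
  for (d in list(time_dist("exp", 2), time_dist("invgauss", 1.26, 1.22),
                 time_dist("gamma", 2, 0.7))) {
    Tmax <- 3
    n <- 400; dt <- Tmax / n
    kg <- kernel_on_grid(d, dt, n)
    vals <- kg$values
    u <- kg$impulse_weight +
      cumsum(c(0, (vals[-1] + vals[-length(vals)]) / 2 * dt))
    mT <- sum((u[-1] + u[-length(u)]) / 2 * dt)
    set.seed(99)
    k <- ceiling(Tmax / dist_moments(d)$mean * 3 + 20)
    draws <- matrix(dist_sample(d, 1e5 * k), 1e5, k)
    counts <- rowSums(t(apply(draws, 1, cumsum)) <= Tmax)
    expect_lt(abs(mT - mean(counts)), 3 * sd(counts) / sqrt(1e5))
  }
})

test_that("distribution spec strings round trip bit-exactly", {
  for (s in c("exp:2.3", "gamma:0.2,2.5", "invgauss:1.26,1.22")) {
    d <- parse_dist(s)
    expect_identical(parse_dist(format(d)), d)
  }
  d <- time_dist("invgauss", mean = 1 / 3, shape = pi)
  expect_identical(parse_dist(format(d)), d)
  expect_error(parse_dist("exp"), "family:p1")
  expect_error(parse_dist("weird:1"), "unknown")
})
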
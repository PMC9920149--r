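test_that("parameter validation rejects non-SPD inputs", {
  expect_error(ou_params(matrix(c(1, 2, 0, 1), 2), diag(2)), "symmetric")
  expect_error(ou_params(diag(c(1, -1)), diag(2)), "positive eigenvalues")
  expect_error(ou_params(diag(2), diag(0, 2)), "positive eigenvalues")
  expect_error(ou_params(diag(2), diag(2), mu = c(1, NA)))
})

test_that("stationary covariance matches the scalar closed form Gamma^2/(2B)", {
  D <- stationary_covariance(ou_params(diag(c(1, 2)), diag(2)))
  expect_equal(D, diag(c(0.5, 0.25)), tolerance = 1e-12)
  D2 <- stationary_covariance(ou_params(diag(2), diag(2)))
  expect_equal(D2, diag(0.5, 2), tolerance = 1e-12)
})

test_that("stationary covariance solves the Lyapunov equation for random SPD pairs", {
  set.seed(11)
  for (i in 1:100) {
    B <- random_spd(); G <- random_spd()
    D <- stationary_covariance(ou_params(B, G))
    expect_lt(max(abs(B %*% D + D %*% t(B) - G %*% G)), 1e-10)
    expect_equal(D, t(D))
    expect_true(all(eigen(D, only.values = TRUE)$values >= 0))
  }
})

test_that("transition moments: identity at dt=0, scalar closed form, stationary limit", {
  p <- ou_params(diag(2), diag(2), mu = c(0, 0))
  m0 <- transition_moments(p, c(3, -2), dt = 0)
  expect_equal(m0$mean, c(3, -2))
  expect_equal(m0$cov_psi, matrix(0, 2, 2), tolerance = 1e-14)

  m1 <- transition_moments(p, c(1, 1), dt = 1)
  expect_equal(m1$mean, rep(exp(-1), 2), tolerance = 1e-12)
  expect_equal(m1$cov_psi, diag(0.5 * (1 - exp(-2)), 2), tolerance = 1e-12)

  mL <- transition_moments(p, c(1, 1), dt = 50)
  expect_equal(mL$mean, c(0, 0), tolerance = 1e-9)
  expect_equal(mL$cov_psi, stationary_covariance(p), tolerance = 1e-9)
})

test_that("Psi grows monotonically in the Loewner order with dt", {
  set.seed(12)
  for (i in 1:10) {
    p <- ou_params(random_spd(), random_spd(), mu = c(0, 0))
    dts <- c(0, 0.5, 1, 2, 5, 10, 50)
    psis <- lapply(dts, function(dt)
      transition_moments(p, c(0, 0), dt)$cov_psi)
    for (j in seq_along(dts)[-1]) {
      diff <- psis[[j]] - psis[[j - 1]]
      expect_gt(min(eigen(diff, only.values = TRUE)$values), -1e-10)
    }
    D <- stationary_covariance(p)
    expect_gt(min(eigen(D - psis[[1]], only.values = TRUE)$values), -1e-10)
  }
})

test_that("exact sampler is deterministic under a seed and degenerates to the mean", {
  p <- fix_params()
  mom <- transition_moments(p, c(90, 95), dt = 1)
  set.seed(5); a <- sample_transition(mom, 10)
  set.seed(5); b <- sample_transition(mom, 10)
  expect_identical(a, b)

  tiny <- structure(list(mean = c(1, 2), cov_psi = diag(1e-12, 2)),
                    class = "ou_moments")
  set.seed(6)
  expect_equal(as.numeric(sample_transition(tiny, 1)), c(1, 2),
               tolerance = 1e-5)
})

test_that("sampler moments match the analytic transition moments", {
  p <- fix_params(mu = c(0, 0))
  mom <- transition_moments(p, c(10, -5), dt = 1)
  set.seed(7)
  d <- sample_transition(mom, 20000)
  se_mean <- sqrt(diag(mom$cov_psi) / 20000)
  expect_true(all(abs(colMeans(d) - mom$mean) < 4 * se_mean))
  emp <- stats::cov(d)
  for (i in 1:2) for (j in 1:2) {
    se <- sqrt((mom$cov_psi[i, i] * mom$cov_psi[j, j] +
                mom$cov_psi[i, j]^2) / 20000)
    expect_lt(abs(emp[i, j] - mom$cov_psi[i, j]), 4 * se)
  }
})

test_that("event log-likelihood equals a naive per-step oracle", {
  set.seed(8)
  p <- ou_params(matrix(c(0.3, 0.05, 0.05, 0.4), 2),
                 matrix(c(1, 0.2, 0.2, 1.5), 2), mu = c(5, 5))
  x <- simulate_event(p, c(0, 0), 50)
  naive <- 0
  for (i in 1:49) {
    mo <- transition_moments(p, x[i, ], 1)
    r <- x[i + 1, ] - mo$mean
    naive <- naive - log(2 * pi) - 0.5 * log(det(mo$cov_psi)) -
      0.5 * sum(r * solve(mo$cov_psi, r))
  }
  expect_equal(event_log_likelihood(x, p), naive, tolerance = 1e-10)

  # two-sample slice is a single bivariate normal log-density
  x2 <- x[1:2, ]
  mo <- transition_moments(p, x2[1, ], 1)
  r <- x2[2, ] - mo$mean
  byhand <- -log(2 * pi) - 0.5 * log(det(mo$cov_psi)) -
    0.5 * sum(r * solve(mo$cov_psi, r))
  expect_equal(event_log_likelihood(x2, p), byhand, tolerance = 1e-10)
  expect_error(event_log_likelihood(x[1, , drop = FALSE], p), "at least 2")
})

test_that("true parameters beat perturbed ones on a long slice", {
  set.seed(9)
  p <- fix_params(mu = c(0, 0))
  x <- simulate_event(p, c(0, 0), 5000)
  doubled <- ou_params(2 * p$B, p$Gamma, p$mu)
  expect_gt(event_log_likelihood(x, p), event_log_likelihood(x, doubled))
})

test_that("diagonal parameters give two independent 1-D processes", {
  set.seed(13)
  p <- ou_params(diag(c(0.1, 0.2)), diag(c(1, 2)), mu = c(0, 0))
  x <- simulate_event(p, c(0, 0), 20000)
  expect_lt(abs(stats::cor(x[, 1], x[, 2])), 0.1)
  D <- stationary_covariance(p)
  expect_equal(D[1, 2], 0)
})

test_that("exact sampler agrees with fine-step Euler-Maruyama moments", {
  p <- ou_params(matrix(c(0.4, 0.1, 0.1, 0.3), 2),
                 matrix(c(1, 0.2, 0.2, 0.8), 2), mu = c(0, 0))
  x0 <- c(5, -3)
  sub <- 200; h <- 1 / sub; n_rep <- 5000
  set.seed(14)
  # Euler-Maruyama over one unit step, many replicates
  X <- matrix(rep(x0, n_rep), ncol = 2, byrow = TRUE)
  drift <- p$B; noise <- p$Gamma * sqrt(h)
  for (s in 1:sub) {
    eps <- matrix(stats::rnorm(2 * n_rep), ncol = 2) %*% t(noise)
    X <- X + t(drift %*% t(-X)) * h + eps
  }
  mom <- transition_moments(p, x0, dt = 1)
  se <- sqrt(diag(mom$cov_psi) / n_rep)
  expect_true(all(abs(colMeans(X) - mom$mean) < 4 * se))
  expect_equal(stats::cov(X), mom$cov_psi, tolerance = 0.05)
})
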
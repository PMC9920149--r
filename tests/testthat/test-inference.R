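test_that("posterior recovers known parameters from a long simulated event", {
  set.seed(51)
  truth <- fix_params()
  ev <- simulated_event(truth, n = 3000)
  ps <- infer_event_posterior(ev)
  tru <- c(0.05, 0.01, 0.06, 1, 0.3, 1.2)
  rel <- abs(ps$mean - tru) / abs(tru)
  # diagonals within 20% relative, off-diagonals within 0.2 absolute
  diag_i <- ps$component %in% c("b_ii", "b_jj", "g_ii", "g_jj")
  expect_true(all(rel[diag_i] <= 0.2))
  expect_true(all(abs(ps$mean - tru)[!diag_i] <= 0.2))
  # a 94% interval misses ~once in 17 per component; demand most cover
  expect_gte(sum(ps$hdi_lower <= tru & tru <= ps$hdi_upper), 5)
  expect_true(all(ps$mean[ps$component %in% c("b_ii", "b_jj", "g_ii",
                                              "g_jj")] > 0))
  expect_equal(attr(ps, "method"), "map_laplace")
})

test_that("variational and Laplace posteriors agree on a long event", {
  set.seed(52)
  ev <- simulated_event(fix_params(), n = 1500)
  a <- infer_event_posterior(ev, method = "map_laplace")
  b <- suppressWarnings(infer_event_posterior(ev, method = "vi"))
  diag_i <- a$component %in% c("b_ii", "b_jj", "g_ii", "g_jj")
  expect_true(all(abs(a$mean - b$mean)[diag_i] /
                  abs(a$mean[diag_i]) <= 0.15))
  expect_true(all(abs(a$mean - b$mean)[!diag_i] <= 0.1))
})

test_that("too-short events are a precondition error", {
  ev <- gaze_event("fixation", 0, 3, samples = matrix(1:6, 3, 2),
                   mu = c(1, 1))
  expect_error(infer_event_posterior(ev, config = list(min_transitions = 5)),
               "transitions")
})

test_that("summarize_draws: degenerate, uniform and arithmetic cases", {
  const <- matrix(3, 100, 2, dimnames = list(NULL, c("a", "b")))
  s <- summarize_draws(const)
  expect_equal(s$mean, c(3, 3))
  expect_equal(s$hdi_upper - s$hdi_lower, c(0, 0))

  set.seed(53)
  u <- matrix(stats::runif(1e5), ncol = 1, dimnames = list(NULL, "u"))
  s2 <- summarize_draws(u, hdi_mass = 0.95)
  expect_equal(s2$hdi_upper - s2$hdi_lower, 0.95, tolerance = 0.011)

  s3 <- summarize_draws(matrix(c(1, 2, 3), ncol = 1))
  expect_equal(s3$mean, 2)
  expect_error(summarize_draws(matrix(1, 1, 1)), "at least 2")
})

test_that("posterior is invariant to translating the slice and attractor", {
  set.seed(54)
  ev <- simulated_event(fix_params(mu = c(0, 0)), n = 600)
  shifted <- gaze_event(ev$kind, ev$start, ev$end,
                        samples = ev$samples + rep(c(250, -80), each = 600),
                        mu = c(250, -80))
  set.seed(99); a <- infer_event_posterior(ev)
  set.seed(99); b <- infer_event_posterior(shifted)
  expect_equal(a$mean, b$mean, tolerance = 1e-6)
})

test_that("mean HDI width shrinks as events get longer", {
  width_at <- function(n, seed) {
    set.seed(seed)
    ps <- infer_event_posterior(simulated_event(fix_params(), n = n))
    mean(ps$hdi_upper - ps$hdi_lower)
  }
  short <- mean(vapply(1:3, function(s) width_at(120, s), 0))
  long <- mean(vapply(1:3, function(s) width_at(1500, s + 10), 0))
  expect_lt(long, short)
})

test_that("94% HDIs are calibrated over prior-drawn parameters", {
  # reduced simulation-based calibration: draw (B, Gamma) from the prior
  # (half-normal scales, LKJ(2) correlations), simulate, infer, count
  # coverage per component
  set.seed(55)
  n_rep <- 50
  covered <- matrix(NA, n_rep, 6)
  for (r in seq_len(n_rep)) {
    draw_spd <- function(sd) {
      s <- abs(stats::rnorm(2, 0, sd))
      s <- pmax(pmin(s, 3 * sd), 0.05)
      rho <- 2 * stats::rbeta(1, 2, 2) - 1   # LKJ(2) marginal for 2x2
      diag(s) %*% matrix(c(1, rho, rho, 1), 2) %*% diag(s)
    }
    truth <- ou_params(draw_spd(1), draw_spd(5), mu = c(0, 0))
    ev <- simulated_event(truth, n = 800)
    ps <- tryCatch(infer_event_posterior(ev, config = list(n_draws = 2000)),
                   warning = function(w) NULL, error = function(e) NULL)
    if (is.null(ps)) next
    tru <- c(truth$B[1, 1], truth$B[1, 2], truth$B[2, 2],
             truth$Gamma[1, 1], truth$Gamma[1, 2], truth$Gamma[2, 2])
    covered[r, ] <- ps$hdi_lower <= tru & tru <= ps$hdi_upper
  }
  cover <- colMeans(covered, na.rm = TRUE)
  expect_true(all(cover >= 0.84))
})

test_that("hdi_interval finds the narrowest mass window", {
  # bimodal sample: mass concentrated near 0, narrow window excludes the
  # far outliers
  x <- c(rep(0, 90), rep(100, 10))
  h <- hdi_interval(x, 0.9)
  expect_equal(h, c(0, 0))
  set.seed(56)
  g <- stats::rnorm(5e4)
  h2 <- hdi_interval(g, 0.94)
  q <- stats::qnorm(c(0.03, 0.97))
  expect_equal(h2, q, tolerance = 0.05)
})
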
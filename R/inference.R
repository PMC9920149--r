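#' Prior specification for the O-U matrices
#'
#' Both `B` and `Gamma` are constrained to be symmetric positive-definite
#' by decomposing them as `S C S` with `S = diag(s)` a positive scale
#' vector and `C` a correlation matrix. The correlation gets an LKJ prior
#' (concentration `eta`, `eta = 1` uniform, larger values shrink towards
#' the identity) and the scales get half-normal priors. Defaults are weakly
#' informative at the data's unit scale: drift scales (1/sqrt(sample))
#' rarely exceed 1, diffusion scales (px^(1/2)/sample^(1/4)) rarely
#' exceed 5.
#'
#' @param lkj_eta_B,lkj_eta_G LKJ concentrations (> 0).
#' @param scale_sd_B,scale_sd_G half-normal standard deviations for the
#'   scale components of `B` and `Gamma`.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(lkj_eta_B = 2, lkj_eta_G = 2,
                       scale_sd_B = 1.0, scale_sd_G = 5.0) {
  stopifnot(lkj_eta_B > 0, lkj_eta_G > 0, scale_sd_B > 0, scale_sd_G > 0)
  structure(list(lkj_eta_B = lkj_eta_B, lkj_eta_G = lkj_eta_G,
                 scale_sd_B = scale_sd_B, scale_sd_G = scale_sd_G),
            class = "prior_spec")
}

# --- unconstrained parameterisation -----------------------------------------
# theta = (log sB1, log sB2, atanh rhoB, log sG1, log sG2, atanh rhoG)
# B = S_B C_B S_B, Gamma = S_G C_G S_G; always SPD for finite theta.

theta_to_mats <- function(theta) {
  sB <- exp(theta[1:2]); rB <- tanh(theta[3])
  sG <- exp(theta[4:5]); rG <- tanh(theta[6])
  list(B = matrix(c(sB[1]^2, rB * sB[1] * sB[2],
                    rB * sB[1] * sB[2], sB[2]^2), 2),
       Gamma = matrix(c(sG[1]^2, rG * sG[1] * sG[2],
                        rG * sG[1] * sG[2], sG[2]^2), 2))
}

# the six free matrix entries in descriptor order
theta_to_entries <- function(theta) {
  m <- theta_to_mats(theta)
  c(b_ii = m$B[1, 1], b_ij = m$B[1, 2], b_jj = m$B[2, 2],
    g_ii = m$Gamma[1, 1], g_ij = m$Gamma[1, 2], g_jj = m$Gamma[2, 2])
}

# log prior density in theta space (half-normal scales + LKJ correlations,
# including the log-Jacobians of exp and tanh)
log_prior_theta <- function(theta, prior) {
  sB <- exp(theta[1:2]); sG <- exp(theta[4:5])
  rB <- tanh(theta[3]); rG <- tanh(theta[6])
  sum(-sB^2 / (2 * prior$scale_sd_B^2) + log(sB)) +
    sum(-sG^2 / (2 * prior$scale_sd_G^2) + log(sG)) +
    prior$lkj_eta_B * log1p(-rB^2) +
    prior$lkj_eta_G * log1p(-rG^2)
}

# fast unit-step O-U log-likelihood: single spectral decomposition of B per
# evaluation; algebra identical to event_log_likelihood()
ou_loglik_fast <- function(theta, Z, jitter = 1e-9) {
  if (any(!is.finite(theta)) || any(abs(theta[c(1, 2, 4, 5)]) > 50))
    return(-Inf)
  m <- theta_to_mats(theta)
  if (any(!is.finite(m$B)) || any(!is.finite(m$Gamma))) return(-Inf)
  e <- eigen(m$B, symmetric = TRUE)
  if (min(e$values) <= 0) return(-Inf)   # |rho| saturated at 1
  V <- e$vectors
  A <- V %*% (exp(-e$values) * t(V))
  Q <- t(V) %*% (m$Gamma %*% m$Gamma) %*% V
  D <- V %*% (Q / outer(e$values, e$values, "+")) %*% t(V)
  Psi <- D - A %*% D %*% t(A)
  Psi <- (Psi + t(Psi)) / 2
  if (any(!is.finite(Psi))) return(-Inf)
  if (min(diag(Psi)) < 1e-12 ||
      Psi[1, 1] * Psi[2, 2] - Psi[1, 2]^2 <
        1e-10 * max(Psi[1, 1] * Psi[2, 2], 1e-300))
    Psi <- Psi + diag(jitter, 2)
  U <- tryCatch(chol(Psi), error = function(e) NULL)
  if (is.null(U)) return(-Inf)
  n <- nrow(Z) - 1L
  R <- Z[-1, , drop = FALSE] - Z[-nrow(Z), , drop = FALSE] %*% t(A)
  quad <- rowSums((R %*% chol2inv(U)) * R)
  -n * log(2 * pi) - n * sum(log(diag(U))) - 0.5 * sum(quad)
}

log_posterior_theta <- function(theta, Z, prior, jitter = 1e-9) {
  lp <- ou_loglik_fast(theta, Z, jitter) + log_prior_theta(theta, prior)
  if (!is.finite(lp)) -1e12 else lp
}

# moment-matched starting point: per-dimension lag-1 autoregression of the
# centred slice gives B_ii and the residual variance gives Gamma_ii
theta_init <- function(Z) {
  n <- nrow(Z)
  u <- numeric(6)
  for (d in 1:2) {
    z0 <- Z[-n, d]; z1 <- Z[-1, d]
    a <- if (sum(z0^2) > 0) sum(z0 * z1) / sum(z0^2) else 0.5
    a <- min(max(a, 0.01), 0.995)
    b <- -log(a)
    psi <- stats::var(z1 - a * z0)
    psi <- max(psi, 1e-6)
    dvar <- psi / (1 - a^2)
    g <- sqrt(2 * b * dvar)        # Gamma_ii estimate
    u[d] <- 0.5 * log(b)
    u[3 + d] <- 0.5 * log(g)
  }
  u
}

#' Infer the per-event posterior over (B, Gamma)
#'
#' Bayesian estimation of the event's drift and diffusion matrices from its
#' sample slice, with the attractor `mu` fixed by segmentation. Both
#' matrices are parameterised as scale vector + LKJ-distributed correlation
#' through an unconstrained transform, so every iterate is symmetric
#' positive-definite.
#'
#' Two approximations are offered: `"map_laplace"` (default) maximises the
#' log posterior (BFGS) and draws from the Gaussian curvature approximation
#' at the mode — fast and deterministic given a seed; `"vi"` runs
#' mean-field variational inference (Adam on the reparameterised evidence
#' bound) in the same unconstrained space, mirroring ADVI-style inference.
#' Either way the posterior is summarised from `n_draws` draws transformed
#' back to the six free matrix entries.
#'
#' @param event a `gaze_event` with samples and attractor attached.
#' @param prior a [prior_spec()].
#' @param method `"map_laplace"` or `"vi"`.
#' @param config list of settings: `n_draws` (default 1000), `hdi_mass`
#'   (0.94), `min_transitions` (5), `jitter` (1e-9), `vi_iters` (2000),
#'   `vi_lr` (0.05), `vi_patience` (300).
#' @return A `posterior_summary` (see [summarize_draws()]) with attributes
#'   `method` and `converged`.
#' @export
infer_event_posterior <- function(event, prior = prior_spec(),
                                  method = c("map_laplace", "vi"),
                                  config = list()) {
  method <- match.arg(method)
  stopifnot(inherits(event, "gaze_event"))
  cfg <- utils::modifyList(list(n_draws = 1000, hdi_mass = 0.94,
                                min_transitions = 5, jitter = 1e-9,
                                vi_iters = 2000, vi_lr = 0.05,
                                vi_patience = 300), config)
  if (is.null(event$samples) || is.null(event$mu))
    stop("event must carry its sample slice and attractor")
  if (event$n_transitions < cfg$min_transitions)
    stop(sprintf("event has %d transitions; at least %d required",
                 event$n_transitions, cfg$min_transitions))
  Z <- sweep(event$samples, 2, event$mu)
  neg <- function(th) -log_posterior_theta(th, Z, prior, cfg$jitter)
  th0 <- theta_init(Z)
  opt <- stats::optim(th0, neg, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
  converged <- opt$convergence == 0
  if (method == "map_laplace") {
    H <- stats::optimHess(opt$par, neg)
    H <- (H + t(H)) / 2
    ridge <- 0
    repeat {
      ch <- tryCatch(chol(H + diag(ridge, 6)), error = function(e) NULL)
      if (!is.null(ch)) break
      ridge <- max(ridge * 10, 1e-6)
      converged <- FALSE
    }
    # draws theta ~ N(mode, H^{-1}) via the Cholesky of the precision
    zmat <- matrix(stats::rnorm(6 * cfg$n_draws), nrow = 6)
    theta_draws <- t(opt$par + backsolve(ch, zmat))
    diagnostic <- c(neg_log_post = opt$value, hess_ridge = ridge)
  } else {
    fit <- advi_meanfield(opt$par, Z, prior, cfg)
    converged <- converged && fit$converged
    zmat <- matrix(stats::rnorm(6 * cfg$n_draws), nrow = 6)
    theta_draws <- t(fit$m + exp(fit$log_s) * zmat)
    diagnostic <- c(elbo = fit$elbo, iters = fit$iters)
  }
  draws <- t(apply(theta_draws, 1, theta_to_entries))
  out <- summarize_draws(draws, hdi_mass = cfg$hdi_mass)
  attr(out, "method") <- method
  attr(out, "converged") <- converged
  attr(out, "diagnostic") <- diagnostic
  if (!converged) warning("posterior approximation flagged as not converged")
  out
}

# mean-field ADVI: maximise E_q[log p] + entropy with q = N(m, diag(s^2)),
# Adam steps on the reparameterised single-sample gradient estimator;
# gradients of the log posterior by central finite differences
advi_meanfield <- function(m0, Z, prior, cfg) {
  m <- m0; log_s <- rep(log(0.1), 6)
  lp <- function(th) log_posterior_theta(th, Z, prior, cfg$jitter)
  grad_lp <- function(th, h = 1e-5) {
    g <- numeric(6)
    for (j in 1:6) {
      e <- numeric(6); e[j] <- h
      g[j] <- (lp(th + e) - lp(th - e)) / (2 * h)
    }
    g
  }
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  mm <- vv <- numeric(12)
  best <- -Inf; since_best <- 0; smoothed <- NULL
  it <- 0
  for (it in seq_len(cfg$vi_iters)) {
    epsd <- stats::rnorm(6)
    s <- exp(log_s)
    th <- m + s * epsd
    g <- grad_lp(th)
    grad <- c(g, g * epsd * s + 1)          # d/dm, d/dlog_s (+entropy)
    mm <- b1 * mm + (1 - b1) * grad
    vv <- b2 * vv + (1 - b2) * grad^2
    step <- cfg$vi_lr * (mm / (1 - b1^it)) / (sqrt(vv / (1 - b2^it)) + eps)
    m <- m + step[1:6]
    log_s <- pmin(log_s + step[7:12], 2)
    elbo_est <- lp(th) + sum(log_s)
    smoothed <- if (is.null(smoothed)) elbo_est
                else 0.98 * smoothed + 0.02 * elbo_est
    if (smoothed > best + 1e-3) { best <- smoothed; since_best <- 0 }
    else since_best <- since_best + 1
    if (since_best > cfg$vi_patience) break
  }
  list(m = m, log_s = log_s, elbo = smoothed, iters = it,
       converged = is.finite(smoothed))
}

#' Summarise posterior draws into means and HDIs
#'
#' The mean is the sample average; the highest density interval is the
#' narrowest contiguous interval of the sorted draws containing `hdi_mass`
#' of them.
#'
#' @param draws matrix of posterior draws, one column per component
#'   (column names are kept).
#' @param hdi_mass probability mass of the interval, in (0, 1).
#' @return A `posterior_summary`: data.frame with columns `component`,
#'   `mean`, `hdi_lower`, `hdi_upper`, plus attributes `n_draws` and
#'   `hdi_mass`.
#' @export
summarize_draws <- function(draws, hdi_mass = 0.94) {
  draws <- as.matrix(draws)
  stopifnot(hdi_mass > 0, hdi_mass < 1)
  if (nrow(draws) < 2) stop("at least 2 draws per component required")
  comp <- colnames(draws) %||% paste0("c", seq_len(ncol(draws)))
  hdis <- apply(draws, 2, hdi_interval, mass = hdi_mass)
  out <- data.frame(component = comp, mean = colMeans(draws),
                    hdi_lower = hdis[1, ], hdi_upper = hdis[2, ],
                    row.names = NULL)
  structure(out, class = c("posterior_summary", "data.frame"),
            n_draws = nrow(draws), hdi_mass = hdi_mass)
}

#' Highest density interval of a sample
#'
#' Narrowest contiguous interval containing `mass` of the sorted draws.
#'
#' @param x numeric draws.
#' @param mass probability mass in (0, 1).
#' @return c(lower, upper).
#' @export
hdi_interval <- function(x, mass = 0.94) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n == 0) return(c(NA_real_, NA_real_))
  m <- min(n, max(1L, ceiling(mass * n)))
  k <- n - m + 1
  widths <- x[m:n] - x[seq_len(k)]
  i <- which.min(widths)
  c(x[i], x[i + m - 1])
}
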
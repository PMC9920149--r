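#' Ornstein-Uhlenbeck parameter set
#'
#' Bundles the parameters of the 2-D mean-reverting diffusion
#' \deqn{dx(t) = B(\mu - x(t))\,dt + \Gamma\,dW(t),}
#' where `B` (units 1/sample) scales the pull of the gaze position towards
#' the attractor `mu` and `Gamma` (px/sqrt(sample)) is the symmetric
#' amplitude of the driving white noise, so the instantaneous noise
#' covariance is `Gamma %*% Gamma`. Both matrices must be symmetric with
#' strictly positive eigenvalues: positive eigenvalues of `B` guarantee
#' convergence to a stationary distribution.
#'
#' @param B 2x2 symmetric matrix with positive eigenvalues (drift).
#' @param Gamma 2x2 symmetric positive-definite matrix (diffusion amplitude).
#' @param mu length-2 attractor point in pixels (saccade landing point or
#'   fixation centre).
#' @return An object of class `ou_params`.
#' @examples
#' p <- ou_params(B = diag(c(1, 2)), Gamma = diag(2), mu = c(0, 0))
#' stationary_covariance(p)
#' @export
ou_params <- function(B, Gamma, mu = c(0, 0)) {
  B <- as.matrix(B); Gamma <- as.matrix(Gamma)
  check_spd(B, "B")
  check_spd(Gamma, "Gamma")
  stopifnot(length(mu) == 2, all(is.finite(mu)))
  structure(list(B = B, Gamma = Gamma, mu = as.numeric(mu)),
            class = "ou_params")
}

# symmetry within a tolerance relative to the matrix scale, eigenvalues > 0
check_spd <- function(M, name, tol = 1e-8) {
  if (!is.matrix(M) || any(dim(M) != 2) || !all(is.finite(M)))
    stop(name, " must be a finite 2x2 matrix", call. = FALSE)
  if (max(abs(M - t(M))) > tol * max(1, max(abs(M))))
    stop(name, " must be symmetric", call. = FALSE)
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0))
    stop(name, " must have strictly positive eigenvalues", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.ou_params <- function(x, ...) {
  cat("O-U parameters (unit time step = 1 sample)\n")
  cat("  B     =", format(x$B[1, 1], digits = 4), format(x$B[1, 2], digits = 4),
      "/", format(x$B[2, 2], digits = 4), "\n")
  cat("  Gamma =", format(x$Gamma[1, 1], digits = 4),
      format(x$Gamma[1, 2], digits = 4), "/",
      format(x$Gamma[2, 2], digits = 4), "\n")
  cat("  mu    = (", x$mu[1], ",", x$mu[2], ") px\n")
  invisible(x)
}

# matrix exponential exp(-B * dt) for symmetric B via spectral decomposition
# (exact for symmetric matrices)
expm_neg_sym <- function(B, dt) {
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  e$vectors %*% (exp(-e$values * dt) * t(e$vectors))
}

#' Stationary covariance of the O-U process
#'
#' Solves the continuous Lyapunov equation `B D + D B^T = Gamma^2` for the
#' long-run covariance `D` of the process. For symmetric `B` the solve is
#' spectral and exact; in the commuting case it reduces to the scalar form
#' `D = Gamma^2 (2B)^{-1}` (componentwise `Gamma_ii^2 / (2 B_ii)` when both
#' matrices are diagonal).
#'
#' @param params An [ou_params()] object.
#' @return A 2x2 symmetric positive-definite matrix (px^2).
#' @export
stationary_covariance <- function(params) {
  stopifnot(inherits(params, "ou_params"))
  B <- params$B
  Q <- params$Gamma %*% params$Gamma
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  V <- e$vectors
  Qt <- t(V) %*% Q %*% V
  M <- Qt / outer(e$values, e$values, "+")
  D <- V %*% M %*% t(V)
  (D + t(D)) / 2
}

#' Exact transition moments of the O-U process
#'
#' Conditional on `x(t) = x`, the position `dt` samples later is Gaussian
#' with mean `mu + exp(-B dt) (x - mu)` and covariance
#' `Psi = D - exp(-B dt) D exp(-B^T dt)`, `D` being the stationary
#' covariance. `Psi` is symmetrised and its eigenvalues clipped at zero at
#' machine tolerance, so `dt = 0` yields exactly the degenerate (zero
#' covariance) case and `dt -> Inf` approaches `D`.
#'
#' @param params An [ou_params()] object.
#' @param x length-2 current position (px).
#' @param dt time step in samples (non-negative; the package's discrete
#'   model uses `dt = 1` throughout).
#' @return An object of class `ou_moments`: list with `mean` (length 2) and
#'   `cov_psi` (2x2 PSD matrix).
#' @export
transition_moments <- function(params, x, dt = 1) {
  stopifnot(inherits(params, "ou_params"), length(x) == 2, dt >= 0)
  A <- expm_neg_sym(params$B, dt)
  D <- stationary_covariance(params)
  Psi <- D - A %*% D %*% t(A)
  Psi <- (Psi + t(Psi)) / 2
  e <- eigen(Psi, symmetric = TRUE)
  Psi <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
  Psi <- (Psi + t(Psi)) / 2
  structure(list(mean = as.numeric(params$mu + A %*% (x - params$mu)),
                 cov_psi = Psi),
            class = "ou_moments")
}

#' Draw from the exact O-U transition density
#'
#' Samples the bivariate normal with the given transition moments. Uses the
#' spectral square root of the covariance so degenerate (rank-deficient)
#' `Psi` is handled exactly. Reproducible under [set.seed()].
#'
#' @param moments An `ou_moments` object from [transition_moments()].
#' @param n number of draws.
#' @return An `n` x 2 matrix of positions (px).
#' @export
sample_transition <- function(moments, n = 1) {
  stopifnot(inherits(moments, "ou_moments"), n >= 1)
  e <- eigen(moments$cov_psi, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), 2)
  z <- matrix(stats::rnorm(2 * n), nrow = 2)
  t(moments$mean + L %*% z)
}

#' Log-likelihood of a gaze-event slice under O-U dynamics
#'
#' Markov factorisation of the slice likelihood: with unit time step the
#' conditional distribution of each sample given its predecessor is Gaussian
#' with constant propagator `A = exp(-B)` and covariance `Psi`, so the
#' log-likelihood is the sum over transitions of the bivariate normal
#' log-density of `x[i+1]` about `mu + A (x[i] - mu)`.
#'
#' A small jitter is added to the diagonal of `Psi` when it is nearly
#' singular (tiny diffusion over a single step), keeping the density proper
#' for short low-noise fixations.
#'
#' @param xe numeric n x 2 matrix, the event slice (n >= 2).
#' @param params An [ou_params()] object; `params$mu` is the event attractor.
#' @param jitter diagonal regularisation (px^2) applied when `Psi` is nearly
#'   singular. Default `1e-9`.
#' @return Scalar log-likelihood.
#' @export
event_log_likelihood <- function(xe, params, jitter = 1e-9) {
  xe <- as.matrix(xe)
  stopifnot(inherits(params, "ou_params"))
  if (nrow(xe) < 2) stop("event slice must contain at least 2 samples")
  mom <- transition_moments(params, xe[1, ], dt = 1)
  A <- expm_neg_sym(params$B, 1)
  Psi <- mom$cov_psi
  ev <- eigen(Psi, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10 * max(ev, 1e-300) || min(ev) < 1e-12)
    Psi <- Psi + diag(jitter, 2)
  n <- nrow(xe) - 1L
  X0 <- sweep(xe[seq_len(n), , drop = FALSE], 2, params$mu)
  X1 <- sweep(xe[seq_len(n) + 1L, , drop = FALSE], 2, params$mu)
  R <- X1 - X0 %*% t(A)
  U <- chol(Psi)
  Z <- R %*% chol2inv(U) # n x 2, Psi^{-1} applied to residual rows
  quad <- rowSums(R * Z)
  -n * log(2 * pi) - n * sum(log(diag(U))) - 0.5 * sum(quad)
}
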
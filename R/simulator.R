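#' Per-subject generative parameters
#'
#' The composite (switching) O-U model gives every subject two parameter
#' regimes: a fixational one (weak drift, small diffusion — local wandering
#' around the fixation centre) and a saccadic one (strong drift towards the
#' landing point). Durations of the two event kinds are drawn from
#' configurable distributions.
#'
#' @param B_fix,Gamma_fix,B_sac,Gamma_sac 2x2 symmetric positive-definite
#'   matrices (units 1/sample and px/sqrt(sample)).
#' @param fix_dur list: `dist = "lognormal"`, `mean`, `sd` in samples.
#' @param sac_dur list: `dist = "uniform"`, `min`, `max` in samples.
#' @return An object of class `subject_params`.
#' @export
subject_params <- function(B_fix = diag(0.03, 2), Gamma_fix = diag(0.4, 2),
                           B_sac = diag(0.5, 2), Gamma_sac = diag(3, 2),
                           fix_dur = list(dist = "lognormal",
                                          mean = 250, sd = 80),
                           sac_dur = list(dist = "uniform",
                                          min = 20, max = 60)) {
  check_spd(as.matrix(B_fix), "B_fix"); check_spd(as.matrix(Gamma_fix), "Gamma_fix")
  check_spd(as.matrix(B_sac), "B_sac"); check_spd(as.matrix(Gamma_sac), "Gamma_sac")
  stopifnot(fix_dur$mean > 0, sac_dur$min > 0, sac_dur$max >= sac_dur$min)
  structure(list(B_fix = as.matrix(B_fix), Gamma_fix = as.matrix(Gamma_fix),
                 B_sac = as.matrix(B_sac), Gamma_sac = as.matrix(Gamma_sac),
                 fix_dur = fix_dur, sac_dur = sac_dur),
            class = "subject_params")
}

draw_duration <- function(spec) {
  d <- switch(spec$dist,
    lognormal = {
      s2 <- log(1 + (spec$sd / spec$mean)^2)
      stats::rlnorm(1, meanlog = log(spec$mean) - s2 / 2, sdlog = sqrt(s2))
    },
    uniform = stats::runif(1, spec$min, spec$max),
    fixed = spec$value,
    stop("unknown duration distribution: ", spec$dist))
  max(2L, as.integer(round(d)))
}

#' Simulate one O-U event by exact transition sampling
#'
#' Iterates the exact unit-step conditional Gaussian of the O-U process
#' starting from `x0`; no time-discretisation error is incurred (the
#' transition density is exact at any step size).
#'
#' @param params [ou_params()] for the event (including its attractor).
#' @param x0 length-2 starting position (px).
#' @param n number of samples returned, including `x0` (n >= 2).
#' @return n x 2 matrix of positions.
#' @export
simulate_event <- function(params, x0, n) {
  stopifnot(n >= 2)
  mom <- transition_moments(params, x0, dt = 1)
  A <- expm_neg_sym(params$B, 1)
  e <- eigen(mom$cov_psi, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), 2)
  out <- matrix(0, n, 2)
  out[1, ] <- x0
  eps <- matrix(stats::rnorm(2 * (n - 1)), ncol = 2) %*% t(L)
  x <- x0 - params$mu
  for (i in 2:n) {
    x <- as.numeric(A %*% x) + eps[i - 1, ]
    out[i, ] <- x + params$mu
  }
  out
}

#' Simulate a full scan path from the switching O-U model
#'
#' Alternates fixations and saccades, starting with a fixation at a
#' uniformly drawn on-screen point. Each saccade is pulled towards a fresh
#' uniformly drawn target (with a 50-px screen inset); each fixation's
#' attractor is the preceding saccade's landing point. Events concatenate
#' continuously: every event starts from the last simulated position.
#' Trajectories are not clipped at the screen edge (clipping would distort
#' the O-U statistics).
#'
#' @param subject a [subject_params()] object.
#' @param screen c(width, height) in px.
#' @param total trajectory length in samples; the last event is truncated
#'   to fit.
#' @param sample_rate_hz sampling rate recorded on the trajectory.
#' @param subject_id,stimulus_id labels for the output.
#' @param inset margin (px) kept between drawn targets and the screen edge.
#' @return List with `trajectory` (a [gaze_trajectory()]) and `events`
#'   (ground-truth `gaze_event` list with true attractors).
#' @export
simulate_scanpath <- function(subject, screen = c(1024, 768), total = 2000,
                              sample_rate_hz = 1000, subject_id = "s01",
                              stimulus_id = "k01", inset = 50) {
  stopifnot(inherits(subject, "subject_params"), total >= 2)
  if (any(screen <= 0)) stop("screen dimensions must be positive")
  draw_target <- function()
    c(stats::runif(1, inset, screen[1] - inset),
      stats::runif(1, inset, screen[2] - inset))
  samples <- matrix(NA_real_, total, 2)
  spans <- list()
  mu <- draw_target()
  x <- mu
  pos <- 0L          # samples emitted so far
  kind <- "fixation"
  while (pos < total) {
    dur <- draw_duration(if (kind == "fixation") subject$fix_dur
                         else subject$sac_dur)
    first <- pos == 0L
    n_emit <- min(dur, total - pos)
    if (n_emit < 2 && !first) break
    par_e <- if (kind == "fixation")
      ou_params(subject$B_fix, subject$Gamma_fix, mu)
    else ou_params(subject$B_sac, subject$Gamma_sac, mu)
    # the first event's span includes x0; later events continue from the
    # previous event's last sample, which is not re-emitted
    seg <- simulate_event(par_e, x, n = max(2L, n_emit + as.integer(!first)))
    emit <- if (first) seg[seq_len(n_emit), , drop = FALSE]
            else seg[1 + seq_len(n_emit), , drop = FALSE]
    samples[pos + seq_len(n_emit), ] <- emit
    spans[[length(spans) + 1]] <-
      list(kind = kind, start = pos, end = pos + n_emit, mu = mu)
    x <- emit[nrow(emit), ]
    pos <- pos + n_emit
    # next event: saccade to a fresh target, or fixation at the landing point
    if (kind == "fixation") { kind <- "saccade"; mu <- draw_target() }
    else { kind <- "fixation"; mu <- x }
  }
  samples <- samples[seq_len(pos), , drop = FALSE]
  traj <- gaze_trajectory(samples, subject_id = subject_id,
                          stimulus_id = stimulus_id,
                          sample_rate_hz = sample_rate_hz)
  events <- lapply(Filter(function(s) s$end - s$start >= 2, spans),
                   function(s)
    gaze_event(s$kind, s$start, s$end,
               samples = samples[(s$start + 1):s$end, , drop = FALSE],
               mu = s$mu, subject_id = subject_id, stimulus_id = stimulus_id))
  list(trajectory = traj, events = events)
}

#' Cohort specification for the synthetic-data generator
#'
#' @param n_subjects,n_scanpaths counts (>= 1).
#' @param length scan-path length in samples.
#' @param screen c(width, height) px.
#' @param separation non-negative scaling of the between-subject spread of
#'   generative parameters: subject-level log-scale parameters are drawn
#'   with log-sd `separation * 0.35` about the hyper-means, correlations
#'   with sd `separation * 0.3` on the atanh scale. `separation = 0` makes
#'   every subject share the hyper-means.
#' @param within_sd optional log-sd of within-subject (per-scan-path)
#'   parameter jitter; default 0 (a subject's parameters are fixed).
#' @param sample_rate_hz sampling rate.
#' @param hyper hyper-mean [subject_params()] the cohort is drawn around.
#' @param seed optional integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 5, n_scanpaths = 12, length = 2000,
                        screen = c(1024, 768), separation = 1,
                        within_sd = 0, sample_rate_hz = 1000,
                        hyper = subject_params(), seed = NULL) {
  stopifnot(n_subjects >= 1, n_scanpaths >= 1, length >= 2,
            separation >= 0, within_sd >= 0, all(screen > 0))
  structure(list(n_subjects = n_subjects, n_scanpaths = n_scanpaths,
                 length = length, screen = screen, separation = separation,
                 within_sd = within_sd, sample_rate_hz = sample_rate_hz,
                 hyper = hyper, seed = seed),
            class = "cohort_spec")
}

# one subject's parameters drawn about the hyper-means: log-normal jitter on
# the scale components, atanh-normal jitter on the correlations. Draws are
# rejected until the fixation/saccade regime contrast that defines the
# composite model survives: fixations must stay the slow regime (weak
# drift, quiet diffusion) and saccades the fast one (drift strong enough
# to reach their target), otherwise the generated event labels would be
# semantically empty at any separation.
draw_subject <- function(hyper, separation, log_cv = 0.35, rho_sd = 0.3) {
  jitter_mat <- function(M) {
    s <- sqrt(diag(M))
    rho <- M[1, 2] / (s[1] * s[2])
    s <- s * exp(stats::rnorm(2, 0, separation * log_cv))
    rho <- tanh(atanh(rho) + stats::rnorm(1, 0, separation * rho_sd))
    out <- diag(s) %*% matrix(c(1, rho, rho, 1), 2) %*% diag(s)
    (out + t(out)) / 2
  }
  for (attempt in 1:200) {
    cand <- subject_params(B_fix = jitter_mat(hyper$B_fix),
                           Gamma_fix = jitter_mat(hyper$Gamma_fix),
                           B_sac = jitter_mat(hyper$B_sac),
                           Gamma_sac = jitter_mat(hyper$Gamma_sac),
                           fix_dur = hyper$fix_dur, sac_dur = hyper$sac_dur)
    ok <- max(diag(cand$Gamma_fix)) <= 1.2 &&
      max(diag(cand$B_fix)) <= 0.3 &&
      min(diag(cand$B_sac)) >= 0.15 &&
      min(diag(cand$Gamma_sac)) >= 0.5
    if (ok) return(cand)
  }
  cand
}

#' Generate a labelled synthetic cohort
#'
#' Draws one parameter set per subject from hyper-distributions whose
#' between-subject spread scales with `spec$separation`, then simulates
#' `n_scanpaths` scan paths per subject. Deterministic under `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return List with `subjects` (list of true [subject_params()]),
#'   `scanpaths` (list of `simulate_scanpath()` results, labelled
#'   subject/stimulus), and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  subjects <- lapply(seq_len(spec$n_subjects), function(i)
    draw_subject(spec$hyper, spec$separation))
  names(subjects) <- sprintf("s%02d", seq_len(spec$n_subjects))
  scanpaths <- list()
  for (i in seq_len(spec$n_subjects)) {
    for (k in seq_len(spec$n_scanpaths)) {
      subj <- subjects[[i]]
      if (spec$within_sd > 0) {
        jit <- function(M) {
          out <- M * exp(stats::rnorm(1, 0, spec$within_sd))
          (out + t(out)) / 2
        }
        subj <- subject_params(jit(subj$B_fix), jit(subj$Gamma_fix),
                               jit(subj$B_sac), jit(subj$Gamma_sac),
                               subj$fix_dur, subj$sac_dur)
      }
      scanpaths[[length(scanpaths) + 1]] <-
        simulate_scanpath(subj, screen = spec$screen, total = spec$length,
                          sample_rate_hz = spec$sample_rate_hz,
                          subject_id = sprintf("s%02d", i),
                          stimulus_id = sprintf("k%02d", k))
    }
  }
  list(subjects = subjects, scanpaths = scanpaths, spec = spec)
}
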
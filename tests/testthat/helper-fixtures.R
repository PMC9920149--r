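# shared fixture builders; everything is generated in code under fixed seeds

random_spd <- function() {
  A <- matrix(stats::rnorm(4), 2)
  crossprod(A) + diag(stats::runif(1, 0.05, 0.5), 2)
}

# a fixation-regime O-U parameter set with mild cross-correlation
fix_params <- function(mu = c(100, 100)) {
  ou_params(B = matrix(c(0.05, 0.01, 0.01, 0.06), 2),
            Gamma = matrix(c(1, 0.3, 0.3, 1.2), 2), mu = mu)
}

# simulated event wrapped as a gaze_event with its true attractor
simulated_event <- function(params, n = 1000, kind = "fixation",
                            x0 = params$mu) {
  x <- simulate_event(params, x0, n)
  gaze_event(kind, 0, n, samples = x, mu = params$mu)
}

# three-phase trajectory: hold at a, linear ramp to b, hold at b
ramp_trajectory <- function(a = c(100, 100), b = c(500, 400),
                            n_hold = 100, n_ramp = 20) {
  ramp <- cbind(seq(a[1], b[1], length.out = n_ramp + 2)[2:(n_ramp + 1)],
                seq(a[2], b[2], length.out = n_ramp + 2)[2:(n_ramp + 1)])
  gaze_trajectory(rbind(matrix(a, n_hold, 2, byrow = TRUE), ramp,
                        matrix(b, n_hold, 2, byrow = TRUE)))
}

# small well-separated cohort reused across identification/evaluation tests
separated_cohort_features <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set.seed(4242)
      co <- generate_cohort(cohort_spec(n_subjects = 3, n_scanpaths = 6,
                                        length = 900, separation = 2,
                                        seed = 99))
      ev <- unlist(lapply(co$scanpaths, function(s)
        segment_velocity(s$trajectory)), recursive = FALSE)
      cache <<- build_features(ev)
    }
    cache
  }
})

# synthetic per-event descriptor table with two linearly separable classes
toy_features <- function(n_per = 20, shift = 6, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (cl in c("a", "b")) for (kind in c("fixation", "saccade")) {
    X <- matrix(stats::rnorm(n_per * 12), n_per, 12)
    if (cl == "b") X <- X + shift
    colnames(X) <- gazeou:::descriptor_cols()
    rows[[length(rows) + 1]] <-
      cbind(data.frame(subject_id = cl,
                       stimulus_id = sprintf("k%02d", seq_len(n_per)),
                       kind = kind), as.data.frame(X))
  }
  do.call(rbind, rows)
}
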
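test_that("constant-position trajectory parses to a single fixation", {
  traj <- gaze_trajectory(matrix(c(100, 100), 200, 2, byrow = TRUE))
  evs <- segment_velocity(traj)
  expect_length(evs, 1)
  expect_equal(evs[[1]]$kind, "fixation")
  expect_equal(c(evs[[1]]$start, evs[[1]]$end), c(0, 200))
  expect_equal(evs[[1]]$mu, c(x = 100, y = 100))
})

test_that("hold-ramp-hold trajectory parses to fixation/saccade/fixation", {
  traj <- ramp_trajectory(c(100, 100), c(500, 400), n_hold = 100, n_ramp = 20)
  # hand-computed speed profile: the ramp moves 500 px over 21 steps
  # (~23.8 px/sample); holds are static, so any threshold in between splits
  evs <- segment_velocity(traj, vel_threshold = 5, min_fix_samples = 40,
                          min_sac_samples = 5)
  expect_equal(vapply(evs, `[[`, "", "kind"),
               c("fixation", "saccade", "fixation"))
  spans <- t(vapply(evs, function(e) c(e$start, e$end), c(0, 0)))
  expect_equal(spans[2:3, 1], spans[1:2, 2]) # spans tile contiguously
  # saccade onset/offset near the constructed ramp (100..120), +-smoothing
  expect_lt(abs(spans[1, 2] - 100), 5)
  expect_lt(abs(spans[2, 2] - 120), 5)
  # attractors: fixation centroids near holds, saccade arrival near target
  expect_lt(max(abs(evs[[1]]$mu - c(100, 100))), 1)
  expect_lt(max(abs(evs[[2]]$mu - c(500, 400))), 60)
  expect_lt(max(abs(evs[[3]]$mu - c(500, 400))), 1)
})

test_that("an all-fast ramp is a single saccade", {
  n <- 50
  traj <- gaze_trajectory(cbind(seq(0, 490, length.out = n),
                                seq(0, 245, length.out = n)))
  evs <- segment_velocity(traj, vel_threshold = 0.8, min_fix_samples = 10,
                          min_sac_samples = 5)
  expect_length(evs, 1)
  expect_equal(evs[[1]]$kind, "saccade")
  expect_equal(c(evs[[1]]$start, evs[[1]]$end), c(0, n))
})

test_that("too-short trajectories yield an empty result with a warning", {
  traj <- gaze_trajectory(matrix(rnorm(20), 10, 2))
  expect_warning(evs <- segment_velocity(traj, min_fix_samples = 40),
                 "shorter")
  expect_length(evs, 0)
})

test_that("attractors follow the centroid / arrival-point rule", {
  ev_f <- gaze_event("fixation", 0, 2, samples = rbind(c(0, 0), c(2, 2)))
  expect_equal(unname(attach_attractors(list(ev_f))[[1]]$mu), c(1, 1))
  ev_s <- gaze_event("saccade", 0, 3,
                     samples = rbind(c(0, 0), c(250, 190), c(512, 384)))
  expect_equal(unname(attach_attractors(list(ev_s))[[1]]$mu), c(512, 384))
  rep10 <- matrix(5, 10, 2)
  for (kind in c("fixation", "saccade")) {
    ev <- gaze_event(kind, 0, 10, samples = rep10)
    expect_equal(unname(attach_attractors(list(ev))[[1]]$mu), c(5, 5))
  }
  ev_bad <- gaze_event("fixation", 0, 5)
  expect_error(attach_attractors(list(ev_bad)), "no samples")
})

test_that("external label import honours runs and drops 'other'", {
  set.seed(21)
  traj <- gaze_trajectory(matrix(rnorm(26), 13, 2))
  labs <- c(rep("fixation", 5), rep("saccade", 4), rep("fixation", 4))
  evs <- import_external_segmentation(traj, labs)
  expect_equal(vapply(evs, `[[`, "", "kind"),
               c("fixation", "saccade", "fixation"))
  expect_equal(t(vapply(evs, function(e) c(e$start, e$end), c(0, 0))),
               cbind(c(0, 5, 9), c(5, 9, 13)))

  expect_length(import_external_segmentation(traj, rep("other", 13)), 0)

  labs2 <- c(rep("fixation", 5), rep("other", 3), rep("saccade", 5))
  evs2 <- import_external_segmentation(traj, labs2)
  expect_equal(t(vapply(evs2, function(e) c(e$start, e$end), c(0, 0))),
               cbind(c(0, 8), c(5, 13)))

  expect_error(import_external_segmentation(traj, labs[1:5]),
               "does not match")
  expect_error(import_external_segmentation(traj, rep("blink", 13)),
               "labels must be")
})

test_that("parsed events never overlap and spans are monotone", {
  set.seed(22)
  sp <- simulate_scanpath(subject_params(), total = 1500)
  evs <- segment_velocity(sp$trajectory)
  spans <- t(vapply(evs, function(e) c(e$start, e$end), c(0, 0)))
  expect_true(all(diff(spans[, 1]) > 0))
  expect_true(all(spans[-1, 1] >= spans[-nrow(spans), 2]))
  kinds <- vapply(evs, `[[`, "", "kind")
  expect_true(all(kinds[-1] != kinds[-length(kinds)])) # strict alternation
})

test_that("segmentation recovers simulator ground-truth boundaries under strong contrast", {
  # strong regime contrast: brisk saccades whose speed stays above threshold
  # almost until the nominal switch, quiet fixations well below it
  subj <- subject_params(B_fix = diag(0.02, 2), Gamma_fix = diag(0.15, 2),
                         B_sac = diag(0.5, 2), Gamma_sac = diag(1.5, 2),
                         fix_dur = list(dist = "lognormal", mean = 180,
                                        sd = 30),
                         sac_dur = list(dist = "uniform", min = 12,
                                        max = 16))
  set.seed(23)
  hits <- 0; total <- 0
  for (r in 1:10) {
    sp <- simulate_scanpath(subj, total = 1500)
    evs <- segment_velocity(sp$trajectory, vel_threshold = 0.5,
                            min_fix_samples = 40, min_sac_samples = 6)
    truth_b <- unique(unlist(lapply(sp$events, function(e)
      c(e$start, e$end))))
    det_b <- unique(unlist(lapply(evs, function(e) c(e$start, e$end))))
    total <- total + length(truth_b)
    hits <- hits + sum(vapply(truth_b, function(b)
      any(abs(det_b - b) <= 5), TRUE))
  }
  expect_gte(hits / total, 0.9)
})
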
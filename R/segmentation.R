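#' Construct a gaze event
#'
#' A fixation or saccade slice of a parent trajectory, with a 0-based
#' half-open sample span `[start, end)` and (once attached) the attractor
#' point `mu` the O-U model reverts to: the centroid for a fixation, the
#' final sample (landing point) for a saccade.
#'
#' @param kind `"fixation"` or `"saccade"`.
#' @param start,end 0-based half-open span indices, `end - start >= 2`.
#' @param samples the slice as an (end-start) x 2 matrix, or `NULL`.
#' @param mu attractor (px, px), or `NULL` before [attach_attractors()].
#' @param subject_id,stimulus_id labels inherited from the trajectory.
#' @return An object of class `gaze_event`.
#' @export
gaze_event <- function(kind, start, end, samples = NULL, mu = NULL,
                       subject_id = NULL, stimulus_id = NULL) {
  kind <- match.arg(kind, c("fixation", "saccade"))
  stopifnot(end - start >= 2, start >= 0)
  if (!is.null(samples)) {
    samples <- as.matrix(samples)
    stopifnot(nrow(samples) == end - start, ncol(samples) == 2)
  }
  structure(list(kind = kind, start = as.integer(start),
                 end = as.integer(end), samples = samples, mu = mu,
                 subject_id = subject_id, stimulus_id = stimulus_id,
                 n_transitions = if (is.null(samples)) end - start - 1L
                                 else nrow(samples) - 1L),
            class = "gaze_event")
}

#' @export
print.gaze_event <- function(x, ...) {
  cat(sprintf("%s [%d, %d)%s\n", x$kind, x$start, x$end,
              if (!is.null(x$mu))
                sprintf("  mu = (%.1f, %.1f)", x$mu[1], x$mu[2]) else ""))
  invisible(x)
}

# per-sample speed (px/sample): centred finite difference, then a 5-sample
# centred moving average; edges padded with the nearest interior value
sample_speed <- function(samples, smooth = 5) {
  n <- nrow(samples)
  v <- matrix(0, n, 2)
  if (n >= 3) v[2:(n - 1), ] <- (samples[3:n, ] - samples[1:(n - 2), ]) / 2
  v[1, ] <- samples[2, ] - samples[1, ]
  v[n, ] <- samples[n, ] - samples[n - 1, ]
  sp <- sqrt(rowSums(v^2))
  if (smooth > 1 && n > smooth) {
    sm <- stats::filter(sp, rep(1 / smooth, smooth), sides = 2)
    sm <- as.numeric(sm)
    half <- (smooth - 1) / 2
    sm[seq_len(half)] <- sm[half + 1]
    sm[(n - half + 1):n] <- sm[n - half]
    sp <- sm
  }
  sp
}

#' Velocity-threshold event segmentation (I-VT style)
#'
#' Parses a raw trajectory into an alternating sequence of fixations and
#' saccades: samples whose smoothed speed (centred finite difference,
#' 5-sample moving average) exceeds `vel_threshold` are saccadic, the rest
#' fixational. Runs shorter than the per-kind minimum are merged into the
#' neighbouring event of the other kind, so the output strictly alternates.
#' This is deliberately simple plumbing: the downstream O-U inference works
#' from the raw samples and is robust to the exact parser used, and an
#' external event classifier can be plugged in through
#' [import_external_segmentation()].
#'
#' @param traj a [gaze_trajectory()].
#' @param vel_threshold speed threshold in px/sample (default 0.8, a
#'   typical magnitude for 1000-Hz screen data).
#' @param min_fix_samples,min_sac_samples minimum run lengths (samples).
#' @param min_transitions events with fewer transitions are flagged
#'   `usable = FALSE` (kept, excluded from inference downstream).
#' @return List of `gaze_event` with attractors attached.
#' @export
segment_velocity <- function(traj, vel_threshold = 0.8, min_fix_samples = 40,
                             min_sac_samples = 10, min_transitions = 5) {
  stopifnot(inherits(traj, "gaze_trajectory"),
            vel_threshold > 0, min_fix_samples > 0, min_sac_samples > 0)
  n <- nrow(traj$samples)
  if (n < min_fix_samples) {
    warning("trajectory shorter than min_fix_samples; no events")
    return(list())
  }
  lab <- ifelse(sample_speed(traj$samples) > vel_threshold,
                "saccade", "fixation")
  runs <- rle(lab)
  min_for <- function(kind) ifelse(kind == "fixation",
                                   min_fix_samples, min_sac_samples)
  # absorb sub-minimum runs into their neighbours, shortest first
  repeat {
    if (length(runs$lengths) <= 1) break
    short <- which(runs$lengths < min_for(runs$values))
    if (length(short) == 0) break
    i <- short[which.min(runs$lengths[short])]
    runs$values[i] <- ifelse(runs$values[i] == "fixation",
                             "saccade", "fixation")
    runs <- rle(inverse.rle(runs))
  }
  starts <- cumsum(c(0L, runs$lengths[-length(runs$lengths)]))
  events <- mapply(function(s, len, kind) {
    if (len < 2) return(NULL)
    gaze_event(kind, s, s + len,
               samples = traj$samples[(s + 1):(s + len), , drop = FALSE],
               subject_id = traj$subject_id, stimulus_id = traj$stimulus_id)
  }, starts, runs$lengths, runs$values, SIMPLIFY = FALSE)
  events <- Filter(Negate(is.null), events)
  events <- attach_attractors(events)
  flag_short_events(events, min_transitions)
}

flag_short_events <- function(events, min_transitions) {
  lapply(events, function(ev) {
    ev$usable <- ev$n_transitions >= min_transitions
    ev
  })
}

#' Attach attractor points to events
#'
#' The attractor `mu` of the O-U model is the fixation centroid
#' (componentwise mean of the slice) for fixations and the arrival point
#' (final sample) for saccades; it is fixed by segmentation, never
#' inferred.
#'
#' @param events list of `gaze_event` carrying their sample slices.
#' @return The events with `mu` set.
#' @export
attach_attractors <- function(events) {
  lapply(events, function(ev) {
    if (is.null(ev$samples) || nrow(ev$samples) == 0)
      stop("cannot attach attractor: event carries no samples")
    ev$mu <- if (ev$kind == "fixation") colMeans(ev$samples)
             else ev$samples[nrow(ev$samples), ]
    ev
  })
}

#' Import an external per-sample event labelling
#'
#' Adapter for labels produced by an external classifier (e.g. a
#' segmented-regression/HMM event classifier): maximal runs of identical
#' labels become
#' events; runs labelled `"other"` (smooth pursuit, post-saccadic
#' oscillations, ...) are dropped and excluded from neighbouring spans.
#'
#' @param traj a [gaze_trajectory()].
#' @param labels character vector, one label per sample, each one of
#'   `"fixation"`, `"saccade"`, `"other"`.
#' @param min_transitions see [segment_velocity()].
#' @return List of `gaze_event` with attractors attached.
#' @export
import_external_segmentation <- function(traj, labels, min_transitions = 5) {
  stopifnot(inherits(traj, "gaze_trajectory"))
  n <- nrow(traj$samples)
  if (length(labels) != n)
    stop(sprintf("label count (%d) does not match sample count (%d)",
                 length(labels), n))
  if (!all(labels %in% c("fixation", "saccade", "other")))
    stop("labels must be 'fixation', 'saccade' or 'other'")
  runs <- rle(as.character(labels))
  starts <- cumsum(c(0L, runs$lengths[-length(runs$lengths)]))
  keep <- runs$values != "other" & runs$lengths >= 2
  events <- mapply(function(s, len, kind) {
    gaze_event(kind, s, s + len,
               samples = traj$samples[(s + 1):(s + len), , drop = FALSE],
               subject_id = traj$subject_id, stimulus_id = traj$stimulus_id)
  }, starts[keep], runs$lengths[keep], runs$values[keep], SIMPLIFY = FALSE)
  events <- attach_attractors(events)
  flag_short_events(events, min_transitions)
}
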
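# fixed descriptor column order: (mean, HDI width) for each of the six free
# entries of B then Gamma
descriptor_cols <- function() {
  comps <- c("b_ii", "b_ij", "b_jj", "g_ii", "g_ij", "g_jj")
  as.vector(rbind(paste0(comps, "_avg"), paste0(comps, "_hdi")))
}

#' Assemble the 12-dimensional event descriptor
#'
#' Flattens a per-event posterior summary into the fixed-order feature
#' vector: for each of the six free matrix entries (B_ii, B_ij, B_jj,
#' Gamma_ii, Gamma_ij, Gamma_jj) the posterior mean followed by the HDI
#' width (upper minus lower), i.e. the estimate and its uncertainty.
#'
#' @param summary a `posterior_summary` from [infer_event_posterior()],
#'   with components `b_ii, b_ij, b_jj, g_ii, g_ij, g_jj`.
#' @param kind `"fixation"` or `"saccade"`.
#' @param subject_id,stimulus_id labels.
#' @return One-row data.frame: `subject_id`, `stimulus_id`, `kind`, then
#'   the twelve descriptor columns (see [write_features()]).
#' @export
event_descriptor <- function(summary, kind, subject_id = NA_character_,
                             stimulus_id = NA_character_) {
  stopifnot(inherits(summary, "posterior_summary"))
  comps <- c("b_ii", "b_ij", "b_jj", "g_ii", "g_ij", "g_jj")
  miss <- setdiff(comps, summary$component)
  if (length(miss) > 0)
    stop("posterior summary missing component(s): ",
         paste(miss, collapse = ", "))
  i <- match(comps, summary$component)
  vec <- as.vector(rbind(summary$mean[i],
                         summary$hdi_upper[i] - summary$hdi_lower[i]))
  names(vec) <- descriptor_cols()
  cbind(data.frame(subject_id = subject_id, stimulus_id = stimulus_id,
                   kind = kind),
        as.data.frame(as.list(vec)))
}

#' Scan-path descriptor: mean fixation and saccade blocks
#'
#' Componentwise mean of the event descriptors of one trajectory within
#' each kind, concatenated fixation block first (24 values). If one kind is
#' absent its block is `NA` and its count zero; downstream fusion treats
#' the absent kind as neutral.
#'
#' @param events data.frame of event descriptors of a single trajectory
#'   (rows from [event_descriptor()]).
#' @return One-row data.frame: ids, `n_fix`, `n_sac`, then `fix_*` and
#'   `sac_*` blocks of 12 columns each.
#' @export
scanpath_descriptor <- function(events) {
  stopifnot(is.data.frame(events))
  if (nrow(events) == 0) stop("no event descriptors supplied")
  cols <- descriptor_cols()
  block <- function(kind) {
    sub <- events[events$kind == kind, cols, drop = FALSE]
    if (nrow(sub) == 0) list(n = 0L, v = rep(NA_real_, length(cols)))
    else list(n = nrow(sub), v = colMeans(sub))
  }
  f <- block("fixation"); s <- block("saccade")
  if (f$n == 0 && s$n == 0) stop("no fixation or saccade descriptors")
  out <- data.frame(subject_id = events$subject_id[1],
                    stimulus_id = events$stimulus_id[1],
                    n_fix = f$n, n_sac = s$n)
  out[paste0("fix_", cols)] <- as.list(f$v)
  out[paste0("sac_", cols)] <- as.list(s$v)
  out
}

#' Subject summary descriptor
#'
#' Componentwise mean of a subject's scan-path descriptors over the K
#' viewed stimuli; blocks missing in individual scan paths (no usable
#' event of that kind) are ignored with renormalised counts.
#'
#' @param scanpaths data.frame of [scanpath_descriptor()] rows of one
#'   subject.
#' @return One-row data.frame with `subject_id`, `k_scanpaths` and the 24
#'   averaged columns.
#' @export
subject_summary <- function(scanpaths) {
  stopifnot(is.data.frame(scanpaths))
  if (nrow(scanpaths) == 0) stop("no scan-path descriptors supplied")
  cols <- c(paste0("fix_", descriptor_cols()), paste0("sac_", descriptor_cols()))
  out <- data.frame(subject_id = scanpaths$subject_id[1],
                    k_scanpaths = nrow(scanpaths))
  out[cols] <- as.list(colMeans(scanpaths[cols], na.rm = TRUE))
  out
}

#' Build the per-event features table for a set of trajectories
#'
#' Runs per-event posterior inference over every usable event and stacks
#' the resulting descriptors. Events flagged too short for inference
#' (fewer than `min_transitions` transitions) are skipped and counted.
#'
#' @param events list of `gaze_event` (attractors attached, labels set).
#' @param prior a [prior_spec()].
#' @param method,config forwarded to [infer_event_posterior()].
#' @param verbose print progress.
#' @return data.frame of event descriptors; attribute `n_excluded` counts
#'   skipped events.
#' @export
build_features <- function(events, prior = prior_spec(),
                           method = "map_laplace", config = list(),
                           verbose = FALSE) {
  min_tr <- config$min_transitions %||% 5
  usable <- vapply(events, function(ev) ev$n_transitions >= min_tr, TRUE)
  rows <- lapply(events[usable], function(ev) {
    ps <- infer_event_posterior(ev, prior = prior, method = method,
                                config = config)
    if (verbose)
      message(sprintf("  %s [%d,%d) inferred (%s)", ev$kind, ev$start,
                      ev$end, attr(ps, "method")))
    event_descriptor(ps, kind = ev$kind, subject_id = ev$subject_id,
                     stimulus_id = ev$stimulus_id)
  })
  out <- if (length(rows) > 0) do.call(rbind, rows)
         else stop("no usable events to featurise")
  attr(out, "n_excluded") <- sum(!usable)
  out
}

#' Scan-path descriptors for a whole features table
#'
#' @param features per-event features table (see [build_features()]).
#' @return data.frame, one [scanpath_descriptor()] row per
#'   (subject, stimulus) pair.
#' @export
build_scanpath_descriptors <- function(features) {
  key <- interaction(features$subject_id, features$stimulus_id, drop = TRUE)
  do.call(rbind, lapply(split(features, key), scanpath_descriptor))
}
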
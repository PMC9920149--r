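#' Construct a gaze trajectory
#'
#' An ordered sequence of 2-D gaze samples recorded on screen at a known
#' sampling rate. Coordinates are screen pixels, origin top-left, x
#' rightward, y downward; sample indices are 0-based and event spans over a
#' trajectory are half-open `[start, end)`.
#'
#' @param samples numeric n x 2 matrix of (x, y) positions in px, n >= 2.
#' @param subject_id,stimulus_id character labels.
#' @param sample_rate_hz positive sampling rate (samples/second).
#' @param t optional numeric timestamps (ms), strictly increasing. When
#'   absent, the sample index at the stated rate substitutes (the discrete
#'   model uses unit steps either way).
#' @return An object of class `gaze_trajectory`.
#' @export
gaze_trajectory <- function(samples, subject_id = "s01", stimulus_id = "k01",
                            sample_rate_hz = 1000, t = NULL) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 2) stop("trajectory must contain at least 2 samples")
  if (!all(is.finite(samples))) stop("all gaze coordinates must be finite")
  stopifnot(ncol(samples) == 2, sample_rate_hz > 0)
  colnames(samples) <- c("x", "y")
  if (!is.null(t)) {
    t <- as.numeric(t)
    if (length(t) != nrow(samples))
      stop("timestamp length must match sample count")
    if (any(diff(t) <= 0))
      stop(sprintf("timestamps not strictly increasing in trajectory %s/%s",
                   subject_id, stimulus_id))
  }
  structure(list(subject_id = as.character(subject_id),
                 stimulus_id = as.character(stimulus_id),
                 sample_rate_hz = sample_rate_hz,
                 samples = samples, t = t),
            class = "gaze_trajectory")
}

#' @export
print.gaze_trajectory <- function(x, ...) {
  cat(sprintf("gaze trajectory %s/%s: %d samples @ %g Hz\n",
              x$subject_id, x$stimulus_id, nrow(x$samples), x$sample_rate_hz))
  invisible(x)
}

default_gaze_schema <- c(subject_id = "subject_id", stimulus_id = "stimulus_id",
                         t_ms = "t_ms", x_px = "x_px", y_px = "y_px")

#' Read gaze trajectories from a CSV table
#'
#' The gaze CSV dialect is comma-separated UTF-8 with a header row and
#' columns `subject_id,stimulus_id,t_ms,x_px,y_px`; `schema` renames them
#' for files using other headers. One trajectory is produced per
#' (subject, stimulus) pair, samples kept in file order; every input row
#' lands in exactly one trajectory.
#'
#' @param path CSV file path.
#' @param schema named character vector mapping the canonical names
#'   (`subject_id`, `stimulus_id`, `t_ms`, `x_px`, `y_px`) to the file's
#'   column names. `t_ms` may be mapped to `NA` for files without
#'   timestamps.
#' @param sample_rate_hz sampling rate attached to every trajectory.
#' @return List of [gaze_trajectory()] objects.
#' @export
read_gaze_table <- function(path, schema = default_gaze_schema,
                            sample_rate_hz = 1000) {
  if (!file.exists(path)) stop("no such file: ", path)
  schema <- utils::modifyList(as.list(default_gaze_schema), as.list(schema))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "stimulus_id", "x_px", "y_px")
  for (nm in needed) {
    col <- schema[[nm]]
    if (is.na(col) || !col %in% names(df))
      stop("missing column: ", col %||% nm, " (schema field '", nm, "')")
  }
  has_t <- !is.na(schema$t_ms) && schema$t_ms %in% names(df)
  key <- paste(df[[schema$subject_id]], df[[schema$stimulus_id]], sep = "\r")
  idx <- split(seq_len(nrow(df)), factor(key, levels = unique(key)))
  trajs <- lapply(idx, function(i) {
    gaze_trajectory(cbind(df[[schema$x_px]][i], df[[schema$y_px]][i]),
                    subject_id = df[[schema$subject_id]][i[1]],
                    stimulus_id = df[[schema$stimulus_id]][i[1]],
                    sample_rate_hz = sample_rate_hz,
                    t = if (has_t) df[[schema$t_ms]][i] else NULL)
  })
  if (sum(vapply(trajs, function(tr) nrow(tr$samples), 0L)) != nrow(df))
    stop("reader dropped rows; input is inconsistent") # defensive, not reachable
  unname(trajs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write gaze trajectories to the gaze CSV dialect
#'
#' @param trajs list of [gaze_trajectory()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_gaze_table <- function(trajs, path) {
  rows <- lapply(trajs, function(tr) {
    n <- nrow(tr$samples)
    data.frame(subject_id = tr$subject_id, stimulus_id = tr$stimulus_id,
               t_ms = if (!is.null(tr$t)) tr$t
                      else (seq_len(n) - 1) * 1000 / tr$sample_rate_hz,
               x_px = tr$samples[, 1], y_px = tr$samples[, 2])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write parsed gaze events to CSV
#'
#' Columns `subject_id,stimulus_id,kind,start,end,mu_x,mu_y` with 0-based
#' half-open sample spans. An empty collection produces a header-only file.
#'
#' @param events list of `gaze_event` objects (see [segment_velocity()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  df <- events_to_df(events)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

events_to_df <- function(events) {
  if (length(events) == 0)
    return(data.frame(subject_id = character(), stimulus_id = character(),
                      kind = character(), start = integer(), end = integer(),
                      mu_x = numeric(), mu_y = numeric()))
  do.call(rbind, lapply(events, function(ev)
    data.frame(subject_id = ev$subject_id %||% NA_character_,
               stimulus_id = ev$stimulus_id %||% NA_character_,
               kind = ev$kind, start = ev$start, end = ev$end,
               mu_x = if (is.null(ev$mu)) NA_real_ else ev$mu[1],
               mu_y = if (is.null(ev$mu)) NA_real_ else ev$mu[2])))
}

#' Read an events CSV (as written by [write_events()])
#'
#' @param path events CSV path.
#' @param trajs optional list of trajectories; when supplied, each event is
#'   re-attached to its trajectory slice.
#' @return List of `gaze_event` objects.
#' @export
read_events <- function(path, trajs = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  traj_key <- NULL
  if (!is.null(trajs))
    traj_key <- stats::setNames(
      trajs, vapply(trajs, function(tr)
        paste(tr$subject_id, tr$stimulus_id, sep = "\r"), ""))
  lapply(seq_len(nrow(df)), function(i) {
    samples <- NULL
    if (!is.null(traj_key)) {
      tr <- traj_key[[paste(df$subject_id[i], df$stimulus_id[i], sep = "\r")]]
      if (!is.null(tr))
        samples <- tr$samples[(df$start[i] + 1):df$end[i], , drop = FALSE]
    }
    gaze_event(kind = df$kind[i], start = df$start[i], end = df$end[i],
               samples = samples, mu = c(df$mu_x[i], df$mu_y[i]),
               subject_id = df$subject_id[i], stimulus_id = df$stimulus_id[i])
  })
}

#' Run configuration
#'
#' Central bundle of tunable settings for the whole pipeline, with
#' validated defaults. Any subset can be overridden; unknown names are an
#' error so config typos never pass silently.
#'
#' @param ... named overrides for the defaults, possibly nested lists for
#'   the groups `segmentation`, `inference`, `classifier`, `cv`,
#'   `simulator`.
#' @return An object of class `run_config` (a validated nested list).
#' @export
run_config <- function(...) {
  defaults <- list(
    seed = 1L,
    segmentation = list(vel_threshold = 0.8, min_fix_samples = 40,
                        min_sac_samples = 10, min_transitions = 5),
    inference = list(method = "map_laplace", n_draws = 1000,
                     hdi_mass = 0.94, vi_iters = 2000, vi_lr = 0.05,
                     jitter = 1e-9),
    classifier = list(kernel = "radial", cost = 1, gamma = "median"),
    cv = list(k = 10),
    simulator = list(n_subjects = 5, n_scanpaths = 12, length = 2000,
                     screen = c(1024, 768), separation = 1, within_sd = 0)
  )
  cfg <- utils::modifyList(defaults, validate_known(list(...), defaults))
  with(cfg$inference, stopifnot(hdi_mass > 0, hdi_mass < 1, n_draws >= 2,
                                vi_iters > 0, vi_lr > 0, jitter >= 0))
  with(cfg$segmentation, stopifnot(vel_threshold > 0, min_fix_samples > 0,
                                   min_sac_samples > 0, min_transitions >= 1))
  with(cfg$cv, stopifnot(k >= 2))
  with(cfg$simulator, stopifnot(n_subjects >= 1, n_scanpaths >= 1,
                                length >= 2, all(screen > 0), separation >= 0))
  structure(cfg, class = "run_config")
}

validate_known <- function(x, defaults) {
  unknown <- setdiff(names(x), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  for (nm in names(x))
    if (is.list(defaults[[nm]]) && is.list(x[[nm]])) {
      bad <- setdiff(names(x[[nm]]), names(defaults[[nm]]))
      if (length(bad) > 0)
        stop("unknown config field(s) in ", nm, ": ",
             paste(bad, collapse = ", "))
    }
  x
}

#' Read/write a run configuration as JSON
#'
#' @param path JSON file path.
#' @return For `read_run_config`, a [run_config()] object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  do.call(run_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname read_run_config
#' @param config a [run_config()] object.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write/read the per-event features table
#'
#' One row per event: `subject_id`, `stimulus_id`, `kind`, then the twelve
#' descriptor columns in fixed order
#' `b_ii_avg,b_ii_hdi,b_ij_avg,b_ij_hdi,b_jj_avg,b_jj_hdi,`
#' `g_ii_avg,g_ii_hdi,g_ij_avg,g_ij_hdi,g_jj_avg,g_jj_hdi`.
#'
#' @param features data.frame as produced by [event_descriptor()] rows.
#' @param path CSV path.
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("subject_id", "stimulus_id", "kind", descriptor_cols()),
                  names(df))
  if (length(miss) > 0)
    stop("features table missing column(s): ", paste(miss, collapse = ", "))
  df
}
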
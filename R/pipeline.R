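#' Run the end-to-end identification pipeline
#'
#' Orchestrates `simulate -> segment -> fit -> featurize -> train ->
#' identify -> evaluate -> report` over documented tabular artefacts in
#' `out_dir`. Any subset of stages can be requested; each stage reads the
#' artefacts its predecessors wrote, so re-running a late stage over
#' existing artefacts is supported and a missing upstream artefact is a
#' dependency error naming the stage. Re-runs with an identical config and
#' seed reproduce identical artefacts for the deterministic stages
#' (everything except `vi`-mode inference, whose draws still depend only
#' on the seed).
#'
#' Artefacts: `gaze.csv`, `events.csv` (and `events_truth.csv` when
#' simulating), `features.csv`, `scanpaths.csv`, `model.rds` +
#' `model_meta.json`, `predictions.csv`, `metrics.json`, `confusion.csv`,
#' `cms.csv`, `roc.csv`, `config.json` (the config snapshot that produced
#' the run).
#'
#' @param config a [run_config()].
#' @param stages character subset of
#'   `c("simulate","segment","fit","featurize","train","identify",
#'   "evaluate","report")`.
#' @param out_dir artefact directory (created if needed).
#' @param verbose print stage progress.
#' @return Named list of artefact paths; when `evaluate` ran, also
#'   `metrics` (a `metrics_report`).
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("simulate", "segment", "fit",
                                    "featurize", "train", "identify",
                                    "evaluate", "report"),
                         out_dir = tempfile("gazeou_run_"),
                         verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, c("simulate", "segment", "fit", "featurize",
                                "train", "identify", "evaluate", "report"),
                      several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  need <- function(f, stage) {
    if (!file.exists(p(f)))
      stop(sprintf("stage '%s' needs missing artefact %s", stage, f))
    p(f)
  }
  say <- function(...) if (verbose) message(sprintf(...))
  write_run_config(config, p("config.json"))
  artefacts <- list(config = p("config.json"))
  metrics <- NULL

  if ("simulate" %in% stages) {
    say("simulate: %d subjects x %d scan paths",
        config$simulator$n_subjects, config$simulator$n_scanpaths)
    sim <- config$simulator
    cohort <- generate_cohort(cohort_spec(
      n_subjects = sim$n_subjects, n_scanpaths = sim$n_scanpaths,
      length = sim$length, screen = sim$screen,
      separation = sim$separation, within_sd = sim$within_sd,
      seed = config$seed))
    write_gaze_table(lapply(cohort$scanpaths, `[[`, "trajectory"),
                     p("gaze.csv"))
    write_events(unlist(lapply(cohort$scanpaths, `[[`, "events"),
                        recursive = FALSE), p("events_truth.csv"))
    artefacts$gaze <- p("gaze.csv")
    artefacts$events_truth <- p("events_truth.csv")
  }

  if ("segment" %in% stages) {
    trajs <- read_gaze_table(need("gaze.csv", "segment"))
    say("segment: %d trajectories", length(trajs))
    seg <- config$segmentation
    events <- unlist(lapply(trajs, function(tr)
      segment_velocity(tr, vel_threshold = seg$vel_threshold,
                       min_fix_samples = seg$min_fix_samples,
                       min_sac_samples = seg$min_sac_samples,
                       min_transitions = seg$min_transitions)),
      recursive = FALSE)
    write_events(events, p("events.csv"))
    artefacts$events <- p("events.csv")
  }

  if ("fit" %in% stages) {
    trajs <- read_gaze_table(need("gaze.csv", "fit"))
    events <- read_events(need("events.csv", "fit"), trajs = trajs)
    say("fit: %d events (%s)", length(events), config$inference$method)
    set.seed(config$seed)
    inf <- config$inference
    features <- build_features(
      events, method = inf$method,
      config = list(n_draws = inf$n_draws, hdi_mass = inf$hdi_mass,
                    min_transitions = config$segmentation$min_transitions,
                    jitter = inf$jitter, vi_iters = inf$vi_iters,
                    vi_lr = inf$vi_lr))
    say("fit: %d events inferred, %d excluded as too short",
        nrow(features), attr(features, "n_excluded"))
    write_features(features, p("features.csv"))
    artefacts$features <- p("features.csv")
  }

  if ("featurize" %in% stages) {
    features <- read_features(need("features.csv", "featurize"))
    sp <- build_scanpath_descriptors(features)
    utils::write.csv(sp, p("scanpaths.csv"), row.names = FALSE)
    subj <- do.call(rbind, lapply(split(sp, sp$subject_id), subject_summary))
    utils::write.csv(subj, p("subjects.csv"), row.names = FALSE)
    artefacts$scanpaths <- p("scanpaths.csv")
    artefacts$subjects <- p("subjects.csv")
  }

  if ("train" %in% stages) {
    features <- read_features(need("features.csv", "train"))
    set.seed(config$seed)
    model <- train_models(features, config = config$classifier)
    saveRDS(model, p("model.rds"))
    jsonlite::write_json(
      list(classes = model$classes, config = model$config,
           fixation_standardiser = model$fixation[c("center", "scale")],
           saccade_standardiser = model$saccade[c("center", "scale")]),
      p("model_meta.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    artefacts$model <- p("model.rds")
  }

  if ("identify" %in% stages) {
    model <- readRDS(need("model.rds", "identify"))
    features <- read_features(need("features.csv", "identify"))
    key <- paste(features$subject_id, features$stimulus_id, sep = "\r")
    rows <- lapply(unique(key), function(kk) {
      sub <- features[key == kk, , drop = FALSE]
      res <- fuse_and_identify(model, sub)
      data.frame(subject_id = sub$subject_id[1],
                 stimulus_id = sub$stimulus_id[1],
                 predicted_id = res$id, top_score = max(res$scores))
    })
    utils::write.csv(do.call(rbind, rows), p("predictions.csv"),
                     row.names = FALSE)
    artefacts$predictions <- p("predictions.csv")
  }

  if ("evaluate" %in% stages) {
    model <- readRDS(need("model.rds", "evaluate"))
    features <- read_features(need("features.csv", "evaluate"))
    say("evaluate: %d-fold CV", config$cv$k)
    metrics <- crossvalidate(features, k = config$cv$k, seed = config$seed,
                             config = model$config)
    jsonlite::write_json(
      list(accuracy = metrics$accuracy, f1 = metrics$f1, eer = metrics$eer,
           auc = metrics$auc, cms = metrics$cms, folds = metrics$folds),
      p("metrics.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(as.data.frame(metrics$confusion), p("confusion.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(rank = seq_along(metrics$cms),
                                cms = metrics$cms),
                     p("cms.csv"), row.names = FALSE)
    utils::write.csv(metrics$roc, p("roc.csv"), row.names = FALSE)
    artefacts$metrics_json <- p("metrics.json")
  }

  if ("report" %in% stages) {
    features <- read_features(need("features.csv", "report"))
    sp <- build_scanpath_descriptors(features)
    ca <- tryCatch(correlation_analyses(sp), error = function(e) NULL)
    rep_lines <- c(
      sprintf("gazeou run report (%s)", format(Sys.time(), "%Y-%m-%d")),
      sprintf("events featurised: %d", nrow(features)),
      sprintf("scan paths: %d, subjects: %d", nrow(sp),
              length(unique(sp$subject_id))),
      if (!is.null(ca))
        sprintf("intra-subject correlation var %.4g, inter %.4g",
                stats::var(ca$intra), stats::var(ca$inter)),
      if (!is.null(metrics))
        sprintf("pooled CV: accuracy %.3f, F1 %.3f, EER %.3f, AUC %.3f",
                metrics$accuracy, metrics$f1, metrics$eer, metrics$auc))
    writeLines(rep_lines, p("report.txt"))
    artefacts$report <- p("report.txt")
  }

  c(artefacts, if (!is.null(metrics)) list(metrics = metrics))
}
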
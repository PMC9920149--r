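#' Train per-kind one-vs-rest identification models
#'
#' Fits, separately for fixations and saccades, one margin classifier per
#' enrolled subject (that subject's events against everyone else's), on
#' z-score-standardised event descriptors. The decision function of class
#' `id` is `w_id' phi(v) + b_id`; raw (uncalibrated) margins are used
#' downstream. Radial-basis kernels with the median heuristic for the
#' kernel width are the default; the standardiser is fitted on the
#' training data only, so cross-validation has no leakage.
#'
#' @param features per-event descriptor table (see [build_features()]).
#' @param config list: `kernel` ("radial" or "linear"), `cost`
#'   (regularisation constant, default 1), `gamma` ("median" for the
#'   median-distance heuristic, or a number).
#' @return An object of class `id_model`: `classes`, and per kind a
#'   standardiser and the list of per-class binary machines.
#' @export
train_models <- function(features, config = list()) {
  cfg <- utils::modifyList(list(kernel = "radial", cost = 1,
                                gamma = "median"), config)
  classes <- sort(unique(features$subject_id))
  if (length(classes) < 2) stop("at least 2 enrolled classes required")
  cols <- descriptor_cols()
  fit_kind <- function(kind) {
    sub <- features[features$kind == kind, , drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    X <- as.matrix(sub[, cols])
    ctr <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    scl[!is.finite(scl) | scl == 0] <- 1
    Xs <- scale(X, center = ctr, scale = scl)
    gamma <- cfg$gamma
    if (identical(gamma, "median")) {
      n <- nrow(Xs)
      idx <- if (n > 200) sample.int(n, 200) else seq_len(n)
      d <- stats::dist(Xs[idx, , drop = FALSE])
      med <- stats::median(d[d > 0])
      gamma <- if (is.finite(med) && med > 0) 1 / (2 * med^2)
               else 1 / ncol(Xs)
    }
    machines <- lapply(classes, function(cl) {
      y <- factor(ifelse(sub$subject_id == cl, "target", "rest"),
                  levels = c("target", "rest"))
      if (sum(y == "target") == 0 || sum(y == "rest") == 0) {
        warning(sprintf(
          "class %s has no %s-event one-vs-rest contrast in training", cl,
          kind))
        return(NULL)
      }
      fit <- e1071::svm(Xs, y, kernel = cfg$kernel, cost = cfg$cost,
                        gamma = gamma, scale = FALSE)
      d <- as.numeric(attr(stats::predict(fit, Xs, decision.values = TRUE),
                           "decision.values"))
      # libsvm's decision sign depends on the first training example;
      # orient so the target class sits on the positive side
      flip <- if (mean(d[y == "target"]) < mean(d[y == "rest"])) -1 else 1
      list(fit = fit, flip = flip)
    })
    names(machines) <- classes
    list(center = ctr, scale = scl, gamma = gamma, machines = machines)
  }
  structure(list(classes = classes, config = cfg,
                 fixation = fit_kind("fixation"),
                 saccade = fit_kind("saccade")),
            class = "id_model")
}

#' @export
print.id_model <- function(x, ...) {
  cat(sprintf("identification model: %d classes (%s)\n", length(x$classes),
              paste(x$classes, collapse = ", ")))
  for (kind in c("fixation", "saccade"))
    cat(sprintf("  %s model: %s\n", kind,
                if (is.null(x[[kind]])) "absent" else
                  sprintf("%s kernel, cost %g", x$config$kernel,
                          x$config$cost)))
  invisible(x)
}

#' Per-event decision vectors
#'
#' Evaluates, for every event, the decision function of each enrolled
#' class using the classifier that matches the event's kind; features are
#' standardised with the model's own training standardiser. Classes with
#' no trained machine for a kind contribute a neutral 0.
#'
#' @param model an [train_models()] output.
#' @param features event descriptor rows to score.
#' @return Numeric matrix, one row per event, one column per class;
#'   attribute `kind` carries the per-row event kinds.
#' @export
decision_vectors <- function(model, features) {
  stopifnot(inherits(model, "id_model"))
  bad <- setdiff(unique(features$kind), c("fixation", "saccade"))
  if (length(bad) > 0) stop("unknown event kind(s): ", paste(bad, collapse = ", "))
  cols <- descriptor_cols()
  out <- matrix(NA_real_, nrow(features), length(model$classes),
                dimnames = list(NULL, model$classes))
  for (kind in c("fixation", "saccade")) {
    rows <- which(features$kind == kind)
    if (length(rows) == 0) next
    mk <- model[[kind]]
    if (is.null(mk)) stop("model has no ", kind, " classifier")
    Xs <- scale(as.matrix(features[rows, cols]),
                center = mk$center, scale = mk$scale)
    for (cl in model$classes) {
      mach <- mk$machines[[cl]]
      out[rows, cl] <- if (is.null(mach)) 0 else
        mach$flip * as.numeric(attr(
          stats::predict(mach$fit, Xs, decision.values = TRUE),
          "decision.values"))
    }
  }
  attr(out, "kind") <- features$kind
  out
}

#' Fuse decision vectors and identify a trajectory's subject
#'
#' Averages the per-event decision vectors over the trajectory's fixations
#' and over its saccades, sums the two averaged vectors (score-level
#' fusion) and returns the argmax class. An absent kind contributes a zero
#' vector, which is neutral under the additive fusion. Ties go to the
#' first class in class-list order.
#'
#' @param model an [train_models()] output.
#' @param features event descriptor rows of a single trajectory.
#' @return List: `id` (predicted class), `scores` (fused vector),
#'   `fix_scores`, `sac_scores` (the per-kind averages).
#' @export
fuse_and_identify <- function(model, features) {
  if (nrow(features) == 0) stop("no events to identify from")
  dv <- decision_vectors(model, features)
  kinds <- attr(dv, "kind")
  avg <- function(kind) {
    rows <- which(kinds == kind)
    if (length(rows) == 0) rep(0, length(model$classes))
    else colMeans(dv[rows, , drop = FALSE])
  }
  fix_scores <- avg("fixation"); sac_scores <- avg("saccade")
  fused <- fix_scores + sac_scores
  names(fused) <- model$classes
  list(id = model$classes[which.max(fused)], scores = fused,
       fix_scores = fix_scores, sac_scores = sac_scores)
}
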
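#' Biometric metrics from fused scores
#'
#' Computes the identification metric suite from one fused score vector
#' per probe trajectory: accuracy and macro-averaged F1 from the argmax
#' predictions; ROC, equal error rate and AUC from micro-averaged
#' one-vs-rest pooling (every (probe, class) pair becomes one binary
#' instance scored by that class's decision value); the confusion matrix;
#' and the cumulative match score curve (fraction of probes whose true
#' class ranks within the top k).
#'
#' The EER is the operating point where the false-acceptance rate equals
#' the false-rejection rate, located by linear interpolation between
#' adjacent ROC points.
#'
#' @param scores numeric probes x classes matrix of fused scores (column
#'   names are the class labels).
#' @param truth character vector of true labels, one per probe.
#' @return An object of class `metrics_report`: list with `accuracy`,
#'   `f1`, `eer`, `auc`, `confusion`, `cms`, `roc` (data.frame of ROC
#'   points) and `n_probes`.
#' @export
compute_metrics <- function(scores, truth) {
  scores <- as.matrix(scores)
  truth <- as.character(truth)
  if (nrow(scores) != length(truth))
    stop("scores/labels shape mismatch: ", nrow(scores), " rows vs ",
         length(truth), " labels")
  classes <- colnames(scores)
  if (is.null(classes)) stop("score matrix must carry class column names")
  if (!all(truth %in% classes))
    stop("true label(s) outside the enrolled class list")
  pred <- classes[max.col(scores, ties.method = "first")]
  accuracy <- mean(pred == truth)
  confusion <- table(factor(truth, classes), factor(pred, classes))
  f1 <- mean(vapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, 0))
  # micro-averaged one-vs-rest pooling
  y <- as.vector(outer(truth, classes, "=="))
  s <- as.vector(scores)
  roc <- roc_points(s, y)
  auc <- roc_auc(roc)
  eer <- roc_eer(roc)
  # CMS: rank of the true class among the probe's sorted scores
  ranks <- vapply(seq_along(truth), function(i) {
    ord <- order(-scores[i, ], seq_along(classes))
    which(classes[ord] == truth[i])
  }, 0L)
  cms <- cumsum(tabulate(ranks, nbins = length(classes))) / length(truth)
  structure(list(accuracy = accuracy, f1 = f1, eer = eer, auc = auc,
                 confusion = unclass(confusion), cms = cms, roc = roc,
                 n_probes = length(truth)),
            class = "metrics_report")
}

# ROC curve over all score thresholds (decreasing), with the (0,0) anchor
roc_points <- function(s, y) {
  ord <- order(-s)
  y <- y[ord]
  tp <- cumsum(y); fp <- cumsum(!y)
  keep <- c(diff(s[ord]) != 0, TRUE)   # one point per distinct threshold
  data.frame(fpr = c(0, fp[keep] / max(sum(!y), 1)),
             tpr = c(0, tp[keep] / max(sum(y), 1)))
}

roc_auc <- function(roc) {
  sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2)
}

# FAR = fpr and FRR = 1 - tpr; interpolate the crossing FAR = FRR
roc_eer <- function(roc) {
  d <- roc$fpr - (1 - roc$tpr)
  i <- which(d >= 0)[1]
  if (is.na(i)) return(roc$fpr[nrow(roc)])
  if (i == 1 || d[i] == 0) return((roc$fpr[i] + 1 - roc$tpr[i]) / 2)
  w <- d[i] / (d[i] - d[i - 1])         # linear interpolation weight
  far <- (1 - w) * roc$fpr[i] + w * roc$fpr[i - 1]
  frr <- (1 - w) * (1 - roc$tpr[i]) + w * (1 - roc$tpr[i - 1])
  (far + frr) / 2
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "identification metrics (%d probes): accuracy %.3f  F1 %.3f  EER %.3f  AUC %.3f\n",
    x$n_probes, x$accuracy, x$f1, x$eer, x$auc))
  cat("  CMS:", paste(sprintf("%.2f", x$cms), collapse = " "), "\n")
  invisible(x)
}

#' Cross-validated identification benchmark
#'
#' K-fold cross-validation with the scan path as the unit of splitting
#' (all events of a trajectory stay in one fold — events within a scan
#' path are dependent and would otherwise leak identity), stratified by
#' subject so every subject appears in every training split. Per fold the
#' per-kind classifiers are trained on the training scan paths' events and
#' every held-out scan path is scored by fusion; metrics are reported per
#' fold and pooled.
#'
#' @param features per-event descriptor table.
#' @param k number of folds (>= 2).
#' @param seed integer seed controlling the fold assignment.
#' @param config classifier settings (see [train_models()]).
#' @return A `metrics_report` (pooled over folds) with an additional
#'   `folds` data.frame of per-fold accuracy/F1/EER/AUC and attribute
#'   `fold_of` (the assignment).
#' @export
crossvalidate <- function(features, k = 10, seed = 1, config = list()) {
  stopifnot(k >= 2)
  sp_key <- paste(features$subject_id, features$stimulus_id, sep = "\r")
  sps <- unique(data.frame(key = sp_key, subject = features$subject_id,
                           stringsAsFactors = FALSE))
  counts <- table(sps$subject)
  if (any(counts < k))
    stop(sprintf("subject %s has %d scan paths; %d required for %d-fold CV",
                 names(counts)[which.min(counts)], min(counts), k, k))
  set.seed(seed)
  fold_of <- stats::setNames(integer(nrow(sps)), sps$key)
  for (subj in unique(sps$subject)) {
    keys <- sample(sps$key[sps$subject == subj])
    fold_of[keys] <- (seq_along(keys) - 1L) %% k + 1L
  }
  all_scores <- NULL; all_truth <- character(); fold_rows <- list()
  fold_id <- integer()
  for (f in seq_len(k)) {
    test_keys <- names(fold_of)[fold_of == f]
    train_feat <- features[!(sp_key %in% test_keys), , drop = FALSE]
    model <- train_models(train_feat, config = config)
    scores <- t(vapply(test_keys, function(key) {
      fuse_and_identify(model,
                        features[sp_key == key, , drop = FALSE])$scores
    }, numeric(length(model$classes))))
    colnames(scores) <- model$classes
    truth <- sps$subject[match(test_keys, sps$key)]
    m <- compute_metrics(scores, truth)
    fold_rows[[f]] <- data.frame(fold = f, accuracy = m$accuracy, f1 = m$f1,
                                 eer = m$eer, auc = m$auc)
    all_scores <- rbind(all_scores, scores)
    all_truth <- c(all_truth, truth)
    fold_id <- c(fold_id, rep(f, length(truth)))
  }
  out <- compute_metrics(all_scores, all_truth)
  out$folds <- do.call(rbind, fold_rows)
  out$scores <- all_scores
  out$truth <- all_truth
  attr(out, "fold_of") <- fold_of
  out
}

#' Intra/inter-subject correlation analyses
#'
#' Gauges how individual the model-based descriptors are: the
#' between-subject correlation matrix of the subject summary vectors (the
#' material of a Hinton diagram), the ensemble of intra-subject
#' correlations (same subject, different stimuli) and of inter-subject
#' correlations (different subjects, different stimuli), and Gaussian
#' kernel density estimates of both ensembles. A peaked intra ensemble
#' against a wide inter ensemble indicates low within-subject variability
#' relative to between-subject variability — the biometric signal.
#'
#' @param scanpaths data.frame of scan-path descriptors
#'   (see [build_scanpath_descriptors()]); needs >= 2 subjects with >= 2
#'   scan paths each.
#' @return List: `between` (subjects x subjects correlation matrix),
#'   `intra`, `inter` (correlation ensembles), `kde_intra`, `kde_inter`
#'   (stats::density objects, Gaussian kernel, reference-rule bandwidth).
#' @export
correlation_analyses <- function(scanpaths) {
  subs <- unique(scanpaths$subject_id)
  if (length(subs) < 2) stop("at least 2 subjects required")
  if (any(table(scanpaths$subject_id) < 2))
    stop("every subject needs at least 2 scan paths")
  cols <- c(paste0("fix_", descriptor_cols()),
            paste0("sac_", descriptor_cols()))
  vecs <- lapply(seq_len(nrow(scanpaths)), function(i)
    as.numeric(scanpaths[i, cols]))
  owner <- scanpaths$subject_id
  safe_cor <- function(a, b) {
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 3 || stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
      message("correlation undefined for a constant vector pair; excluded")
      return(NA_real_)
    }
    stats::cor(a[ok], b[ok])
  }
  summaries <- lapply(subs, function(s)
    as.numeric(subject_summary(
      scanpaths[scanpaths$subject_id == s, , drop = FALSE])[, cols]))
  between <- diag(1, length(subs))
  dimnames(between) <- list(subs, subs)
  for (i in seq_along(subs)) for (j in seq_along(subs)) if (i < j)
    between[i, j] <- between[j, i] <- safe_cor(summaries[[i]], summaries[[j]])
  n <- length(vecs)
  intra <- c(); inter <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- safe_cor(vecs[[i]], vecs[[j]])
    if (is.na(r)) next
    if (owner[i] == owner[j]) intra <- c(intra, r) else inter <- c(inter, r)
  }
  kde <- function(x) if (length(x) >= 2) stats::density(x, bw = "nrd0")
  list(between = between, intra = intra, inter = inter,
       kde_intra = kde(intra), kde_inter = kde(inter))
}
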
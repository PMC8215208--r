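#' Accuracy, sensitivity and specificity from confusion counts
#'
#' `accuracy = (TP+TN)/total`, `sensitivity = TP/(TP+FN)`,
#' `specificity = TN/(TN+FP)`. A zero denominator yields `NA` (flagged
#' undefined) rather than an error.
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return Named list `accuracy`, `sensitivity`, `specificity`.
#' @export
binary_metrics <- function(tp, fp, tn, fn) {
  total <- tp + fp + tn + fn
  if (total <= 0) stopf("domain error: zero evaluated samples")
  list(accuracy = (tp + tn) / total,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' ROC curve and AUC for one class
#'
#' AUC is the Mann-Whitney rank statistic: the probability that a
#' uniformly chosen positive outscores a uniformly chosen negative, ties
#' counted 1/2. The curve sweeps every distinct score threshold and
#' reports (1 - specificity, sensitivity) points from (0,0) to (1,1).
#'
#' @param scores Numeric vector of per-sample probabilities.
#' @param labels 0/1 vector of the same length.
#' @return List with `auc` and `curve` (data frame `threshold`, `fpr`,
#'   `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) stopf("shape error: length mismatch")
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stopf("domain error: both label values must be present")
  }
  r <- rank(scores)  # average ranks = half-credit for ties
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  keep <- c(s[-1] != s[-length(s)], TRUE)  # last index of each distinct score
  tpr <- cumsum(y == 1)[keep] / n_pos
  fpr <- cumsum(y == 0)[keep] / n_neg
  curve <- data.frame(threshold = c(Inf, s[keep]),
                      fpr = c(0, fpr), tpr = c(0, tpr))
  list(auc = auc, curve = curve)
}

#' Per-level confusion matrix (argmax rule)
#'
#' Rows are the true class, columns the argmax of the level's score
#' vector. Only samples with exactly one positive truth bit at this level
#' enter the matrix; multi-label samples are excluded and their count
#' reported in the `n_excluded` attribute.
#'
#' @param scores `N x n_classes` score matrix, columns in canonical class
#'   order.
#' @param truth `N x n_classes` 0/1 truth matrix of the same shape.
#' @param class_ids Character vector naming the classes (canonical order).
#' @param normalize If `TRUE`, rows are normalized to proportions.
#' @return `n x n` matrix with `n_excluded` attribute.
#' @export
confusion_matrix <- function(scores, truth, class_ids = colnames(scores),
                             normalize = FALSE) {
  scores <- as.matrix(scores); truth <- as.matrix(truth)
  if (!all(dim(scores) == dim(truth))) stopf("shape error: score/truth mismatch")
  single <- rowSums(truth) == 1
  if (!any(single)) stopf("domain error: no single-label samples to tally")
  truth_cls <- max.col(truth[single, , drop = FALSE], ties.method = "first")
  pred_cls <- max.col(scores[single, , drop = FALSE], ties.method = "first")
  n <- ncol(scores)
  m <- matrix(0L, n, n, dimnames = list(truth = class_ids,
                                        predicted = class_ids))
  for (i in seq_along(truth_cls)) {
    m[truth_cls[i], pred_cls[i]] <- m[truth_cls[i], pred_cls[i]] + 1L
  }
  if (normalize) {
    rs <- rowSums(m)
    m <- sweep(m, 1, pmax(rs, 1), "/")
  }
  attr(m, "n_excluded") <- sum(!single)
  m
}

#' Seeded k-fold assignment
#'
#' Folds are disjoint, exhaustive and balanced (sizes differ by at most
#' one), and identical across reruns with the same seed.
#'
#' @param n_samples Number of samples (`>= k`).
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return Integer vector in `1..k`, one fold per sample.
#' @export
kfold_split <- function(n_samples, k = 5, seed = 1) {
  if (n_samples < k) stopf("domain error: need at least k samples")
  with_seed(seed, sample(rep_len(seq_len(k), n_samples)))
}

#' Top-k correctness rule
#'
#' A prediction is correct when the true class appears anywhere in the
#' ranked top-k list (screening rule used for the top-3 comparison).
#'
#' @param truth True class id.
#' @param topk Character vector (or `topk` data frame from
#'   [predict_calls()]) of ranked class ids.
#' @return Logical scalar.
#' @export
topk_correct <- function(truth, topk) {
  if (is.data.frame(topk)) topk <- topk$class_id
  truth %in% topk
}

#' Evaluate a model on a labelled manifest
#'
#' Produces the full evaluation report: per-class AUC and ROC curves
#' (every sample enters per-class ROC, including multi-label ones),
#' per-class accuracy/sensitivity/specificity at the positive-call
#' threshold, and the per-level argmax confusion matrix (multi-label
#' samples excluded and counted).
#'
#' @param model A `hier_model`.
#' @param manifest Labelled manifest data frame.
#' @param images Optional preloaded image array.
#' @param threshold Positive-call threshold (default 0.5).
#' @return An `eval_report`: list with one entry per level (`auc` named
#'   vector, `roc` list, `metrics` data frame, `confusion` matrix) plus
#'   `threshold` and `n`.
#' @export
evaluate_model <- function(model, manifest, images = NULL, threshold = 0.5) {
  if (is.null(images)) images <- load_images(manifest)
  scores <- model_forward(model, images)
  truth <- label_matrices(model$taxonomy,
                          lapply(manifest_labels(manifest), expand_labels,
                                 tax = model$taxonomy))
  report <- list(threshold = threshold, n = nrow(manifest))
  for (l in 1:2) {
    sc <- scores[[l]]; tr <- truth[[l]]
    ids <- class_order(model$taxonomy, l)
    auc <- stats::setNames(rep(NA_real_, length(ids)), ids)
    roc <- stats::setNames(vector("list", length(ids)), ids)
    met <- data.frame(class_id = ids, accuracy = NA_real_,
                      sensitivity = NA_real_, specificity = NA_real_,
                      stringsAsFactors = FALSE)
    for (ci in seq_along(ids)) {
      y <- tr[, ci]
      if (length(unique(y)) == 2) {
        r <- roc_auc(sc[, ci], y)
        auc[ci] <- r$auc
        roc[[ci]] <- r$curve
      }
      pos <- sc[, ci] > threshold
      bm <- binary_metrics(sum(pos & y == 1), sum(pos & y == 0),
                           sum(!pos & y == 0), sum(!pos & y == 1))
      met$accuracy[ci] <- bm$accuracy
      met$sensitivity[ci] <- bm$sensitivity
      met$specificity[ci] <- bm$specificity
    }
    report[[paste0("level", l)]] <- list(
      auc = auc, roc = roc, metrics = met,
      confusion = confusion_matrix(sc, tr, ids))
  }
  structure(report, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n=%d, threshold=%g\n", x$n, x$threshold))
  for (l in 1:2) {
    lv <- x[[paste0("level", l)]]
    cat(sprintf("  level %d mean AUC: %.3f (%d classes)\n", l,
                mean(lv$auc, na.rm = TRUE), length(lv$auc)))
  }
  invisible(x)
}

#' Vertical average of ROC curves across folds
#'
#' Interpolates each fold's sensitivity onto a common false-positive-rate
#' grid and averages (vertical threshold averaging; so labelled in the
#' output).
#'
#' @param curves List of ROC curve data frames (from [roc_auc()]).
#' @param grid FPR grid (default 101 points on `[0,1]`).
#' @return Data frame `fpr`, `tpr_mean` with attribute
#'   `method = "vertical_average"`.
#' @export
mean_roc <- function(curves, grid = seq(0, 1, by = 0.01)) {
  tprs <- vapply(curves, function(cv) {
    stats::approx(cv$fpr, cv$tpr, xout = grid, ties = max, rule = 2)$y
  }, numeric(length(grid)))
  out <- data.frame(fpr = grid, tpr_mean = rowMeans(as.matrix(tprs)))
  attr(out, "method") <- "vertical_average"
  out
}

#' k-fold cross-validation of the full pipeline
#'
#' Splits the manifest into k seeded folds; each fold is held out in turn
#' while a fresh model (from `model_factory`) trains on the remainder.
#' Reports per-fold evaluation plus the cross-fold mean AUC and mean ROC
#' curve per class.
#'
#' @param manifest Labelled manifest data frame.
#' @param model_factory Zero-argument function returning an untrained
#'   `hier_model`.
#' @param config A [train_config()].
#' @param k Number of folds (default 5).
#' @param seed Fold-assignment seed.
#' @param images Optional preloaded image array.
#' @return A `cv_report`: list with `folds` (per-fold `eval_report`s),
#'   `fold_assignment`, `mean_auc` per level, and `mean_roc` per class
#'   per level.
#' @export
cross_validate <- function(manifest, model_factory, config, k = 5, seed = 1,
                           images = NULL) {
  if (is.null(images)) images <- load_images(manifest)
  folds <- kfold_split(nrow(manifest), k, seed)
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    tr_idx <- which(folds != f); te_idx <- which(folds == f)
    fit <- train_model(model_factory(), manifest[tr_idx, , drop = FALSE],
                       config, images = images[, , , tr_idx, drop = FALSE])
    reports[[f]] <- evaluate_model(fit$model,
                                   manifest[te_idx, , drop = FALSE],
                                   images = images[, , , te_idx, drop = FALSE])
  }
  out <- list(folds = reports, fold_assignment = folds, k = k)
  for (l in 1:2) {
    key <- paste0("level", l)
    aucs <- do.call(rbind, lapply(reports, function(r) r[[key]]$auc))
    out$mean_auc[[key]] <- colMeans(aucs, na.rm = TRUE)
    ids <- colnames(aucs)
    out$mean_roc[[key]] <- lapply(stats::setNames(ids, ids), function(id) {
      cvs <- Filter(Negate(is.null), lapply(reports, function(r)
        r[[key]]$roc[[id]]))
      if (length(cvs)) mean_roc(cvs) else NULL
    })
  }
  structure(out, class = "cv_report")
}
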
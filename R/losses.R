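#' Focal loss term for one predicted probability
#'
#' Computes `(1 - p_t)^gamma * (-log p_t)` where `p_t = p` when `y = 1` and
#' `1 - p` otherwise: binary cross-entropy scaled by a modulating factor
#' that down-weights well-classified cells, so training under class
#' imbalance concentrates on hard examples. `gamma = 0` recovers plain
#' cross-entropy.
#'
#' @param p Predicted probability of the positive class, in `[0,1]`
#'   (vectorized). Values are clamped to `[eps, 1-eps]` before the log.
#' @param y Ground-truth label in `{0,1}` (vectorized, recycled against `p`).
#' @param gamma Focusing parameter, `>= 0`. Default 2.
#' @param eps Clamping epsilon guarding `log(0)`. Default `1e-7`.
#' @return Non-negative numeric vector of per-cell losses.
#' @export
focal_term <- function(p, y, gamma = 2, eps = 1e-7) {
  if (any(gamma < 0)) stopf("gamma must be >= 0")
  if (any(p < 0 | p > 1)) stopf("domain error: probabilities must lie in [0,1]")
  if (!all(y %in% c(0, 1))) stopf("labels must be 0 or 1")
  p <- pmin(pmax(p, eps), 1 - eps)
  pt <- ifelse(y == 1, p, 1 - p)
  (1 - pt)^gamma * (-log(pt))
}

# d focal_term / d p (not d/d pt): used by the training backward pass,
# chained with the sigmoid derivative. Zero outside the clamp interval,
# matching the clamped forward value.
focal_grad_p <- function(p, y, gamma = 2, eps = 1e-7) {
  inside <- p > eps & p < 1 - eps
  p <- pmin(pmax(p, eps), 1 - eps)
  pt <- ifelse(y == 1, p, 1 - p)
  # d/d pt [ (1-pt)^g * (-log pt) ]
  dpt <- -gamma * (1 - pt)^(gamma - 1) * (-log(pt)) - (1 - pt)^gamma / pt
  g <- ifelse(y == 1, dpt, -dpt)
  g * as.numeric(inside)
}

#' Per-level multi-label focal loss
#'
#' Mean of [focal_term()] over every (sample, class) cell of one taxonomy
#' level. Scores are post-sigmoid per-class probabilities (multi-label:
#' rows need not sum to 1).
#'
#' @param scores Numeric matrix, samples x classes, values in `[0,1]`.
#' @param labels 0/1 matrix of the same shape.
#' @param gamma Focusing parameter (default 2).
#' @param eps Probability clamp (default `1e-7`).
#' @return Non-negative scalar.
#' @export
level_loss <- function(scores, labels, gamma = 2, eps = 1e-7) {
  scores <- as.matrix(scores); labels <- as.matrix(labels)
  if (!all(dim(scores) == dim(labels))) {
    stopf("shape error: scores %dx%d vs labels %dx%d",
          nrow(scores), ncol(scores), nrow(labels), ncol(labels))
  }
  if (length(scores) == 0) stopf("domain error: empty batch")
  mean(focal_term(as.numeric(scores), as.numeric(labels), gamma, eps))
}

# Gradient of level_loss w.r.t. the score matrix (same shape).
level_loss_grad <- function(scores, labels, gamma = 2, eps = 1e-7) {
  g <- focal_grad_p(as.numeric(scores), as.numeric(labels), gamma, eps)
  matrix(g / length(scores), nrow(scores), ncol(scores))
}

#' Level weights for the multi-level total loss
#'
#' For two levels the weights are `(alpha, 1 - alpha)` with
#' `alpha` constrained to (0, 0.5): the finer level carries more weight
#' because the finer diagnosis is the ultimate goal. The default
#' `alpha = 0.3` gives the 3:7 level-1:level-2 weight ratio. For more
#' levels pass the full weight vector (must sum to 1).
#'
#' @param alpha Level-1 weight for the two-level case, in (0, 0.5).
#' @param weights Optional explicit weight vector overriding `alpha`.
#' @return A `level_weights` object (numeric vector of weights).
#' @export
level_weights <- function(alpha = 0.3, weights = NULL) {
  if (is.null(weights)) {
    if (alpha <= 0 || alpha >= 0.5) {
      stopf("alpha must lie strictly inside (0, 0.5); got %g", alpha)
    }
    weights <- c(alpha, 1 - alpha)
  } else {
    if (any(weights < 0 | weights > 1) || abs(sum(weights) - 1) > 1e-12) {
      stopf("level weights must lie in [0,1] and sum to 1")
    }
  }
  structure(as.numeric(weights), class = "level_weights")
}

#' Multi-level total loss
#'
#' Convex combination of the per-level losses:
#' `sum_l w_l * loss_l`, the disease-guided objective minimized during
#' training. With the default two-level weights this is
#' `alpha * loss_l1 + (1 - alpha) * loss_l2`.
#'
#' @param level_losses Numeric vector of per-level losses.
#' @param weights A [level_weights()] object (or plain weight vector
#'   summing to 1) of matching length.
#' @return Non-negative scalar.
#' @export
total_loss <- function(level_losses, weights = level_weights()) {
  if (length(level_losses) != length(weights)) {
    stopf("shape error: %d level losses vs %d weights",
          length(level_losses), length(weights))
  }
  sum(as.numeric(weights) * as.numeric(level_losses))
}
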
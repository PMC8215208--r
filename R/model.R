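#' Backbone specification
#'
#' The default backbone is a compact stack of convolution blocks, each a
#' 3x3 convolution with zero padding and ReLU, halving the spatial grid
#' per block (stride-2 convolution by default, or stride-1 convolution
#' plus 2x2 max pooling with `downsample = "pool"`), ending in global
#' average pooling. The pooled feature dimension `D` equals the final
#' channel count. Any backbone honouring this contract (final spatial
#' feature map + pooled vector) can be plugged in by editing the channel
#' schedule.
#'
#' @param channels Integer vector, output channels of each block.
#' @param kernel Convolution kernel size (odd). Default 3.
#' @param downsample `"stride"` (conv 3x3/2) or `"pool"` (conv 3x3/1 +
#'   2x2 max pool).
#' @return A `backbone_spec` list.
#' @export
backbone_spec <- function(channels = c(16, 32, 64, 128), kernel = 3,
                          downsample = c("stride", "pool")) {
  if (kernel %% 2 != 1) stopf("kernel size must be odd")
  structure(list(channels = as.integer(channels), kernel = as.integer(kernel),
                 downsample = match.arg(downsample)),
            class = "backbone_spec")
}

#' Branch head configuration
#'
#' Each taxonomy level gets its own branch of stacked fully connected
#' units ending in one sigmoid output per class. The hierarchical wiring
#' feeds the level-1 branch's penultimate hidden activations, concatenated
#' with the pooled backbone features, into the level-2 branch.
#'
#' @param hidden Integer vector of hidden-layer widths per branch.
#' @return A `head_config` list.
#' @export
head_config <- function(hidden = c(256, 128)) {
  if (length(hidden) < 1) stopf("need at least one hidden layer per branch")
  structure(list(hidden = as.integer(hidden)), class = "head_config")
}

build_model_internal <- function(taxonomy, backbone, heads, input_size, seed,
                                 type) {
  nb <- length(backbone$channels)
  if (input_size %% (2^nb) != 0 || input_size / 2^nb < 1) {
    stopf("config error: input_size %d not divisible by 2^%d blocks",
          input_size, nb)
  }
  n1 <- length(class_order(taxonomy, 1))
  n2 <- length(class_order(taxonomy, 2))
  D <- backbone$channels[nb]
  with_seed(seed, {
    conv <- list()
    c_in <- 3L
    for (i in seq_len(nb)) {
      conv[[i]] <- conv_block_init(c_in, backbone$channels[i], backbone$kernel)
      c_in <- backbone$channels[i]
    }
    make_branch <- function(d_in, n_out) {
      widths <- c(heads$hidden, n_out)
      layers <- list()
      prev <- d_in
      for (w in widths) {
        layers[[length(layers) + 1]] <- dense_init(prev, w)
        prev <- w
      }
      layers
    }
    penult_width <- heads$hidden[length(heads$hidden)]
    l2_in <- if (type == "hierarchical") D + penult_width else D
    params <- list(conv = conv,
                   l1 = make_branch(D, n1),
                   l2 = make_branch(l2_in, n2))
    structure(list(type = type, taxonomy = taxonomy,
                   taxonomy_hash = taxonomy_hash(taxonomy),
                   input_size = as.integer(input_size),
                   backbone = backbone, heads = heads,
                   n1 = n1, n2 = n2, D = D, params = params),
              class = "hier_model")
  })
}

#' Build the hierarchical multi-task & multi-label model
#'
#' The backbone feeds both level branches: the level-1 branch consumes the
#' pooled backbone vector directly, while the level-2 branch consumes the
#' concatenation of that vector with the level-1 branch's penultimate
#' hidden activations, so coarse-level evidence acts as a prior for the
#' finer level. Every branch ends in independent per-class sigmoids
#' (multi-label: scores do not sum to 1).
#'
#' @param taxonomy A validated `disease_taxonomy`; fixes the output sizes.
#' @param backbone A [backbone_spec()].
#' @param heads A [head_config()].
#' @param input_size Input image side in pixels (square RGB); must be
#'   divisible by `2^nblocks`.
#' @param seed Integer seed making weight initialization deterministic.
#' @return A `hier_model` object.
#' @export
build_hierarchical_model <- function(taxonomy, backbone = backbone_spec(),
                                     heads = head_config(),
                                     input_size = 96, seed = 1) {
  build_model_internal(taxonomy, backbone, heads, input_size, seed,
                       "hierarchical")
}

#' Build the flat multi-task baseline
#'
#' Ablation comparator: identical backbone and branch widths, but each
#' level's classifiers are independent binary heads fed by the pooled
#' backbone vector only — no level-1 to level-2 connection. Consumes the
#' same inputs and emits the same output shapes as the hierarchical model.
#'
#' @inheritParams build_hierarchical_model
#' @return A `hier_model` object with `type = "flat"`.
#' @export
build_flat_baseline <- function(taxonomy, backbone = backbone_spec(),
                                heads = head_config(),
                                input_size = 96, seed = 1) {
  build_model_internal(taxonomy, backbone, heads, input_size, seed, "flat")
}

model_num_params <- function(model) {
  sum(rapply(model$params, length, how = "unlist", classes = "ANY"))
}

# images: array H x W x 3 x N (or H x W x 3) of intensities in [0,1].
as_batch_matrix <- function(images, input_size) {
  if (length(dim(images)) == 3) dim(images) <- c(dim(images), 1L)
  d <- dim(images)
  if (d[1] != input_size || d[2] != input_size || d[3] != 3) {
    stopf("shape error: expected %dx%dx3 RGB images, got %dx%dx%d",
          input_size, input_size, d[1], d[2], d[3])
  }
  x <- aperm(images, c(3, 1, 2, 4))
  dim(x) <- c(3L, d[1] * d[2] * d[4])
  list(x = x, N = d[4])
}

# Full forward pass. Returns per-level probability matrices (classes x N)
# plus, when `keep_cache`, everything the backward pass needs.
forward_internal <- function(model, images, keep_cache = FALSE) {
  bm <- as_batch_matrix(images, model$input_size)
  x <- bm$x; N <- bm$N
  H <- model$input_size; W <- model$input_size
  k <- model$backbone$kernel
  nb <- length(model$params$conv)
  blocks <- vector("list", nb)
  ds <- model$backbone$downsample %||% "stride"
  for (i in seq_len(nb)) {
    bf <- block_forward(x, model$params$conv[[i]], H, W, N, k, ds, keep_cache)
    blocks[[i]] <- bf$cache
    x <- bf$out; H <- bf$H; W <- bf$W
  }
  hw <- H * W
  f <- gap_forward(x, hw, N)
  c1 <- dense_stack_forward(f, model$params$l1)
  g2 <- if (model$type == "hierarchical") rbind(f, c1$penultimate) else f
  c2 <- dense_stack_forward(g2, model$params$l2)
  p1 <- sigmoid(c1$logits); p2 <- sigmoid(c2$logits)
  rownames(p1) <- class_order(model$taxonomy, 1)
  rownames(p2) <- class_order(model$taxonomy, 2)
  out <- list(p1 = p1, p2 = p2, z1 = c1$logits, z2 = c2$logits, N = N)
  if (keep_cache) {
    out$cache <- list(blocks = blocks, hw = hw, f = f, c1 = c1, c2 = c2,
                      final_H = H, final_W = W)
  }
  out
}

# Backward pass from logit gradients; returns parameter gradients (same
# structure as model$params) and per-block gradients w.r.t. the post-ReLU
# pre-pool activation maps (consumed by Grad-CAM).
backward_internal <- function(model, fw, dZ1, dZ2, need_block_grads = FALSE,
                              stop_at_block = 0L) {
  cache <- fw$cache
  D <- model$D
  b2 <- dense_stack_backward(dZ2, model$params$l2, cache$c2)
  if (model$type == "hierarchical") {
    dF2 <- b2$d_input[seq_len(D), , drop = FALSE]
    dPen <- b2$d_input[-seq_len(D), , drop = FALSE]
  } else {
    dF2 <- b2$d_input
    dPen <- NULL
  }
  b1 <- dense_stack_backward(dZ1, model$params$l1, cache$c1,
                             d_penultimate = dPen)
  dF <- b1$d_input + dF2
  g <- gap_backward(dF, cache$hw, fw$N)
  nb <- length(model$params$conv)
  conv_grads <- vector("list", nb)
  block_dA <- vector("list", nb)
  k <- model$backbone$kernel
  if (stop_at_block <= nb) {
    for (i in rev(seq_len(nb))) {
      bb <- block_backward(g, model$params$conv[[i]], cache$blocks[[i]], k,
                           need_input_grad = (i > 1 && i > stop_at_block))
      conv_grads[[i]] <- list(W = bb$dW, b = bb$db)
      if (need_block_grads) block_dA[[i]] <- bb$dA
      if (i == stop_at_block) break
      g <- bb$dX
    }
  }
  list(grads = list(conv = conv_grads,
                    l1 = lapply(b1$grads, function(g) list(W = g$dW, b = g$db)),
                    l2 = lapply(b2$grads, function(g) list(W = g$dW, b = g$db))),
       block_dA = block_dA)
}

#' Forward pass: per-level class probabilities
#'
#' @param model A `hier_model`.
#' @param images Array `H x W x 3 x N` (or a single `H x W x 3` image) of
#'   RGB intensities in `[0,1]`, sides equal to the model's `input_size`.
#' @return List with `level1` and `level2`: `N x n_classes` matrices of
#'   per-class sigmoid probabilities, columns named by [class_order()].
#' @export
model_forward <- function(model, images) {
  fw <- forward_internal(model, images, keep_cache = FALSE)
  list(level1 = t(fw$p1), level2 = t(fw$p2))
}

#' Positive calls and top-k ranking from prediction scores
#'
#' A class is called positive when its score strictly exceeds `threshold`
#' (screening rule: a score of exactly the threshold is negative). The
#' top-k list ranks classes by descending score, ties broken by canonical
#' class order; `k` beyond the class count is truncated.
#'
#' @param scores Named numeric vector of per-class probabilities for one
#'   sample at one level, ordered by [class_order()], or a list of such
#'   vectors per level.
#' @param threshold Positive-call threshold (default 0.5).
#' @param k Size of the ranked list (default 3).
#' @return For a single vector: list with `positive` (character vector of
#'   called ids) and `topk` (data frame `class_id`, `score`). For a list of
#'   levels: a list of such results per level.
#' @export
predict_calls <- function(scores, threshold = 0.5, k = 3) {
  if (threshold <= 0 || threshold >= 1) stopf("threshold must be in (0,1)")
  if (k < 1) stopf("k must be >= 1")
  one <- function(s) {
    kk <- min(k, length(s))
    ord <- order(-s)[seq_len(kk)]   # order() breaks ties by position
    list(positive = names(s)[s > threshold],
         topk = data.frame(class_id = names(s)[ord], score = unname(s[ord]),
                           stringsAsFactors = FALSE))
  }
  if (is.list(scores) && !is.data.frame(scores)) lapply(scores, one) else one(scores)
}

#' Save / load a model checkpoint
#'
#' Checkpoints embed the taxonomy hash; loading verifies it so a model can
#' never be applied against a reordered or edited class list.
#'
#' @param model A `hier_model`.
#' @param path Checkpoint path.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @param taxonomy Optional taxonomy to verify the checkpoint against.
#' @export
load_model <- function(path, taxonomy = NULL) {
  model <- readRDS(path)
  if (!inherits(model, "hier_model")) stopf("not a hicnet model checkpoint: %s", path)
  if (!is.null(taxonomy) && !identical(taxonomy_hash(taxonomy), model$taxonomy_hash)) {
    stopf("checkpoint taxonomy hash %s does not match the supplied taxonomy (%s)",
          model$taxonomy_hash, taxonomy_hash(taxonomy))
  }
  model
}

#' @export
print.hier_model <- function(x, ...) {
  cat(sprintf("<hier_model> type=%s, input=%dpx, D=%d, outputs=%d/%d, params=%d\n",
              x$type, x$input_size, x$D, x$n1, x$n2, model_num_params(x)))
  invisible(x)
}
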
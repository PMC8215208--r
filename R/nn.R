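# Minimal CNN substrate: convolution / ReLU / 2x2 max-pool blocks and
# fully connected stacks with hand-derived backward passes. Activations
# travel as matrices with `channels` rows and H*W*N columns (column index
# h + H*(w + W*n), h fastest); convolutions are im2col (C++) followed by a
# single BLAS GEMM in R, and the backward pass mirrors each step.

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

conv_block_init <- function(c_in, c_out, k = 3) {
  list(W = he_init(c_out, k * k * c_in, k * k * c_in),
       b = numeric(c_out))
}

dense_init <- function(d_in, d_out) {
  list(W = he_init(d_out, d_in, d_in), b = numeric(d_out))
}

# One backbone block. Downsampling is either a stride-2 convolution
# (conv 3x3/2 -> ReLU, the default) or a stride-1 convolution followed by
# ReLU and 2x2 max pooling. x: c_in x (H*W*N).
block_forward <- function(x, par, H, W, N, k = 3,
                          downsample = c("stride", "pool"),
                          keep_cache = TRUE) {
  downsample <- match.arg(downsample)
  pad <- (k - 1L) %/% 2L
  stride <- if (downsample == "stride") 2L else 1L
  Hc <- (H + 2L * pad - k) %/% stride + 1L
  Wc <- (W + 2L * pad - k) %/% stride + 1L
  cols <- cpp_im2col(x, H, W, N, k, stride, pad)
  z <- par$W %*% cols
  z <- z + par$b            # column recycling over b (length c_out) by row
  a <- z
  a[a < 0] <- 0
  cache <- if (keep_cache) {
    list(cols = cols, mask = (z > 0), a = a, H = H, W = W, N = N,
         Hc = Hc, Wc = Wc, downsample = downsample)
  }
  if (downsample == "pool") {
    pool <- cpp_maxpool(a, Hc, Wc, N)
    if (keep_cache) cache$idx <- pool$idx
    list(out = pool$out, H = Hc %/% 2L, W = Wc %/% 2L, cache = cache)
  } else {
    list(out = a, H = Hc, W = Wc, cache = cache)
  }
}

# g_out: gradient w.r.t. the block output. Returns parameter gradients,
# gradient w.r.t. the block input and (for Grad-CAM) the gradient w.r.t.
# the post-ReLU conv activation map.
block_backward <- function(g_out, par, cache, k = 3, need_input_grad = TRUE) {
  dA <- if (cache$downsample == "pool") {
    cpp_maxpool_backward(g_out, cache$idx, nrow(g_out),
                         cache$Hc * cache$Wc * cache$N)
  } else {
    g_out
  }
  dZ <- dA * cache$mask
  dW <- dZ %*% t(cache$cols)
  db <- rowSums(dZ)
  dX <- NULL
  if (need_input_grad) {
    dcols <- t(par$W) %*% dZ
    c_in <- nrow(dcols) / (k * k)
    stride <- if (cache$downsample == "stride") 2L else 1L
    dX <- cpp_col2im(dcols, cache$H, cache$W, c_in, cache$N, k, stride,
                     (k - 1L) %/% 2L)
  }
  list(dW = dW, db = db, dX = dX, dA = dA)
}

# Fully connected stack: hidden layers with ReLU, final layer linear
# (logits). x: d_in x N.
dense_stack_forward <- function(x, layers) {
  J <- length(layers)
  inputs <- vector("list", J)   # input fed to each layer
  masks <- vector("list", J)    # ReLU masks (NULL for final layer)
  h <- x
  for (j in seq_len(J)) {
    inputs[[j]] <- h
    z <- layers[[j]]$W %*% h + layers[[j]]$b
    if (j < J) {
      masks[[j]] <- z > 0
      z[z < 0] <- 0
      h <- z
    } else {
      h <- z
    }
  }
  # penultimate activation = input of the final layer
  list(logits = h, penultimate = inputs[[J]], inputs = inputs, masks = masks)
}

# d_logits: gradient w.r.t. the stack's logits; d_penultimate: extra
# gradient injected at the final layer's input (used when a deeper branch
# consumed the penultimate activations via concatenation).
dense_stack_backward <- function(d_logits, layers, cache, d_penultimate = NULL) {
  J <- length(layers)
  grads <- vector("list", J)
  d <- d_logits
  for (j in rev(seq_len(J))) {
    grads[[j]] <- list(dW = d %*% t(cache$inputs[[j]]), db = rowSums(d))
    d <- t(layers[[j]]$W) %*% d
    if (j == J && !is.null(d_penultimate)) d <- d + d_penultimate
    if (j > 1) d <- d * cache$masks[[j - 1]]
  }
  list(grads = grads, d_input = d)
}

# Global average pooling over the spatial grid: x is C x (h*w*N),
# returns C x N.
gap_forward <- function(x, hw, N) {
  a <- array(x, c(nrow(x), hw, N))
  f <- apply(a, 3, rowMeans)
  matrix(f, nrow(x), N)
}

gap_backward <- function(dF, hw, N) {
  dF[, rep(seq_len(N), each = hw), drop = FALSE] / hw
}

# --- Adam over an arbitrary nested list of numeric arrays ----------------

adam_init <- function(params) {
  rapply(params, function(p) list(m = p * 0, v = p * 0), how = "list",
         classes = "ANY")
}

# params / grads / state share structure; `update` is a parallel structure
# of logicals (or TRUE scalars) gating which leaves move.
adam_step_leaf <- function(p, g, s, lr, b1, b2, eps, t) {
  s$m <- b1 * s$m + (1 - b1) * g
  s$v <- b2 * s$v + (1 - b2) * g * g
  mhat <- s$m / (1 - b1^t)
  vhat <- s$v / (1 - b2^t)
  p <- p - lr * mhat / (sqrt(vhat) + eps)
  list(p = p, s = s)
}
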
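# Bilinear resize of a single-channel map (used to upsample coarse
# class-activation maps to input resolution).
bilinear_resize <- function(m, H_out, W_out) {
  H <- nrow(m); W <- ncol(m)
  sy <- (seq_len(H_out) - 0.5) * H / H_out + 0.5
  sx <- (seq_len(W_out) - 0.5) * W / W_out + 0.5
  y0 <- pmin(pmax(floor(sy), 1), H); y1 <- pmin(y0 + 1, H)
  x0 <- pmin(pmax(floor(sx), 1), W); x1 <- pmin(x0 + 1, W)
  fy <- pmin(pmax(sy - y0, 0), 1); fx <- pmin(pmax(sx - x0, 0), 1)
  a <- m[y0, x0, drop = FALSE]; b <- m[y0, x1, drop = FALSE]
  c <- m[y1, x0, drop = FALSE]; d <- m[y1, x1, drop = FALSE]
  FY <- matrix(fy, H_out, W_out); FX <- matrix(fx, H_out, W_out, byrow = TRUE)
  (1 - FY) * (1 - FX) * a + (1 - FY) * FX * b + FY * (1 - FX) * c + FY * FX * d
}

#' Grad-CAM heatmap for one (image, level, class)
#'
#' Computes the gradient of the class logit with respect to the post-ReLU
#' activation maps of a backbone convolutional block (the last block by
#' default), average-pools those gradients spatially into per-channel
#' importance weights, forms the weighted combination of the forward
#' activation maps, rectifies it, bilinearly upsamples to the input size
#' and max-normalizes to `[0,1]`. An identically zero combination stays
#' all-zero rather than NaN. Because the gradient is taken on the logit,
#' the map is invariant to constant shifts of the class bias.
#'
#' @param model A `hier_model`.
#' @param image Single `H x W x 3` image in `[0,1]`.
#' @param level Taxonomy level of the target class (1 or 2).
#' @param class_id Target class id at that level.
#' @param block Backbone block whose activations are inspected (default:
#'   last block).
#' @return A `heatmap` object: list with `map` (`H x W` in `[0,1]`),
#'   `class_id`, `level`, `block`.
#' @export
grad_cam <- function(model, image, level, class_id,
                     block = length(model$params$conv)) {
  ids <- class_order(model$taxonomy, level)
  ci <- match(class_id, ids)
  if (is.na(ci)) stopf("lookup error: '%s' is not a level-%d class",
                       class_id, level)
  nb <- length(model$params$conv)
  if (block < 1 || block > nb) stopf("lookup error: no backbone block %s", block)
  fw <- forward_internal(model, image, keep_cache = TRUE)
  dZ1 <- matrix(0, model$n1, 1); dZ2 <- matrix(0, model$n2, 1)
  if (level == 1) dZ1[ci, 1] <- 1 else dZ2[ci, 1] <- 1
  bw <- backward_internal(model, fw, dZ1, dZ2, need_block_grads = TRUE,
                          stop_at_block = block)
  dA <- bw$block_dA[[block]]                   # channels x (h*w)
  A <- fw$cache$blocks[[block]]$a              # post-ReLU conv activations
  wts <- rowMeans(dA)                          # spatially average-pooled grads
  cam <- colSums(A * wts)                      # weighted combination over channels
  cam[cam < 0] <- 0                            # ReLU
  cam <- matrix(cam, fw$cache$blocks[[block]]$Hc,
                fw$cache$blocks[[block]]$Wc)   # column index h-fastest
  up <- bilinear_resize(cam, model$input_size, model$input_size)
  mx <- max(up)
  if (mx > 0) up <- up / mx
  structure(list(map = up, class_id = class_id, level = level, block = block),
            class = "heatmap")
}

#' Fraction of heatmap mass inside a lesion box
#'
#' Quantifies localization: the share of total heatmap mass falling inside
#' an axis-aligned ground-truth box (0-based, half-open pixel
#' coordinates). A well-localized map concentrates far more mass in the
#' box than the box's share of image area. All-zero maps score 0.
#'
#' @param heatmap A `heatmap` (or plain matrix in `[0,1]`).
#' @param box Named vector `x0, y0, x1, y1` (x = column, y = row).
#' @return Fraction in `[0,1]`.
#' @export
localization_score <- function(heatmap, box) {
  m <- if (inherits(heatmap, "heatmap")) heatmap$map else heatmap
  if (box["x1"] <= box["x0"] || box["y1"] <= box["y0"]) {
    stopf("domain error: degenerate lesion box")
  }
  if (box["x0"] < 0 || box["y0"] < 0 || box["x1"] > ncol(m) ||
        box["y1"] > nrow(m)) {
    stopf("domain error: box outside image bounds")
  }
  total <- sum(m)
  if (total == 0) return(0)
  sum(m[(box["y0"] + 1):box["y1"], (box["x0"] + 1):box["x1"]]) / total
}

#' Render a heatmap (and overlay) to PNG
#'
#' Uses a blue-low / red-high colormap; the overlay blends the colormap
#' over the source image.
#'
#' @param heatmap A `heatmap` object.
#' @param path Output PNG path for the colormapped heatmap.
#' @param image Optional source image for an overlay written alongside
#'   (`*_overlay.png`).
#' @param alpha Overlay blend weight (default 0.5).
#' @export
save_heatmap_png <- function(heatmap, path, image = NULL, alpha = 0.5) {
  m <- heatmap$map
  ramp <- grDevices::colorRamp(c("#2c2cb4", "#20c0c0", "#f2f20c", "#e00000"))
  rgb <- ramp(as.numeric(m)) / 255
  col <- array(0, c(nrow(m), ncol(m), 3))
  for (ch in 1:3) col[, , ch] <- matrix(rgb[, ch], nrow(m))
  png::writePNG(col, path)
  if (!is.null(image)) {
    over <- clamp01((1 - alpha) * image + alpha * col)
    png::writePNG(over, sub("\\.png$", "_overlay.png", path))
  }
  invisible(path)
}
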
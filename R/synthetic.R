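#' Synthetic hierarchical image datasets
#'
#' The generator emulates the structure the classifier assumes, not the
#' optics of any camera: each level-1 class fixes a coarse whole-image
#' attribute (a background hue band plus a large low-contrast motif) and
#' each level-2 subclass fixes a fine attribute (a sinusoidal stripe
#' texture of class-specific frequency and orientation) confined to a
#' lesion box placed uniformly at random. Composite images superimpose the
#' lesions of two subclasses of the same coarse group and carry both
#' labels. Class counts are deliberately unbalanced so the focal loss has
#' something to do, and every lesion box is recorded so Grad-CAM
#' localization can be scored against ground truth.
#'
#' @name synthetic_data
NULL

#' Configuration for the synthetic generator
#'
#' @param taxonomy A `disease_taxonomy` (two levels used).
#' @param image_size Pixels per side (default 96; use 299 to mirror the
#'   full-scale input size).
#' @param n_per_class Named integer vector: images per level-2 class.
#'   Defaults to [default_class_counts()] over the taxonomy (about 600
#'   images at a 10:1 largest:smallest ratio).
#' @param composite_fraction Fraction of images carrying two level-2
#'   labels, in `[0,1]` (default 0.1).
#' @param noise_sd Additive Gaussian pixel noise SD in intensity units
#'   (default 0.02).
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the configuration.
#' @return A `synth_config` list.
#' @export
synth_config <- function(taxonomy, image_size = 96, n_per_class = NULL,
                         composite_fraction = 0.1, noise_sd = 0.02,
                         seed = 1) {
  if (is.null(n_per_class)) n_per_class <- default_class_counts(taxonomy)
  ord2 <- class_order(taxonomy, 2)
  unknown <- setdiff(names(n_per_class), ord2)
  if (length(unknown)) {
    stopf("config error: unknown level-2 class id(s) in n_per_class: %s",
          paste(unknown, collapse = ", "))
  }
  if (any(n_per_class < 0)) stopf("config error: class counts must be >= 0")
  if (composite_fraction < 0 || composite_fraction > 1) {
    stopf("config error: composite_fraction must lie in [0,1]")
  }
  if (noise_sd < 0) stopf("config error: noise_sd must be >= 0")
  structure(list(taxonomy = taxonomy, image_size = as.integer(image_size),
                 n_per_class = n_per_class,
                 composite_fraction = composite_fraction,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synth_config")
}

#' Default unbalanced class counts
#'
#' Counts decay geometrically across the level-2 classes (canonical
#' order) from `ratio` down to 1, scaled to roughly `total` images —
#' mirroring the long-tailed spread of clinical class frequencies.
#'
#' @param taxonomy A `disease_taxonomy`.
#' @param total Approximate total image count (default 600).
#' @param ratio Largest:smallest class ratio (default 10).
#' @return Named integer vector over the level-2 classes.
#' @export
default_class_counts <- function(taxonomy, total = 600, ratio = 10) {
  ord2 <- class_order(taxonomy, 2)
  k <- length(ord2)
  w <- ratio^seq(1, 0, length.out = k)
  stats::setNames(as.integer(round(total * w / sum(w))), ord2)
}

hue_rgb <- function(h, s, v) {
  as.numeric(grDevices::col2rgb(grDevices::hsv(h %% 1, s, v))) / 255
}

# Paint one lesion: class-specific stripe texture inside an axis-aligned
# box. Boxes are 0-based, half-open [x0,x1) x [y0,y1) in pixel coords
# (x = column, y = row).
paint_lesion <- function(img, box, freq, horizontal, phase, amp = 0.35) {
  ys <- (box["y0"] + 1):box["y1"]   # 1-based row range
  xs <- (box["x0"] + 1):box["x1"]
  bs <- length(ys)
  t <- if (horizontal) {
    matrix(rep(seq_along(ys), times = length(xs)), bs)
  } else {
    matrix(rep(seq_along(xs), each = length(ys)), bs)
  }
  wave <- amp * sin(2 * pi * freq * (t - 1) / bs + phase)
  for (ch in 1:3) img[ys, xs, ch] <- img[ys, xs, ch] + wave
  img
}

sample_box <- function(S, bs, avoid = NULL, max_tries = 40) {
  for (i in seq_len(max_tries)) {
    x0 <- sample.int(S - bs + 1, 1) - 1L
    y0 <- sample.int(S - bs + 1, 1) - 1L
    box <- c(x0 = x0, y0 = y0, x1 = x0 + bs, y1 = y0 + bs)
    if (is.null(avoid)) return(box)
    overlap <- !(box["x1"] <= avoid["x0"] || avoid["x1"] <= box["x0"] ||
                   box["y1"] <= avoid["y0"] || avoid["y1"] <= box["y0"])
    if (!overlap) return(box)
  }
  box
}

render_image <- function(tax, S, labels2, boxes, phases, value_jitter) {
  ord1 <- class_order(tax, 1)
  ord2 <- class_order(tax, 2)
  parent1 <- node_lookup(tax, labels2[1])$parent
  j <- match(parent1, ord1)
  base <- hue_rgb((j - 1) / length(ord1) + 0.05, 0.5, 0.55 + value_jitter)
  img <- array(0, c(S, S, 3))
  for (ch in 1:3) img[, , ch] <- base[ch]
  # large low-contrast motif keyed to the level-1 class
  cx <- (S + 1) / 2; cy <- (S + 1) / 2; r <- 0.33 * S
  u <- matrix(rep(seq_len(S), times = S), S) - cy   # rows
  v <- matrix(rep(seq_len(S), each = S), S) - cx    # cols
  inside <- switch(((j - 1) %% 3) + 1,
                   u^2 + v^2 < r^2,
                   abs(u) < r * 0.82 & abs(v) < r * 0.82,
                   abs(u) + abs(v) < r * 1.2)
  for (ch in 1:3) img[, , ch] <- img[, , ch] + 0.08 * inside
  for (i in seq_along(labels2)) {
    id <- labels2[i]
    sibs <- ord2[vapply(ord2, function(s) identical(node_lookup(tax, s)$parent,
                                                    node_lookup(tax, id)$parent),
                        logical(1))]
    kth <- match(id, sibs)
    freq <- 3 + 2 * ((kth - 1) %/% 2)
    img <- paint_lesion(img, boxes[[i]], freq, horizontal = (kth %% 2 == 1),
                        phase = phases[i])
  }
  img
}

#' Generate a synthetic dataset on disk
#'
#' Writes 8-bit RGB PNG images and a `manifest.csv` with columns
#' `image_path` (relative to the output directory), `level2_labels`
#' (";"-joined level-2 ids) and `lesion_boxes` (JSON array of
#' `{id, x0, y0, x1, y1}` boxes, 0-based half-open pixel coordinates, one
#' per positive level-2 label). The same configuration and seed always
#' reproduce a byte-identical manifest.
#'
#' @param config A [synth_config()].
#' @param out_dir Writable output directory (created if needed).
#' @return A `synthetic_dataset`: list with `manifest` (data frame), `dir`
#'   and `config`.
#' @export
generate_dataset <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tax <- config$taxonomy
  S <- config$image_size
  bs <- as.integer(round(S / 3))
  counts <- config$n_per_class
  primary <- rep(names(counts), times = counts)
  total <- length(primary)
  if (total == 0) stopf("config error: empty dataset requested")
  ord2 <- class_order(tax, 2)
  siblings <- lapply(ord2, function(id) {
    p <- node_lookup(tax, id)$parent
    setdiff(ord2[vapply(ord2, function(s)
      identical(node_lookup(tax, s)$parent, p), logical(1))], id)
  })
  names(siblings) <- ord2

  with_seed(config$seed, {
    primary <- sample(primary)
    eligible <- which(vapply(primary, function(id)
      length(siblings[[id]]) > 0, logical(1)))
    n_comp <- min(round(config$composite_fraction * total), length(eligible))
    comp_idx <- if (n_comp > 0) sort(sample(eligible, n_comp)) else integer(0)

    rows <- vector("list", total)
    for (i in seq_len(total)) {
      labels2 <- primary[i]
      if (i %in% comp_idx) {
        sib <- siblings[[primary[i]]]
        labels2 <- c(labels2, if (length(sib) == 1) sib else sample(sib, 1))
      }
      boxes <- list(sample_box(S, bs))
      if (length(labels2) == 2) {
        boxes[[2]] <- sample_box(S, bs, avoid = boxes[[1]])
      }
      phases <- stats::runif(length(labels2), 0, 2 * pi)
      vj <- stats::runif(1, -0.05, 0.05)
      img <- render_image(tax, S, labels2, boxes, phases, vj)
      if (config$noise_sd > 0) {
        img <- img + stats::rnorm(length(img), sd = config$noise_sd)
      }
      img <- clamp01(img)
      fname <- sprintf("img_%05d.png", i)
      png::writePNG(img, file.path(out_dir, fname))
      box_json <- as.character(jsonlite::toJSON(
        lapply(seq_along(labels2), function(t)
          c(list(id = labels2[t]), as.list(boxes[[t]]))),
        auto_unbox = TRUE))
      rows[[i]] <- data.frame(image_path = fname,
                              level2_labels = paste(labels2, collapse = ";"),
                              lesion_boxes = box_json,
                              stringsAsFactors = FALSE)
    }
    manifest <- do.call(rbind, rows)
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    attr(manifest, "dir") <- out_dir
    structure(list(manifest = manifest, dir = out_dir, config = config),
              class = "synthetic_dataset")
  })
}

#' Read a dataset manifest
#'
#' @param path Path to a `manifest.csv` written by [generate_dataset()].
#' @return Data frame with an attribute `dir` (the manifest's directory).
#' @export
load_manifest <- function(path) {
  m <- utils::read.csv(path, colClasses = "character")
  attr(m, "dir") <- dirname(path)
  m
}

manifest_labels <- function(manifest) {
  strsplit(manifest$level2_labels, ";", fixed = TRUE)
}

manifest_boxes <- function(manifest) {
  lapply(manifest$lesion_boxes, function(s) {
    lapply(jsonlite::fromJSON(s, simplifyVector = FALSE), function(b)
      list(id = b$id, box = c(x0 = b$x0, y0 = b$y0, x1 = b$x1, y1 = b$y1)))
  })
}

#' Load manifest images into an array
#'
#' @param manifest Manifest data frame (paths resolved against `dir`).
#' @param dir Image directory; defaults to the manifest's `dir` attribute.
#' @return Array `H x W x 3 x N` of intensities in `[0,1]`.
#' @export
load_images <- function(manifest, dir = attr(manifest, "dir")) {
  stopifnot(nrow(manifest) > 0)
  first <- png::readPNG(file.path(dir, manifest$image_path[1]))
  out <- array(0, c(dim(first)[1], dim(first)[2], 3, nrow(manifest)))
  out[, , , 1] <- first[, , 1:3]
  for (i in seq_len(nrow(manifest))[-1]) {
    out[, , , i] <- png::readPNG(file.path(dir, manifest$image_path[i]))[, , 1:3]
  }
  out
}

#' Stratified train/test partition of a manifest
#'
#' Splits by image, stratified by each image's primary (first) level-2
#' label, using largest-remainder allocation so the test set size is
#' exactly `round(fraction_test * n)`; any class with at least 5 records
#' is guaranteed representation in both parts.
#'
#' @param manifest Manifest data frame.
#' @param fraction_test Fraction in (0,1).
#' @param seed Integer seed.
#' @return List with `train` and `test` manifest data frames (disjoint,
#'   exhaustive; `dir` attribute preserved).
#' @export
train_test_partition <- function(manifest, fraction_test = 0.2, seed = 1) {
  if (nrow(manifest) == 0) stopf("manifest is empty")
  if (fraction_test <= 0 || fraction_test >= 1) {
    stopf("config error: fraction_test must lie in (0,1)")
  }
  primary <- vapply(manifest_labels(manifest), `[`, character(1), 1)
  classes <- unique(primary)
  n_c <- vapply(classes, function(cl) sum(primary == cl), integer(1))
  target <- round(fraction_test * nrow(manifest))
  base <- floor(fraction_test * n_c)
  rem <- fraction_test * n_c - base
  extra <- target - sum(base)
  if (extra > 0) {
    give <- order(-rem)[seq_len(min(extra, length(classes)))]
    base[give] <- base[give] + 1
  } else if (extra < 0) {
    take <- order(rem)[seq_len(min(-extra, sum(base > 0)))]
    base[take] <- pmax(base[take] - 1, 0)
  }
  # both-part guarantee for classes with >= 5 records
  base <- ifelse(n_c >= 5, pmin(pmax(base, 1), n_c - 1), pmin(base, n_c))
  test_idx <- integer(0)
  with_seed(seed, {
    for (ci in seq_along(classes)) {
      rows <- which(primary == classes[ci])
      if (base[ci] > 0) {
        test_idx <- c(test_idx, rows[sample.int(length(rows), base[ci])])
      }
    }
  })
  test_idx <- sort(test_idx)
  out <- list(train = manifest[setdiff(seq_len(nrow(manifest)), test_idx), ,
                               drop = FALSE],
              test = manifest[test_idx, , drop = FALSE])
  for (nm in names(out)) attr(out[[nm]], "dir") <- attr(manifest, "dir")
  out
}
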
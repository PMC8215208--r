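test_that("generation is deterministic and respects the class budget", {
  tax <- demo_tax()
  cfg <- synth_config(tax, image_size = 32,
                      n_per_class = c(a1 = 10, a2 = 6, b1 = 4, b2 = 2),
                      composite_fraction = 0.2, seed = 99)
  d1 <- generate_dataset(cfg, file.path(tempdir(), "det1"))
  d2 <- generate_dataset(cfg, file.path(tempdir(), "det2"))
  # byte-identical manifests
  expect_identical(readLines(file.path(d1$dir, "manifest.csv")),
                   readLines(file.path(d2$dir, "manifest.csv")))
  expect_identical(nrow(d1$manifest), 22L)    # sum of n_per_class
  # primary labels honour the requested counts
  primary <- vapply(strsplit(d1$manifest$level2_labels, ";"), `[`,
                    character(1), 1)
  expect_identical(as.integer(table(primary)[c("a1", "a2", "b1", "b2")]),
                   c(10L, 6L, 4L, 2L))
})

test_that("composite fraction controls multi-label records", {
  tax <- demo_tax()
  d0 <- generate_dataset(synth_config(tax, image_size = 32,
                                      n_per_class = c(a1 = 6, a2 = 6, b1 = 6,
                                                      b2 = 6),
                                      composite_fraction = 0, seed = 1),
                         file.path(tempdir(), "nocomp"))
  labs <- strsplit(d0$manifest$level2_labels, ";")
  expect_true(all(lengths(labs) == 1))
  d5 <- generate_dataset(synth_config(tax, image_size = 32,
                                      n_per_class = c(a1 = 10, a2 = 10,
                                                      b1 = 10, b2 = 10),
                                      composite_fraction = 0.5, seed = 1),
                         file.path(tempdir(), "comp"))
  labs5 <- strsplit(d5$manifest$level2_labels, ";")
  expect_identical(sum(lengths(labs5) == 2), 20L)   # round(0.5 * 40)
  # composite partners are distinct subclasses of the same coarse group
  for (l in labs5[lengths(labs5) == 2]) {
    expect_false(l[1] == l[2])
    expect_identical(ancestors(tax, l[1]), ancestors(tax, l[2]))
  }
})

test_that("emitted labels expand consistently and boxes lie inside images", {
  ds <- small_dataset()
  tax <- demo_tax()
  labs <- strsplit(ds$manifest$level2_labels, ";")
  boxes <- manifest_boxes(ds$manifest)
  S <- ds$config$image_size
  for (i in seq_len(nrow(ds$manifest))) {
    lab <- expand_labels(tax, labs[[i]])   # errors if not valid level-2 ids
    expect_identical(sum(lab$levels[[2]]), length(labs[[i]]))
    expect_identical(length(boxes[[i]]), length(labs[[i]]))
    for (b in boxes[[i]]) {
      expect_true(b$box["x0"] >= 0 && b$box["y0"] >= 0)
      expect_true(b$box["x1"] <= S && b$box["y1"] <= S)
      expect_true(b$box["x1"] > b$box["x0"])
    }
  }
  # images decode to the configured size and range
  imgs <- load_images(ds$manifest)
  expect_identical(dim(imgs), c(S, S, 3L, nrow(ds$manifest)))
  expect_true(all(imgs >= 0 & imgs <= 1))
})

test_that("noise-free classes are separable by a pixel-statistics oracle", {
  tax <- demo_tax()
  ds <- generate_dataset(synth_config(tax, image_size = 48,
                                      n_per_class = c(a1 = 15, a2 = 15,
                                                      b1 = 15, b2 = 15),
                                      composite_fraction = 0, noise_sd = 0,
                                      seed = 21),
                         file.path(tempdir(), "sep"))
  imgs <- load_images(ds$manifest)
  # oracle: nearest centroid on per-channel mean intensities, leave-one-in
  feats <- t(apply(imgs, 4, function(im) c(mean(im[, , 1]), mean(im[, , 2]),
                                           mean(im[, , 3]))))
  l1 <- vapply(strsplit(ds$manifest$level2_labels, ";"),
               function(l) ancestors(tax, l[1]), character(1))
  cents <- do.call(rbind, lapply(unique(l1), function(g)
    colMeans(feats[l1 == g, , drop = FALSE])))
  rownames(cents) <- unique(l1)
  pred <- rownames(cents)[apply(feats, 1, function(f)
    which.min(colSums((t(cents) - f)^2)))]
  expect_gt(mean(pred == l1), 0.9)
})

test_that("stratified partition is exact, disjoint and exhaustive", {
  ds <- small_dataset()
  part <- train_test_partition(ds$manifest, 0.25, seed = 3)
  n <- nrow(ds$manifest)
  expect_identical(nrow(part$test), as.integer(round(0.25 * n)))
  expect_identical(nrow(part$train) + nrow(part$test), n)
  expect_identical(sort(c(part$train$image_path, part$test$image_path)),
                   sort(ds$manifest$image_path))
  # every class with >= 5 records appears in both parts
  primary <- function(m) vapply(strsplit(m$level2_labels, ";"), `[`,
                                character(1), 1)
  counts <- table(primary(ds$manifest))
  for (cl in names(counts)[counts >= 5]) {
    expect_true(cl %in% primary(part$train))
    expect_true(cl %in% primary(part$test))
  }
  # determinism
  part2 <- train_test_partition(ds$manifest, 0.25, seed = 3)
  expect_identical(part2$test$image_path, part$test$image_path)
  expect_error(train_test_partition(ds$manifest, 0), "fraction_test")
  expect_error(train_test_partition(ds$manifest, 1), "fraction_test")
})

test_that("configuration errors are caught early", {
  tax <- demo_tax()
  expect_error(synth_config(tax, n_per_class = c(zzz = 5)), "unknown")
  expect_error(synth_config(tax, composite_fraction = 1.2), "composite")
  expect_error(synth_config(tax, noise_sd = -1), "noise_sd")
  expect_error(synth_config(tax, n_per_class = c(a1 = -2)), "counts")
})
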
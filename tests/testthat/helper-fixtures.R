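# Shared fixtures. Heavy artifacts (the fully trained desk model) are
# built once per test session and cached in this environment so several
# test files can reuse them.

.cache <- new.env(parent = emptyenv())

demo_tax <- function() taxonomy_fixture("demo")

# Tiny model for structural / gradient tests: 16 px input, 2 small blocks.
tiny_model <- function(tax = demo_tax(), type = "hierarchical", seed = 3,
                       input_size = 16) {
  builder <- if (type == "hierarchical") build_hierarchical_model
             else build_flat_baseline
  builder(tax, backbone_spec(channels = c(4, 6)),
          head_config(hidden = c(8, 5)), input_size, seed)
}

random_images <- function(n, size = 16, seed = 9) {
  withr::with_seed(seed, array(runif(size * size * 3 * n),
                               c(size, size, 3, n)))
}

# Small generated dataset reused across synthetic/training tests.
small_dataset <- function() {
  if (is.null(.cache$small_ds)) {
    cfg <- synth_config(demo_tax(), image_size = 48,
                        n_per_class = c(a1 = 20, a2 = 12, b1 = 8, b2 = 6),
                        composite_fraction = 0.15, noise_sd = 0.02, seed = 5)
    .cache$small_ds <- generate_dataset(cfg, file.path(tempdir(), "small_ds"))
  }
  .cache$small_ds
}

# The full desk-profile run used by the end-to-end, ablation and saliency
# acceptance tests: demo taxonomy, ~600 images at 96 px, 10:1 imbalance,
# 10% composites, seed 42; 80/20 split; desk training preset.
desk_run <- function() {
  if (is.null(.cache$desk)) {
    tax <- demo_tax()
    ds <- generate_dataset(synth_config(tax, seed = 42),
                           file.path(tempdir(), "desk_ds"))
    part <- train_test_partition(ds$manifest, 0.2, seed = 42)
    tr_imgs <- load_images(part$train)
    te_imgs <- load_images(part$test)
    cfg <- train_config("desk", seed = 42)
    model <- build_hierarchical_model(tax, cfg$backbone, cfg$heads,
                                      cfg$input_size, seed = 42)
    ckpt <- file.path(tempdir(), "desk_ckpt")
    fit <- train_model(model, part$train, cfg, images = tr_imgs,
                       checkpoint_dir = ckpt)
    .cache$desk <- list(tax = tax, ds = ds, part = part,
                        tr_imgs = tr_imgs, te_imgs = te_imgs,
                        cfg = cfg, init_model = model, fit = fit,
                        ckpt = ckpt)
  }
  .cache$desk
}
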
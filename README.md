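# hicnet — taxonomy-guided hierarchical multi-label image classification

`hicnet` classifies images against a two-level disease taxonomy in a
coarse-to-fine manner: a shared convolutional backbone feeds one
classification branch per taxonomy level, the coarse branch's hidden
state is concatenated into the fine branch as a prior, and every class
gets its own sigmoid output so several diseases can be detected in one
image. It was built for eye-disease screening workloads (anterior
segment and retinal photographs, long-tailed class frequencies,
co-occurring diagnoses) but the machinery is generic: any two-level
taxonomy plus an image manifest works.

The package provides, as testable R functions:

* **Taxonomy label algebra** — JSON taxonomies with validation,
  upward label expansion (`expand_labels`), and inference-time
  consistency reporting (`check_consistency`).
* **The model** — `build_hierarchical_model()` /
  `build_flat_baseline()` (the ablation comparator), with a
  hand-rolled, gradient-checked forward/backward pass (Rcpp + BLAS).
* **The objective** — per-level multi-label focal loss
  `FL(p_t) = (1 − p_t)^γ · (−log p_t)` and the level-weighted total
  `L = α·L₁ + (1−α)·L₂`, α ∈ (0, 0.5), default α = 0.3, γ = 2.
* **Training** — on-the-fly augmentation and the staged fine-tuning
  schedule: heads-only with a frozen backbone, then step-wise
  unfreezing (last blocks first) at geometrically decreasing learning
  rates. Presets `"full"` (299 px, 5 + 4×20 epochs) and `"desk"`
  (96 px, 5 + 2×8 epochs, minutes on one CPU).
* **Evaluation** — per-class ROC/AUC (Mann–Whitney, oracle-tested),
  accuracy/sensitivity/specificity, per-level argmax confusion
  matrices, stratified splits, seeded 5-fold cross-validation with
  vertically averaged mean ROC, the strict >0.5 screening rule and
  top-3 correctness.
* **Saliency** — Grad-CAM heatmaps for any (image, level, class) with
  a quantitative `localization_score()` against ground-truth lesion
  boxes.
* **Synthetic data** — a seeded generator emulating the assumed data
  structure: level-1 classes set a background hue + large motif,
  level-2 subclasses set a stripe texture inside a randomly placed
  lesion box, with class imbalance (10:1), multi-label composites and
  recorded lesion geometry.

## Worked example

```r
library(hicnet)

tax  <- taxonomy_fixture("demo")            # 2 coarse x 4 fine classes
ds   <- generate_dataset(synth_config(tax, seed = 42), "demo_ds")
part <- train_test_partition(ds$manifest, fraction_test = 0.2, seed = 42)

cfg   <- train_config("desk", seed = 42)
model <- build_hierarchical_model(tax, cfg$backbone, cfg$heads,
                                  cfg$input_size, seed = 42)
fit    <- train_model(model, part$train, cfg)
report <- evaluate_model(fit$model, part$test)
report
#> <eval_report> n=120, threshold=0.5
#>   level 1 mean AUC: 1.000 (2 classes)
#>   level 2 mean AUC: 1.000 (4 classes)
round(report$level2$auc, 3)
#> a1 a2 b1 b2
#>  1  1  1  1
```

Level-1 separation (the coarse background attribute) is learned
perfectly and all four fine subclasses (lesion textures) reach held-out
AUC 1 on this seed. Multi-label screening on a composite test image
(row 5 carries the truth `b1;b2`) calls both diseases at the >0.5
rule:

```r
scores <- model_forward(fit$model, load_images(part$test))$level2
predict_calls(scores[5, ], threshold = 0.5, k = 3)$positive
#> [1] "b1" "b2"
```

Grad-CAM shows where the evidence sits, and the synthetic ground truth
makes that quantitative: for the first test image the fraction of
heatmap mass inside the true lesion box is 0.301, against a box area
share of 0.111 (across all correctly classified single-label test
images the median is ≈ 0.27).

```r
img <- load_images(part$test)[, , , 1]
truth <- strsplit(part$test$level2_labels[1], ";")[[1]][1]
hm  <- grad_cam(fit$model, img, level = 2, class_id = truth)
localization_score(hm, hicnet:::manifest_boxes(part$test)[[1]][[1]]$box)
#> [1] 0.3011225
```

A command-line front door wraps the same functions
(`inst/cli/hicnet`): subcommands `simulate`, `train`, `crossval`,
`evaluate`, `predict`, `gradcam`, each writing a `provenance.json`
alongside its artifacts.

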
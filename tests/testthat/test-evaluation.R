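test_that("binary metrics follow their defining ratios", {
  m <- binary_metrics(tp = 91, fp = 10, tn = 90, fn = 9)
  expect_equal(m$sensitivity, 0.91, tolerance = 1e-12)
  expect_equal(m$specificity, 0.90, tolerance = 1e-12)
  expect_equal(m$accuracy, 0.905, tolerance = 1e-12)
  perfect <- binary_metrics(10, 0, 10, 0)
  expect_identical(unlist(perfect), c(accuracy = 1, sensitivity = 1,
                                      specificity = 1))
  # 0/0 sensitivity is flagged undefined, not an error
  expect_true(is.na(binary_metrics(0, 5, 5, 0)$sensitivity))
  expect_error(binary_metrics(0, 0, 0, 0), "zero")
})

test_that("AUC reproduces the worked pairwise instance exactly", {
  r <- roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))
  expect_identical(r$auc, 0.75)   # 3 of 4 positive x negative pairs concordant
  expect_identical(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  # curve spans (0,0) to (1,1)
  expect_identical(r$curve$fpr[1], 0)
  expect_identical(r$curve$tpr[nrow(r$curve)], 1)
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "both label")
})

test_that("AUC equals the brute-force rank oracle with half-credit ties", {
  brute <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (p in pos) for (q in neg) {
      tot <- tot + (p > q) + 0.5 * (p == q)
    }
    tot / (length(pos) * length(neg))
  }
  gap <- withr::with_seed(31, {
    worst <- 0
    for (i in 1:200) {
      n <- sample(4:200, 1)
      s <- round(runif(n), sample(c(1, 2, 6), 1))   # induce ties sometimes
      y <- rbinom(n, 1, runif(1, 0.2, 0.8))
      if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
      worst <- max(worst, abs(roc_auc(s, y)$auc - brute(s, y)))
    }
    worst
  })
  expect_lt(gap, 1e-9)
})

test_that("AUC agrees with an independent ROC library", {
  withr::with_seed(37, {
    s <- runif(300)
    y <- rbinom(300, 1, plogis(4 * s - 2))
  })
  ours <- roc_auc(s, y)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("random scores give chance-level AUC", {
  withr::with_seed(41, {
    s <- runif(2000)
    y <- rbinom(2000, 1, 0.4)
  })
  expect_lt(abs(roc_auc(s, y)$auc - 0.5), 0.03)
})

test_that("confusion matrix matches a hand tally and conserves counts", {
  withr::with_seed(43, {
    sc <- matrix(runif(90), 30, 3, dimnames = list(NULL, c("x", "y", "z")))
    truth_cls <- sample(1:3, 30, replace = TRUE)
  })
  tr <- matrix(0L, 30, 3); tr[cbind(1:30, truth_cls)] <- 1L
  m <- confusion_matrix(sc, tr)
  # brute-force tally oracle
  for (a in 1:3) for (b in 1:3) {
    expect_identical(m[a, b], sum(truth_cls == a &
                                    apply(sc, 1, which.max) == b))
  }
  expect_identical(sum(m), 30L)
  expect_identical(attr(m, "n_excluded"), 0L)
  # perfect predictor: diagonal; constant predictor: single column
  expect_true(all(confusion_matrix(tr, tr)[lower.tri(m) | upper.tri(m)] == 0))
  const <- matrix(rep(c(1, 0, 0), each = 30), 30, 3)
  mc <- confusion_matrix(const, tr)
  expect_true(all(mc[, 2:3] == 0))
  # multi-label rows are excluded and counted
  tr2 <- tr; tr2[1, ] <- 1L
  m2 <- confusion_matrix(sc, tr2)
  expect_identical(attr(m2, "n_excluded"), 1L)
  expect_identical(sum(m2), 29L)
})

test_that("k-fold splits are balanced, exhaustive and reproducible", {
  f <- kfold_split(100, 5, seed = 2)
  expect_identical(as.integer(table(f)), rep(20L, 5))
  expect_identical(kfold_split(100, 5, seed = 2), f)
  expect_false(identical(kfold_split(100, 5, seed = 3), f))
  expect_error(kfold_split(3, 5), "at least k")
  bad <- withr::with_seed(47, {
    b <- 0L
    for (i in 1:50) {
      n <- sample(5:500, 1)
      fi <- kfold_split(n, 5, seed = i)
      ok <- length(fi) == n && all(sort(unique(fi)) == 1:5) &&
        diff(range(table(fi))) <= 1
      if (!ok) b <- b + 1L
    }
    b
  })
  expect_identical(bad, 0L)
})

test_that("top-k correctness is simple membership", {
  expect_true(topk_correct("glaucoma", c("cataract", "myopia", "glaucoma")))
  expect_false(topk_correct("scleritis", c("cataract", "myopia", "glaucoma")))
  s <- c(a = 0.2, b = 0.9, c = 0.5)
  expect_true(topk_correct("b", predict_calls(s, k = 1)$topk))   # argmax
  expect_false(topk_correct("a", predict_calls(s, k = 1)$topk))
})

test_that("vertical ROC averaging is labelled and bounded", {
  c1 <- data.frame(threshold = c(Inf, 1, 0), fpr = c(0, 0, 1),
                   tpr = c(0, 1, 1))
  c2 <- data.frame(threshold = c(Inf, 1, 0), fpr = c(0, 0.5, 1),
                   tpr = c(0, 0.5, 1))
  mr <- mean_roc(list(c1, c2))
  expect_identical(attr(mr, "method"), "vertical_average")
  expect_true(all(mr$tpr_mean >= 0 & mr$tpr_mean <= 1))
  expect_equal(mr$tpr_mean[mr$fpr == 0.5], mean(c(1, 0.5)),
               tolerance = 1e-9)
})

test_that("cross-validation trains k models over disjoint exhaustive folds", {
  ds <- small_dataset()
  cfg <- train_config("desk", input_size = 48, batch_size = 16, seed = 8,
                      backbone = backbone_spec(channels = c(4, 8)),
                      heads = head_config(hidden = c(16, 8)),
                      stage1 = list(epochs = 1),
                      stage2 = list(steps = 1, epochs_per_step = 1))
  cv <- cross_validate(ds$manifest,
                       function() build_hierarchical_model(
                         demo_tax(), cfg$backbone, cfg$heads, 48, seed = 8),
                       cfg, k = 3, seed = 8)
  expect_length(cv$folds, 3)
  expect_identical(length(cv$fold_assignment), nrow(ds$manifest))
  expect_identical(sum(vapply(cv$folds, function(r) r$n, numeric(1))),
                   as.numeric(nrow(ds$manifest)))
  expect_named(cv$mean_auc, c("level1", "level2"))
  expect_length(cv$mean_auc$level2, 4)
})
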
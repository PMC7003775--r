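test_that("Dice boundary cases, arithmetic and symmetry", {
  a <- array(FALSE, c(4, 4, 2)); a[1:2, 1:2, 1] <- TRUE
  expect_equal(dice(a, a), 1.0)
  b <- array(FALSE, c(4, 4, 2)); b[3:4, 3:4, 2] <- TRUE
  expect_equal(dice(a, b), 0)
  # 2 voxels each, 1 shared
  c1 <- array(FALSE, c(4, 4, 2)); c1[c(1, 2)] <- TRUE
  c2 <- array(FALSE, c(4, 4, 2)); c2[c(2, 3)] <- TRUE
  expect_equal(dice(c1, c2), 0.5)
  expect_equal(dice(c1, c2), dice(c2, c1))
  expect_warning(z <- dice(a & FALSE, b & FALSE), "empty")
  expect_equal(z, 0)
  expect_error(dice(a, array(FALSE, c(3, 4, 2))), "mismatch")
})

test_that("confusion metrics from the 2x2 table", {
  pred <- c(rep("malignant", 86), rep("benign", 14),
            rep("benign", 86), rep("malignant", 14))
  truth <- c(rep("malignant", 100), rep("benign", 100))
  cm <- confusion_metrics(pred, truth)
  expect_equal(cm$sensitivity, 0.86)
  expect_equal(cm$specificity, 0.86)

  perf <- confusion_metrics(truth, truth)
  expect_equal(unlist(perf), c(sensitivity = 1, specificity = 1,
                               ppv = 1, npv = 1))

  allpos <- confusion_metrics(rep("malignant", 200), truth)
  expect_equal(allpos$specificity, 0)
  expect_true(is.na(allpos$npv))
  expect_error(confusion_metrics(pred, rep("malignant", 200)), "both")
})

test_that("ROC/AUC: separable, chance level, pairwise oracle with ties", {
  r <- roc_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(r$auc, 1.0)
  expect_true(all(diff(r$tpr) >= 0) && all(diff(r$fpr) >= 0))

  set.seed(6)
  y <- rep(c(0, 1), 250)
  expect_lt(abs(roc_auc(rnorm(500), y)$auc - 0.5), 0.08)

  for (rep in 1:10) {
    n <- sample(6:20, 1)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE) # forces ties
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_equal(roc_auc(scores, labels)$auc, auc_oracle(scores, labels))
  }
  expect_error(roc_auc(1:4, rep(1, 4)), "class")
})

test_that("lesion volume and percent difference", {
  m <- array(FALSE, c(5, 5, 2)); m[1:10] <- TRUE
  expect_equal(lesion_volume(m, c(1, 1, 3)), 30)
  expect_equal(lesion_volume(m & FALSE, c(1, 1, 3)), 0)
  expect_equal(lesion_volume(m, c(1, 1, 1.5)), 15)

  expect_equal(percent_volume_difference(104.4, 100), 4.4)
  expect_equal(percent_volume_difference(100, 100), 0)
  expect_equal(percent_volume_difference(110, 100, mode = "symmetric"),
               100 * 10 / 105, tolerance = 1e-9)
  expect_equal(percent_volume_difference(110, 100, mode = "symmetric"),
               9.52, tolerance = 1e-2)
  expect_error(percent_volume_difference(10, 0), "positive")
})

test_that("Bland-Altman limits and recomputation from returned diffs", {
  ba <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$loa_high - ba$loa_low, 0)

  ba2 <- bland_altman(c(1, 2, 3), c(3, 4, 5))
  expect_equal(ba2$mean_diff, -2)
  expect_equal(sd(ba2$diffs), 0)

  ba3 <- bland_altman(c(10, 20, 30), c(10, 22, 29))
  expect_equal(ba3$mean_diff, -1 / 3)
  expect_equal(sd(ba3$diffs), sqrt(7 / 3))
  expect_equal(ba3$loa_low, mean(ba3$diffs) - 1.96 * sd(ba3$diffs))
  expect_equal(ba3$loa_high, mean(ba3$diffs) + 1.96 * sd(ba3$diffs))
  expect_error(bland_altman(1:3, 1:4), "length")
  expect_error(bland_altman(1:2, 1:2), "3")
})

test_that("twofold CV bookkeeping: one score per subject, opposite fold, seeded", {
  cohort <- lapply(1:6, function(i)
    generate_phantom(phantom_spec(grid_shape = c(16, 16, 4),
                                  lesion_radius_voxels = 3,
                                  noise_sd = 0, heterogeneity_amp = 0,
                                  lesion_phenotype =
                                    if (i <= 3) "benign" else "malignant",
                                  seed = i)))
  for (i in seq_along(cohort))
    cohort[[i]]$study$subject_id <- sprintf("sub%03d", i)
  cfg <- tiny_cfg(3)
  tab <- twofold_cv_segmentation(cohort, cfg, seed = 5)
  expect_equal(nrow(tab), 6)
  expect_setequal(tab$subject_id, sprintf("sub%03d", 1:6))
  expect_setequal(unique(tab$fold), 1:2)
  # stratified halves: equal sizes here, both phenotypes in each fold
  expect_equal(sum(tab$fold == 1), 3)
  expect_setequal(unique(tab$phenotype[tab$fold == 1]),
                  c("benign", "malignant"))

  tab2 <- twofold_cv_segmentation(cohort, cfg, seed = 5)
  expect_identical(tab, tab2)

  # noiseless, homogeneous phantoms segment perfectly
  expect_equal(tab$dice, rep(1, 6))
  expect_error(twofold_cv_segmentation(cohort[1], cfg, seed = 1), "2")
})

test_that("LOOCV harness agrees with an explicit nested-loop recomputation", {
  set.seed(13)
  X <- rbind(matrix(rnorm(16, 0, 1.6), 8, 2),
             matrix(rnorm(16, 2.5, 1.6), 8, 2))
  y <- rep(c("benign", "malignant"), each = 8)
  res <- loocv_classification(X, y, ratios = 2.5)

  # independent bookkeeping: train on all-but-i, score i, pool
  oracle_scores <- vapply(seq_len(nrow(X)), function(i) {
    fit <- train_cost_weighted_svm(X[-i, ], y[-i], ratios = 2.5,
                                   cv = "kfold10", seed = 1)
    classify_lesion(fit$model, X[i, , drop = FALSE])$score
  }, numeric(1))
  expect_equal(res$scores, oracle_scores, tolerance = 1e-6)
  expect_length(res$scores, nrow(X))
  expect_equal(res$roc$auc, roc_auc(oracle_scores, y)$auc,
               tolerance = 1e-9)
})
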
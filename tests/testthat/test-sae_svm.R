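test_that("statistics layer: hand case, degenerate, invariances", {
  enc <- matrix(c(0.2, 0.4, 0.6), 3, 1)
  s <- statistics_layer(enc)
  expect_equal(as.numeric(s), c(0.4, 0.2, 0.6, 0.2))

  one <- statistics_layer(matrix(0.7, 1, 3))
  expect_equal(as.numeric(one), c(rep(0.7, 3), rep(0, 3), rep(0.7, 3),
                                  rep(0.7, 3)))

  set.seed(3)
  E <- matrix(runif(50), 10, 5)
  expect_equal(statistics_layer(E), statistics_layer(E[sample(10), ]))
  s2 <- statistics_layer(E)
  means <- s2[1:5]; sds <- s2[6:10]; maxs <- s2[11:15]; mins <- s2[16:20]
  expect_true(all(mins <= means & means <= maxs))
  expect_true(all(sds >= 0))
  expect_error(statistics_layer(matrix(numeric(0), 0, 3)), "empty")
})

test_that("lesion SAE is sigmoid-encoded, unsupervised and deterministic", {
  set.seed(7)
  X <- matrix(runif(60 * 13), 60, 13)
  cfg <- ssae_config(max_epochs = 80, seed = 11)
  sae <- train_lesion_sae(X, cfg)
  expect_identical(sae$activation, "sigmoid")
  H <- sae_encode(sae, X)
  expect_true(all(H > 0 & H < 1))
  expect_equal(ncol(H), 10)

  # degenerate one-vector dataset reconstructs
  v <- runif(13)
  Xd <- matrix(rep(v, each = 50), 50, 13)
  saed <- train_lesion_sae(Xd, ssae_config(max_epochs = 200,
                                           sparsity_weight = 0, seed = 2))
  expect_lt(mean(rowSums((Xd - sae_reconstruct(saed, Xd))^2)), 1e-3)

  # no label argument exists; retraining on identical data is bit-identical
  sae2 <- train_lesion_sae(X, cfg)
  expect_identical(sae$W_enc, sae2$W_enc)
  expect_false("labels" %in% names(formals(train_lesion_sae)))
})

test_that("feature vectors: lengths per mode, identical lesions match", {
  set.seed(8)
  sig <- matrix(runif(20 * 13), 20, 13)
  enc <- matrix(runif(20 * 10), 20, 10)
  rec <- lesion_record("s1", array(TRUE, c(2, 2, 5)), sig, encoded = enc)
  expect_length(build_feature_vector(rec, "node_stats"), 40)
  expect_length(build_feature_vector(rec, "node_plus_channel_stats"),
                40 + 4 * 13)
  rec2 <- lesion_record("s2", array(TRUE, c(2, 2, 5)), sig, encoded = enc)
  expect_equal(build_feature_vector(rec), build_feature_vector(rec2))
  expect_error(build_feature_vector(lesion_record("s", NULL, sig)),
               "encoded")
})

test_that("cost grid is exactly the seven printed ratios and is respected", {
  expect_equal(cost_ratio_grid(), c(1, 1.5, 2, 2.5, 3, 3.5, 4))
  set.seed(9)
  X <- rbind(matrix(rnorm(20, 0, 0.5), 10, 2),
             matrix(rnorm(20, 10, 0.5), 10, 2))
  y <- rep(c("benign", "malignant"), each = 10)
  res <- train_cost_weighted_svm(X, y, cv = "loocv")
  expect_equal(res$grid$ratios, cost_ratio_grid())
  expect_true(res$grid$best_ratio %in% cost_ratio_grid())
  # fully separable: AUC 1 everywhere, tie broken toward the smaller ratio
  expect_equal(res$grid$auc_per_ratio, rep(1, 7))
  expect_equal(res$grid$best_ratio, 1)
  expect_error(train_cost_weighted_svm(X, rep("benign", 20)), "class")
})

test_that("label permutation gives chance-level cross-validated AUC", {
  # LOOCV AUC under the permutation null is known to sit slightly below 0.5
  # (each left-out case is anti-correlated with its training fold), so the
  # null band is asymmetric; real signal must clear it by a wide margin.
  set.seed(10)
  X <- matrix(rnorm(16 * 4), 16, 4)
  y <- rep(c(0, 1), each = 8)
  aucs <- replicate(100, {
    yp <- sample(y)
    sc <- mpmriseg:::svm_cv_scores(X, yp, benign_cost = 1, cv = "loocv",
                                   seed = 1)
    roc_auc(sc, yp)$auc
  })
  expect_gt(mean(aucs), 0.3)
  expect_lt(mean(aucs), 0.6)
  # separable data under the true labels clears the null distribution
  Xs <- X; Xs[y == 1, 1] <- Xs[y == 1, 1] + 10
  sc <- mpmriseg:::svm_cv_scores(Xs, y, benign_cost = 1, cv = "loocv",
                                 seed = 1)
  expect_gt(roc_auc(sc, y)$auc, max(aucs))
})

test_that("classification: separable training points, scale identity, k-fold", {
  set.seed(11)
  X <- rbind(matrix(rnorm(24, 0, 0.4), 12, 2),
             matrix(rnorm(24, 8, 0.4), 12, 2))
  y <- rep(c("benign", "malignant"), each = 12)
  res <- train_cost_weighted_svm(X, y, cv = "kfold10", seed = 3)
  cl <- classify_lesion(res$model, X)
  expect_true(all(cl$label == y))
  expect_true(all(cl$score[y == "malignant"] > 0))
  expect_identical(classify_lesion(res$model, X * 1.0)$score, cl$score)
  expect_error(classify_lesion(res$model, X[, 1, drop = FALSE]), "layout")
})

test_that("SVM model JSON round trip preserves scores", {
  dir <- withr::local_tempdir()
  set.seed(12)
  X <- rbind(matrix(rnorm(20), 10, 2), matrix(rnorm(20, 4), 10, 2))
  y <- rep(c(0, 1), each = 10)
  res <- train_cost_weighted_svm(X, y)
  p <- file.path(dir, "svm.json")
  write_svm_model(res$model, p)
  back <- read_svm_model(p)
  expect_equal(classify_lesion(back, X)$score,
               classify_lesion(res$model, X)$score, tolerance = 1e-12)
  expect_equal(back$ratio, res$model$ratio)
})

test_that("lesion extraction keeps the largest connected component", {
  tc <- trained_clean_model()
  ph <- tc$phantoms[[1]]
  seg <- segment_study(tc$model, tc$studies[[1]])
  rec <- lesion_from_segmentation(tc$studies[[1]], seg, label = "malignant")
  expect_s3_class(rec, "lesion_record")
  expect_equal(nrow(rec$signatures), sum(rec$lesion_mask))
  lab <- mpmriseg:::.cc_label(as.logical(rec$lesion_mask),
                              dim(rec$lesion_mask))
  expect_lte(max(lab), 1L)
  # no lesion voxels -> NULL
  empty <- label_map(array(0L, dim(ph$truth$labels)))
  expect_null(lesion_from_segmentation(tc$studies[[1]], empty))
})
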
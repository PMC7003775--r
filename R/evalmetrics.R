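#' Dice similarity coefficient
#'
#' `2 |A n B| / (|A| + |B|)`: 1 for full overlap, 0 for none. When both
#' masks are empty the value is defined as 0 (with a warning).
#'
#' @param mask_a,mask_b logical arrays on one grid.
#' @return real in \[0, 1\].
#' @export
dice <- function(mask_a, mask_b) {
  check_same_dim(mask_a, mask_b, "masks")
  a <- as_mask(mask_a); b <- as_mask(mask_b)
  denom <- sum(a) + sum(b)
  if (denom == 0) {
    warnf("both masks are empty; Dice defined as 0")
    return(0)
  }
  2 * sum(a & b) / denom
}

#' Confusion-table metrics for binary classification
#'
#' Sensitivity, specificity, positive and negative predictive value from the
#' 2x2 table; ratios with zero denominator are reported as `NA`.
#'
#' @param pred_labels,true_labels label vectors.
#' @param positive_class value treated as positive (default `"malignant"`).
#' @return named list `sensitivity`, `specificity`, `ppv`, `npv`.
#' @export
confusion_metrics <- function(pred_labels, true_labels,
                              positive_class = "malignant") {
  p <- pred_labels == positive_class
  t <- true_labels == positive_class
  if (length(unique(t)) < 2L) stopf("truth must contain both classes")
  tp <- sum(p & t); fn <- sum(!p & t); tn <- sum(!p & !t); fp <- sum(p & !t)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  list(sensitivity = ratio(tp, tp + fn), specificity = ratio(tn, tn + fp),
       ppv = ratio(tp, tp + fp), npv = ratio(tn, tn + fn))
}

#' ROC curve and AUC from decision scores
#'
#' Threshold sweep over the unique scores; the trapezoidal AUC is tie-aware
#' and equals the normalized Mann-Whitney U statistic (ties counted 1/2).
#'
#' @param scores numeric decision scores (higher = more positive).
#' @param labels binary labels (1/`"malignant"` positive).
#' @return object of class `roc_result`: `thresholds`, `tpr`, `fpr`, `auc`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as_malignant01(labels)
  if (length(unique(y)) < 2L) stopf("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  np <- sum(y == 1); nn <- sum(y == 0)
  tpr <- vapply(thr, function(t) sum(scores >= t & y == 1) / np, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & y == 0) / nn, numeric(1))
  tpr <- c(0, tpr); fpr <- c(0, fpr)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(thresholds = c(Inf, thr), tpr = tpr, fpr = fpr, auc = auc),
            class = "roc_result")
}

#' Lesion volume from a mask
#' @param mask logical array.
#' @param voxel_spacing spacing triple in mm.
#' @return volume in mm^3.
#' @export
lesion_volume <- function(mask, voxel_spacing) {
  sum(as_mask(mask)) * prod(as.numeric(voxel_spacing))
}

#' Percent volume difference
#'
#' Default: `100 * |v_test - v_ref| / v_ref` with the reference (ground
#' truth) volume as denominator. `mode = "symmetric"` uses the mean of the
#' two volumes as denominator.
#'
#' @param v_test,v_ref volumes; `v_ref > 0`.
#' @param mode `"reference"` (default) or `"symmetric"`.
#' @return percent difference.
#' @export
percent_volume_difference <- function(v_test, v_ref,
                                      mode = c("reference", "symmetric")) {
  mode <- match.arg(mode)
  if (any(v_ref <= 0)) stopf("reference volume must be positive")
  den <- if (mode == "reference") v_ref else (v_test + v_ref) / 2
  100 * abs(v_test - v_ref) / den
}

#' Bland-Altman limits of agreement
#'
#' Differences are `v1 - v2`; limits are `mean_diff +/- 1.96 * sd(diffs)`.
#'
#' @param v1,v2 paired measurement vectors (length >= 3).
#' @return object of class `bland_altman_result`: `mean_diff`, `loa_low`,
#'   `loa_high`, `diffs`, `means`.
#' @export
bland_altman <- function(v1, v2) {
  if (length(v1) != length(v2)) stopf("paired vectors differ in length")
  if (length(v1) < 3L) stopf("need at least 3 pairs")
  d <- v1 - v2
  m <- mean(d); s <- sd(d)
  structure(list(mean_diff = m, loa_low = m - 1.96 * s,
                 loa_high = m + 1.96 * s, diffs = d, means = (v1 + v2) / 2),
            class = "bland_altman_result")
}

#' Twofold cross-validated segmentation evaluation
#'
#' Randomly halves the cohort; the model trained on each half segments the
#' subjects of the other half, so every subject is scored exactly once by a
#' model that never saw it. Lesion-class Dice is computed against phantom
#' truth or against the eigenimage-defined radiological ground truth.
#'
#' @param cohort list of `phantom_study`.
#' @param cfg an [ssae_config].
#' @param seed split seed.
#' @param truth `"phantom"` (label-map truth) or `"eigenimage"`.
#' @param cap_per_class balanced-sampling cap.
#' @param n_seeds_per_class auto-seeds per class per subject.
#' @param tolerance_fraction region-growing tolerance.
#' @return data frame: `subject_id`, `phenotype`, `fold`, `dice`.
#' @export
twofold_cv_segmentation <- function(cohort, cfg = ssae_config(), seed = 1L,
                                    truth = c("phantom", "eigenimage"),
                                    cap_per_class = 1000L,
                                    n_seeds_per_class = 3L,
                                    tolerance_fraction = 0.05) {
  truth <- match.arg(truth)
  n <- length(cohort)
  if (n < 2L) stopf("need at least 2 subjects")
  folds <- stratified_halves(vapply(cohort, `[[`, character(1),
                                    "lesion_phenotype"), seed)
  seed_tabs <- lapply(seq_len(n), function(i)
    auto_seeds(cohort[[i]]$truth, n_seeds_per_class,
               seed = seed + i))
  rows <- list()
  for (f in 1:2) {
    train_idx <- folds[[f]]
    test_idx <- folds[[3 - f]]
    # intensity scale and signatures come from the training fold only
    bounds <- compute_channel_bounds(lapply(cohort[train_idx],
                                            `[[`, "study"))
    norm_of <- function(i) normalize_channels(cohort[[i]]$study,
                                              bounds = bounds)
    harvested <- lapply(train_idx, function(i)
      harvest_signatures(norm_of(i), seed_tabs[[i]], tolerance_fraction))
    train_set <- sample_balanced(harvested, cap_per_class,
                                 seed = seed + 100 + f)
    model <- train_ssae(train_set, cfg,
                        channel_order = cohort[[1]]$study$channel_order)
    for (i in test_idx) {
      ns_i <- norm_of(i)
      seg <- segment_study(model, ns_i)
      ref <- if (truth == "phantom") cohort[[i]]$truth$labels == 3L else {
        ei_ground_truth(ns_i,
                        harvest_signatures(ns_i, seed_tabs[[i]],
                                           tolerance_fraction))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = cohort[[i]]$study$subject_id,
        phenotype = cohort[[i]]$lesion_phenotype,
        fold = 3 - f,
        dice = dice(seg$labels == 3L, ref))
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$subject_id), ]
}

# Eigenimage-defined radiological ground-truth lesion mask for one study:
# fit the filter on the subject's own harvested signatures (desired = lesion,
# undesired = glandular + fat), apply, threshold over the breast foreground.
ei_ground_truth <- function(study_norm, harvested) {
  pick <- function(cl) {
    idx <- harvested$labels == cl
    signature_set(harvested$signatures[idx, , drop = FALSE],
                  harvested$labels[idx])
  }
  wts <- fit_eigenimage_filter(pick(3L),
                               bind_signature_sets(list(pick(2L), pick(1L))))
  ei <- apply_eigenimage(study_norm, wts)
  fg <- array(TRUE, dim(ei))
  threshold_eigenimage(ei, fg)
}

#' Leave-one-out cross-validated lesion classification
#'
#' Runs the cost-ratio grid search by LOOCV AUC, then reports the pooled
#' LOOCV decision scores at the selected ratio as an ROC plus the confusion
#' metrics at the zero-score operating point (malignant = positive).
#'
#' @param features n x p lesion feature matrix.
#' @param labels phenotype labels.
#' @param ratios cost-ratio grid.
#' @param seed seed (forwarded; LOOCV itself is deterministic).
#' @return list with `roc` (`roc_result`), `confusion` (at score 0),
#'   `scores`, `grid` (`cost_grid_result`).
#' @export
loocv_classification <- function(features, labels,
                                 ratios = cost_ratio_grid(), seed = 1L) {
  res <- train_cost_weighted_svm(features, labels, ratios, cv = "loocv",
                                 seed = seed)
  scores <- res$grid$cv_scores
  y <- ifelse(as_malignant01(labels) == 1, "malignant", "benign")
  pred <- ifelse(scores > 0, "malignant", "benign")
  list(roc = roc_auc(scores, labels),
       confusion = confusion_metrics(pred, y),
       scores = scores, grid = res$grid, model = res$model)
}
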
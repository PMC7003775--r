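#' Train the unsupervised lesion encoder
#'
#' Single sparse autoencoder (10 hidden nodes, sigmoid encoder, linear
#' decoder; L2 0.001, sparsity proportion 0.25, sparsity weight 4) trained on
#' the pooled lesion signatures. Entirely unsupervised: benign/malignant
#' labels are never consulted.
#'
#' @param all_lesion_signatures matrix of lesion-voxel signatures pooled over
#'   the cohort (>= 10 rows).
#' @param cfg an [ssae_config].
#' @return a `sae_layer` with sigmoid activation.
#' @export
train_lesion_sae <- function(all_lesion_signatures, cfg = ssae_config()) {
  train_sae_layer(all_lesion_signatures, cfg$d_hidden, cfg, "sigmoid")
}

#' Statistics layer over a lesion's node activations
#'
#' Characterizes each hidden node of the lesion feature map by the mean,
#' standard deviation (unbiased; 0 for a single voxel), maximum and minimum
#' of its activations over the lesion voxels. Layout: all node means (nodes
#' 1..d), then all SDs, then maxima, then minima — length `4 * d`.
#'
#' @param encoded N_les x d activation matrix.
#' @return numeric vector of length `4 * d`.
#' @export
statistics_layer <- function(encoded) {
  encoded <- as.matrix(encoded)
  if (nrow(encoded) < 1L) stopf("empty activation matrix")
  sds <- if (nrow(encoded) == 1L) rep(0, ncol(encoded)) else apply(encoded, 2, sd)
  out <- c(colMeans(encoded), sds,
           apply(encoded, 2, max), apply(encoded, 2, min))
  names(out) <- c(paste0("mean_n", seq_len(ncol(encoded))),
                  paste0("sd_n", seq_len(ncol(encoded))),
                  paste0("max_n", seq_len(ncol(encoded))),
                  paste0("min_n", seq_len(ncol(encoded))))
  out
}

#' Lesion record
#'
#' Bundles one segmented lesion: its mask, per-voxel signatures, encoded
#' feature map and phenotype label (if known).
#'
#' @param subject_id subject identifier.
#' @param lesion_mask logical array.
#' @param signatures N_les x D matrix of lesion-voxel signatures.
#' @param encoded N_les x d encoded feature map (may be `NULL` until the
#'   lesion SAE is applied).
#' @param label `"benign"`, `"malignant"` or `NA`.
#' @return object of class `lesion_record`.
#' @export
lesion_record <- function(subject_id, lesion_mask, signatures,
                          encoded = NULL, label = NA_character_) {
  if (nrow(signatures) < 1L) stopf("a lesion needs at least one voxel")
  structure(list(subject_id = subject_id, lesion_mask = lesion_mask,
                 signatures = as.matrix(signatures), encoded = encoded,
                 label = label),
            class = "lesion_record")
}

#' Extract the largest segmented lesion of a subject
#'
#' Takes the lesion-class voxels of a segmentation, keeps the largest
#' 26-connected component (one lesion per subject, the documented default),
#' and collects its signatures from the (normalized) study.
#'
#' @param study normalized [mp_study].
#' @param seg [label_map] from [segment_study] (or phantom truth).
#' @param label optional phenotype label.
#' @param lesion_class label value of the lesion class.
#' @return a [lesion_record], or `NULL` when no lesion voxel was segmented.
#' @export
lesion_from_segmentation <- function(study, seg, label = NA_character_,
                                     lesion_class = 3L) {
  mask <- seg$labels == lesion_class
  if (!any(mask)) return(NULL)
  mask <- largest_component(mask)
  sset <- extract_signatures(study, mask, lesion_class)
  lesion_record(study$subject_id, mask, sset$signatures, label = label)
}

#' Build the lesion classification feature vector
#'
#' Default mode `node_stats` is the statistics layer over the SAE node
#' activations (length `4 * d`, 40 with ten nodes). Mode
#' `node_plus_channel_stats` appends (mean, sd, max, min) of each raw input
#' channel over the lesion voxels (length `4 * d + 4 * D`).
#'
#' @param record a [lesion_record] with `encoded` present.
#' @param mode feature layout mode.
#' @return named numeric feature vector.
#' @export
build_feature_vector <- function(record,
                                 mode = c("node_stats",
                                          "node_plus_channel_stats")) {
  mode <- match.arg(mode)
  if (is.null(record$encoded)) stopf("lesion record has no encoded feature map")
  f <- statistics_layer(record$encoded)
  if (mode == "node_plus_channel_stats") {
    ch <- statistics_layer(record$signatures)
    names(ch) <- sub("_n", "_ch", names(ch))
    f <- c(f, ch)
  }
  f
}

# ---- cost-weighted linear SVM (squared-hinge primal, BFGS) ----------------

# y in {-1, +1}; weights: per-sample misclassification cost.
svm_fit_core <- function(X, y, weights, C = 1) {
  d <- ncol(X)
  obj <- function(theta) {
    w <- theta[1:d]; b <- theta[d + 1]
    m <- 1 - y * (X %*% w + b)
    act <- m > 0
    0.5 * sum(w^2) + C * sum(weights[act] * m[act]^2)
  }
  grd <- function(theta) {
    w <- theta[1:d]; b <- theta[d + 1]
    m <- as.vector(1 - y * (X %*% w + b))
    act <- m > 0
    coef <- numeric(length(y))
    coef[act] <- -2 * C * weights[act] * m[act] * y[act]
    c(w + as.vector(crossprod(X, coef)), sum(coef))
  }
  fit <- optim(rep(0, d + 1), obj, grd, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  list(w = fit$par[1:d], b = fit$par[d + 1])
}

svm_standardize <- function(X) {
  mu <- colMeans(X)
  s <- apply(X, 2, sd)
  s[!is.finite(s) | s == 0] <- 1
  list(mu = mu, s = s, X = sweep(sweep(X, 2, mu), 2, s, `/`))
}

#' The printed misclassification-penalty ratio grid
#'
#' Benign:malignant cost ratios searched by the classifier:
#' 1:1, 1.5:1, 2:1, 2.5:1, 3:1, 3.5:1, 4:1.
#' @return numeric vector of the seven benign-cost multipliers.
#' @export
cost_ratio_grid <- function() c(1, 1.5, 2, 2.5, 3, 3.5, 4)

svm_cv_scores <- function(X, y01, benign_cost, cv, seed, C = 1) {
  n <- length(y01)
  folds <- if (cv == "loocv") as.list(seq_len(n)) else {
    ord <- with_seed(seed, sample(n))
    split(ord, rep_len(seq_len(10L), n))
  }
  scores <- numeric(n)
  for (te in folds) {
    tr <- setdiff(seq_len(n), te)
    if (length(unique(y01[tr])) < 2L)
      stopf("a training fold lost one class; need >= 2 subjects per class")
    st <- svm_standardize(X[tr, , drop = FALSE])
    wts <- ifelse(y01[tr] == 1, 1, benign_cost)   # benign errors cost more
    fit <- svm_fit_core(st$X, ifelse(y01[tr] == 1, 1, -1), wts, C)
    Xte <- sweep(sweep(X[te, , drop = FALSE], 2, st$mu), 2, st$s, `/`)
    scores[te] <- as.vector(Xte %*% fit$w + fit$b)
  }
  scores
}

#' Cost-weighted linear SVM with misclassification-penalty grid search
#'
#' For each benign:malignant cost ratio in the grid, trains a linear
#' soft-margin SVM with per-class error weights (benign errors weighted by
#' the ratio) and evaluates it by the requested cross-validation using the
#' decision scores for ROC/AUC. The ratio with maximum cross-validated AUC
#' wins (ties break toward the smaller ratio); the final model is refit on
#' all data at that ratio. Features are standardized inside each training
#' fold. Malignant is the positive class throughout.
#'
#' @param features n x p feature matrix (one row per lesion).
#' @param labels `"benign"`/`"malignant"` (or 0/1) of length n.
#' @param ratios benign-cost multipliers; defaults to [cost_ratio_grid()].
#' @param cv `"loocv"` or `"kfold10"`.
#' @param seed RNG seed (used only for the k-fold split).
#' @param C soft-margin penalty.
#' @return list with `model` (class `svm_model`) and `grid` (class
#'   `cost_grid_result`: `ratios`, `auc_per_ratio`, `best_ratio`,
#'   `cv_scores` at the best ratio).
#' @export
train_cost_weighted_svm <- function(features, labels,
                                    ratios = cost_ratio_grid(),
                                    cv = c("loocv", "kfold10"), seed = 1L,
                                    C = 1) {
  cv <- match.arg(cv)
  X <- as.matrix(features)
  y01 <- as_malignant01(labels)
  if (length(unique(y01)) < 2L) stopf("both classes must be present")
  if (length(ratios) == 0L) stopf("ratio grid is empty")
  aucs <- numeric(length(ratios))
  all_scores <- vector("list", length(ratios))
  for (i in seq_along(ratios)) {
    sc <- svm_cv_scores(X, y01, ratios[i], cv, seed, C)
    all_scores[[i]] <- sc
    aucs[i] <- roc_auc(sc, y01)$auc
  }
  best <- which.max(aucs)   # which.max takes the first maximum = smaller ratio
  st <- svm_standardize(X)
  wts <- ifelse(y01 == 1, 1, ratios[best])
  fit <- svm_fit_core(st$X, ifelse(y01 == 1, 1, -1), wts, C)
  model <- structure(list(w = fit$w, b = fit$b, scaler = st[c("mu", "s")],
                          ratio = ratios[best], C = C,
                          feature_names = colnames(X),
                          positive_class = "malignant"),
                     class = "svm_model")
  grid <- structure(list(ratios = ratios, auc_per_ratio = aucs,
                         best_ratio = ratios[best],
                         cv_scores = all_scores[[best]]),
                    class = "cost_grid_result")
  list(model = model, grid = grid)
}

as_malignant01 <- function(labels) {
  if (is.numeric(labels)) return(as.integer(labels != 0))
  as.integer(tolower(as.character(labels)) == "malignant")
}

#' Score and label a lesion with a trained SVM
#'
#' Signed decision score; label is malignant iff the score is positive
#' (malignant = positive class).
#'
#' @param model an `svm_model`.
#' @param features feature vector or matrix matching the model layout, or a
#'   [lesion_record] with `encoded` (default `node_stats` features).
#' @param mode feature mode used when `features` is a lesion record.
#' @return list with `score` and `label` (vectors for matrix input).
#' @export
classify_lesion <- function(model, features, mode = "node_stats") {
  if (inherits(features, "lesion_record"))
    features <- build_feature_vector(features, mode)
  X <- if (is.null(dim(features))) matrix(features, nrow = 1) else as.matrix(features)
  if (ncol(X) != length(model$w))
    stopf("feature layout mismatch: model expects %d features, got %d",
          length(model$w), ncol(X))
  Xs <- sweep(sweep(X, 2, model$scaler$mu), 2, model$scaler$s, `/`)
  score <- as.vector(Xs %*% model$w + model$b)
  list(score = score, label = ifelse(score > 0, "malignant", "benign"))
}

#' Serialize / load an SVM model as JSON
#' @param model an `svm_model`.
#' @param path JSON path.
#' @export
write_svm_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_svm_model
#' @export
read_svm_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(w = as.numeric(j$w), b = as.numeric(j$b),
                 scaler = list(mu = as.numeric(j$scaler$mu),
                               s = as.numeric(j$scaler$s)),
                 ratio = j$ratio, C = j$C,
                 feature_names = j$feature_names,
                 positive_class = j$positive_class),
            class = "svm_model")
}
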
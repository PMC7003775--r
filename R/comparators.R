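#' Rectified linear activation
#'
#' `f(x) = 0` for `x < 0`, `x` otherwise; the transfer function of the CNN
#' comparator's convolutional layers.
#'
#' @param x numeric vector/array.
#' @return elementwise max(x, 0).
#' @export
relu <- function(x) pmax(x, 0)

#' Supervised multilayer perceptron with the SSAE's architecture
#'
#' Identical layer dimensions to the segmentation stack (five hidden layers
#' of ten saturating-linear nodes plus a softmax head) but trained entirely
#' supervised from random initialization — no unsupervised pretraining. Used
#' to isolate the value of pretraining.
#'
#' @param set labeled `signature_set` with all four classes.
#' @param cfg an [ssae_config]; `max_epochs` drives the supervised training.
#' @return an [ssae_model] (usable with [segment_study]).
#' @export
train_mlp <- function(set, cfg = ssae_config()) {
  X <- set$signatures
  d_in <- ncol(X)
  dims <- c(d_in, rep(cfg$d_hidden, cfg$n_layers))
  seeds <- derive_seeds(cfg$seed, cfg$n_layers + 1L)
  layers <- lapply(seq_len(cfg$n_layers), function(k) {
    with_seed(seeds[k], structure(
      list(W_enc = t(init_weights(dims[k], dims[k + 1])),
           b_enc = rep(0.25, dims[k + 1]),
           W_dec = NULL, b_dec = NULL,
           activation = "satlin", decoder_activation = "linear"),
      class = "sae_layer"))
  })
  head <- list(W = with_seed(seeds[cfg$n_layers + 1L],
                             init_weights(cfg$d_hidden, 4L)),
               b = rep(0, 4L), classes = 0:3)
  model <- ssae_model(layers, head)
  tcfg <- cfg
  tcfg$fine_tune <- TRUE
  tcfg$fine_tune_epochs <- cfg$max_epochs
  fine_tune(model, X, set$labels, tcfg)
}

reflect_index <- function(idx, n) {
  # mirror reflection about the edges, excluding the edge sample itself
  if (n == 1L) return(rep(1L, length(idx)))
  idx <- ifelse(idx < 1L, 2L - idx, idx)
  idx <- ifelse(idx > n, 2L * n - idx, idx)
  pmin(pmax(idx, 1L), n)
}

#' Extract in-slice signature patches
#'
#' For each voxel, the 5 x 5 in-slice neighbourhood across all channels
#' (a 5 x 5 x D patch); borders use reflect padding. The patch centre equals
#' the voxel's signature.
#'
#' @param study an [mp_study].
#' @param voxels n x 3 integer matrix of voxel indices (1-based).
#' @param labels optional n class labels carried along.
#' @param size odd patch side length (default 5).
#' @return object of class `patch_set`: `patches` (n, size, size, D array),
#'   `labels`, `center_index`.
#' @export
extract_patches <- function(study, voxels, labels = NULL, size = 5L) {
  voxels <- matrix(as.integer(voxels), ncol = 3)
  if (nrow(voxels) == 0L) stopf("empty voxel list")
  shp <- study_dim(study)
  if (any(voxels < 1L) || any(voxels[, 1] > shp[1]) ||
      any(voxels[, 2] > shp[2]) || any(voxels[, 3] > shp[3]))
    stopf("voxel indices outside the grid")
  D <- study_D(study)
  half <- (size - 1L) %/% 2L
  n <- nrow(voxels)
  patches <- array(0, c(n, size, size, D))
  offs <- (-half):half
  for (i in seq_len(n)) {
    xs <- reflect_index(voxels[i, 1] + offs, shp[1])
    ys <- reflect_index(voxels[i, 2] + offs, shp[2])
    z <- voxels[i, 3]
    for (d in seq_len(D))
      patches[i, , , d] <- study$channels[[d]][xs, ys, z]
  }
  structure(list(patches = patches, labels = labels, center_index = voxels),
            class = "patch_set")
}

# ---- minimal 2-D CNN (same-padding 3x3 conv, ReLU, 2x2 max pool) ----------

# Deterministic full-batch Adam; used for the CNN, whose loss surface makes
# plain steepest descent impractically slow. Aborts on divergence.
adam_minimize <- function(params, fn, epochs, lr = 0.02, b1 = 0.9,
                          b2 = 0.999, eps = 1e-8) {
  m <- lapply(params, function(p) p * 0)
  v <- lapply(params, function(p) p * 0)
  ev <- fn(params)
  loss0 <- ev$loss
  best <- list(params = params, loss = ev$loss)
  for (t in seq_len(epochs)) {
    g <- ev$grad
    for (nm in names(params)) {
      m[[nm]] <- b1 * m[[nm]] + (1 - b1) * g[[nm]]
      v[[nm]] <- b2 * v[[nm]] + (1 - b2) * g[[nm]]^2
      mh <- m[[nm]] / (1 - b1^t)
      vh <- v[[nm]] / (1 - b2^t)
      params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
    }
    ev <- fn(params)
    if (!is.finite(ev$loss)) stopf("training diverged at epoch %d", t)
    if (ev$loss < best$loss) best <- list(params = params, loss = ev$loss)
  }
  list(params = best$params, loss = best$loss, loss0 = loss0)
}

conv2d_forward <- function(A, W, b) {
  d <- dim(A); N <- d[1]; H <- d[2]; Wd <- d[3]; cin <- d[4]
  cout <- dim(W)[4]
  Ap <- array(0, c(N, H + 2L, Wd + 2L, cin))
  Ap[, 2:(H + 1), 2:(Wd + 1), ] <- A
  out <- matrix(rep(b, each = N * H * Wd), N * H * Wd, cout)
  for (di in 1:3) for (dj in 1:3) {
    S <- Ap[, di:(di + H - 1), dj:(dj + Wd - 1), , drop = FALSE]
    dim(S) <- c(N * H * Wd, cin)
    out <- out + S %*% matrix(W[di, dj, , ], cin, cout)
  }
  array(out, c(N, H, Wd, cout))
}

conv2d_backward <- function(A, W, dOut) {
  d <- dim(A); N <- d[1]; H <- d[2]; Wd <- d[3]; cin <- d[4]
  cout <- dim(W)[4]
  Ap <- array(0, c(N, H + 2L, Wd + 2L, cin))
  Ap[, 2:(H + 1), 2:(Wd + 1), ] <- A
  dAp <- array(0, c(N, H + 2L, Wd + 2L, cin))
  dO <- dOut; dim(dO) <- c(N * H * Wd, cout)
  gW <- array(0, dim(W))
  for (di in 1:3) for (dj in 1:3) {
    S <- Ap[, di:(di + H - 1), dj:(dj + Wd - 1), , drop = FALSE]
    dim(S) <- c(N * H * Wd, cin)
    Wk <- matrix(W[di, dj, , ], cin, cout)
    gW[di, dj, , ] <- crossprod(S, dO)
    dS <- dO %*% t(Wk)
    dim(dS) <- c(N, H, Wd, cin)
    dAp[, di:(di + H - 1), dj:(dj + Wd - 1), ] <-
      dAp[, di:(di + H - 1), dj:(dj + Wd - 1), , drop = FALSE] + dS
  }
  list(gW = gW, gb = colSums(dO),
       dA = dAp[, 2:(H + 1), 2:(Wd + 1), , drop = FALSE])
}

maxpool_forward <- function(A) {
  d <- dim(A); N <- d[1]; H2 <- d[2] %/% 2L; W2 <- d[3] %/% 2L; C <- d[4]
  s <- function(oi, oj) A[, seq_len(H2) * 2L - 2L + oi,
                          seq_len(W2) * 2L - 2L + oj, , drop = FALSE]
  s11 <- s(1, 1); s21 <- s(2, 1); s12 <- s(1, 2); s22 <- s(2, 2)
  out <- pmax(s11, s21, s12, s22)
  dim(out) <- c(N, H2, W2, C)
  list(out = out, slices = list(s11, s21, s12, s22))
}

maxpool_backward <- function(pool, dOut, in_dim) {
  d <- dim(dOut); H2 <- d[2]; W2 <- d[3]
  dA <- array(0, in_dim)
  taken <- array(FALSE, d)
  offs <- list(c(1, 1), c(2, 1), c(1, 2), c(2, 2))
  for (k in 1:4) {
    hit <- (pool$slices[[k]] == pool$out) & !taken
    taken <- taken | hit
    oi <- offs[[k]][1]; oj <- offs[[k]][2]
    dA[, seq_len(H2) * 2L - 2L + oi, seq_len(W2) * 2L - 2L + oj, ] <-
      dOut * hit
  }
  dA
}

cnn_init <- function(cin, filters = c(128L, 64L, 32L, 16L), n_classes = 4L,
                     seed = 1L) {
  with_seed(seed, {
    convs <- list()
    c_prev <- cin
    for (k in seq_along(filters)) {
      lim <- sqrt(6 / (9 * c_prev + filters[k]))
      convs[[k]] <- list(W = array(runif(9 * c_prev * filters[k], -lim, lim),
                                   c(3, 3, c_prev, filters[k])),
                         b = rep(0, filters[k]))
      c_prev <- filters[k]
    }
    lim <- sqrt(6 / (c_prev + n_classes))
    list(convs = convs,
         fc = list(W = matrix(runif(c_prev * n_classes, -lim, lim),
                              c_prev, n_classes),
                   b = rep(0, n_classes)),
         filters = filters, classes = 0:(n_classes - 1L))
  })
}

cnn_forward <- function(net, P, keep = FALSE) {
  A <- P
  cache <- list()
  for (k in seq_along(net$convs)) {
    Z <- conv2d_forward(A, net$convs[[k]]$W, net$convs[[k]]$b)
    R <- relu(Z)
    pooled <- NULL
    if (dim(R)[2] >= 2L && dim(R)[3] >= 2L) {
      pooled <- maxpool_forward(R)
      Anew <- pooled$out
    } else Anew <- R
    if (keep) cache[[k]] <- list(A = A, Z = Z, R = R, pool = pooled)
    A <- Anew
  }
  feat <- A
  dim(feat) <- c(dim(A)[1], prod(dim(A)[-1]))
  probs <- softmax_probs(sweep(feat %*% net$fc$W, 2, net$fc$b, `+`))
  list(probs = probs, feat = feat, cache = cache, feat_dim = dim(A))
}

#' Number of trainable parameters of the CNN comparator
#' @param cin input channel count D.
#' @param filters convolutional filter counts.
#' @param n_classes output classes.
#' @return integer parameter count (conv stack + fully connected head).
#' @export
cnn_param_count <- function(cin, filters = c(128L, 64L, 32L, 16L),
                            n_classes = 4L) {
  total <- 0L
  c_prev <- cin
  for (f in filters) {
    total <- total + (3L * 3L * c_prev + 1L) * f
    c_prev <- f
  }
  total + (c_prev + 1L) * n_classes
}

#' Train the patch-based 2-D CNN comparator
#'
#' Four convolutional layers of 128, 64, 32 and 16 trainable 3 x 3 filters
#' (same padding), each followed by ReLU and — while the spatial extent is at
#' least 2 — a 2 x 2 max-pooling (with 5 x 5 inputs only the first two layers
#' can pool; pooling is skipped afterwards), then a fully connected layer and
#' softmax. Full-batch gradient descent with momentum, deterministic given
#' the seed.
#'
#' @param patches a `patch_set` with labels for all four classes.
#' @param cfg an [ssae_config] (learning rate, momentum, L2, seed).
#' @param epochs training epochs (default `cfg$max_epochs`).
#' @param filters filter counts per layer.
#' @return object of class `cnn_model`.
#' @export
train_cnn <- function(patches, cfg = ssae_config(), epochs = cfg$max_epochs,
                      filters = c(128L, 64L, 32L, 16L)) {
  P <- patches$patches
  labels <- patches$labels
  if (is.null(labels)) stopf("patch set has no labels")
  if (length(setdiff(0:3, unique(labels))) > 0L)
    stopf("all four classes must be present")
  N <- dim(P)[1]
  net0 <- cnn_init(dim(P)[4], filters, 4L, cfg$seed)
  Y <- matrix(0, N, 4L)
  Y[cbind(seq_len(N), match(labels, net0$classes))] <- 1
  l2 <- cfg$l2_penalty
  nl <- length(net0$convs)
  pack <- function(net) {
    p <- list()
    for (k in seq_len(nl)) {
      p[[paste0("cW", k)]] <- net$convs[[k]]$W
      p[[paste0("cb", k)]] <- net$convs[[k]]$b
    }
    p$fW <- net$fc$W; p$fb <- net$fc$b
    p
  }
  unpack <- function(p) {
    net <- net0
    for (k in seq_len(nl)) {
      net$convs[[k]]$W <- p[[paste0("cW", k)]]
      net$convs[[k]]$b <- p[[paste0("cb", k)]]
    }
    net$fc$W <- p$fW; net$fc$b <- p$fb
    net
  }
  fn <- function(p) {
    net <- unpack(p)
    fw <- cnn_forward(net, P, keep = TRUE)
    l2term <- sum(vapply(net$convs, function(cv) sum(cv$W^2), numeric(1))) +
      sum(net$fc$W^2)
    loss <- -sum(Y * log(pmax(fw$probs, 1e-12))) / N + l2 * l2term
    dZfc <- (fw$probs - Y) / N
    grad <- list(fW = crossprod(fw$feat, dZfc) + 2 * l2 * net$fc$W,
                 fb = colSums(dZfc))
    dA <- array(dZfc %*% t(net$fc$W), fw$feat_dim)
    for (k in rev(seq_len(nl))) {
      cc <- fw$cache[[k]]
      dR <- if (!is.null(cc$pool))
        maxpool_backward(cc$pool, dA, dim(cc$R)) else dA
      dZ <- dR * (cc$Z > 0)
      bk <- conv2d_backward(cc$A, net$convs[[k]]$W, dZ)
      grad[[paste0("cW", k)]] <- bk$gW + 2 * l2 * net$convs[[k]]$W
      grad[[paste0("cb", k)]] <- bk$gb
      dA <- bk$dA
    }
    list(loss = loss, grad = grad)
  }
  fit <- adam_minimize(pack(net0), fn, epochs, lr = 0.02)
  net <- unpack(fit$params)
  structure(c(net, list(n_params = cnn_param_count(dim(P)[4], filters),
                        loss_initial = fit$loss0, loss_final = fit$loss)),
            class = "cnn_model")
}

#' Predict tissue classes for patches with a trained CNN
#' @param net a `cnn_model`.
#' @param patches a `patch_set` (labels ignored).
#' @param chunk voxels per forward chunk (memory bound).
#' @return integer class labels.
#' @export
predict_cnn <- function(net, patches, chunk = 2048L) {
  P <- patches$patches
  N <- dim(P)[1]
  out <- integer(N)
  for (start in seq(1L, N, by = chunk)) {
    idx <- start:min(start + chunk - 1L, N)
    probs <- cnn_forward(net, P[idx, , , , drop = FALSE])$probs
    out[idx] <- net$classes[max.col(probs, ties.method = "first")]
  }
  out
}

segment_study_cnn <- function(net, study, chunk = 2048L) {
  shp <- study_dim(study)
  vox <- arrayInd(seq_len(prod(shp)), shp)
  cls <- integer(nrow(vox))
  for (start in seq(1L, nrow(vox), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(vox))
    ps <- extract_patches(study, vox[idx, , drop = FALSE])
    cls[idx] <- predict_cnn(net, ps, chunk)
  }
  label_map(array(cls, shp))
}

#' Compare SSAE, MLP and CNN segmentation on a phantom subset
#'
#' Trains the three architectures on identical twofold splits of a randomly
#' selected subset (default 20 phantoms, balanced benign/malignant when
#' available) and reports mean and SD lesion Dice against phantom truth per
#' architecture, plus trainable parameter counts.
#'
#' @param cohort list of `phantom_study`.
#' @param cfg an [ssae_config].
#' @param seed subset/split seed.
#' @param n_subset subset size.
#' @param cap_per_class balanced-sampling cap.
#' @param cnn_epochs CNN training epochs.
#' @return data frame with one row per architecture: `architecture`,
#'   `mean_dice`, `sd_dice`, `n_params`.
#' @export
compare_architectures <- function(cohort, cfg = ssae_config(), seed = 1L,
                                  n_subset = min(20L, length(cohort)),
                                  cap_per_class = 1000L,
                                  cnn_epochs = max(50L, cfg$max_epochs %/% 4L)) {
  phenos <- vapply(cohort, `[[`, character(1), "lesion_phenotype")
  sel <- with_seed(seed, {
    ben <- which(phenos == "benign"); mal <- which(phenos == "malignant")
    k <- n_subset %/% 2L
    if (length(ben) >= k && length(mal) >= n_subset - k)
      sort(c(resample(ben, k), resample(mal, n_subset - k)))
    else sort(resample(seq_along(cohort), n_subset))
  })
  sub <- cohort[sel]
  n <- length(sub)
  bounds <- compute_channel_bounds(lapply(sub, `[[`, "study"))
  norm_studies <- lapply(sub, function(ph)
    normalize_channels(ph$study, bounds = bounds))
  harvested <- lapply(seq_len(n), function(i)
    harvest_signatures(norm_studies[[i]],
                       auto_seeds(sub[[i]]$truth, 3L, seed = seed + i)))
  folds <- stratified_halves(vapply(sub, `[[`, character(1),
                                    "lesion_phenotype"), seed + 1L)
  dices <- list(ssae = numeric(0), mlp = numeric(0), cnn = numeric(0))
  mlp_params <- NA_integer_
  cnn_params <- NA_integer_
  for (f in 1:2) {
    tr <- folds[[f]]; te <- folds[[3 - f]]
    train_set <- sample_balanced(harvested[tr], cap_per_class,
                                 seed = seed + 10 + f)
    m_ssae <- train_ssae(train_set, cfg)
    m_mlp <- train_mlp(train_set, cfg)
    # patches at the sampled signature voxels of the training subjects
    idx_by_subj <- split(seq_len(nrow(train_set$provenance)),
                         train_set$provenance$subject_id)
    plist <- list()
    for (sid in names(idx_by_subj)) {
      i <- which(vapply(sub, function(p) p$study$subject_id, character(1)) == sid)
      rows <- idx_by_subj[[sid]]
      ps <- extract_patches(norm_studies[[i]],
                            as.matrix(train_set$provenance[rows, c("x", "y", "z")]),
                            labels = train_set$labels[rows])
      plist[[sid]] <- ps
    }
    all_patches <- structure(list(
      patches = do.call(abind_first, lapply(plist, `[[`, "patches")),
      labels = unlist(lapply(plist, `[[`, "labels")),
      center_index = do.call(rbind, lapply(plist, `[[`, "center_index"))),
      class = "patch_set")
    m_cnn <- train_cnn(all_patches, cfg, epochs = cnn_epochs)
    mlp_params <- sum(vapply(m_mlp$layers, function(l)
      length(l$W_enc) + length(l$b_enc), numeric(1))) +
      length(m_mlp$softmax$W) + length(m_mlp$softmax$b)
    cnn_params <- m_cnn$n_params
    for (i in te) {
      truth_mask <- sub[[i]]$truth$labels == 3L
      dices$ssae <- c(dices$ssae,
                      dice(segment_study(m_ssae, norm_studies[[i]])$labels == 3L,
                           truth_mask))
      dices$mlp <- c(dices$mlp,
                     dice(segment_study(m_mlp, norm_studies[[i]])$labels == 3L,
                          truth_mask))
      dices$cnn <- c(dices$cnn,
                     dice(segment_study_cnn(m_cnn, norm_studies[[i]])$labels == 3L,
                          truth_mask))
    }
  }
  data.frame(architecture = c("SSAE", "MLP", "2D-CNN"),
             mean_dice = c(mean(dices$ssae), mean(dices$mlp), mean(dices$cnn)),
             sd_dice = c(sd(dices$ssae), sd(dices$mlp), sd(dices$cnn)),
             n_params = c(mlp_params, mlp_params, cnn_params),
             stringsAsFactors = FALSE)
}

# rbind-like concatenation of 4-D arrays along the first axis
abind_first <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  n <- sum(vapply(arrs, function(a) dim(a)[1], numeric(1)))
  out <- array(0, c(n, d[-1]))
  at <- 0L
  for (a in arrs) {
    na <- dim(a)[1]
    out[at + seq_len(na), , , ] <- a
    at <- at + na
  }
  out
}
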
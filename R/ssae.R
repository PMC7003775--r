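#' Saturating linear activation
#'
#' `f(x) = 0` for `x <= 0`, `x` for `0 < x < 1`, `1` for `x >= 1`; applied
#' elementwise. This is the transfer function of the segmentation
#' autoencoder's hidden nodes, so encodings always lie in \[0, 1\].
#'
#' @param x numeric vector/array.
#' @return values clipped to \[0, 1\].
#' @export
satlin <- function(x) pmin(pmax(x, 0), 1)

satlin_grad <- function(z) (z > 0 & z < 1) * 1

sigmoid <- function(x) 1 / (1 + exp(-x))

#' KL-divergence sparsity penalty
#'
#' `sum_j [rho * ln(rho / rho_hat_j) + (1 - rho) * ln((1 - rho) / (1 - rho_hat_j))]`
#' over hidden nodes, where `rho_hat_j` is the mean activation of node `j`
#' and `rho` the target sparsity proportion. Zero iff every `rho_hat_j`
#' equals `rho`, strictly positive otherwise.
#'
#' @param rho_hat vector of mean activations (clipped into `(eps, 1 - eps)`).
#' @param rho target sparsity proportion in (0, 1).
#' @param eps clipping bound.
#' @return non-negative scalar.
#' @export
kl_sparsity <- function(rho_hat, rho, eps = 1e-8) {
  r <- pmin(pmax(rho_hat, eps), 1 - eps)
  sum(rho * log(rho / r) + (1 - rho) * log((1 - rho) / (1 - r)))
}

kl_sparsity_grad <- function(rho_hat, rho, eps = 1e-8) {
  r <- pmin(pmax(rho_hat, eps), 1 - eps)
  -rho / r + (1 - rho) / (1 - r)
}

#' Training configuration for the sparse-autoencoder stack
#'
#' Defaults are the reported segmentation-network hyperparameters: L2
#' regularization penalty 0.001, sparsity proportion 0.25, sparsity
#' regularization weight 4, five layers of ten nodes. The optimizer is
#' deterministic full-batch gradient descent with momentum; learning rate and
#' epoch counts are implementation defaults (the original optimizer is
#' unspecified) and are echoed in pipeline logs.
#'
#' @param l2_penalty L2 weight penalty.
#' @param sparsity_proportion target mean activation rho.
#' @param sparsity_weight KL penalty weight beta.
#' @param max_epochs pretraining epochs per layer (also softmax epochs).
#' @param fine_tune_epochs supervised fine-tuning epochs.
#' @param learning_rate gradient-descent step size.
#' @param momentum heavy-ball momentum coefficient.
#' @param n_layers,d_hidden stack depth and hidden width.
#' @param seed RNG seed for weight initialization.
#' @param fine_tune run supervised fine-tuning after pretraining.
#' @return list of class `ssae_config`.
#' @export
ssae_config <- function(l2_penalty = 0.001, sparsity_proportion = 0.25,
                        sparsity_weight = 4, max_epochs = 400,
                        fine_tune_epochs = 200, learning_rate = 0.1,
                        momentum = 0.9, n_layers = 5L, d_hidden = 10L,
                        seed = 1L, fine_tune = TRUE) {
  if (sparsity_proportion <= 0 || sparsity_proportion >= 1)
    stopf("sparsity_proportion must be in (0, 1)")
  if (l2_penalty < 0 || sparsity_weight < 0) stopf("penalties must be >= 0")
  structure(list(l2_penalty = l2_penalty,
                 sparsity_proportion = sparsity_proportion,
                 sparsity_weight = sparsity_weight,
                 max_epochs = as.integer(max_epochs),
                 fine_tune_epochs = as.integer(fine_tune_epochs),
                 learning_rate = learning_rate, momentum = momentum,
                 n_layers = as.integer(n_layers),
                 d_hidden = as.integer(d_hidden),
                 seed = as.integer(seed), fine_tune = fine_tune),
            class = "ssae_config")
}

# Loss and analytic gradient of one sparse-autoencoder layer.
# params: list(W1 d_in x d_out, b1, W2 d_out x d_in, b2)
# Exposed internally for the finite-difference gradient tests.
sae_loss_grad <- function(params, X, cfg, activation = "satlin",
                          want_grad = TRUE) {
  N <- nrow(X)
  act <- if (activation == "satlin") satlin else sigmoid
  Z1 <- sweep(X %*% params$W1, 2, params$b1, `+`)
  H <- act(Z1)
  Xhat <- sweep(H %*% params$W2, 2, params$b2, `+`)
  R <- Xhat - X
  rho <- cfg$sparsity_proportion
  rho_hat <- colMeans(H)
  loss <- sum(R^2) / N +
    cfg$l2_penalty * (sum(params$W1^2) + sum(params$W2^2)) +
    cfg$sparsity_weight * kl_sparsity(rho_hat, rho)
  if (!want_grad) return(list(loss = loss))
  dXhat <- 2 * R / N
  gW2 <- crossprod(H, dXhat) + 2 * cfg$l2_penalty * params$W2
  gb2 <- colSums(dXhat)
  dH <- dXhat %*% t(params$W2)
  dH <- sweep(dH, 2, cfg$sparsity_weight *
                kl_sparsity_grad(rho_hat, rho) / N, `+`)
  dZ1 <- dH * (if (activation == "satlin") satlin_grad(Z1) else H * (1 - H))
  gW1 <- crossprod(X, dZ1) + 2 * cfg$l2_penalty * params$W1
  gb1 <- colSums(dZ1)
  list(loss = loss, grad = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2))
}

init_weights <- function(d_in, d_out) {
  lim <- sqrt(6 / (d_in + d_out))
  matrix(runif(d_in * d_out, -lim, lim), d_in, d_out)
}

# Deterministic full-batch gradient descent with backtracking line search:
# a step that does not decrease the loss is halved (up to max_halve times);
# accepted steps grow the rate slightly. Monotone by construction, which the
# layer/ head training contracts require (final loss <= initial loss).
gd_minimize <- function(params, fn, epochs, lr = 0.1, grow = 1.1,
                        shrink = 0.5, max_halve = 30L) {
  ev <- fn(params)
  loss0 <- ev$loss
  if (!is.finite(loss0)) stopf("non-finite loss at initialization")
  for (ep in seq_len(epochs)) {
    halved <- 0L
    repeat {
      trial <- params
      for (nm in names(params))
        trial[[nm]] <- params[[nm]] - lr * ev$grad[[nm]]
      ev2 <- fn(trial)
      if (is.finite(ev2$loss) && ev2$loss <= ev$loss) break
      lr <- lr * shrink
      halved <- halved + 1L
      if (halved > max_halve)
        return(list(params = params, loss = ev$loss, loss0 = loss0))
    }
    params <- trial
    ev <- ev2
    lr <- lr * grow
  }
  list(params = params, loss = ev$loss, loss0 = loss0)
}

#' Train one sparse-autoencoder layer
#'
#' Minimizes mean squared reconstruction error plus the L2 weight penalty and
#' the KL sparsity penalty on mean hidden activations, by deterministic
#' full-batch gradient descent with momentum. Encoder activation is
#' saturating-linear (segmentation stack) or sigmoid (lesion encoder);
#' the decoder is linear.
#'
#' @param X N x d_in matrix with values in \[0, 1\] (N >= d_out).
#' @param d_out hidden width.
#' @param cfg an [ssae_config].
#' @param activation `"satlin"` or `"sigmoid"`.
#' @return object of class `sae_layer` with encoder/decoder weights, the
#'   activation names and the initial/final loss.
#' @export
train_sae_layer <- function(X, d_out = cfg$d_hidden, cfg = ssae_config(),
                            activation = c("satlin", "sigmoid")) {
  activation <- match.arg(activation)
  X <- as.matrix(X)
  if (nrow(X) < d_out)
    stopf("need at least d_out = %d training rows (got %d)", d_out, nrow(X))
  d_in <- ncol(X)
  params <- with_seed(cfg$seed, list(
    W1 = init_weights(d_in, d_out),
    b1 = rep(if (activation == "satlin") 0.25 else 0, d_out),
    W2 = init_weights(d_out, d_in),
    b2 = colMeans(X)))
  fit <- gd_minimize(params,
                     function(p) sae_loss_grad(p, X, cfg, activation),
                     cfg$max_epochs, lr = cfg$learning_rate)
  structure(list(W_enc = t(fit$params$W1), b_enc = fit$params$b1,
                 W_dec = t(fit$params$W2), b_dec = fit$params$b2,
                 activation = activation, decoder_activation = "linear",
                 loss_initial = fit$loss0, loss_final = fit$loss),
            class = "sae_layer")
}

#' Encode / reconstruct with a trained SAE layer
#' @param layer a `sae_layer`.
#' @param X N x d_in matrix.
#' @return `sae_encode`: N x d_out activations; `sae_reconstruct`: N x d_in.
#' @export
sae_encode <- function(layer, X) {
  Z <- sweep(as.matrix(X) %*% t(layer$W_enc), 2, layer$b_enc, `+`)
  if (layer$activation == "satlin") satlin(Z) else sigmoid(Z)
}

#' @rdname sae_encode
#' @export
sae_reconstruct <- function(layer, X) {
  sweep(sae_encode(layer, X) %*% t(layer$W_dec), 2, layer$b_dec, `+`)
}

#' Greedy layer-wise pretraining of the autoencoder stack
#'
#' Trains `cfg$n_layers` sparse autoencoders; each layer is trained on the
#' encodings produced by the layers before it. Layer seeds are derived
#' deterministically from `cfg$seed`.
#'
#' @param X N x D matrix (or `signature_set`) of training signatures.
#' @param cfg an [ssae_config].
#' @return list of `sae_layer`.
#' @export
pretrain_stack <- function(X, cfg = ssae_config()) {
  if (inherits(X, "signature_set")) X <- X$signatures
  X <- as.matrix(X)
  seeds <- derive_seeds(cfg$seed, cfg$n_layers)
  layers <- vector("list", cfg$n_layers)
  H <- X
  for (k in seq_len(cfg$n_layers)) {
    lcfg <- cfg
    lcfg$seed <- seeds[k]
    layers[[k]] <- train_sae_layer(H, cfg$d_hidden, lcfg, "satlin")
    H <- sae_encode(layers[[k]], H)
  }
  layers
}

encode_stack <- function(layers, X) {
  H <- as.matrix(X)
  for (l in layers) H <- sae_encode(l, H)
  H
}

softmax_probs <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Train the softmax classification head
#'
#' Multinomial logistic regression on the stack encodings by full-batch
#' gradient descent on cross-entropy plus an L2 penalty. All four tissue
#' classes must be present.
#'
#' @param encoded N x d matrix of stack encodings.
#' @param labels N integer class labels.
#' @param cfg an [ssae_config].
#' @param classes class codes the head must cover.
#' @return list with `W` (d x K), `b` (K), `classes`.
#' @export
train_softmax_head <- function(encoded, labels, cfg = ssae_config(),
                               classes = 0:3) {
  H <- as.matrix(encoded)
  miss <- setdiff(classes, unique(labels))
  if (length(miss) > 0)
    stopf("missing class(es) in training labels: %s",
          paste(miss, collapse = ", "))
  K <- length(classes)
  N <- nrow(H)
  Y <- matrix(0, N, K)
  Y[cbind(seq_len(N), match(labels, classes))] <- 1
  params <- with_seed(cfg$seed, list(W = init_weights(ncol(H), K),
                                     b = rep(0, K)))
  fn <- function(p) {
    P <- softmax_probs(sweep(H %*% p$W, 2, p$b, `+`))
    dZ <- (P - Y) / N
    list(loss = -sum(Y * log(pmax(P, 1e-12))) / N +
           cfg$l2_penalty * sum(p$W^2),
         grad = list(W = crossprod(H, dZ) + 2 * cfg$l2_penalty * p$W,
                     b = colSums(dZ)))
  }
  fit <- gd_minimize(params, fn, cfg$max_epochs, lr = cfg$learning_rate)
  list(W = fit$params$W, b = fit$params$b, classes = classes)
}

#' Assemble a stacked-sparse-autoencoder segmentation model
#' @param layers list of `sae_layer` from [pretrain_stack].
#' @param softmax head from [train_softmax_head].
#' @param channel_order channel layout the model was trained on; studies
#'   with a different layout are refused at segmentation time.
#' @param class_legend value -> class-name map.
#' @return object of class `ssae_model`.
#' @export
ssae_model <- function(layers, softmax, channel_order = NULL,
                       class_legend = c(`0` = "background", `1` = "fat",
                                        `2` = "glandular", `3` = "lesion")) {
  structure(list(layers = layers, softmax = softmax,
                 channel_order = channel_order, class_legend = class_legend),
            class = "ssae_model")
}

# class probabilities for an N x D signature matrix
ssae_predict <- function(model, X) {
  H <- encode_stack(model$layers, X)
  softmax_probs(sweep(H %*% model$softmax$W, 2, model$softmax$b, `+`))
}

#' Supervised fine-tuning of the full stack plus softmax head
#'
#' Joint full-batch gradient descent on cross-entropy through all encoder
#' layers and the head. If the final training loss exceeds the initial one
#' the pre-fine-tune model is returned with a warning.
#'
#' @param model an [ssae_model].
#' @param X N x D training signatures.
#' @param labels N integer class labels.
#' @param cfg an [ssae_config]; `cfg$fine_tune = FALSE` returns the model
#'   unchanged.
#' @return fine-tuned [ssae_model].
#' @export
fine_tune <- function(model, X, labels, cfg = ssae_config()) {
  if (!isTRUE(cfg$fine_tune)) return(model)
  X <- as.matrix(X)
  N <- nrow(X)
  classes <- model$softmax$classes
  K <- length(classes)
  Y <- matrix(0, N, K)
  Y[cbind(seq_len(N), match(labels, classes))] <- 1
  L <- length(model$layers)
  params <- list()
  for (k in seq_len(L)) {
    params[[paste0("W", k)]] <- t(model$layers[[k]]$W_enc)
    params[[paste0("b", k)]] <- model$layers[[k]]$b_enc
  }
  params$Ws <- model$softmax$W
  params$bs <- model$softmax$b
  fn <- function(p) {
    A <- vector("list", L + 1)
    Z <- vector("list", L)
    A[[1]] <- X
    for (k in seq_len(L)) {
      Z[[k]] <- sweep(A[[k]] %*% p[[paste0("W", k)]], 2,
                      p[[paste0("b", k)]], `+`)
      A[[k + 1]] <- satlin(Z[[k]])
    }
    P <- softmax_probs(sweep(A[[L + 1]] %*% p$Ws, 2, p$bs, `+`))
    l2 <- sum(vapply(seq_len(L), function(k)
      sum(p[[paste0("W", k)]]^2), numeric(1))) + sum(p$Ws^2)
    loss <- -sum(Y * log(pmax(P, 1e-12))) / N + cfg$l2_penalty * l2
    dZ <- (P - Y) / N
    grad <- list(Ws = crossprod(A[[L + 1]], dZ) + 2 * cfg$l2_penalty * p$Ws,
                 bs = colSums(dZ))
    dA <- dZ %*% t(p$Ws)
    for (k in rev(seq_len(L))) {
      dZk <- dA * satlin_grad(Z[[k]])
      grad[[paste0("W", k)]] <- crossprod(A[[k]], dZk) +
        2 * cfg$l2_penalty * p[[paste0("W", k)]]
      grad[[paste0("b", k)]] <- colSums(dZk)
      dA <- dZk %*% t(p[[paste0("W", k)]])
    }
    list(loss = loss, grad = grad)
  }
  fit <- gd_minimize(params, fn, cfg$fine_tune_epochs,
                     lr = cfg$learning_rate)
  if (!is.finite(fit$loss) || fit$loss > fit$loss0) {
    warnf("fine-tuning did not improve training loss (%.4g -> %.4g); reverting",
          fit$loss0, fit$loss)
    return(model)
  }
  tuned <- model
  for (k in seq_len(L)) {
    tuned$layers[[k]]$W_enc <- t(fit$params[[paste0("W", k)]])
    tuned$layers[[k]]$b_enc <- fit$params[[paste0("b", k)]]
  }
  tuned$softmax$W <- fit$params$Ws
  tuned$softmax$b <- fit$params$bs
  tuned
}

#' Train the full segmentation model on a labeled signature set
#'
#' Greedy pretraining, softmax head, then (by default) supervised
#' fine-tuning. Convenience wrapper used by the pipeline.
#'
#' @param set class-balanced `signature_set`.
#' @param cfg an [ssae_config].
#' @param channel_order layout stamp stored in the model.
#' @return an [ssae_model].
#' @export
train_ssae <- function(set, cfg = ssae_config(), channel_order = NULL) {
  layers <- pretrain_stack(set$signatures, cfg)
  H <- encode_stack(layers, set$signatures)
  head <- train_softmax_head(H, set$labels, cfg)
  model <- ssae_model(layers, head, channel_order = channel_order)
  fine_tune(model, set$signatures, set$labels, cfg)
}

#' Voxelwise segmentation of a study
#'
#' Assigns every voxel the argmax class probability from the model; ties
#' break toward the lower class id. The study must be normalized and have
#' the model's channel layout.
#'
#' @param model an [ssae_model].
#' @param study a normalized [mp_study].
#' @return a [label_map] with legend background/fat/glandular/lesion.
#' @export
segment_study <- function(model, study) {
  D <- ncol(model$layers[[1]]$W_enc) # W_enc is d_out x d_in
  if (study_D(study) != D)
    stopf("study has D = %d channels but model expects %d", study_D(study), D)
  if (!is.null(model$channel_order) &&
      !identical(model$channel_order, study$channel_order))
    stopf("study channel order does not match the model's training layout")
  P <- ssae_predict(model, study_matrix(study))
  cls <- model$softmax$classes[max.col(P, ties.method = "first")]
  label_map(array(cls, study_dim(study)), legend = model$class_legend)
}

#' Serialize / load an SSAE model as JSON
#' @param model an [ssae_model].
#' @param path JSON path.
#' @export
write_ssae_model <- function(model, path) {
  enc_layer <- function(l) list(W_enc = l$W_enc, b_enc = l$b_enc,
                                W_dec = l$W_dec, b_dec = l$b_dec,
                                activation = l$activation,
                                decoder_activation = l$decoder_activation)
  jsonlite::write_json(list(layers = lapply(model$layers, enc_layer),
                            softmax = list(W = model$softmax$W,
                                           b = model$softmax$b,
                                           classes = model$softmax$classes),
                            channel_order = model$channel_order,
                            class_legend = as.list(model$class_legend)),
                       path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_ssae_model
#' @export
read_ssae_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  layers <- lapply(seq_len(if (is.data.frame(j$layers)) nrow(j$layers)
                           else length(j$layers)), function(k) {
    l <- if (is.data.frame(j$layers)) lapply(j$layers, `[[`, k) else j$layers[[k]]
    structure(list(W_enc = as.matrix(l$W_enc), b_enc = as.numeric(l$b_enc),
                   W_dec = as.matrix(l$W_dec), b_dec = as.numeric(l$b_dec),
                   activation = l$activation,
                   decoder_activation = l$decoder_activation),
              class = "sae_layer")
  })
  ssae_model(layers,
             list(W = as.matrix(j$softmax$W), b = as.numeric(j$softmax$b),
                  classes = as.integer(j$softmax$classes)),
             channel_order = as.character(j$channel_order),
             class_legend = unlist(j$class_legend))
}
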
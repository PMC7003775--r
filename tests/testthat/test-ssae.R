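test_that("satlin branch table and vectorization", {
  expect_equal(satlin(-0.5), 0)
  expect_equal(satlin(0.3), 0.3)
  expect_equal(satlin(1.7), 1)
  expect_equal(satlin(c(-1, 0, 0.5, 1, 2)), c(0, 0, 0.5, 1, 1))
})

test_that("KL sparsity penalty: closed form, non-negativity, zero iff equal", {
  expect_equal(kl_sparsity(c(0.25, 0.25), 0.25), 0)
  expect_equal(kl_sparsity(0.5, 0.25),
               0.25 * log(0.25 / 0.5) + 0.75 * log(0.75 / 0.5),
               tolerance = 1e-12)
  expect_equal(kl_sparsity(0.5, 0.25), 0.1308, tolerance = 1e-4)
  set.seed(5)
  for (i in 1:20) {
    rh <- runif(6, 0.01, 0.99)
    v <- kl_sparsity(rh, 0.25)
    expect_gte(v, 0)
    if (max(abs(rh - 0.25)) > 1e-6) expect_gt(v, 0)
  }
})

test_that("analytic layer gradients match central finite differences", {
  set.seed(8)
  cfg <- ssae_config(seed = 1)
  X <- matrix(runif(8 * 4), 8, 4)
  for (act in c("satlin", "sigmoid")) {
    params <- list(W1 = matrix(rnorm(4 * 3, sd = 0.4), 4, 3),
                   b1 = rnorm(3, 0.3, 0.1),
                   W2 = matrix(rnorm(3 * 4, sd = 0.4), 3, 4),
                   b2 = rnorm(4, 0.5, 0.1))
    an <- mpmriseg:::sae_loss_grad(params, X, cfg, act)
    h <- 1e-6
    for (nm in names(params)) {
      num <- params[[nm]]
      for (j in seq_along(num)) {
        pp <- params; pp[[nm]][j] <- pp[[nm]][j] + h
        pm <- params; pm[[nm]][j] <- pm[[nm]][j] - h
        num[j] <- (mpmriseg:::sae_loss_grad(pp, X, cfg, act,
                                            want_grad = FALSE)$loss -
                   mpmriseg:::sae_loss_grad(pm, X, cfg, act,
                                            want_grad = FALSE)$loss) / (2 * h)
      }
      denom <- pmax(abs(num), abs(an$grad[[nm]]), 1e-4)
      expect_lt(max(abs(num - an$grad[[nm]]) / denom), 1e-5)
    }
  }
})

test_that("layer training: degenerate reconstruction, descent, determinism", {
  v <- runif(6)
  X <- matrix(rep(v, each = 200), 200, 6)
  cfg <- ssae_config(sparsity_weight = 0, max_epochs = 200, seed = 4)
  lay <- train_sae_layer(X, 5, cfg)
  recon <- sae_reconstruct(lay, X)
  expect_lt(mean(rowSums((X - recon)^2)), 1e-3)
  expect_lte(lay$loss_final, lay$loss_initial)

  lay2 <- train_sae_layer(X, 5, cfg)
  expect_identical(lay$W_enc, lay2$W_enc)
  expect_identical(lay$b_dec, lay2$b_dec)
  expect_error(train_sae_layer(X[1:3, ], 5, cfg), "rows")
})

test_that("sparsity penalty pulls mean activations toward the target", {
  set.seed(9)
  X <- matrix(runif(300 * 6), 300, 6)
  cfg0 <- ssae_config(sparsity_weight = 0, max_epochs = 150, seed = 2)
  cfg4 <- ssae_config(sparsity_weight = 4, max_epochs = 150, seed = 2)
  rho0 <- colMeans(sae_encode(train_sae_layer(X, 8, cfg0), X))
  rho4 <- colMeans(sae_encode(train_sae_layer(X, 8, cfg4), X))
  expect_lt(mean(abs(rho4 - 0.25)), mean(abs(rho0 - 0.25)))
})

test_that("greedy stack: dimensions, satlin range, distinct encodings", {
  ph <- clean_phantom(seed = 3)
  ns <- normalize_channels(ph$study)
  hv <- harvest_signatures(ns, auto_seeds(ph$truth, 2, seed = 2))
  ts <- sample_balanced(hv, 80, seed = 1)
  cfg <- tiny_cfg(5)
  layers <- pretrain_stack(ts$signatures, cfg)
  expect_length(layers, 5)
  dims_in <- vapply(layers, function(l) ncol(l$W_enc), numeric(1))
  expect_equal(dims_in, c(ncol(ts$signatures), 10, 10, 10, 10))
  H <- mpmriseg:::encode_stack(layers, ts$signatures)
  expect_true(all(H >= 0 & H <= 1))
  expect_equal(ncol(H), 10)
  # distinct class-mean signatures encode differently
  m2 <- colMeans(ts$signatures[ts$labels == 2, , drop = FALSE])
  m3 <- colMeans(ts$signatures[ts$labels == 3, , drop = FALSE])
  e23 <- mpmriseg:::encode_stack(layers, rbind(m2, m3))
  expect_gt(max(abs(e23[1, ] - e23[2, ])), 1e-6)
})

test_that("satlin encodings stay in [0,1] under random weights (property)", {
  set.seed(10)
  for (i in 1:10) {
    lay <- structure(list(W_enc = matrix(rnorm(10 * 6, sd = 3), 10, 6),
                          b_enc = rnorm(10, sd = 3),
                          W_dec = NULL, b_dec = NULL,
                          activation = "satlin"), class = "sae_layer")
    H <- sae_encode(lay, matrix(rnorm(20 * 6, sd = 2), 20, 6))
    expect_true(all(H >= 0 & H <= 1))
  }
})

test_that("softmax head: separable clusters, simplex outputs, batch invariance", {
  set.seed(12)
  centers <- diag(4)[, 1:4] * 5
  H <- do.call(rbind, lapply(1:4, function(k)
    matrix(rep(centers[k, ], 30), 30, 4, byrow = TRUE) +
      matrix(rnorm(120, sd = 0.1), 30, 4)))
  labels <- rep(0:3, each = 30)
  cfg <- ssae_config(max_epochs = 300, seed = 3)
  head <- train_softmax_head(H, labels, cfg)
  P <- mpmriseg:::softmax_probs(sweep(H %*% head$W, 2, head$b, `+`))
  expect_equal(mean(head$classes[max.col(P, "first")] == labels), 1.0)
  expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-9)

  perm <- sample(nrow(H))
  head_p <- train_softmax_head(H[perm, ], labels[perm], cfg)
  P2 <- mpmriseg:::softmax_probs(sweep(H %*% head_p$W, 2, head_p$b, `+`))
  expect_equal(P2, P, tolerance = 1e-8)

  expect_error(train_softmax_head(H, rep(0:2, each = 40), cfg), "missing")
})

test_that("fine-tuning descends, is seeded, and can be disabled", {
  tc <- trained_clean_model()
  ts <- tc$train_set
  cfg <- tiny_cfg(7)
  layers <- pretrain_stack(ts$signatures, cfg)
  H <- mpmriseg:::encode_stack(layers, ts$signatures)
  head <- train_softmax_head(H, ts$labels, cfg)
  model <- ssae_model(layers, head)

  off <- cfg; off$fine_tune <- FALSE
  expect_identical(fine_tune(model, ts$signatures, ts$labels, off), model)

  ce <- function(m) {
    P <- mpmriseg:::ssae_predict(m, ts$signatures)
    Y <- matrix(0, nrow(P), 4); Y[cbind(seq_len(nrow(P)),
                                        ts$labels + 1)] <- 1
    -sum(Y * log(pmax(P, 1e-12))) / nrow(P)
  }
  tuned <- fine_tune(model, ts$signatures, ts$labels, cfg)
  expect_lte(ce(tuned), ce(model) + 1e-9)
  tuned2 <- fine_tune(model, ts$signatures, ts$labels, cfg)
  expect_identical(tuned$softmax$W, tuned2$softmax$W)
})

test_that("segmentation: near-perfect on clean phantoms, legend, guards", {
  tc <- trained_clean_model()
  ph <- tc$phantoms[[1]]
  seg <- segment_study(tc$model, tc$studies[[1]])
  expect_gt(mean(seg$labels == ph$truth$labels), 0.99)
  expect_identical(seg$legend,
                   c(`0` = "background", `1` = "fat", `2` = "glandular",
                     `3` = "lesion"))

  zero <- tc$studies[[1]]
  for (nm in zero$channel_order) zero$channels[[nm]][] <- 0
  segz <- segment_study(tc$model, zero)
  expect_length(unique(as.vector(segz$labels)), 1L)

  small <- mp_study(list(a = ph$study$channels$T1w))
  expect_error(segment_study(tc$model, small), "channels")
  wrong_order <- tc$studies[[1]]
  wrong_order$channel_order <- rev(wrong_order$channel_order)
  wrong_order$channels <- wrong_order$channels[wrong_order$channel_order]
  expect_error(segment_study(tc$model, wrong_order), "order")
})

test_that("SSAE model JSON round trip preserves predictions", {
  dir <- withr::local_tempdir()
  tc <- trained_clean_model()
  p <- file.path(dir, "m.json")
  write_ssae_model(tc$model, p)
  back <- read_ssae_model(p)
  X <- tc$train_set$signatures[1:20, ]
  expect_equal(mpmriseg:::ssae_predict(back, X),
               mpmriseg:::ssae_predict(tc$model, X), tolerance = 1e-12)
  expect_identical(back$channel_order, tc$model$channel_order)
})
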
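test_that("eigenimage filter closed form on axis-aligned cases", {
  des <- signature_set(matrix(c(1, 0), 1, 2), 3L)
  und <- signature_set(matrix(rep(c(0, 1), 5), 5, 2, byrow = TRUE), 2L)
  w <- fit_eigenimage_filter(des, und, ridge = 1e-9)
  expect_equal(as.numeric(w$w), c(1, 0), tolerance = 1e-6)
  expect_equal(sum(w$w * w$desired_mean), 1, tolerance = 1e-9)

  # d = (1,1), undesired all (1,0): as ridge -> 0, w -> (0,1)
  des2 <- signature_set(matrix(c(1, 1), 1, 2), 3L)
  und2 <- signature_set(matrix(rep(c(1, 0), 5), 5, 2, byrow = TRUE), 2L)
  w2 <- fit_eigenimage_filter(des2, und2, ridge = 1e-10)
  expect_equal(as.numeric(w2$w), c(0, 1), tolerance = 1e-4)

  # applying w to the desired-class mean gives contrast exactly 1
  expect_equal(sum(w2$w * w2$desired_mean), 1, tolerance = 1e-9)
})

test_that("closed form matches a brute-force constrained minimizer (D <= 3)", {
  set.seed(13)
  for (D in 2:3) {
    des <- signature_set(matrix(runif(6 * D, 0.5, 1), 6, D), 3L)
    und <- signature_set(matrix(runif(15 * D, 0, 0.6), 15, D), 2L)
    ridge <- 1e-6
    wts <- fit_eigenimage_filter(des, und, ridge)
    dbar <- colMeans(des$signatures)
    U <- und$signatures
    objective <- function(w) sum((U %*% w)^2) + ridge * sum(w^2)
    # parameterize the constraint plane w = w0 + N t and minimize over t
    w0 <- dbar / sum(dbar^2)
    Nmat <- svd(matrix(dbar, ncol = 1), nu = D)$u[, -1, drop = FALSE]
    brute <- optim(rep(0, D - 1),
                   function(t) objective(w0 + Nmat %*% t),
                   method = "BFGS",
                   control = list(maxit = 1000, reltol = 1e-15))
    w_brute <- w0 + Nmat %*% brute$par
    expect_equal(as.numeric(wts$w), as.numeric(w_brute), tolerance = 1e-6)
  }
})

test_that("ridge regularization shrinks the filter monotonically", {
  set.seed(14)
  des <- signature_set(matrix(runif(10 * 3, 0.5, 1), 10, 3), 3L)
  und <- signature_set(matrix(runif(20 * 3, 0, 0.6), 20, 3), 2L)
  norms <- vapply(c(1e-6, 1e-2, 1, 100), function(r)
    sqrt(sum(fit_eigenimage_filter(des, und, r)$w^2)), numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("apply_eigenimage is the linear projection", {
  ph <- clean_phantom(seed = 4)
  ns <- normalize_channels(ph$study)
  hv <- harvest_signatures(ns, auto_seeds(ph$truth, 2, seed = 2))
  pick <- function(cl) signature_set(
    hv$signatures[hv$labels == cl, , drop = FALSE], hv$labels[hv$labels == cl])
  wts <- fit_eigenimage_filter(pick(3),
                               bind_signature_sets(list(pick(2), pick(1))))
  ei <- apply_eigenimage(ns, wts)
  # piecewise constant per class on a noiseless phantom
  for (cl in 0:3)
    expect_lt(diff(range(ei[ph$truth$labels == cl])), 1e-9)
  # zero signature -> 0, and linearity in the input
  zero <- ns
  for (nm in zero$channel_order) zero$channels[[nm]][] <- 0
  expect_equal(apply_eigenimage(zero, wts), array(0, dim(ei)))
  half <- ns
  for (nm in half$channel_order) half$channels[[nm]] <-
      0.5 * half$channels[[nm]]
  expect_equal(apply_eigenimage(half, wts), 0.5 * ei, tolerance = 1e-12)
  # dimension mismatch is refused
  small <- mp_study(list(a = ph$study$channels$T1w))
  expect_error(apply_eigenimage(small, wts), "dimension|match")
})

test_that("thresholding recovers a hot block and is shift invariant", {
  set.seed(15)
  ei <- array(rnorm(16 * 16 * 4), c(16, 16, 4))
  ei[6:9, 6:9, 2] <- 10
  fg <- array(TRUE, dim(ei))
  m <- threshold_eigenimage(ei, fg)
  want <- array(FALSE, dim(ei)); want[6:9, 6:9, 2] <- TRUE
  expect_identical(m, want)
  expect_identical(threshold_eigenimage(ei + 5, fg), m)
  expect_error(threshold_eigenimage(array(1, c(4, 4, 2)),
                                    array(TRUE, c(4, 4, 2))), "variance")
  expect_error(threshold_eigenimage(ei, fg & FALSE), "empty")
})

test_that("largest_component keeps the biggest 26-connected blob", {
  m <- array(FALSE, c(10, 10, 1))
  m[1:2, 1:2, 1] <- TRUE        # 4 voxels
  m[6:9, 6:9, 1] <- TRUE        # 16 voxels
  l <- largest_component(m)
  expect_equal(sum(l), 16)
  expect_true(all(l[6:9, 6:9, 1]))
})

test_that("eigenimage ground truth has Dice 1.0 on noiseless phantoms", {
  ph <- clean_phantom(seed = 21)
  ns <- normalize_channels(ph$study)
  hv <- harvest_signatures(ns, auto_seeds(ph$truth, 2, seed = 5))
  mask <- mpmriseg:::ei_ground_truth(ns, hv)
  expect_equal(dice(mask, ph$truth$labels == 3L), 1.0)
})

test_that("eigen filter JSON round trip", {
  dir <- withr::local_tempdir()
  des <- signature_set(matrix(c(1, 0), 1, 2,
                              dimnames = list(NULL, c("a", "b"))), 3L)
  und <- signature_set(matrix(rep(c(0, 1), 4), 4, 2, byrow = TRUE), 2L)
  w <- fit_eigenimage_filter(des, und)
  p <- file.path(dir, "w.json")
  write_eigen_filter(w, p)
  back <- read_eigen_filter(p)
  expect_equal(back$w, w$w)
  expect_equal(back$desired_mean, as.numeric(w$desired_mean))
})
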
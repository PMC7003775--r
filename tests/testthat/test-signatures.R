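test_that("region growing separates contrasting regions and floods constants", {
  # 5x5 slice: centre 3x3 block at 100, border at 200
  vol <- array(200, c(5, 5, 1))
  vol[2:4, 2:4, 1] <- 100
  m <- region_grow(vol, c(3, 3, 1))
  want <- array(FALSE, c(5, 5, 1)); want[2:4, 2:4, 1] <- TRUE
  expect_identical(m, want)

  const <- array(7, c(4, 4, 3))
  expect_true(all(region_grow(const, c(2, 2, 2))))

  expect_error(region_grow(const, c(9, 1, 1)), "outside")
  nf <- const; nf[1, 1, 1] <- NA
  expect_error(region_grow(nf, c(1, 1, 1)), "non-finite")
})

test_that("4% intensity step merges, 6% does not; oracle agreement", {
  base <- array(100, c(6, 6, 2))
  for (step in c(104, 106)) {
    vol <- base
    vol[4:6, , ] <- step
    m <- region_grow(vol, c(2, 2, 1), eps_abs = 0)
    o <- rg_oracle(vol, c(2, 2, 1), eps_abs = 0)
    expect_identical(m, o)
    if (step == 104) expect_true(all(m)) else {
      expect_true(all(m[1:3, , ])); expect_false(any(m[4:6, , ]))
    }
  }
})

test_that("region growing matches the BFS oracle on random volumes", {
  set.seed(11)
  for (rep in 1:5) {
    vol <- array(sample(c(10, 10.3, 11, 20), 80, replace = TRUE), c(5, 4, 4))
    seedv <- c(sample(5, 1), sample(4, 1), sample(4, 1))
    m <- region_grow(vol, seedv)
    expect_identical(m, rg_oracle(vol, seedv))
    # result is one connected component containing the seed
    expect_true(m[seedv[1], seedv[2], seedv[3]])
    lab <- mpmriseg:::.cc_label(as.logical(m), dim(m))
    expect_lte(max(lab), 1L)
    # determinism
    expect_identical(m, region_grow(vol, seedv))
  }
})

test_that("logical-AND ROI fusion", {
  a <- array(c(TRUE, FALSE), c(4, 4, 1))
  expect_identical(multiparametric_roi(list(a, a)), a)
  b <- !a
  expect_warning(e <- multiparametric_roi(list(a, b)), "empty")
  expect_false(any(e))
  expect_error(multiparametric_roi(list()), "empty")

  set.seed(4)
  ms <- lapply(1:3, function(i) array(runif(16) > 0.5, c(4, 4, 1)))
  fused <- multiparametric_roi(ms)
  expect_identical(fused, array(ms[[1]] & ms[[2]] & ms[[3]], c(4, 4, 1)))
  for (m in ms) expect_true(all(!fused | m)) # fused is a subset of every mask
})

test_that("extract_signatures pulls channel columns per ROI voxel", {
  ph <- clean_phantom(seed = 9)
  st <- ph$study
  roi1 <- array(FALSE, dim(ph$truth$labels)); roi1[5, 6, 2] <- TRUE
  s1 <- extract_signatures(st, roi1, 2L)
  expect_equal(dim(s1$signatures), c(1L, length(st$channel_order)))
  expect_equal(as.vector(s1$signatures),
               vapply(st$channels, function(ch) ch[5, 6, 2], numeric(1)),
               ignore_attr = TRUE)

  roi <- ph$truth$labels == 3L
  s <- extract_signatures(st, roi, 3L)
  expect_equal(nrow(s$signatures), sum(roi))
  # noiseless phantom: all lesion rows identical
  expect_equal(max(apply(s$signatures, 2, function(x) diff(range(x)))), 0,
               tolerance = 1e-12)
  expect_error(extract_signatures(st, roi & FALSE, 3L), "empty")
})

test_that("balanced sampling follows the min-count rule and is seeded", {
  set.seed(2)
  mk <- function(n, cl) signature_set(matrix(runif(n * 3), n, 3),
                                      rep(cl, n))
  sets <- list(mk(2000, 0), mk(1500, 1), mk(1200, 2), mk(900, 3))
  bal <- sample_balanced(sets, cap_per_class = 1000, seed = 5)
  expect_equal(as.vector(table(bal$labels)), rep(900L, 4))
  expect_equal(nrow(bal$signatures), 3600L)

  bal10 <- sample_balanced(sets, cap_per_class = 10, seed = 5)
  expect_equal(as.vector(table(bal10$labels)), rep(10L, 4))

  expect_identical(sample_balanced(sets, 50, seed = 8)$signatures,
                   sample_balanced(sets, 50, seed = 8)$signatures)

  # every sampled row exists in the pool
  pool <- do.call(rbind, lapply(sets, `[[`, "signatures"))
  hits <- apply(bal10$signatures, 1, function(r)
    any(colSums(abs(t(pool) - r)) == 0))
  expect_true(all(hits))

  expect_error(sample_balanced(sets[1:3], 10, seed = 1), NA)
  # a required class with zero rows is an error
  expect_error(sample_balanced(sets[1:3], 10, seed = 1, classes = 0:3), "3")
})

test_that("harvesting labels signatures by seeded class and caps nothing", {
  ph <- clean_phantom(seed = 12)
  ns <- normalize_channels(ph$study)
  seeds <- auto_seeds(ph$truth, 2, seed = 3)
  expect_setequal(unique(seeds$class_id), 0:3)
  # auto seeds sit on their own class
  for (i in seq_len(nrow(seeds)))
    expect_equal(ph$truth$labels[seeds$x[i], seeds$y[i], seeds$z[i]],
                 seeds$class_id[i])
  hv <- harvest_signatures(ns, seeds)
  expect_setequal(unique(hv$labels), 0:3)
  # on a noiseless phantom region growing recovers each full class region
  expect_equal(sum(hv$labels == 3), sum(ph$truth$labels == 3))
})

test_that("signature set CSV round trip", {
  dir <- withr::local_tempdir()
  set.seed(6)
  s <- signature_set(matrix(runif(12), 4, 3,
                            dimnames = list(NULL, c("a", "b", "c"))),
                     c(0, 1, 2, 3),
                     data.frame(subject_id = "s", x = 1:4, y = 1, z = 1))
  p <- file.path(dir, "sig.csv")
  write_signature_set(s, p)
  back <- read_signature_set(p)
  expect_equal(back$signatures, s$signatures, ignore_attr = TRUE)
  expect_identical(back$labels, s$labels)
})
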
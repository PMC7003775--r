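#' Seeded region growing with a running-mean acceptance band
#'
#' Grows a connected region from a seed voxel. A frontier voxel `v` is
#' accepted iff `|I(v) - mu_R| <= max(tol * |mu_R|, eps_abs)` where `mu_R` is
#' the running mean intensity of the region accepted so far. The default
#' tolerance is the 5% band used for tissue-signature harvesting. Frontier
#' voxels are evaluated exactly once, in increasing linear-index order
#' (x fastest), so the result is deterministic. Connectivity is 26-connected
#' in 3-D mode and 8-connected within the seed's slice in 2-D mode.
#'
#' Tolerance semantics ("5% of the signal intensity of the surrounding
#' pixels") are ambiguous; the default is a coefficient-of-variation band
#' around the running region mean, with an absolute floor `eps_abs` that
#' defaults to `tolerance_fraction * sd(volume)` (the alternate global-SD
#' reading). Set `eps_abs = 0` for a pure relative band.
#'
#' @param volume 3-D numeric array.
#' @param seed_voxel integer triple (1-based voxel index).
#' @param tolerance_fraction relative acceptance band, default 0.05.
#' @param eps_abs absolute acceptance floor; `NULL` (default) uses
#'   `tolerance_fraction * sd(volume)`.
#' @param mode `"3d"` (default) or `"2d"` (grow within the seed's slice).
#' @return logical array of the same shape: the grown region mask.
#' @export
region_grow <- function(volume, seed_voxel, tolerance_fraction = 0.05,
                        eps_abs = NULL, mode = c("3d", "2d")) {
  mode <- match.arg(mode)
  shp <- dim(volume)
  if (length(shp) != 3L) stopf("volume must be a 3-D array")
  seed_voxel <- as.integer(seed_voxel)
  if (length(seed_voxel) != 3L || any(seed_voxel < 1) ||
      any(seed_voxel > shp))
    stopf("seed voxel (%s) outside grid (%s)",
          paste(seed_voxel, collapse = ","), paste(shp, collapse = "x"))
  if (is.null(eps_abs))
    eps_abs <- tolerance_fraction * sd(as.vector(volume))
  if (!is.finite(eps_abs)) eps_abs <- 0
  lin0 <- (seed_voxel[3] - 1L) * shp[1] * shp[2] +
    (seed_voxel[2] - 1L) * shp[1] + (seed_voxel[1] - 1L)
  if (!is.finite(volume[seed_voxel[1], seed_voxel[2], seed_voxel[3]]))
    stopf("seed lies on a non-finite voxel")
  .rg_core(as.numeric(volume), as.integer(shp), as.integer(lin0),
           tolerance_fraction, eps_abs, mode == "2d")
}

#' Logical-AND fusion of per-channel ROIs
#'
#' Voxelwise conjunction of the region masks grown on each channel; using
#' several channels concurrently reduces the chance that noise or partial
#' volume admits a voxel of another tissue. Warns if the fused ROI is empty.
#'
#' @param masks non-empty list of logical arrays on one grid.
#' @return logical array, subset of every input mask.
#' @export
multiparametric_roi <- function(masks) {
  if (length(masks) == 0L) stopf("mask list is empty")
  out <- as_mask(masks[[1]])
  for (m in masks[-1]) {
    check_same_dim(out, m, "masks")
    out <- out & as_mask(m)
  }
  if (!any(out)) warnf("fused ROI is empty (disjoint channel ROIs)")
  out
}

#' Extract labeled tissue signatures from an ROI
#'
#' One row per ROI voxel; values are the voxel's channel column in
#' `channel_order`. Returns a `signature_set`: list with `signatures`
#' (N x D matrix, columns named by channel), `labels` (N integers) and
#' `provenance` (data frame of subject and voxel indices).
#'
#' @param study an [mp_study].
#' @param roi non-empty logical array on the study grid.
#' @param class_id tissue class code 0..3 assigned to all rows.
#' @return object of class `signature_set`.
#' @export
extract_signatures <- function(study, roi, class_id) {
  check_same_dim(study$channels[[1]], roi, "study and roi")
  idx <- which(as_mask(roi))
  if (length(idx) == 0L) stopf("roi is empty")
  X <- vapply(study$channels, function(ch) ch[idx], numeric(length(idx)))
  if (length(idx) == 1L) X <- matrix(X, nrow = 1,
                                     dimnames = list(NULL, study$channel_order))
  vox <- arrayInd(idx, dim(roi))
  signature_set(X, rep(as.integer(class_id), length(idx)),
                data.frame(subject_id = study$subject_id,
                           x = vox[, 1], y = vox[, 2], z = vox[, 3],
                           stringsAsFactors = FALSE))
}

#' @rdname extract_signatures
#' @param signatures N x D numeric matrix.
#' @param labels N class labels (integers 0..3).
#' @param provenance data frame with one row per signature.
#' @export
signature_set <- function(signatures, labels, provenance = NULL) {
  signatures <- as.matrix(signatures)
  if (length(labels) == 1L && nrow(signatures) > 1L)
    labels <- rep(labels, nrow(signatures))
  if (nrow(signatures) != length(labels))
    stopf("signatures and labels are misaligned")
  if (is.null(provenance))
    provenance <- data.frame(subject_id = NA_character_,
                             x = NA_integer_, y = NA_integer_,
                             z = NA_integer_)[rep(1, nrow(signatures)), ]
  if (nrow(provenance) != nrow(signatures))
    stopf("provenance rows are misaligned")
  structure(list(signatures = signatures, labels = as.integer(labels),
                 provenance = provenance),
            class = "signature_set")
}

#' Concatenate signature sets
#' @param sets list of `signature_set` with consistent D.
#' @return one combined `signature_set`.
#' @export
bind_signature_sets <- function(sets) {
  sets <- Filter(Negate(is.null), sets)
  if (length(sets) == 0L) stopf("no signature sets to combine")
  signature_set(do.call(rbind, lapply(sets, `[[`, "signatures")),
                unlist(lapply(sets, `[[`, "labels")),
                do.call(rbind, lapply(sets, `[[`, "provenance")))
}

#' Balanced per-class sampling of pooled signatures
#'
#' Pools the given sets, then per class samples uniformly without replacement
#' `min(cap_per_class, available)` rows; finally all classes are subsampled
#' to the same count (the minimum across classes), so the training set is
#' exactly class-balanced. Deterministic given `seed`. The 1000-row default
#' cap is applied per class pooled across the cohort.
#'
#' @param sets list of `signature_set` (or a single set).
#' @param cap_per_class maximum rows per class, default 1000.
#' @param seed RNG seed.
#' @param classes class codes that must all be represented; `NULL` (default)
#'   balances whatever classes occur in the pool.
#' @return a class-balanced `signature_set`.
#' @export
sample_balanced <- function(sets, cap_per_class = 1000L, seed = 1L,
                            classes = NULL) {
  if (inherits(sets, "signature_set")) sets <- list(sets)
  pool <- bind_signature_sets(sets)
  if (is.null(classes)) classes <- sort(unique(pool$labels))
  counts <- vapply(classes, function(cl) sum(pool$labels == cl), integer(1))
  if (any(counts == 0L))
    stopf("class(es) with zero signatures: %s",
          paste(classes[counts == 0L], collapse = ", "))
  n_per <- min(pmin(counts, cap_per_class))
  keep <- with_seed(seed, {
    unlist(lapply(classes, function(cl) {
      rows <- which(pool$labels == cl)
      sort(resample(rows, n_per))
    }))
  })
  signature_set(pool$signatures[keep, , drop = FALSE], pool$labels[keep],
                pool$provenance[keep, , drop = FALSE])
}

#' Automatic class-representative seed voxels from a truth label map
#'
#' Testing convenience for phantom runs (real studies take user seed points):
#' per class, samples seed voxels from the class interior (voxels whose
#' 6-neighbourhood is entirely the same class, falling back to any class
#' voxel when no interior exists). Deterministic given `seed`.
#'
#' @param truth a [label_map].
#' @param n_per_class seeds per class.
#' @param seed RNG seed.
#' @return data frame with columns `class_id`, `x`, `y`, `z`.
#' @export
auto_seeds <- function(truth, n_per_class = 3L, seed = 1L) {
  lab <- truth$labels
  shp <- dim(lab)
  interior_of <- function(cl) {
    m <- lab == cl
    er <- m
    # 6-neighbour erosion by array shifts
    shift_ok <- function(d) {
      s <- array(FALSE, shp)
      i <- seq_len(shp[1]); j <- seq_len(shp[2]); k <- seq_len(shp[3])
      ii <- pmin(pmax(i + d[1], 1), shp[1])
      jj <- pmin(pmax(j + d[2], 1), shp[2])
      kk <- pmin(pmax(k + d[3], 1), shp[3])
      s[i, j, k] <- m[ii, jj, kk]
      s
    }
    for (d in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0),
                   c(0,0,1), c(0,0,-1)))
      er <- er & shift_ok(d)
    if (any(er)) which(er) else which(m)
  }
  with_seed(seed, {
    rows <- lapply(0:3, function(cl) {
      cand <- interior_of(cl)
      if (length(cand) == 0L) return(NULL)
      pick <- cand[sample.int(length(cand), min(n_per_class, length(cand)))]
      v <- arrayInd(pick, shp)
      data.frame(class_id = cl, x = v[, 1], y = v[, 2], z = v[, 3])
    })
    do.call(rbind, rows)
  })
}

#' Harvest a labeled signature set from one study via region growing
#'
#' For each class and each of its seeds, grows a region on every channel,
#' fuses the per-channel masks with [multiparametric_roi], unions the fused
#' ROIs over the class's seeds, and extracts signatures. Seeds whose fused
#' ROI is empty contribute the seed voxel itself (so every class yields at
#' least its seeds).
#'
#' ROIs are grown on one representative image per MRI sequence (default:
#' T1w, T2w, both DWI images, the ADC map and one early post-contrast DCE
#' frame), not on every DCE frame separately — the frames of one dynamic
#' series are a single sequence. The extracted signature vectors still span
#' all channels.
#'
#' @param study a (normalized) [mp_study].
#' @param seeds data frame with columns `class_id`, `x`, `y`, `z`.
#' @param tolerance_fraction region-growing tolerance.
#' @param mode `"3d"` or `"2d"` growing.
#' @param fusion_channels channel names whose grown ROIs are AND-fused;
#'   `NULL` selects the per-sequence default above.
#' @return a `signature_set` covering the seeded classes.
#' @export
harvest_signatures <- function(study, seeds, tolerance_fraction = 0.05,
                               mode = "3d", fusion_channels = NULL) {
  shp <- study_dim(study)
  if (is.null(fusion_channels)) {
    dce <- grep("^DCE_", study$channel_order, value = TRUE)
    fusion_channels <- c(setdiff(study$channel_order, dce),
                         if (length(dce)) dce[min(3L, length(dce))])
  }
  miss <- setdiff(fusion_channels, study$channel_order)
  if (length(miss)) stopf("unknown fusion channels: %s",
                          paste(miss, collapse = ", "))
  sets <- list()
  for (cl in sort(unique(seeds$class_id))) {
    sc <- seeds[seeds$class_id == cl, , drop = FALSE]
    roi <- array(FALSE, shp)
    for (i in seq_len(nrow(sc))) {
      sv <- c(sc$x[i], sc$y[i], sc$z[i])
      masks <- lapply(study$channels[fusion_channels], region_grow,
                      seed_voxel = sv,
                      tolerance_fraction = tolerance_fraction, mode = mode)
      fused <- suppressWarnings(multiparametric_roi(masks))
      if (!any(fused)) fused[sv[1], sv[2], sv[3]] <- TRUE
      roi <- roi | fused
    }
    sets[[as.character(cl)]] <- extract_signatures(study, roi, cl)
  }
  bind_signature_sets(sets)
}

#' Write / read a signature set as a columnar table
#'
#' One row per signature: D channel-value columns, `label`, and provenance
#' columns (`subject_id`, `x`, `y`, `z`).
#'
#' @param set a `signature_set`.
#' @param path CSV path.
#' @return `read_signature_set` returns a `signature_set`.
#' @export
write_signature_set <- function(set, path) {
  tab <- cbind(as.data.frame(set$signatures), label = set$labels,
               set$provenance)
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signature_set
#' @export
read_signature_set <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  prov_cols <- c("subject_id", "x", "y", "z")
  d_cols <- setdiff(names(tab), c(prov_cols, "label"))
  signature_set(as.matrix(tab[, d_cols, drop = FALSE]), tab$label,
                tab[, prov_cols, drop = FALSE])
}
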
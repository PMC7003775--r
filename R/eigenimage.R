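#' Fit the eigenimage linear contrast filter
#'
#' Finds the D-dimensional linear filter `w` that maximizes the projection of
#' the desired tissue signature while suppressing the undesired tissues:
#' `w = argmin sum_i (w' u_i)^2 + ridge * ||w||^2` subject to `w' dbar = 1`,
#' where `u_i` are the undesired signatures and `dbar` the desired-class mean
#' signature. Closed form: `w` proportional to `C^-1 dbar` with
#' `C = sum u_i u_i' + ridge * I`, rescaled so `w' dbar = 1`.
#'
#' @param desired `signature_set` of the desired (lesion) class.
#' @param undesired `signature_set` of undesired tissues (defaults in the
#'   pipeline: glandular + fat).
#' @param ridge non-negative Tikhonov stabilizer.
#' @return object of class `eigen_filter`: list with `w` (named by channel),
#'   `desired_mean`, `ridge`.
#' @export
fit_eigenimage_filter <- function(desired, undesired, ridge = 1e-6) {
  if (nrow(desired$signatures) == 0L || nrow(undesired$signatures) == 0L)
    stopf("desired and undesired signature sets must be nonempty")
  D <- ncol(desired$signatures)
  if (ncol(undesired$signatures) != D)
    stopf("signature dimensionality mismatch (%d vs %d)", D,
          ncol(undesired$signatures))
  dbar <- colMeans(desired$signatures)
  U <- undesired$signatures
  C <- crossprod(U) + ridge * diag(D)
  w <- tryCatch(solve(C, dbar),
                error = function(e) stopf(
                  "undesired covariance is singular; increase ridge (%s)",
                  conditionMessage(e)))
  denom <- sum(w * dbar)
  if (abs(denom) < 1e-12)
    stopf("degenerate contrast: desired mean is orthogonal to C^-1 image")
  w <- w / denom
  structure(list(w = stats::setNames(as.numeric(w), colnames(desired$signatures)),
                 desired_mean = dbar, ridge = ridge),
            class = "eigen_filter")
}

#' Apply an eigenimage filter to a study
#'
#' `EI(v) = w' signature(v)` for every voxel; a linear projection of the
#' multichannel study onto the contrast axis.
#'
#' @param study an [mp_study] with D matching the filter.
#' @param weights an `eigen_filter`.
#' @return 3-D numeric array (the eigenimage contrast volume).
#' @export
apply_eigenimage <- function(study, weights) {
  if (study_D(study) != length(weights$w))
    stopf("filter dimension %d does not match study D = %d",
          length(weights$w), study_D(study))
  shp <- study_dim(study)
  out <- array(0, shp)
  for (k in seq_along(study$channel_order))
    out <- out + weights$w[k] * study$channels[[k]]
  out
}

#' Threshold an eigenimage into a lesion mask
#'
#' Threshold `t = mean + 1.96 * SD` of the eigenimage over the foreground
#' (the one-sided upper 95% cut on the EI histogram); the mask is
#' `{v in foreground : EI(v) > t}`, optionally reduced to its largest
#' 26-connected component to remove speckle.
#'
#' @param ei eigenimage volume.
#' @param foreground non-empty logical array (e.g. the breast region).
#' @param keep_largest retain only the largest connected component.
#' @param z upper cut multiplier (1.96 = 95% one-sided).
#' @return logical lesion mask.
#' @export
threshold_eigenimage <- function(ei, foreground, keep_largest = TRUE,
                                 z = 1.96) {
  check_same_dim(ei, foreground, "eigenimage and foreground")
  fg <- as_mask(foreground)
  if (!any(fg)) stopf("foreground is empty")
  vals <- ei[fg]
  s <- sd(vals)
  if (!is.finite(s) || s == 0)
    stopf("eigenimage has zero variance over the foreground")
  t <- mean(vals) + z * s
  mask <- fg & (ei > t)
  if (keep_largest && any(mask)) mask <- largest_component(mask)
  mask
}

#' Largest 26-connected component of a mask
#' @param mask logical 3-D array.
#' @return logical array keeping only the largest component (ties broken by
#'   first occurrence in linear-index order).
#' @export
largest_component <- function(mask) {
  mask <- as_mask(mask)
  if (!any(mask)) return(mask)
  lab <- .cc_label(as.logical(mask), as.integer(dim(mask)))
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

#' Serialize / load eigenimage filter weights as JSON
#' @param weights an `eigen_filter`.
#' @param path JSON path.
#' @export
write_eigen_filter <- function(weights, path) {
  jsonlite::write_json(list(channels = names(weights$w),
                            w = as.numeric(weights$w),
                            desired_mean = as.numeric(weights$desired_mean),
                            ridge = weights$ridge),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_eigen_filter
#' @export
read_eigen_filter <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(w = stats::setNames(as.numeric(j$w), j$channels),
                 desired_mean = as.numeric(j$desired_mean), ridge = j$ridge),
            class = "eigen_filter")
}
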
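#' Multiparametric MRI study container
#'
#' An `mp_study` holds an ordered set of co-registered 3-D scalar channel
#' volumes sharing one grid, plus the voxel spacing. The per-voxel column
#' across channels, taken in `channel_order`, is the raw tissue-signature
#' vector of that voxel; its dimensionality D equals the number of channels.
#'
#' @param channels named list of 3-D numeric arrays, all the same shape.
#' @param voxel_spacing voxel spacing in mm (length 3).
#' @param subject_id subject identifier string.
#' @param channel_order character vector fixing the signature layout; defaults
#'   to `names(channels)`.
#' @return object of class `mp_study`.
#' @export
mp_study <- function(channels, voxel_spacing = c(1, 1, 1),
                     subject_id = "subject", channel_order = names(channels)) {
  if (length(channels) == 0L) stopf("study must contain at least one channel")
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stopf("channels must be a named list")
  if (!setequal(channel_order, names(channels)) ||
      length(channel_order) != length(channels))
    stopf("channel_order must be a permutation of channel names")
  shp <- dim(channels[[1]])
  if (length(shp) != 3L) stopf("channels must be 3-D arrays")
  for (nm in names(channels)) check_same_dim(channels[[1]], channels[[nm]],
                                             sprintf("channels '%s'", nm))
  structure(list(channels = channels[channel_order],
                 channel_order = channel_order,
                 voxel_spacing = as.numeric(voxel_spacing),
                 subject_id = subject_id),
            class = "mp_study")
}

#' @export
print.mp_study <- function(x, ...) {
  cat(sprintf("mp_study '%s': %d channels, grid %s, spacing %s mm\n",
              x$subject_id, length(x$channels),
              paste(dim(x$channels[[1]]), collapse = "x"),
              paste(signif(x$voxel_spacing, 3), collapse = "x")))
  cat("  channels:", paste(x$channel_order, collapse = ", "), "\n")
  invisible(x)
}

study_dim <- function(study) dim(study$channels[[1]])

study_D <- function(study) length(study$channels)

# Voxels-by-channels signature matrix for all voxels (column-major voxel order).
study_matrix <- function(study) {
  vapply(study$channels, as.vector, numeric(prod(study_dim(study))))
}

#' Tissue label map
#'
#' Integer 3-D volume with values in \{0 background, 1 fat, 2 glandular,
#' 3 lesion\} plus a legend.
#'
#' @param labels 3-D integer array with values in 0..3.
#' @param legend named map from value to class name.
#' @return object of class `label_map`.
#' @export
label_map <- function(labels,
                      legend = c(`0` = "background", `1` = "fat",
                                 `2` = "glandular", `3` = "lesion")) {
  if (length(dim(labels)) != 3L) stopf("labels must be a 3-D array")
  vals <- unique(as.vector(labels))
  if (!all(vals %in% as.integer(names(legend))))
    stopf("label values outside legend: %s",
          paste(setdiff(vals, as.integer(names(legend))), collapse = ", "))
  structure(list(labels = array(as.integer(labels), dim(labels)),
                 legend = legend),
            class = "label_map")
}

#' Apparent diffusion coefficient map from a DWI pair
#'
#' `ADC(v) = ln(s0(v) / s_b(v)) / b`, reported in units of
#' 1e-3 mm^2/s, at voxels where both signals exceed `eps`; 0 elsewhere.
#' Output is clipped to `[0, adc_max]`.
#'
#' @param s0 b=0 DWI volume.
#' @param s_b high-b DWI volume (same grid).
#' @param b b-value in s/mm^2 (positive).
#' @param eps signal floor below which a voxel is masked to 0.
#' @param adc_max upper clip, 1e-3 mm^2/s.
#' @return 3-D volume of ADC values (1e-3 mm^2/s).
#' @export
compute_adc <- function(s0, s_b, b, eps = 1e-6, adc_max = 4.0) {
  check_same_dim(s0, s_b, "DWI volumes")
  if (!is.numeric(b) || length(b) != 1L || b <= 0) stopf("b must be a positive scalar (s/mm^2)")
  ok <- is.finite(s0) & is.finite(s_b) & s0 > eps & s_b > eps
  adc <- array(0, dim(s0))
  adc[ok] <- log(s0[ok] / s_b[ok]) / b * 1000  # -> 1e-3 mm^2/s
  adc[adc < 0] <- 0
  adc[adc > adc_max] <- adc_max
  adc
}

#' Robust per-channel intensity normalization
#'
#' Maps each channel independently to \[0, 1\] by robust min-max: the given
#' low/high percentiles are mapped to 0/1 and values outside are clipped.
#' The saturating-linear autoencoder unit operates on \[0, 1\], so studies are
#' normalized before signature extraction. Constant channels map to all zeros
#' with a warning. Idempotent (up to clipping) on already-normalized input.
#'
#' When several subjects must share one intensity scale (training a model
#' across subjects, then applying it to new ones), pass fixed per-channel
#' `bounds` computed on the training cohort with [compute_channel_bounds];
#' per-study percentile bounds (the default) rescale every subject by its own
#' anatomy and can wash out between-subject tissue contrast.
#'
#' @param study an [mp_study].
#' @param method `"percentile"` (robust, default) or `"minmax"` (exact range).
#' @param probs length-2 percentile pair used by the percentile method.
#' @param bounds optional named list `channel -> c(lo, hi)` of fixed
#'   normalization bounds (overrides `method`).
#' @return normalized [mp_study].
#' @export
normalize_channels <- function(study, method = c("percentile", "minmax"),
                               probs = c(0.01, 0.99), bounds = NULL) {
  method <- match.arg(method)
  out <- study
  for (nm in study$channel_order) {
    v <- study$channels[[nm]]
    rng <- if (!is.null(bounds)) {
      if (is.null(bounds[[nm]])) stopf("no bounds for channel '%s'", nm)
      as.numeric(bounds[[nm]])
    } else if (method == "percentile")
      quantile(v, probs = probs, names = FALSE, na.rm = TRUE)
    else range(v, finite = TRUE)
    if (!is.finite(rng[1]) || !is.finite(rng[2]) || rng[2] <= rng[1]) {
      warnf("channel '%s' is constant; normalized to all zeros", nm)
      out$channels[[nm]] <- array(0, dim(v))
    } else {
      x <- (v - rng[1]) / (rng[2] - rng[1])
      x[x < 0] <- 0
      x[x > 1] <- 1
      out$channels[[nm]] <- x
    }
  }
  out
}

#' Pooled per-channel normalization bounds over a cohort
#'
#' Robust low/high percentiles of each channel pooled over the given studies;
#' pass the result as `bounds` to [normalize_channels] so all subjects share
#' one intensity scale.
#'
#' @param studies list of [mp_study] with identical channel order.
#' @param probs length-2 percentile pair.
#' @return named list `channel -> c(lo, hi)`.
#' @export
compute_channel_bounds <- function(studies, probs = c(0.01, 0.99)) {
  stopifnot(length(studies) >= 1L)
  order <- studies[[1]]$channel_order
  bounds <- list()
  for (nm in order) {
    pooled <- unlist(lapply(studies, function(s) as.vector(s$channels[[nm]])))
    bounds[[nm]] <- as.numeric(quantile(pooled, probs = probs, names = FALSE,
                                        na.rm = TRUE))
  }
  bounds
}

#' Write / read a study as per-channel NIfTI volumes plus a JSON manifest
#'
#' One NIfTI file per channel (lossless float64) and `manifest.json` recording
#' subject id, channel order, spacing and file names; truth labels, when
#' present, are stored as int16 NIfTI. Round trips are bit-exact.
#'
#' @param study an [mp_study].
#' @param dir output directory (created if needed).
#' @param truth optional [label_map] written alongside.
#' @param gz write gzip-compressed `.nii.gz` files.
#' @return `write_study` returns the manifest path invisibly; `read_study`
#'   returns a list with `study` and (possibly `NULL`) `truth`.
#' @export
write_study <- function(study, dir, truth = NULL, gz = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (gz) ".nii.gz" else ".nii"
  files <- list()
  for (nm in study$channel_order) {
    fn <- paste0(study$subject_id, "_", nm, ext)
    nifti_write(study$channels[[nm]], file.path(dir, fn),
                spacing = study$voxel_spacing)
    files[[nm]] <- fn
  }
  manifest <- list(subject_id = study$subject_id,
                   channel_order = as.list(study$channel_order),
                   voxel_spacing = study$voxel_spacing,
                   axis_order = "xyz, 0-based voxel indices in seed files",
                   channel_files = files)
  if (!is.null(truth)) {
    fn <- paste0(study$subject_id, "_truth", ext)
    nifti_write(truth$labels, file.path(dir, fn),
                spacing = study$voxel_spacing, datatype = "int16")
    manifest$truth_file <- fn
    manifest$legend <- as.list(truth$legend)
  }
  mpath <- file.path(dir, paste0(study$subject_id, "_manifest.json"))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}

#' @rdname write_study
#' @param manifest_path path to a study manifest written by `write_study`.
#' @export
read_study <- function(manifest_path) {
  if (!file.exists(manifest_path)) stopf("manifest not found: %s", manifest_path)
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  dir <- dirname(manifest_path)
  order <- as.character(m$channel_order)
  channels <- list()
  spacing <- as.numeric(m$voxel_spacing)
  for (nm in order) {
    fn <- m$channel_files[[nm]]
    if (is.null(fn)) stopf("manifest is missing channel '%s'", nm)
    path <- file.path(dir, fn)
    if (!file.exists(path)) stopf("channel file for '%s' not found: %s", nm, path)
    vol <- nifti_read(path)
    channels[[nm]] <- vol$data
  }
  shp <- dim(channels[[1]])
  for (nm in order)
    if (!identical(dim(channels[[nm]]), shp))
      stopf("channel '%s' grid shape differs from '%s'", nm, order[1])
  study <- mp_study(channels, voxel_spacing = spacing,
                    subject_id = m$subject_id, channel_order = order)
  truth <- NULL
  if (!is.null(m$truth_file)) {
    tl <- nifti_read(file.path(dir, m$truth_file))
    legend <- unlist(m$legend)
    truth <- label_map(tl$data, legend = legend)
  }
  list(study = study, truth = truth)
}
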
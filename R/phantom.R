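#' Tissue class specification for the synthetic phantom
#'
#' Describes one of the four tissue classes (background, fat, glandular,
#' lesion) by its mean signal per base channel, cohort-level jitter SDs, its
#' apparent diffusion coefficient (ADC, 1e-3 mm^2/s) and a DCE enhancement
#' curve descriptor. Lesion defaults follow the reported breast-cohort
#' statistics: malignant ADC 1.26 +/- 0.13, benign 1.74 +/- 0.17
#' (1e-3 mm^2/s); malignant lesions wash in fast and wash out (late-frame
#' slope < 0), benign lesions rise slowly and persist, with malignant peak
#' enhancement above benign, mirroring the K-trans ordering (0.55 vs 0.25
#' 1/min).
#'
#' @param class_id integer class code in 0..3.
#' @param per_channel_mean named numeric vector of clean signal means for the
#'   base channels `T1w`, `T2w`, `DWI_b0`, `DCE_base` (arbitrary units).
#' @param per_channel_sd cohort jitter SD per base channel (same names).
#' @param adc_mean,adc_sd class ADC mean and cohort SD, 1e-3 mm^2/s.
#' @param enhancement list describing the DCE curve: `shape` one of
#'   `"none"`, `"persistent"`, `"washin_washout"`; `peak` relative peak
#'   enhancement fraction; `peak_frame` (washout only) frame of the peak;
#'   `final` (washout only) relative enhancement at the last frame.
#' @return object of class `tissue_class_spec`.
#' @export
tissue_class_spec <- function(class_id, per_channel_mean, per_channel_sd,
                              adc_mean, adc_sd,
                              enhancement = list(shape = "none", peak = 0)) {
  stopifnot(class_id %in% 0:3)
  nm <- c("T1w", "T2w", "DWI_b0", "DCE_base")
  if (!all(nm %in% names(per_channel_mean)) ||
      !all(nm %in% names(per_channel_sd)))
    stopf("per_channel_mean/sd must be named with %s", paste(nm, collapse = ", "))
  if (adc_sd < 0 || any(per_channel_sd < 0)) stopf("SDs must be non-negative")
  if ((enhancement$peak %||% 0) < 0) stopf("enhancement fractions must be >= 0")
  structure(list(class_id = as.integer(class_id),
                 per_channel_mean = per_channel_mean[nm],
                 per_channel_sd = per_channel_sd[nm],
                 adc_mean = adc_mean, adc_sd = adc_sd,
                 enhancement = enhancement),
            class = "tissue_class_spec")
}

#' Default four-class breast tissue specifications
#'
#' Signal levels are arbitrary units qualitatively matching fat-suppressed
#' 3-T breast MRI contrasts (bright fat on T1w, bright glandular/lesion on
#' fat-suppressed T2w); ADC statistics follow the reported cohort values.
#'
#' @param lesion_phenotype `"malignant"` or `"benign"`.
#' @return named list of [tissue_class_spec] for `background`, `fat`,
#'   `glandular`, `lesion`.
#' @export
default_class_specs <- function(lesion_phenotype = c("malignant", "benign")) {
  lesion_phenotype <- match.arg(lesion_phenotype)
  base <- function(t1, t2, b0, dce) {
    m <- c(T1w = t1, T2w = t2, DWI_b0 = b0, DCE_base = dce)
    list(mean = m, sd = 0.05 * m)
  }
  bg <- base(30, 30, 30, 30)
  fat <- base(800, 150, 250, 700)
  gl <- base(350, 550, 600, 400)
  les <- base(420, 620, 700, 450)
  lesion <- if (lesion_phenotype == "malignant") {
    tissue_class_spec(3L, les$mean, les$sd, adc_mean = 1.26, adc_sd = 0.13,
                      enhancement = list(shape = "washin_washout", peak = 1.2,
                                         peak_frame = 3, final = 0.85))
  } else {
    tissue_class_spec(3L, les$mean, les$sd, adc_mean = 1.74, adc_sd = 0.17,
                      enhancement = list(shape = "persistent", peak = 0.7))
  }
  list(background = tissue_class_spec(0L, bg$mean, bg$sd, 0.0, 0.0),
       fat = tissue_class_spec(1L, fat$mean, fat$sd, 0.40, 0.05),
       glandular = tissue_class_spec(2L, gl$mean, gl$sd, 2.16, 0.40,
                                     enhancement = list(shape = "persistent",
                                                        peak = 0.25)),
       lesion = lesion)
}

# Relative enhancement fraction at each DCE frame for a curve descriptor.
enhancement_fractions <- function(enh, n_frames) {
  shape <- enh$shape %||% "none"
  k <- seq_len(n_frames)
  switch(shape,
         none = rep(0, n_frames),
         persistent = enh$peak * k / n_frames,
         washin_washout = {
           pf <- enh$peak_frame %||% max(2, round(n_frames / 3))
           fin <- enh$final %||% (0.7 * enh$peak)
           up <- enh$peak * pmin(k, pf) / pf
           down <- enh$peak + (fin - enh$peak) * (k - pf) / (n_frames - pf)
           ifelse(k <= pf, up, down)
         },
         stopf("unknown enhancement shape '%s'", shape))
}

#' Phantom specification
#'
#' Describes one synthetic co-registered multiparametric study: grid, voxel
#' spacing, DCE sampling, DWI b-values, the four tissue class specs, lesion
#' phenotype and geometry, additive noise level and RNG seed.
#'
#' Defaults: 64 x 64 x 8 voxels at 1 x 1 x 3 mm, 8 DCE frames,
#' b = (0, 800) s/mm^2. `noise_sd` is the additive Gaussian noise SD expressed
#' as a fraction of each channel's clean dynamic range; the default 0.02
#' corresponds to an SNR of roughly 50, typical of 3-T breast imaging.
#'
#' @param grid_shape integer triple, voxels.
#' @param voxel_spacing real triple, mm.
#' @param n_dce_frames number of DCE frames (positive).
#' @param b_values pair of b-values (s/mm^2), low then high.
#' @param class_specs list of four [tissue_class_spec]; defaults to
#'   [default_class_specs] for the phenotype.
#' @param lesion_phenotype `"malignant"` or `"benign"`.
#' @param lesion_radius_voxels in-plane lesion radius, voxels.
#' @param lesion_center lesion centre (voxel triple); default grid centre.
#' @param noise_sd fractional additive Gaussian noise level.
#' @param heterogeneity_amp amplitude of the smooth intra-lesion intensity
#'   field (fraction of signal; 0 disables).
#' @param seed RNG seed for noise and heterogeneity phases.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 8),
                         voxel_spacing = c(1, 1, 3),
                         n_dce_frames = 8, b_values = c(0, 800),
                         class_specs = NULL,
                         lesion_phenotype = c("malignant", "benign"),
                         lesion_radius_voxels = 6,
                         lesion_center = NULL,
                         noise_sd = 0.02,
                         heterogeneity_amp = 0.05,
                         seed = 1L) {
  lesion_phenotype <- match.arg(lesion_phenotype)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape <= 0))
    stopf("grid_shape must be 3 positive integers")
  if (n_dce_frames < 1) stopf("n_dce_frames must be positive")
  if (length(b_values) != 2L || any(b_values < 0) || b_values[2] <= b_values[1])
    stopf("b_values must be an increasing non-negative pair (s/mm^2)")
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  if (is.null(class_specs)) class_specs <- default_class_specs(lesion_phenotype)
  need <- c("background", "fat", "glandular", "lesion")
  if (!all(need %in% names(class_specs)))
    stopf("class_specs must contain all of: %s (missing %s)",
          paste(need, collapse = ", "),
          paste(setdiff(need, names(class_specs)), collapse = ", "))
  if (lesion_radius_voxels <= 0 ||
      lesion_radius_voxels >= min(grid_shape[1:2]) / 2)
    stopf("lesion radius must be positive and smaller than half the smallest in-plane grid dimension")
  if (is.null(lesion_center)) lesion_center <- (grid_shape + 1) / 2
  structure(list(grid_shape = grid_shape,
                 voxel_spacing = as.numeric(voxel_spacing),
                 n_dce_frames = as.integer(n_dce_frames),
                 b_values = as.numeric(b_values),
                 class_specs = class_specs,
                 lesion_phenotype = lesion_phenotype,
                 lesion_radius_voxels = lesion_radius_voxels,
                 lesion_center = as.numeric(lesion_center),
                 noise_sd = noise_sd,
                 heterogeneity_amp = heterogeneity_amp,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Ellipsoid mask helper on voxel-index coordinates.
ellipsoid_mask <- function(shape, center, semi) {
  x <- (seq_len(shape[1]) - center[1]) / semi[1]
  y <- (seq_len(shape[2]) - center[2]) / semi[2]
  z <- (seq_len(shape[3]) - center[3]) / semi[3]
  d2 <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  d2 <= 1
}

#' Generate one synthetic multiparametric phantom study
#'
#' Builds a four-class anatomy (background, fat shell, glandular core, one
#' ellipsoidal lesion), synthesizes channels `T1w`, `T2w`, `DWI_b0`,
#' `DWI_b<high>`, `ADC` and the DCE frames, and returns the study with its
#' ground-truth label map. The high-b DWI follows the monoexponential forward
#' model `S_b = S_0 * exp(-b * ADC)` per class; the ADC channel is then
#' derived from the (possibly noisy) DWI pair via [compute_adc], so at
#' `noise_sd = 0` it equals the class ADC values exactly. Identical specs with
#' identical seeds give bit-identical output.
#'
#' @param spec a [phantom_spec].
#' @return object of class `phantom_study`: list with `study` ([mp_study]),
#'   `truth` ([label_map]), `lesion_phenotype`, `lesion_volume_mm3`, `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shp <- spec$grid_shape
  sp <- spec$voxel_spacing
  ctr <- (shp + 1) / 2

  breast <- ellipsoid_mask(shp, ctr, c(0.42, 0.42, 0.48) * shp)
  gland <- ellipsoid_mask(shp, ctr, c(0.42, 0.42, 0.48) * shp * 0.55)
  r <- spec$lesion_radius_voxels
  rz <- max(1, r * sp[1] / sp[3])
  lesion <- ellipsoid_mask(shp, spec$lesion_center, c(r, r, rz))

  labels <- array(0L, shp)
  labels[breast] <- 1L
  labels[gland] <- 2L
  labels[lesion] <- 3L
  classes <- list(`0` = spec$class_specs$background,
                  `1` = spec$class_specs$fat,
                  `2` = spec$class_specs$glandular,
                  `3` = spec$class_specs$lesion)

  b_high <- spec$b_values[2]
  nf <- spec$n_dce_frames
  with_seed(spec$seed, {
    # smooth multiplicative heterogeneity field inside the lesion
    het <- array(0, shp)
    if (spec$heterogeneity_amp > 0) {
      ph <- runif(3, 0, 2 * pi)
      gx <- sin(2 * pi * 3 * seq_len(shp[1]) / shp[1] + ph[1])
      gy <- sin(2 * pi * 3 * seq_len(shp[2]) / shp[2] + ph[2])
      gz <- sin(2 * pi * 2 * seq_len(shp[3]) / shp[3] + ph[3])
      het <- spec$heterogeneity_amp *
        outer(outer(gx, gy, `+`), gz, `+`) / 3
      het[!lesion] <- 0
    }

    fill <- function(field) {
      v <- array(0, shp)
      for (cl in names(classes)) v[labels == as.integer(cl)] <- field(classes[[cl]])
      v
    }
    t1w <- fill(function(cs) cs$per_channel_mean[["T1w"]]) * (1 + het)
    t2w <- fill(function(cs) cs$per_channel_mean[["T2w"]]) * (1 + het)
    b0 <- fill(function(cs) cs$per_channel_mean[["DWI_b0"]]) * (1 + het)
    dce_base <- fill(function(cs) cs$per_channel_mean[["DCE_base"]]) * (1 + het)
    adc_true <- fill(function(cs) cs$adc_mean)
    bhigh <- b0 * exp(-b_high * adc_true / 1000)

    dce <- lapply(seq_len(nf), function(k) {
      ek <- fill(function(cs)
        enhancement_fractions(cs$enhancement, nf)[k])
      dce_base * (1 + ek)
    })
    names(dce) <- sprintf("DCE_%02d", seq_len(nf))

    channels <- c(list(T1w = t1w, T2w = t2w, DWI_b0 = b0), dce)
    channels[[sprintf("DWI_b%d", round(b_high))]] <- bhigh
    if (spec$noise_sd > 0) {
      for (nm in names(channels)) {
        scale <- diff(range(channels[[nm]]))
        if (scale <= 0) scale <- max(abs(channels[[nm]]), 1)
        channels[[nm]] <- channels[[nm]] +
          array(rnorm(prod(shp), 0, spec$noise_sd * scale), shp)
      }
    }
    # low-signal (air) voxels are masked from the ADC map at 3x the noise
    # level, as clinical ADC software does; without noise the floor is inert
    adc_floor <- max(1e-6, 3 * spec$noise_sd * diff(range(b0)))
    channels$ADC <- compute_adc(channels$DWI_b0,
                                channels[[sprintf("DWI_b%d", round(b_high))]],
                                b_high, eps = adc_floor)
    order <- c("T1w", "T2w", "DWI_b0", sprintf("DWI_b%d", round(b_high)),
               "ADC", names(dce))
    study <- mp_study(channels, voxel_spacing = sp,
                      subject_id = sprintf("phantom_seed%d", spec$seed),
                      channel_order = order)
    structure(list(study = study,
                   truth = label_map(labels),
                   lesion_phenotype = spec$lesion_phenotype,
                   lesion_volume_mm3 = sum(labels == 3L) * prod(sp),
                   spec = spec),
              class = "phantom_study")
  })
}

#' Generate a cohort of jittered phantom studies
#'
#' Per-subject specs are derived from `base_spec` with deterministic
#' per-subject seeds: lesion centre and radius are jittered, class signal
#' means and ADC means are drawn around their class means using the class SDs
#' (so the cohort-level ADC distribution matches the configured mean +/- SD),
#' and lesion enhancement peaks get multiplicative log-normal jitter
#' reflecting the large reported K-trans spread. The first
#' `round(n * benign_fraction)` subjects are benign, the rest malignant.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param benign_fraction fraction of benign phenotypes in \[0, 1\].
#' @param base_spec template [phantom_spec] (phenotype field is overridden
#'   per subject).
#' @param seed cohort seed.
#' @param jitter_intensities draw per-subject class means around the class
#'   SDs (`TRUE`, the stated cohort world); `FALSE` jitters geometry only,
#'   giving a fully deterministic intensity world for noiseless checks.
#' @return list of `phantom_study`, with subject ids `sub001`, `sub002`, ...
#' @export
generate_cohort <- function(n_subjects, benign_fraction = 0.5,
                            base_spec = phantom_spec(), seed = 1L,
                            jitter_intensities = TRUE) {
  if (n_subjects < 2) stopf("n_subjects must be >= 2")
  if (benign_fraction < 0 || benign_fraction > 1)
    stopf("benign_fraction must be in [0, 1]")
  n_benign <- round(n_subjects * benign_fraction)
  phenos <- c(rep("benign", n_benign),
              rep("malignant", n_subjects - n_benign))
  seeds <- derive_seeds(seed, n_subjects)
  lapply(seq_len(n_subjects), function(i) {
    sspec <- with_seed(seeds[i], {
      cs <- default_class_specs(phenos[i])
      if (jitter_intensities) {
        for (nm in names(cs)) {
          jit <- rnorm(length(cs[[nm]]$per_channel_mean), 0,
                       cs[[nm]]$per_channel_sd)
          cs[[nm]]$per_channel_mean <- pmax(cs[[nm]]$per_channel_mean + jit, 1)
          cs[[nm]]$adc_mean <- max(cs[[nm]]$adc_mean +
                                     rnorm(1, 0, cs[[nm]]$adc_sd), 0)
          if ((cs[[nm]]$enhancement$peak %||% 0) > 0 && nm == "lesion")
            cs[[nm]]$enhancement$peak <-
              cs[[nm]]$enhancement$peak * exp(rnorm(1, 0, 0.25))
        }
      }
      ctr_jit <- base_spec$lesion_center +
        c(runif(2, -3, 3), runif(1, -0.5, 0.5))
      rad <- base_spec$lesion_radius_voxels * runif(1, 0.8, 1.2)
      phantom_spec(grid_shape = base_spec$grid_shape,
                   voxel_spacing = base_spec$voxel_spacing,
                   n_dce_frames = base_spec$n_dce_frames,
                   b_values = base_spec$b_values,
                   class_specs = cs,
                   lesion_phenotype = phenos[i],
                   lesion_radius_voxels = rad,
                   lesion_center = ctr_jit,
                   noise_sd = base_spec$noise_sd,
                   heterogeneity_amp = base_spec$heterogeneity_amp,
                   seed = seeds[i])
    })
    ph <- generate_phantom(sspec)
    ph$study$subject_id <- sprintf("sub%03d", i)
    ph
  })
}

#' Write a cohort to disk with a manifest table
#'
#' Each study is written via [write_study] (with truth labels); a delimited
#' `cohort_manifest.csv` records subject id, phenotype, lesion volume and the
#' per-study manifest path.
#'
#' @param cohort list of `phantom_study` from [generate_cohort].
#' @param dir output directory.
#' @return path of the cohort manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(ph) {
    sdir <- file.path(dir, ph$study$subject_id)
    mp <- write_study(ph$study, sdir, truth = ph$truth)
    data.frame(subject_id = ph$study$subject_id,
               phenotype = ph$lesion_phenotype,
               lesion_volume_mm3 = ph$lesion_volume_mm3,
               manifest = mp, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  out <- file.path(dir, "cohort_manifest.csv")
  write.csv(tab, out, row.names = FALSE)
  invisible(out)
}
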
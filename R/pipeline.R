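#' Default pipeline configuration
#'
#' Every tunable of the pipeline with its default; the reported network
#' hyperparameters (five layers of ten nodes, L2 0.001, sparsity proportion
#' 0.25, sparsity weight 4, the seven-ratio cost grid) appear here explicitly
#' and are echoed into the run report. Override any subset via a nested list
#' or a YAML/JSON config file.
#'
#' @param overrides nested list (or path to a YAML/JSON file) of overrides.
#' @return full configuration list.
#' @export
pipeline_config <- function(overrides = NULL) {
  cfg <- list(
    seed = 1L,
    cohort = list(n_subjects = 20L, benign_fraction = 0.5,
                  grid_shape = c(64L, 64L, 8L), voxel_spacing = c(1, 1, 3),
                  n_dce_frames = 8L, b_values = c(0, 800),
                  lesion_radius_voxels = 6, noise_sd = 0.02,
                  heterogeneity_amp = 0.05, jitter_intensities = TRUE),
    signatures = list(tolerance_fraction = 0.05, cap_per_class = 1000L,
                      n_seeds_per_class = 3L),
    eigenimage = list(ridge = 1e-6, keep_largest = TRUE),
    ssae = list(l2_penalty = 0.001, sparsity_proportion = 0.25,
                sparsity_weight = 4, max_epochs = 400L,
                fine_tune_epochs = 200L, learning_rate = 0.1,
                momentum = 0.9, n_layers = 5L, d_hidden = 10L,
                fine_tune = TRUE),
    classifier = list(cv = "loocv", ratios = cost_ratio_grid(),
                      feature_mode = "node_stats"),
    evaluation = list(truth = "phantom"))
  if (is.character(overrides)) overrides <- read_config_file(overrides)
  if (!is.null(overrides)) cfg <- modify_deep(cfg, overrides)
  cfg
}

read_config_file <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

modify_deep <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- modify_deep(base[[nm]], over[[nm]])
    else base[[nm]] <- over[[nm]]
  }
  base
}

pipeline_stages <- function() c("simulate", "signatures", "ei_truth",
                                "train_seg", "segment", "train_clf",
                                "classify", "evaluate")

ssae_config_from <- function(cfg, seed) {
  s <- cfg$ssae
  ssae_config(l2_penalty = s$l2_penalty,
              sparsity_proportion = s$sparsity_proportion,
              sparsity_weight = s$sparsity_weight,
              max_epochs = s$max_epochs,
              fine_tune_epochs = s$fine_tune_epochs,
              learning_rate = s$learning_rate, momentum = s$momentum,
              n_layers = s$n_layers, d_hidden = s$d_hidden,
              seed = seed, fine_tune = isTRUE(s$fine_tune))
}

#' Run the full segmentation + classification pipeline
#'
#' Executes phantom simulation, signature harvesting, eigenimage ground
#' truth, twofold segmentation training, voxelwise segmentation, lesion-SAE
#' + cost-weighted-SVM classifier training, per-subject classification and
#' evaluation. All artifacts (NIfTI volumes, CSV tables, JSON models) are
#' written under `outdir`; `summary.json` holds per-subject Dice, cohort
#' AUC/sensitivity/specificity, volume agreement and every seed and config
#' switch. With `resume = TRUE`, stages whose artifacts exist under an
#' unchanged config are reloaded from disk instead of recomputed.
#'
#' @param config config list / file path / `NULL` (defaults); see
#'   [pipeline_config].
#' @param outdir output directory.
#' @param seed master seed (overrides the config seed when given).
#' @param stages subset of [pipeline_stages()] to run through (all stages up
#'   to the last named one are included).
#' @param resume reuse completed stage artifacts when possible.
#' @param quiet suppress progress messages.
#' @return the summary list, invisibly (or the partial state if stopped
#'   before `evaluate`).
#' @export
run_pipeline <- function(config = NULL, outdir = "mpdl_run", seed = NULL,
                         stages = pipeline_stages(), resume = FALSE,
                         quiet = FALSE) {
  cfg <- if (is.list(config) && !is.null(config$cohort)) config
         else pipeline_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  stages <- match.arg(stages, pipeline_stages(), several.ok = TRUE)
  last <- max(match(stages, pipeline_stages()))
  todo <- pipeline_stages()[seq_len(last)]
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "pipeline.log")
  say <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    cat(msg, "\n", file = log_path, append = TRUE)
    if (!quiet) message(msg)
  }
  cfg_hash <- digest::digest(cfg)
  state_path <- file.path(outdir, "state.json")
  state <- if (resume && file.exists(state_path))
    jsonlite::read_json(state_path, simplifyVector = TRUE) else list()
  if (!identical(state$config_hash, cfg_hash)) state <- list(done = character(0))
  state$config_hash <- cfg_hash
  mark_done <- function(stage) {
    state$done <<- union(state$done, stage)
    jsonlite::write_json(state, state_path, auto_unbox = TRUE)
  }
  can_skip <- function(stage, files) {
    resume && stage %in% state$done && all(file.exists(files))
  }
  seeds <- derive_seeds(cfg$seed, 8L)
  names(seeds) <- pipeline_stages()
  say("run starting: seed %d, config hash %s", cfg$seed, cfg_hash)

  env <- new.env()

  run_stage <- function(stage, fn) {
    t0 <- Sys.time()
    ok <- tryCatch({ fn(); TRUE },
                   error = function(e) {
                     say("stage '%s' FAILED: %s", stage, conditionMessage(e))
                     stopf("pipeline aborted at stage '%s': %s (artifacts under %s)",
                           stage, conditionMessage(e), outdir)
                   })
    say("stage '%s' done (%.1fs)", stage,
        as.numeric(difftime(Sys.time(), t0, units = "secs")))
    mark_done(stage)
  }

  # -- simulate --------------------------------------------------------------
  if ("simulate" %in% todo) {
    cman <- file.path(outdir, "cohort", "cohort_manifest.csv")
    if (can_skip("simulate", cman)) {
      say("simulate: reusing artifacts")
      env$cohort <- load_cohort(cman)
    } else run_stage("simulate", function() {
      cc <- cfg$cohort
      base <- phantom_spec(grid_shape = cc$grid_shape,
                           voxel_spacing = cc$voxel_spacing,
                           n_dce_frames = cc$n_dce_frames,
                           b_values = cc$b_values,
                           lesion_radius_voxels = cc$lesion_radius_voxels,
                           noise_sd = cc$noise_sd,
                           heterogeneity_amp = cc$heterogeneity_amp)
      env$cohort <- generate_cohort(cc$n_subjects, cc$benign_fraction, base,
                                    seed = seeds[["simulate"]],
                                    jitter_intensities =
                                      !isFALSE(cc$jitter_intensities))
      write_cohort(env$cohort, file.path(outdir, "cohort"))
    })
  }

  norm_studies <- function() {
    if (is.null(env$norm)) {
      env$bounds <- compute_channel_bounds(lapply(env$cohort, `[[`, "study"))
      env$norm <- lapply(env$cohort, function(p)
        normalize_channels(p$study, bounds = env$bounds))
    }
    env$norm
  }

  # -- signatures ------------------------------------------------------------
  if ("signatures" %in% todo) {
    sdir <- file.path(outdir, "signatures")
    files <- file.path(sdir, sprintf("%s.csv", subject_ids(env$cohort)))
    if (can_skip("signatures", files)) {
      say("signatures: reusing artifacts")
      env$harvested <- lapply(files, read_signature_set)
    } else run_stage("signatures", function() {
      dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
      ns <- norm_studies()
      env$harvested <- lapply(seq_along(env$cohort), function(i) {
        hs <- harvest_signatures(ns[[i]],
                auto_seeds(env$cohort[[i]]$truth,
                           cfg$signatures$n_seeds_per_class,
                           seed = seeds[["signatures"]] + i),
                cfg$signatures$tolerance_fraction)
        write_signature_set(hs, files[i])
        hs
      })
    })
  }

  # -- ei_truth --------------------------------------------------------------
  if ("ei_truth" %in% todo) {
    edir <- file.path(outdir, "ei")
    files <- file.path(edir, sprintf("%s_ei_mask.nii", subject_ids(env$cohort)))
    if (can_skip("ei_truth", files)) {
      say("ei_truth: reusing artifacts")
      env$ei_masks <- lapply(files, function(f) nifti_read(f)$data > 0.5)
    } else run_stage("ei_truth", function() {
      dir.create(edir, recursive = TRUE, showWarnings = FALSE)
      ns <- norm_studies()
      env$ei_masks <- lapply(seq_along(env$cohort), function(i) {
        hv <- env$harvested[[i]]
        pick <- function(cl) signature_set(
          hv$signatures[hv$labels == cl, , drop = FALSE],
          hv$labels[hv$labels == cl])
        wts <- fit_eigenimage_filter(pick(3L),
                 bind_signature_sets(list(pick(2L), pick(1L))),
                 ridge = cfg$eigenimage$ridge)
        write_eigen_filter(wts, file.path(edir,
          sprintf("%s_ei_weights.json", env$cohort[[i]]$study$subject_id)))
        ei <- apply_eigenimage(ns[[i]], wts)
        mask <- threshold_eigenimage(ei, array(TRUE, dim(ei)),
                                     keep_largest = cfg$eigenimage$keep_largest)
        nifti_write(ei, file.path(edir,
          sprintf("%s_ei.nii", env$cohort[[i]]$study$subject_id)),
          spacing = env$cohort[[i]]$study$voxel_spacing)
        nifti_write(mask * 1L, files[i],
          spacing = env$cohort[[i]]$study$voxel_spacing, datatype = "int16")
        mask
      })
    })
  }

  # -- train_seg -------------------------------------------------------------
  if ("train_seg" %in% todo) {
    mdir <- file.path(outdir, "models")
    files <- c(file.path(mdir, "ssae_fold1.json"),
               file.path(mdir, "ssae_fold2.json"),
               file.path(mdir, "folds.json"))
    if (can_skip("train_seg", files)) {
      say("train_seg: reusing artifacts")
      env$fold_models <- list(read_ssae_model(files[1]),
                              read_ssae_model(files[2]))
      env$folds <- lapply(jsonlite::read_json(files[3],
                                              simplifyVector = TRUE), as.integer)
    } else run_stage("train_seg", function() {
      dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
      env$folds <- stratified_halves(
        vapply(env$cohort, `[[`, character(1), "lesion_phenotype"),
        seeds[["train_seg"]])
      env$fold_models <- lapply(1:2, function(f) {
        ts <- sample_balanced(env$harvested[env$folds[[f]]],
                              cfg$signatures$cap_per_class,
                              seed = seeds[["train_seg"]] + f)
        m <- train_ssae(ts, ssae_config_from(cfg, seeds[["train_seg"]] + 10 + f),
                        channel_order = env$cohort[[1]]$study$channel_order)
        write_ssae_model(m, files[f])
        m
      })
      jsonlite::write_json(env$folds, files[3])
    })
  }

  # -- segment ---------------------------------------------------------------
  if ("segment" %in% todo) {
    gdir <- file.path(outdir, "segmentations")
    files <- file.path(gdir, sprintf("%s_seg.nii", subject_ids(env$cohort)))
    if (can_skip("segment", files)) {
      say("segment: reusing artifacts")
      env$segs <- lapply(files, function(f) label_map(nifti_read(f)$data))
    } else run_stage("segment", function() {
      dir.create(gdir, recursive = TRUE, showWarnings = FALSE)
      ns <- norm_studies()
      env$segs <- lapply(seq_along(env$cohort), function(i) {
        f <- if (i %in% env$folds[[1]]) 2L else 1L  # opposite-fold model
        seg <- segment_study(env$fold_models[[f]], ns[[i]])
        nifti_write(seg$labels, files[i],
                    spacing = env$cohort[[i]]$study$voxel_spacing,
                    datatype = "int16")
        seg
      })
    })
  }

  # -- train_clf -------------------------------------------------------------
  if ("train_clf" %in% todo) {
    cdir <- file.path(outdir, "classifier")
    files <- c(file.path(cdir, "lesion_sae.json"),
               file.path(cdir, "features.csv"),
               file.path(cdir, "svm.json"),
               file.path(cdir, "grid.json"))
    if (can_skip("train_clf", files)) {
      say("train_clf: reusing artifacts")
      env$features <- read.csv(files[2], check.names = FALSE)
      env$svm <- read_svm_model(files[3])
      env$grid <- jsonlite::read_json(files[4], simplifyVector = TRUE)
    } else run_stage("train_clf", function() {
      dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
      ns <- norm_studies()
      records <- lapply(seq_along(env$cohort), function(i)
        lesion_from_segmentation(ns[[i]], env$segs[[i]],
                                 label = env$cohort[[i]]$lesion_phenotype))
      keep <- !vapply(records, is.null, logical(1))
      if (sum(keep) < 4L) stopf("too few segmented lesions to classify")
      records <- records[keep]
      pooled <- do.call(rbind, lapply(records, `[[`, "signatures"))
      sae <- train_lesion_sae(pooled,
               ssae_config_from(cfg, seeds[["train_clf"]]))
      jsonlite::write_json(list(W_enc = sae$W_enc, b_enc = sae$b_enc,
                                W_dec = sae$W_dec, b_dec = sae$b_dec,
                                activation = sae$activation),
                           files[1], matrix = "rowmajor", digits = NA,
                           auto_unbox = TRUE)
      feats <- t(vapply(records, function(r) {
        r$encoded <- sae_encode(sae, r$signatures)
        build_feature_vector(r, cfg$classifier$feature_mode)
      }, numeric(feature_length(cfg))))
      env$features <- data.frame(subject_id = vapply(records, `[[`,
                                                     character(1), "subject_id"),
                                 label = vapply(records, `[[`,
                                                character(1), "label"),
                                 feats, check.names = FALSE)
      write.csv(env$features, files[2], row.names = FALSE)
      res <- train_cost_weighted_svm(feats,
               env$features$label, cfg$classifier$ratios,
               cv = cfg$classifier$cv, seed = seeds[["train_clf"]])
      env$svm <- res$model
      env$grid <- res$grid
      write_svm_model(res$model, files[3])
      jsonlite::write_json(unclass(res$grid), files[4], auto_unbox = TRUE,
                           digits = NA)
    })
  }

  # -- classify --------------------------------------------------------------
  if ("classify" %in% todo) {
    pfile <- file.path(outdir, "classifier", "predictions.csv")
    if (can_skip("classify", pfile)) {
      say("classify: reusing artifacts")
      env$predictions <- read.csv(pfile)
    } else run_stage("classify", function() {
      fcols <- setdiff(names(env$features), c("subject_id", "label"))
      cl <- classify_lesion(env$svm, as.matrix(env$features[, fcols]))
      env$predictions <- data.frame(subject_id = env$features$subject_id,
                                    label = env$features$label,
                                    score = cl$score, predicted = cl$label)
      write.csv(env$predictions, pfile, row.names = FALSE)
    })
  }

  # -- evaluate --------------------------------------------------------------
  if ("evaluate" %in% todo) {
    run_stage("evaluate", function() {
      truth_kind <- cfg$evaluation$truth
      dice_rows <- lapply(seq_along(env$cohort), function(i) {
        ref <- if (truth_kind == "phantom") env$cohort[[i]]$truth$labels == 3L
               else env$ei_masks[[i]]
        data.frame(subject_id = env$cohort[[i]]$study$subject_id,
                   phenotype = env$cohort[[i]]$lesion_phenotype,
                   dice = dice(env$segs[[i]]$labels == 3L, ref))
      })
      dice_tab <- do.call(rbind, dice_rows)
      write.csv(dice_tab, file.path(outdir, "dice.csv"), row.names = FALSE)
      vols_seg <- vapply(seq_along(env$cohort), function(i)
        lesion_volume(env$segs[[i]]$labels == 3L,
                      env$cohort[[i]]$study$voxel_spacing), numeric(1))
      vols_ref <- vapply(env$cohort, `[[`, numeric(1), "lesion_volume_mm3")
      ok <- vols_ref > 0
      ba <- bland_altman(vols_seg[ok], vols_ref[ok])
      cls <- if (!is.null(env$grid)) {
        y <- env$features$label
        sc <- env$grid$cv_scores
        roc <- roc_auc(sc, y)
        cm <- confusion_metrics(ifelse(sc > 0, "malignant", "benign"), y)
        list(cv = cfg$classifier$cv, best_ratio = env$grid$best_ratio,
             auc = roc$auc, sensitivity = cm$sensitivity,
             specificity = cm$specificity, ppv = cm$ppv, npv = cm$npv)
      } else NULL
      summ <- list(
        seeds = as.list(seeds), config = cfg,
        segmentation = list(
          truth = truth_kind,
          per_subject = dice_tab,
          mean_dice_malignant = mean(dice_tab$dice[dice_tab$phenotype ==
                                                     "malignant"]),
          mean_dice_benign = mean(dice_tab$dice[dice_tab$phenotype ==
                                                  "benign"])),
        classification = cls,
        volume_agreement = list(
          mean_percent_difference = mean(percent_volume_difference(
            vols_seg[ok], vols_ref[ok])),
          sd_percent_difference = sd(percent_volume_difference(
            vols_seg[ok], vols_ref[ok])),
          correlation = cor(vols_seg[ok], vols_ref[ok]),
          bland_altman = list(mean_diff = ba$mean_diff,
                              loa_low = ba$loa_low, loa_high = ba$loa_high)))
      jsonlite::write_json(summ, file.path(outdir, "summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           dataframe = "rows")
      env$summary <- summ
    })
  }
  invisible(env$summary %||% as.list(env))
}

subject_ids <- function(cohort) vapply(cohort, function(p) p$study$subject_id,
                                       character(1))

feature_length <- function(cfg) {
  d <- cfg$ssae$d_hidden
  if (cfg$classifier$feature_mode == "node_stats") 4L * d
  else 4L * d + 4L * (5L + cfg$cohort$n_dce_frames)
}

load_cohort <- function(manifest_csv) {
  tab <- read.csv(manifest_csv, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tab)), function(i) {
    st <- read_study(tab$manifest[i])
    structure(list(study = st$study, truth = st$truth,
                   lesion_phenotype = tab$phenotype[i],
                   lesion_volume_mm3 = tab$lesion_volume_mm3[i], spec = NULL),
              class = "phantom_study")
  })
}

#' Validate a trained segmentation model on an external cohort
#'
#' Segments each validation study with the given model and compares MPDL
#' lesion volumes against the cohort's reference volumes: per-subject percent
#' differences, Pearson correlation and Bland-Altman limits of agreement.
#' Channel layout is checked before segmentation, so axis-permuted but
#' channel-consistent studies validate cleanly.
#'
#' @param model a trained [ssae_model].
#' @param cohort list of `phantom_study` (or anything with `study`, `truth`,
#'   `lesion_volume_mm3`); reference volumes must be present.
#' @return list with the per-subject table and the agreement statistics.
#' @export
validate_external_cohort <- function(model, cohort) {
  vols_ref <- vapply(cohort, `[[`, numeric(1), "lesion_volume_mm3")
  if (any(!is.finite(vols_ref)))
    stopf("cohort lacks reference lesion volumes")
  rows <- lapply(cohort, function(ph) {
    ns <- normalize_channels(ph$study)
    seg <- segment_study(model, ns)
    v <- lesion_volume(seg$labels == 3L, ph$study$voxel_spacing)
    data.frame(subject_id = ph$study$subject_id, volume_mpdl = v,
               volume_reference = ph$lesion_volume_mm3)
  })
  tab <- do.call(rbind, rows)
  ok <- tab$volume_reference > 0
  pd <- percent_volume_difference(tab$volume_mpdl[ok], tab$volume_reference[ok])
  list(per_subject = tab,
       mean_percent_difference = mean(pd),
       sd_percent_difference = sd(pd),
       correlation = cor(tab$volume_mpdl[ok], tab$volume_reference[ok]),
       bland_altman = bland_altman(tab$volume_mpdl[ok],
                                   tab$volume_reference[ok]))
}
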
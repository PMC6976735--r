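#' Pipeline configuration
#'
#' Assembles (or reads from YAML) the configuration driving
#' [run_pipeline()]: phantom geometry and contrast, preprocessing,
#' training profile and evaluation settings.  Every random stage derives
#' its seed from the single master `seed`, so a config reproduces a run.
#'
#' @param path Optional YAML file; its entries override the defaults.
#' @param ... Further overrides (same names as the returned list).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- list(
    seed = 1L,
    profile = "desk",
    n_subjects = 5L,
    k_folds = 5L,
    shape = c(80L, 80L, 32L),
    spacing = c(3, 3, 3),
    mr_noise_sd = 15,
    bias_amplitude = 0.05,
    ct_texture_sd = 0,
    n_patches = 40L,
    patch_side = 64L,
    min_body_fraction = 0.5,
    epochs = 12L,
    batch_size = 16L,
    predicted_slice_frac = 0.7,
    beam_angles = c(181, 179, 2),
    gamma_criteria = list(c(3, 3), c(2, 2), c(1, 1)),
    prescription = 20,
    n_beams_dose = 7L
  )
  if (!is.null(path)) {
    y <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, y)
  }
  cfg <- utils::modifyList(cfg, list(...))
  structure(cfg, class = "pipeline_config")
}

pipeline_contrast <- function(cfg) {
  contrast_model(noise_sd = c(t1 = cfg$mr_noise_sd, t2 = cfg$mr_noise_sd,
                              flair = cfg$mr_noise_sd),
                 bias_amplitude = cfg$bias_amplitude)
}

simulate_subject <- function(cfg, subject) {
  cm <- pipeline_contrast(cfg)
  sd_ph <- cfg$seed * 1000L + subject
  ph <- generate_head_phantom(shape = cfg$shape, spacing = cfg$spacing,
                              model = cm, texture_sd = cfg$ct_texture_sd,
                              seed = sd_ph)
  mr <- simulate_mr(ph$labels, cm, seed = sd_ph + 500L)
  list(labels = ph$labels, ct = ph$ct, mr = mr)
}

preprocess_subject <- function(sub) {
  mask <- compute_body_mask(sub$ct)
  filled <- fill_background(sub$ct, sub$mr, mask)
  c(sub, list(mask = mask, ct_f = filled$ct, mr_f = filled$mr))
}

standardize_subject <- function(sub, stds) {
  seqs <- unstack_sequences(sub$mr_f)
  std <- lapply(names(seqs), function(s)
    apply_intensity_standardizer(seqs[[s]], sub$mask, stds[[s]]))
  names(std) <- names(seqs)
  mr_std <- stack_sequences(std$t1, std$t2, std$flair)
  fill_background(sub$ct_f, mr_std, sub$mask)$mr
}

#' Run the full phantom-to-evaluation pipeline
#'
#' Executes, per cross-validation fold: phantom simulation, preprocessing
#' (masking, background fill, per-sequence intensity standardization fitted
#' on the fold's training subjects), patch sampling, conditional-GAN
#' training on the desk profile, full-size slice-wise prediction for the
#' held-out subject, missing-slice compensation, image-quality evaluation,
#' and dosimetric evaluation (EPL sweep, gamma analysis, DVH metrics),
#' finishing with paired statistics across folds.  All artifacts land in
#' `out_dir` together with a machine-readable `summary.json` stamped with
#' the config hash and seeds; a failing stage aborts with its name, keeping
#' partial outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param verbose Print per-stage progress.
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("mr2sct_run"),
                         verbose = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))

  ids <- seq_len(config$n_subjects)
  folds <- stage("folds", make_cv_folds(ids, config$k_folds, config$seed))

  say("simulating %d phantom subjects ...", config$n_subjects)
  subjects <- stage("simulate", lapply(ids, function(s) simulate_subject(config, s)))
  subjects <- stage("preprocess", lapply(subjects, preprocess_subject))

  ph_dir <- file.path(out_dir, "phantoms")
  dir.create(ph_dir, showWarnings = FALSE)
  ph_hashes <- character(length(ids))
  for (s in ids) {
    p <- file.path(ph_dir, sprintf("subject%02d_ct.nii.gz", s))
    write_volume(subjects[[s]]$ct, p)
    ph_hashes[s] <- unname(tools::md5sum(p))
  }

  fold_results <- list()
  for (fi in seq_len(folds$k)) {
    test_ids <- folds$folds[[fi]]
    train_ids <- setdiff(ids, test_ids)
    say("fold %d: train on {%s}, test on {%s}", fi,
        paste(train_ids, collapse = ","), paste(test_ids, collapse = ","))

    stds <- stage("standardizer", {
      out <- lapply(c("t1", "t2", "flair"), function(sq) {
        tr <- lapply(train_ids, function(s)
          list(mr = unstack_sequences(subjects[[s]]$mr_f)[[sq]],
               mask = subjects[[s]]$mask))
        fit_intensity_standardizer(tr)
      })
      names(out) <- c("t1", "t2", "flair")
      out
    })

    patches <- stage("patches", {
      pl <- list()
      for (s in train_ids) {
        mr_std <- standardize_subject(subjects[[s]], stds)
        ps <- sample_patches(mr_std, subjects[[s]]$ct_f, subjects[[s]]$mask,
                             n = config$n_patches, side = config$patch_side,
                             min_body_fraction = config$min_body_fraction,
                             seed = config$seed * 100L + s)
        for (i in seq_along(ps)) ps[[i]]$subject <- s
        pl <- c(pl, ps)
      }
      pl
    })

    prof <- cgan_profile(config$profile)
    tc <- prof$train
    tc$epochs <- as.integer(config$epochs)
    tc$batch_size <- as.integer(config$batch_size)
    tc$patch_side <- as.integer(config$patch_side)
    tc$seed <- config$seed + fi
    model <- stage("train", fit_cgan(patches, prof$gen, prof$disc, tc,
                                     verbose = FALSE))
    utils::write.csv(model$history,
                     file.path(out_dir, sprintf("history_fold%d.csv", fi)),
                     row.names = FALSE)

    per_test <- lapply(test_ids, function(s) {
      sub <- subjects[[s]]
      mr_std <- standardize_subject(sub, stds)
      sct_full <- stage("predict", predict_sct(model, mr_std))
      nsl <- dim(sub$ct$data)[3]
      nkeep <- max(1L, round(config$predicted_slice_frac * nsl))
      lo <- (nsl - nkeep) %/% 2 + 1L
      rng <- lo:(lo + nkeep - 1L)
      lut <- build_hu_lookup(crop_slices(sub$ct_f, rng), crop_slices(sct_full, rng),
                             crop_mask(sub$mask, rng))
      sct <- stage("assemble",
                   compensate_missing_slices(sct_full, sub$ct_f, rng, lut))
      qa <- stage("evaluate-image", region_mae(sct, sub$ct_f, sub$mask))
      prof_bins <- binned_difference(sct, sub$ct_f, sub$mask)

      iso <- round(dim(sub$ct$data) / 2)
      angs <- enumerate_beam_angles(config$beam_angles[1], config$beam_angles[2],
                                    config$beam_angles[3])
      epl <- stage("evaluate-dose",
                   epl_sweep(sub$ct_f, sct, sub$mask, iso, angs))
      beams <- lapply(seq(0, 359, length.out = config$n_beams_dose + 1)[-(config$n_beams_dose + 1)],
                      function(a) list(angle = a, mu = 0.004, width = 45))
      dose_r <- analytic_dose_grid(sub$mask, beams, config$prescription,
                                   iso = iso, ct = sub$ct_f)
      dose_s <- analytic_dose_grid(sub$mask, beams, config$prescription,
                                   iso = iso, ct = sct)
      gam <- lapply(config$gamma_criteria, function(cr)
        gamma_2d(dose_r, dose_s, dd = cr[1], dta = cr[2], slice = iso[3],
                 mask = sub$mask$data[, , iso[3]]))
      dvh_r <- dvh_metrics(dose_r, sub$mask)
      dvh_s <- dvh_metrics(dose_s, sub$mask)
      list(subject = s, mae = qa, bins = prof_bins, epl = epl, gamma = gam,
           dvh_r = dvh_r, dvh_s = dvh_s,
           iso_dose_r = dose_r$data[iso[1], iso[2], iso[3]],
           iso_dose_s = dose_s$data[iso[1], iso[2], iso[3]])
    })
    fold_results[[fi]] <- list(fold = fi, test_ids = test_ids,
                               final_val_l1 = utils::tail(model$history$g_l1_val, 1),
                               tests = per_test)
  }

  all_tests <- unlist(lapply(fold_results, `[[`, "tests"), recursive = FALSE)
  d50_r <- vapply(all_tests, function(t) t$dvh_r$D50, 0)
  d50_s <- vapply(all_tests, function(t) t$dvh_s$D50, 0)
  stats_d50 <- if (length(d50_r) >= 3) paired_compare(d50_s, d50_r) else NULL

  epl_tab <- do.call(rbind, lapply(all_tests, function(t) as.data.frame(t$epl)))
  utils::write.csv(epl_tab, file.path(out_dir, "epl_table.csv"), row.names = FALSE)

  summary <- list(
    config_hash = cfg_hash,
    seed = config$seed,
    folds = lapply(folds$folds, as.integer),
    phantom_hashes = ph_hashes,
    per_fold = lapply(fold_results, function(fr) list(
      fold = fr$fold,
      test_subjects = as.integer(fr$test_ids),
      final_val_l1_hu = fr$final_val_l1,
      mae = lapply(fr$tests, function(t) list(
        subject = t$subject, body = t$mae$mae_body, soft = t$mae$mae_soft,
        bone = t$mae$mae_bone)),
      gamma_pass = lapply(fr$tests, function(t)
        vapply(t$gamma, `[[`, 0, "pass_rate")),
      epl_mean_diff_mm = vapply(fr$tests, function(t)
        attr(t$epl, "summary")$mean, 0),
      iso_dose = lapply(fr$tests, function(t)
        list(rct = t$iso_dose_r, sct = t$iso_dose_s))
    )),
    paired_d50 = if (!is.null(stats_d50)) list(
      test = stats_d50$test, statistic = stats_d50$statistic,
      p_value = stats_d50$p_value) else NULL
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("run complete: %s", out_dir)
  invisible(summary)
}

crop_slices <- function(vol, rng) {
  image_volume(vol$data[, , rng, drop = FALSE], vol$spacing, vol$origin)
}

crop_mask <- function(mask, rng) {
  body_mask(mask$data[, , rng, drop = FALSE], mask$spacing, mask$origin)
}
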
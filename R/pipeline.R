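#' Simulate the imaging arm of a synthetic study
#'
#' Generates the atlas, per-patient lesion masks, and — for patients with
#' recurrent tumor — a noisy PET volume that is then segmented by TBR
#' thresholding (threshold 1.6 against the mean uptake of healthy brain,
#' here brain outside the T2/FLAIR lesion). The segmented PET mask, not the
#' generative truth, enters the overlap table, so the segmentation stage is
#' exercised end to end; the Dice agreement with the true tumor mask is
#' recorded per patient.
#'
#' @param config A [synthetic_config()].
#' @param tbr A [tbr_params()] used for the segmentation stage.
#' @param verbose Emit stage messages.
#' @return List with `atlas`, `lesions` (per subject), `overlaps`,
#'   `pet_dice` (named vector over PET-positive patients), `recurrent`
#'   (named logical).
#' @export
simulate_imaging <- function(config, tbr = tbr_params(threshold = 1.6),
                             verbose = FALSE) {
  cfg <- validate_synthetic_config(config)
  atlas <- generate_atlas(cfg)
  brain <- atlas_brain_mask(atlas)
  ids <- sprintf("P%03d", seq_len(cfg$n_patients))
  lesions <- list()
  pet_dice <- c()
  recurrent <- setNames(logical(length(ids)), ids)
  for (id in ids) {
    l <- generate_lesions(atlas, cfg, id)
    recurrent[id] <- attr(l, "recurrent")
    truth <- l$pet
    if (any(truth$mask)) {
      vol <- generate_pet_volume(atlas, truth, cfg$tbr_true, cfg$pet_noise_sd,
                                 seed = derive_seed(cfg$seed,
                                                    paste0("petvol_", id)))
      seg <- segment_tbr(vol, brain, brain & !l$flair$mask, tbr,
                         affine = atlas$affine, subject_id = id)
      pet_dice[id] <- dice_coefficient(seg$mask, truth$mask)
      l$pet <- seg
    }
    lesions[[id]] <- l
  }
  overlaps <- overlap_table(lesions, atlas)
  if (verbose)
    message(sprintf(
      "imaging: %d regions, %d patients, %d PET-positive, median flair %.1f mL",
      nrow(atlas$regions), length(ids), sum(recurrent),
      median(sapply(lesions, function(l) total_lesion_volume_ml(l$flair)))))
  list(atlas = atlas, lesions = lesions, overlaps = overlaps,
       pet_dice = pet_dice, recurrent = recurrent)
}

#' Plant a calibrated lesion-cognition effect into a configuration
#'
#' Chooses a planted region (by default the node whose T2/FLAIR overlap
#' fraction varies most across patients, i.e. the most informative one) and
#' calibrates its gamma so the expected Kendall tau-b between overlap
#' fraction and score equals `tau_target` under the configured noise.
#'
#' @param config A [synthetic_config()].
#' @param overlaps Overlap table of the generated patients.
#' @param test_name Test carrying the planted effect.
#' @param region_id Region to plant into; `NULL` picks automatically.
#' @param tau_target Target absolute tau-b.
#' @param atlas Atlas (used to restrict automatic choice to nodes).
#' @return The config with `planted_effects` set.
#' @export
plant_effect <- function(config, overlaps, test_name = "wordlist_immediate",
                         region_id = NULL, tau_target = 0.3, atlas = NULL) {
  cfg <- validate_synthetic_config(config)
  fr <- overlap_matrix(overlaps, "flair", "fraction")
  if (is.null(region_id)) {
    cand <- colnames(fr)
    if (!is.null(atlas)) {
      nodes <- atlas$regions$id[atlas$regions$kind == "node"]
      cand <- intersect(cand, as.character(nodes))
    }
    sds <- apply(fr[, cand, drop = FALSE], 2, sd)
    region_id <- as.integer(cand[which.max(sds)])
  }
  f <- fr[, as.character(region_id)]
  tk <- cfg$tests[cfg$tests$test == test_name, ]
  if (nrow(tk) != 1) stop("unknown test: ", test_name)
  # the screen sees the raw score, so the effective noise around the lesion
  # term includes the age and education contributions, not just sigma
  sigma_eff <- sqrt(tk$sigma^2 + (tk$beta_age * cfg$age_sd)^2 +
                      (tk$beta_edu * cfg$edu_sd)^2)
  gamma <- calibrate_planted_gamma(f, sigma_eff, tau_target,
                                   seed = derive_seed(cfg$seed, "calibrate"))
  cfg$planted_effects <- data.frame(region_id = region_id,
                                    test_name = test_name, gamma = gamma)
  cfg
}

#' Simulate the cohort arm: covariates, scores, matched controls
#'
#' Draws patient covariates and a healthy pool, generates scores (patients
#' receive the planted lesion effects through their overlap fractions,
#' controls do not), and selects the matched control group by propensity
#' matching on age, gender and education.
#'
#' @param config A [synthetic_config()].
#' @param overlaps Overlap table of the patients.
#' @param score_seed Seed for the score noise (vary it to replicate the
#'   cohort over fixed imaging).
#' @param verbose Emit stage messages.
#' @return List with `patients`, `controls` (matched), `pool`.
#' @export
simulate_cohort <- function(config, overlaps,
                            score_seed = derive_seed(config$seed,
                                                     "cognition"),
                            verbose = FALSE) {
  cfg <- validate_synthetic_config(config)
  pat_cov <- generate_covariates(cfg$n_patients, "patient", cfg,
                                 derive_seed(cfg$seed, "covariates_patients"))
  pool_n <- cfg$n_controls * cfg$control_pool_factor
  if (pool_n < cfg$n_patients)
    stop("control pool smaller than the patient group")
  pool_cov <- generate_covariates(pool_n, "control", cfg,
                                  derive_seed(cfg$seed, "covariates_pool"))
  all_cov <- rbind(pat_cov, pool_cov)
  scored <- generate_cognition(all_cov, cfg, overlaps, seed = score_seed)
  scored <- add_derived_scores(scored)
  patients <- scored[scored$group == "patient", , drop = FALSE]
  pool <- scored[scored$group == "control", , drop = FALSE]
  controls <- match_controls(patients, pool)
  if (verbose)
    message(sprintf("cohort: %d patients, %d matched controls (pool %d)",
                    nrow(patients), nrow(controls), nrow(pool)))
  list(patients = patients, controls = controls, pool = pool)
}

#' Run the full synthetic lesion-cognition pipeline
#'
#' Stages: imaging simulation (atlas, lesions, PET segmentation, overlaps) ->
#' cohort simulation (scores, propensity-matched controls) -> normative
#' deficit thresholds -> group comparison -> mass-univariate tau-b screen ->
#' base and node-augmented logistic deficit models -> (synthetic truth only)
#' recovery report. When `out_dir` is given, all tables are written as CSV/
#' JSON and a manifest with the config, seed, package version and MD5 hashes
#' of every output records the run; rerunning with the same config yields
#' identical hashes.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory, or `NULL` for an in-memory run.
#' @param alpha,family,measure,subgroup Screen options
#'   (see [correlation_screen()]).
#' @param cutoff Classification cutoff for the deficit models.
#' @param outcomes Outcomes to model; defaults to the planted tests, or the
#'   word-list immediate recall when nothing is planted.
#' @param verbose Emit stage messages.
#' @return List with `atlas`, `overlaps`, `pet_dice`, `cohort`,
#'   `thresholds`, `table1`, `screen`, `models`, `table2`, `recovery`,
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, alpha = 0.05,
                         family = c("per_atlas", "global"),
                         measure = c("fraction", "ml"),
                         subgroup = c("all", "pet_negative"),
                         cutoff = 0.5, outcomes = NULL, verbose = FALSE) {
  family <- match.arg(family); measure <- match.arg(measure)
  subgroup <- match.arg(subgroup)
  cfg <- validate_synthetic_config(config)

  imaging <- simulate_imaging(cfg, verbose = verbose)
  cohort <- simulate_cohort(cfg, imaging$overlaps, verbose = verbose)
  thresholds <- deficit_thresholds(cohort$controls, cfg$tests)
  table1 <- compare_groups(cohort$patients, cohort$controls,
                           thresholds = thresholds)
  screen <- correlation_screen(imaging$overlaps, cohort$patients,
                               imaging$atlas, alpha = alpha, family = family,
                               measure = measure, subgroup = subgroup)
  if (verbose)
    message(sprintf("screen: %d cells, %d computable, %d significant",
                    nrow(screen), sum(!is.na(screen$p_raw)),
                    sum(screen$significant)))

  pe <- cfg$planted_effects
  if (is.null(outcomes))
    outcomes <- if (!is.null(pe) && nrow(pe) > 0) unique(pe$test_name)
                else "wordlist_immediate"
  models <- list()
  table2 <- NULL
  for (oc in outcomes) {
    md <- tryCatch(
      build_model_data(cohort$patients, imaging$overlaps, thresholds, oc,
                       augment_region = pick_representative(screen, oc),
                       measure = measure),
      error = function(e) NULL)
    if (is.null(md) || sum(md$y) == 0 || sum(md$y) == length(md$y)) next
    base <- fit_deficit_model(md$x_base, md$y, cutoff)
    table2 <- rbind(table2, model_row(oc, "base", base, FALSE))
    aug <- cmp <- NULL
    if (!is.null(md$x_aug)) {
      aug <- fit_deficit_model(md$x_aug, md$y, cutoff)
      cmp <- compare_models(base, aug)
      table2 <- rbind(table2, model_row(oc, "augmented", aug, cmp$improved))
    }
    models[[oc]] <- list(base = base, augmented = aug, comparison = cmp)
  }

  recovery <- if (!is.null(pe) && nrow(pe) > 0)
    recovery_report(screen, pe) else NULL

  manifest <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c()
    wr <- function(obj, name) {
      p <- file.path(out_dir, name)
      write.csv(obj, p, row.names = FALSE)
      files[name] <<- p
    }
    wr(imaging$overlaps, "overlaps.csv")
    wr(cohort$patients, "cohort_patients.csv")
    wr(cohort$controls, "cohort_controls.csv")
    wr(table1, "table1_summary.csv")
    thr_path <- file.path(out_dir, "thresholds.json")
    jsonlite::write_json(lapply(thresholds, unclass), thr_path,
                         auto_unbox = TRUE, digits = NA)
    files["thresholds.json"] <- thr_path
    wr(as.data.frame(screen), "screen.csv")
    hm <- screen_heatmap(screen)
    for (nm in names(hm)) wr(hm[[nm]], sprintf("heatmap_%s.csv", nm))
    if (!is.null(table2)) wr(table2, "table2_models.csv")
    if (!is.null(recovery))
      wr(recovery$per_cell, "recovery_cells.csv")
    hashes <- tools::md5sum(unname(files))
    names(hashes) <- names(files)
    manifest <- list(
      config = unclass(cfg), seed = cfg$seed,
      package_version = as.character(utils::packageVersion("lesioncog")),
      options = list(alpha = alpha, family = family, measure = measure,
                     subgroup = subgroup, cutoff = cutoff),
      counts = list(
        n_patients = nrow(cohort$patients),
        n_controls = nrow(cohort$controls),
        n_regions = nrow(imaging$atlas$regions),
        cells_tested = sum(!is.na(screen$p_raw)),
        cells_significant = sum(screen$significant)),
      recovered_regions = if (!is.null(recovery))
        recovery$recovered_regions else integer(0),
      hashes = as.list(hashes))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  invisible(list(atlas = imaging$atlas, overlaps = imaging$overlaps,
                 pet_dice = imaging$pet_dice, recurrent = imaging$recurrent,
                 cohort = cohort, thresholds = thresholds, table1 = table1,
                 screen = screen, models = models, table2 = table2,
                 recovery = recovery, manifest = manifest))
}

# the screen's smallest-p T2/FLAIR region for an outcome (representative
# augmentation covariate); NULL when nothing is computable
pick_representative <- function(screen, outcome) {
  sub <- screen[screen$lesion_type == "flair" &
                  screen$test_name == outcome & !is.na(screen$p_raw), ]
  if (nrow(sub) == 0) return(NULL)
  sub$region_id[which.min(sub$p_raw)]
}

model_row <- function(outcome, which, report, improved) {
  m <- report$metrics
  data.frame(outcome = outcome, model = which,
             prevalence = report$prevalence, n = report$n,
             sensitivity = m$sensitivity, specificity = m$specificity,
             ppv = m$ppv, npv = m$npv, accuracy = m$accuracy,
             auc = report$auc, p_roc = report$p_roc,
             improved = improved, flag = report$flag,
             stringsAsFactors = FALSE)
}

#' Recovery of planted effects by the screen
#'
#' Bonferroni-significant T2/FLAIR cells are treated as calls and compared
#' with the planted (region, test) pairs. Precision is the fraction of calls
#' that are planted pairs, recall the fraction of planted pairs called; both
#' are `NA` when their denominator is empty.
#'
#' @param screen A [correlation_screen()] result.
#' @param planted_effects Data frame with `region_id` and `test_name`.
#' @return List with `precision`, `recall`, `n_calls`, `recovered_regions`
#'   and a `per_cell` data frame of the calls.
#' @export
recovery_report <- function(screen, planted_effects) {
  if (is.null(planted_effects)) planted_effects <- data.frame(
    region_id = integer(0), test_name = character(0))
  calls <- screen[screen$significant & screen$lesion_type == "flair", ,
                  drop = FALSE]
  key <- function(r, t) paste(r, t, sep = "|")
  called <- unique(key(calls$region_id, calls$test_name))
  truth <- unique(key(planted_effects$region_id,
                      planted_effects$test_name))
  precision <- if (length(called) == 0) NA_real_
               else mean(called %in% truth)
  recall <- if (length(truth) == 0) NA_real_
            else mean(truth %in% called)
  list(precision = precision, recall = recall, n_calls = length(called),
       recovered_regions = unique(calls$region_id[
         key(calls$region_id, calls$test_name) %in% truth]),
       per_cell = calls)
}

#' Replicate the screen over fresh cohorts on fixed imaging
#'
#' The validation harness behind the familywise-error and power checks: a
#' small number of imaging sets (atlas + lesions + overlaps) is generated,
#' and for each, many cohort replicates (fresh covariates and score noise)
#' are screened. Under a null configuration (no planted effects) the scores
#' are independent of the overlaps, so any Bonferroni-significant cell is a
#' familywise type-I error; under a planted configuration the harness
#' records whether the planted cell was recovered.
#'
#' @param config A [synthetic_config()] (its `planted_effects` are ignored;
#'   use `planted = TRUE` to plant per imaging set).
#' @param n_reps Total cohort replicates.
#' @param n_mask_sets Number of independent imaging sets.
#' @param planted Plant a calibrated effect per imaging set?
#' @param test_name,tau_target Planted-effect settings.
#' @param alpha,family,measure Screen options.
#' @return Data frame, one row per replicate: `mask_set`, `rep`,
#'   `n_significant`, `any_significant`, `recovered`.
#' @export
replicate_screen <- function(config, n_reps = 200L, n_mask_sets = 10L,
                             planted = FALSE,
                             test_name = "wordlist_immediate",
                             tau_target = 0.3, alpha = 0.05,
                             family = c("per_atlas", "global"),
                             measure = c("fraction", "ml"),
                             tests = NULL) {
  family <- match.arg(family); measure <- match.arg(measure)
  cfg <- validate_synthetic_config(config)
  per_set <- ceiling(n_reps / n_mask_sets)
  out <- list()
  done <- 0L
  for (ms in seq_len(n_mask_sets)) {
    cfg_ms <- cfg
    cfg_ms$seed <- derive_seed(cfg$seed, paste0("maskset_", ms))
    cfg_ms$planted_effects <- NULL
    imaging <- simulate_imaging(cfg_ms)
    if (planted)
      cfg_ms <- plant_effect(cfg_ms, imaging$overlaps, test_name,
                             tau_target = tau_target, atlas = imaging$atlas)
    for (r in seq_len(per_set)) {
      if (done >= n_reps) break
      done <- done + 1L
      coh <- simulate_cohort(
        cfg_ms, imaging$overlaps,
        score_seed = derive_seed(cfg_ms$seed, paste0("scores_", r)))
      scr <- correlation_screen(imaging$overlaps, coh$patients,
                                imaging$atlas, tests = tests,
                                alpha = alpha, family = family,
                                measure = measure)
      recovered <- NA
      if (planted) {
        rec <- recovery_report(scr, cfg_ms$planted_effects)
        recovered <- isTRUE(rec$recall >= 1)
      }
      out[[done]] <- data.frame(
        mask_set = ms, rep = r, n_significant = sum(scr$significant),
        any_significant = any(scr$significant), recovered = recovered)
    }
  }
  do.call(rbind, out)
}

#' Replicate base vs node-augmented deficit models over fresh cohorts
#'
#' Companion harness to [replicate_screen()] for the model-augmentation
#' property: on cohorts with one planted node effect, the deficit model for
#' the planted test is fitted with and without the planted region's overlap
#' fraction, and the sensitivity gain recorded.
#'
#' @inheritParams replicate_screen
#' @param cutoff Probability cutoff of the contingency table.
#' @return Data frame per replicate: sensitivities, AUCs, and whether the
#'   augmented model's sensitivity was at least the base model's.
#' @export
replicate_models <- function(config, n_reps = 200L, n_mask_sets = 10L,
                             test_name = "wordlist_immediate",
                             tau_target = 0.3, cutoff = 0.5) {
  cfg <- validate_synthetic_config(config)
  per_set <- ceiling(n_reps / n_mask_sets)
  out <- list()
  done <- 0L
  for (ms in seq_len(n_mask_sets)) {
    cfg_ms <- cfg
    cfg_ms$seed <- derive_seed(cfg$seed, paste0("maskset_", ms))
    cfg_ms$planted_effects <- NULL
    imaging <- simulate_imaging(cfg_ms)
    cfg_ms <- plant_effect(cfg_ms, imaging$overlaps, test_name,
                           tau_target = tau_target, atlas = imaging$atlas)
    region <- cfg_ms$planted_effects$region_id[1]
    for (r in seq_len(per_set)) {
      if (done >= n_reps) break
      done <- done + 1L
      coh <- simulate_cohort(
        cfg_ms, imaging$overlaps,
        score_seed = derive_seed(cfg_ms$seed, paste0("scores_", r)))
      thr <- deficit_thresholds(coh$controls, cfg_ms$tests)
      md <- build_model_data(coh$patients, imaging$overlaps, thr, test_name,
                             augment_region = region)
      if (sum(md$y) == 0 || sum(md$y) == length(md$y)) next
      base <- fit_deficit_model(md$x_base, md$y, cutoff)
      aug <- fit_deficit_model(md$x_aug, md$y, cutoff)
      out[[done]] <- data.frame(
        mask_set = ms, rep = r,
        sens_base = base$metrics$sensitivity,
        sens_aug = aug$metrics$sensitivity,
        auc_base = base$auc, auc_aug = aug$auc,
        aug_not_worse = aug$metrics$sensitivity >=
          base$metrics$sensitivity)
    }
  }
  do.call(rbind, out)
}
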
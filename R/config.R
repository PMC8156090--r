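#' Configuration for the synthetic study
#'
#' Bundles every knob of the synthetic-cohort generator. The defaults encode
#' the study conditions the pipeline is validated under: a 2 x 50-node
#' parcellation organised in 7 resting-state networks plus 2 x 24 white-matter
#' tracts, 121 patients and 121 healthy controls, T2/FLAIR lesion volumes
#' drawn from a lognormal with median 53.4 mL, and a PET tumor-to-brain
#' contrast of 2.0 with additive noise.
#'
#' @param grid_shape Integer vector of length 3; voxel grid of the synthetic
#'   head volume.
#' @param voxel_size_mm Isotropic voxel edge length in mm.
#' @param n_nodes_per_hemisphere,n_tracts_per_hemisphere Region counts per
#'   hemisphere for the cortical-node and white-matter-tract compartments.
#' @param shell_fraction Normalised ellipsoid radius separating the deep
#'   (tract) compartment from the cortical shell (node) compartment.
#' @param n_patients,n_controls Cohort sizes. The control pool drawn for
#'   propensity matching is `control_pool_factor` times `n_controls`.
#' @param control_pool_factor Oversampling factor for the healthy pool.
#' @param flair_median_ml,flair_sigma Median (mL) and lognormal sigma of the
#'   T2/FLAIR lesion volume distribution.
#' @param cavity_prob Probability that a patient has a resection cavity.
#' @param cavity_frac_range,t1ce_frac_range Uniform ranges for cavity and
#'   T1-CE volumes as fractions of the patient's T2/FLAIR volume.
#' @param t1ce_prob Probability that a patient has an enhancing lesion.
#' @param recurrent_fraction Fraction of patients with PET-positive recurrent
#'   tumor (the complement is the PET-negative subgroup).
#' @param pet_frac_range Uniform range for the PET-positive volume as a
#'   fraction of the T1-CE volume.
#' @param blob_radius_range Sphere radii (voxels) used by the lesion grower.
#' @param lesion_cluster_weight Probability that a patient's T2/FLAIR seed is
#'   drawn from the cohort-level predilection site rather than uniformly in
#'   the brain. Gliomas (and the radiotherapy fields around them) cluster
#'   topographically, so lesions co-affect the same regions across patients;
#'   without this clustering no region is affected often enough for
#'   region-level associations to be detectable, contradicting the
#'   association structure the generator is meant to emulate.
#' @param lesion_cluster_sd_mm Spatial SD (mm) of the predilection site.
#' @param lesion_cluster_center_frac Predilection-site center as fractions of
#'   the brain semi-axes (default left-anterior, mirroring the
#'   fronto-temporal predominance of gliomas).
#' @param tbr_true True tumor-to-brain ratio of synthetic PET tumor voxels.
#' @param pet_noise_sd Additive Gaussian noise SD of the synthetic PET volume.
#' @param age_mean,age_sd,age_range Age distribution (years) of both groups.
#' @param male_prob Probability of male gender.
#' @param edu_mean,edu_sd,edu_range ISCED-like education score distribution.
#' @param tests Data frame of test definitions; see [test_definitions()].
#' @param planted_effects `NULL` or a data frame with columns `region_id`,
#'   `test_name`, `gamma` (score units per unit overlap fraction; positive
#'   gamma always worsens performance).
#' @param seed Master integer seed; all stages derive their own seeds from it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(grid_shape = c(32L, 32L, 32L),
                             voxel_size_mm = 5,
                             n_nodes_per_hemisphere = 50L,
                             n_tracts_per_hemisphere = 24L,
                             shell_fraction = 0.7,
                             n_patients = 121L,
                             n_controls = 121L,
                             control_pool_factor = 4L,
                             flair_median_ml = 53.4,
                             flair_sigma = 0.74,
                             cavity_prob = 0.87,
                             cavity_frac_range = c(0.15, 0.5),
                             t1ce_prob = 0.8,
                             t1ce_frac_range = c(0.05, 0.3),
                             recurrent_fraction = 58 / 121,
                             pet_frac_range = c(0.3, 0.8),
                             blob_radius_range = c(1, 2.5),
                             lesion_cluster_weight = 0.7,
                             lesion_cluster_sd_mm = 15,
                             lesion_cluster_center_frac = c(-0.45, 0.25, 0.1),
                             tbr_true = 2.0,
                             pet_noise_sd = 0.1,
                             age_mean = 51.6, age_sd = 11.6,
                             age_range = c(20, 85),
                             male_prob = 75 / 121,
                             edu_mean = 7.4, edu_sd = 1.7,
                             edu_range = c(1, 10),
                             tests = test_definitions(),
                             planted_effects = NULL,
                             seed = 1L) {
  cfg <- list(
    grid_shape = as.integer(grid_shape), voxel_size_mm = voxel_size_mm,
    n_nodes_per_hemisphere = as.integer(n_nodes_per_hemisphere),
    n_tracts_per_hemisphere = as.integer(n_tracts_per_hemisphere),
    shell_fraction = shell_fraction,
    n_patients = as.integer(n_patients),
    n_controls = as.integer(n_controls),
    control_pool_factor = as.integer(control_pool_factor),
    flair_median_ml = flair_median_ml, flair_sigma = flair_sigma,
    cavity_prob = cavity_prob, cavity_frac_range = cavity_frac_range,
    t1ce_prob = t1ce_prob, t1ce_frac_range = t1ce_frac_range,
    recurrent_fraction = recurrent_fraction, pet_frac_range = pet_frac_range,
    blob_radius_range = blob_radius_range,
    lesion_cluster_weight = lesion_cluster_weight,
    lesion_cluster_sd_mm = lesion_cluster_sd_mm,
    lesion_cluster_center_frac = lesion_cluster_center_frac,
    tbr_true = tbr_true, pet_noise_sd = pet_noise_sd,
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    male_prob = male_prob,
    edu_mean = edu_mean, edu_sd = edu_sd, edu_range = edu_range,
    tests = tests, planted_effects = planted_effects,
    seed = as.integer(seed))
  validate_synthetic_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

validate_synthetic_config <- function(cfg) {
  stopifnot(
    length(cfg$grid_shape) == 3L, all(cfg$grid_shape >= 8L),
    cfg$voxel_size_mm > 0,
    cfg$n_nodes_per_hemisphere >= 1L, cfg$n_tracts_per_hemisphere >= 0L,
    cfg$shell_fraction > 0, cfg$shell_fraction < 1,
    cfg$flair_median_ml > 0, cfg$flair_sigma > 0,
    cfg$tbr_true > 1, cfg$pet_noise_sd >= 0,
    cfg$lesion_cluster_weight >= 0, cfg$lesion_cluster_weight <= 1,
    cfg$lesion_cluster_sd_mm > 0,
    length(cfg$lesion_cluster_center_frac) == 3L,
    cfg$age_sd > 0, cfg$edu_sd > 0,
    all(c("test", "direction", "mu", "sigma", "beta_age", "beta_edu")
        %in% names(cfg$tests)),
    all(cfg$tests$sigma >= 0))
  if (!is.null(cfg$planted_effects)) {
    pe <- cfg$planted_effects
    stopifnot(is.data.frame(pe),
              all(c("region_id", "test_name", "gamma") %in% names(pe)),
              all(pe$test_name %in% cfg$tests$test))
  }
  invisible(cfg)
}

#' Cognitive test battery definitions
#'
#' The ten tests of the battery with their domains, score directions and the
#' generative parameters of the synthetic cohort (healthy baseline mean and
#' noise SD, plus moderate age and education effects). TMT-A and TMT-B are
#' completion times, so lower scores are better; all other tests count items,
#' so higher scores are better. The derived TMT-B/TMT-A ratio is computed
#' downstream, not generated.
#'
#' Baselines and SDs are typical healthy-adult values for this battery
#' (e.g. TMT-A 30.9 (12.1) s, word-list immediate recall 14.1 (2.6) items).
#' Age and education slopes are set to `0.04 * sigma` per year and
#' `0.10 * sigma` per education step (signed toward worse performance with
#' age, better with education). With an age SD of 11.6 years this gives an
#' age-score correlation of about 0.4, in line with the moderate age
#' dependence such batteries show across an adult cohort.
#'
#' @return Data frame with columns `test`, `domain`, `direction`, `mu`,
#'   `sigma`, `beta_age`, `beta_edu`.
#' @export
test_definitions <- function() {
  d <- data.frame(
    test = c("tmt_a", "tmt_b", "supermarket", "number_transcoding",
             "digit_span_forward", "digit_span_backward",
             "cbt_forward", "cbt_backward",
             "wordlist_immediate", "wordlist_delayed"),
    domain = c("attention", "executive", "language", "language",
               "verbal_working_memory", "verbal_working_memory",
               "visual_working_memory", "visual_working_memory",
               "verbal_episodic_memory", "verbal_episodic_memory"),
    direction = c("lower_better", "lower_better", rep("higher_better", 8)),
    mu = c(30.9, 68.2, 26.8, 3.6, 8.3, 8.0, 7.4, 6.0, 14.1, 5.4),
    sigma = c(12.1, 40.1, 4.4, 0.6, 2.3, 2.3, 1.9, 2.0, 2.6, 2.4),
    stringsAsFactors = FALSE)
  worse <- ifelse(d$direction == "lower_better", 1, -1)
  d$beta_age <- worse * 0.04 * d$sigma
  d$beta_edu <- -worse * 0.10 * d$sigma
  d
}

#' Write / read a synthetic configuration as JSON
#'
#' @param cfg A `synthetic_config`.
#' @param path File path.
#' @return `write_config` returns `path` invisibly; `read_config` returns the
#'   reconstructed `synthetic_config`.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$tests <- as.data.frame(raw$tests, stringsAsFactors = FALSE)
  if (!is.null(raw$planted_effects))
    raw$planted_effects <- as.data.frame(raw$planted_effects,
                                         stringsAsFactors = FALSE)
  do.call(synthetic_config, raw)
}
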
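# Synthetic lesion growth: a blob is the union of random-radius spheres whose
# centers random-walk over the already-grown blob, intersected with a domain
# mask. Spheres always contain their center voxel, so blobs stay contiguous.
grow_blob <- function(domain, target_voxels, r_range = c(1, 2.5),
                      seed_voxel = NULL) {
  dm <- dim(domain)
  mask <- array(FALSE, dm)
  if (target_voxels <= 0) return(mask)
  n_dom <- sum(domain)
  if (n_dom == 0) return(mask)
  if (target_voxels > n_dom) {
    message(sprintf(
      "lesion target volume (%d voxels) exceeds domain (%d); truncating",
      target_voxels, n_dom))
    target_voxels <- n_dom
  }
  dom_idx <- which(domain)
  if (is.null(seed_voxel)) seed_voxel <- sample(dom_idx, 1L)
  center <- arrayInd(seed_voxel, dm)[1, ]
  repeat {
    r <- runif(1, r_range[1], r_range[2])
    rr <- ceiling(r)
    ir <- max(1L, center[1] - rr):min(dm[1], center[1] + rr)
    jr <- max(1L, center[2] - rr):min(dm[2], center[2] + rr)
    kr <- max(1L, center[3] - rr):min(dm[3], center[3] + rr)
    cube <- as.matrix(expand.grid(i = ir, j = jr, k = kr))
    d2 <- (cube[, 1] - center[1])^2 + (cube[, 2] - center[2])^2 +
      (cube[, 3] - center[3])^2
    inside <- cube[d2 <= r^2, , drop = FALSE]
    lin <- inside[, 1] + dm[1] * (inside[, 2] - 1L +
                                    dm[2] * (inside[, 3] - 1L))
    lin <- lin[domain[lin]]
    mask[lin] <- TRUE
    if (sum(mask) >= target_voxels) break
    center <- arrayInd(sample(which(mask), 1L), dm)[1, ]
  }
  mask
}

#' Generate the four lesion masks of one synthetic patient
#'
#' Grows a contiguous T2/FLAIR hyperintensity blob around a random in-brain
#' seed until its volume reaches a draw from the configured lognormal
#' (median `flair_median_ml`). A resection cavity and a T1-CE enhancing
#' lesion are grown inside the T2/FLAIR blob, so `cavity` and `t1ce` are
#' subsets of `flair` by construction. Patients flagged recurrent also get a
#' PET-positive tumor mask grown inside the T1-CE lesion (`pet` a subset of
#' `t1ce`); all masks may be empty. Per-subject seeds are derived from the
#' config seed and the subject id, so each subject is reproducible in
#' isolation.
#'
#' @param atlas A [label_atlas()]; lesions live on its grid.
#' @param config A [synthetic_config()].
#' @param subject_id Character id.
#' @param recurrent Logical; `NULL` draws it with probability
#'   `config$recurrent_fraction`.
#' @return Named list of four [lesion_mask()] objects (`cavity`, `t1ce`,
#'   `flair`, `pet`) with attribute `recurrent`.
#' @export
generate_lesions <- function(atlas, config, subject_id, recurrent = NULL) {
  cfg <- validate_synthetic_config(config)
  brain <- atlas_brain_mask(atlas)
  if (!any(brain)) stop("atlas has an empty brain mask")
  vvol <- voxel_volume_ml(atlas$affine)
  with_seed(derive_seed(cfg$seed, paste0("lesions_", subject_id)), {
    target_ml <- rlnorm(1, meanlog = log(cfg$flair_median_ml),
                        sdlog = cfg$flair_sigma)
    # seed location: mixture of the cohort-level predilection site and a
    # uniform in-brain draw (lesion topography clusters across patients)
    seed_voxel <- NULL
    if (runif(1) < cfg$lesion_cluster_weight) {
      xyz <- voxel_coords_mm(dim(brain), atlas$affine)
      semi <- 0.45 * dim(brain) * cfg$voxel_size_mm
      ctr <- cfg$lesion_cluster_center_frac * semi
      bidx <- which(brain)
      d2 <- (xyz[bidx, 1] - ctr[1])^2 + (xyz[bidx, 2] - ctr[2])^2 +
        (xyz[bidx, 3] - ctr[3])^2
      w <- exp(-d2 / (2 * cfg$lesion_cluster_sd_mm^2))
      if (sum(w) > 0) seed_voxel <- sample(bidx, 1L, prob = w)
    }
    flair <- grow_blob(brain, round(target_ml / vvol),
                       cfg$blob_radius_range, seed_voxel = seed_voxel)
    nf <- sum(flair)
    cavity <- array(FALSE, dim(brain))
    if (runif(1) < cfg$cavity_prob && nf > 0) {
      frac <- runif(1, cfg$cavity_frac_range[1], cfg$cavity_frac_range[2])
      cavity <- grow_blob(flair, round(frac * nf), cfg$blob_radius_range)
    }
    t1ce <- array(FALSE, dim(brain))
    if (runif(1) < cfg$t1ce_prob && nf > 0) {
      frac <- runif(1, cfg$t1ce_frac_range[1], cfg$t1ce_frac_range[2])
      t1ce <- grow_blob(flair, round(frac * nf), cfg$blob_radius_range)
    }
    if (is.null(recurrent)) recurrent <- runif(1) < cfg$recurrent_fraction
    pet <- array(FALSE, dim(brain))
    if (recurrent && any(t1ce)) {
      frac <- runif(1, cfg$pet_frac_range[1], cfg$pet_frac_range[2])
      pet <- grow_blob(t1ce, round(frac * sum(t1ce)), cfg$blob_radius_range)
    }
    out <- list(
      cavity = lesion_mask(cavity, atlas$affine, "cavity", subject_id),
      t1ce = lesion_mask(t1ce, atlas$affine, "t1ce", subject_id),
      flair = lesion_mask(flair, atlas$affine, "flair", subject_id),
      pet = lesion_mask(pet, atlas$affine, "pet", subject_id))
    attr(out, "recurrent") <- recurrent
    out
  })
}

#' Generate a synthetic PET intensity volume
#'
#' Healthy brain tissue gets intensity 1.0, tumor voxels `tbr_true`, with
#' additive Gaussian noise of SD `noise_sd` inside the brain; voxels outside
#' the brain are 0. This emulates an amino-acid PET scan normalised so the
#' healthy-background uptake is 1.
#'
#' @param atlas A [label_atlas()] supplying grid and brain mask.
#' @param tumor_mask A [lesion_mask()] on the atlas grid.
#' @param tbr_true True tumor-to-brain ratio (> 1).
#' @param noise_sd Nonnegative noise SD.
#' @param seed Integer seed for the noise.
#' @return Numeric 3D array on the atlas grid.
#' @export
generate_pet_volume <- function(atlas, tumor_mask, tbr_true = 2.0,
                                noise_sd = 0.1, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (tbr_true <= 1) stop("tbr_true must exceed 1")
  if (!identical(dim(atlas$labels), dim(tumor_mask$mask)))
    stop("tumor mask is not on the atlas grid")
  brain <- atlas_brain_mask(atlas)
  with_seed(seed, {
    vol <- array(0, dim(brain))
    vol[brain] <- 1
    vol[tumor_mask$mask & brain] <- tbr_true
    if (noise_sd > 0)
      vol[brain] <- vol[brain] + rnorm(sum(brain), 0, noise_sd)
    vol
  })
}
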
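#' Voxel volume in millilitres
#'
#' Absolute determinant of the 3x3 spatial part of the affine, in mm^3,
#' divided by 1000.
#'
#' @param affine 4x4 voxel-to-mm matrix.
#' @return Positive volume in mL.
#' @export
voxel_volume_ml <- function(affine) {
  stopifnot(all(dim(affine) == c(4, 4)))
  d <- det(affine[1:3, 1:3])
  if (!is.finite(d) || abs(d) < .Machine$double.eps)
    stop("affine is singular")
  abs(d) / 1000
}

#' Total lesion volume in millilitres
#' @param mask A [lesion_mask()].
#' @return Nonnegative volume in mL.
#' @export
total_lesion_volume_ml <- function(mask) {
  sum(mask$mask) * voxel_volume_ml(mask$affine)
}

#' Resample a binary mask onto an atlas grid
#'
#' Nearest-neighbour resampling through the affine composition
#' `solve(source_affine) %*% target_affine`: each target voxel takes the
#' value of the nearest source voxel, or 0 outside the source grid.
#' Nearest-neighbour (not linear) interpolation preserves binarity. When the
#' grids already match the mask is returned unchanged.
#'
#' @param mask A [lesion_mask()].
#' @param target A [label_atlas()] (or anything with `$labels` and
#'   `$affine`).
#' @return A [lesion_mask()] on the target grid.
#' @export
resample_to_grid <- function(mask, target) {
  tdim <- dim(target$labels)
  if (identical(dim(mask$mask), tdim) &&
      affines_match(mask$affine, target$affine))
    return(mask)
  m <- solve(mask$affine) %*% target$affine  # target index -> source index
  idx <- as.matrix(expand.grid(i = seq_len(tdim[1]) - 1,
                               j = seq_len(tdim[2]) - 1,
                               k = seq_len(tdim[3]) - 1))
  src <- round(sweep(idx %*% t(m[1:3, 1:3]), 2, m[1:3, 4], `+`))
  sdim <- dim(mask$mask)
  ok <- src[, 1] >= 0 & src[, 1] < sdim[1] &
    src[, 2] >= 0 & src[, 2] < sdim[2] &
    src[, 3] >= 0 & src[, 3] < sdim[3]
  out <- logical(nrow(idx))
  lin <- src[ok, 1] + 1 + sdim[1] * (src[ok, 2] + sdim[2] * src[ok, 3])
  out[ok] <- mask$mask[lin]
  dim(out) <- tdim
  lesion_mask(out, target$affine, mask$lesion_type, mask$subject_id)
}

#' Partial volumetric overlap of a lesion mask with atlas regions
#'
#' One row per atlas region: the overlap volume in mL (lesion voxels carrying
#' that region's label times the voxel volume), the fraction of the region
#' affected, the region volume and the total lesion volume. Regions the
#' lesion misses are included with zero overlap.
#'
#' @param mask A [lesion_mask()] on the atlas grid (use [resample_to_grid()]
#'   first otherwise).
#' @param atlas A [label_atlas()].
#' @return Data frame with columns `subject_id`, `lesion_type`, `region_id`,
#'   `overlap_ml`, `overlap_fraction`, `region_volume_ml`,
#'   `lesion_total_ml`.
#' @export
compute_overlap <- function(mask, atlas) {
  if (!identical(dim(mask$mask), dim(atlas$labels)) ||
      !affines_match(mask$affine, atlas$affine))
    stop("mask and atlas grids differ; call resample_to_grid() first")
  vvol <- voxel_volume_ml(atlas$affine)
  ids <- atlas$regions$id
  nmax <- max(ids)
  region_vox <- tabulate(atlas$labels, nbins = nmax)[ids]
  hit_vox <- tabulate(atlas$labels[mask$mask], nbins = nmax)[ids]
  data.frame(
    subject_id = mask$subject_id,
    lesion_type = mask$lesion_type,
    region_id = ids,
    overlap_ml = hit_vox * vvol,
    overlap_fraction = ifelse(region_vox > 0, hit_vox / region_vox, 0),
    region_volume_ml = region_vox * vvol,
    lesion_total_ml = sum(mask$mask) * vvol,
    stringsAsFactors = FALSE)
}

#' Overlap table for a full set of subjects
#'
#' Convenience wrapper stacking [compute_overlap()] over every subject and
#' lesion type.
#'
#' @param lesions Named list (by subject id) of lesion-mask lists as returned
#'   by [generate_lesions()].
#' @param atlas A [label_atlas()].
#' @return Long-format overlap data frame.
#' @export
overlap_table <- function(lesions, atlas) {
  rows <- lapply(lesions, function(subj)
    do.call(rbind, lapply(subj, compute_overlap, atlas = atlas)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# subjects x regions matrix of one overlap measure for one lesion type
overlap_matrix <- function(overlaps, lesion_type,
                           measure = c("fraction", "ml"),
                           subjects = NULL) {
  measure <- match.arg(measure)
  col <- if (measure == "fraction") "overlap_fraction" else "overlap_ml"
  sub <- overlaps[overlaps$lesion_type == lesion_type, ]
  if (is.null(subjects)) subjects <- unique(sub$subject_id)
  ids <- sort(unique(sub$region_id))
  m <- matrix(0, length(subjects), length(ids),
              dimnames = list(subjects, as.character(ids)))
  sub <- sub[sub$subject_id %in% subjects, ]
  m[cbind(match(sub$subject_id, subjects),
          match(sub$region_id, ids))] <- sub[[col]]
  m
}
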
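#' Reference (healthy background) PET uptake
#'
#' The denominator of the tumor-to-brain ratio: the mean (default) or median
#' PET intensity over a user-supplied reference mask of healthy brain.
#'
#' @param pet Numeric 3D array.
#' @param reference_mask Logical 3D array on the same grid.
#' @param statistic `"mean"` or `"median"`.
#' @return Positive scalar uptake.
#' @export
reference_uptake <- function(pet, reference_mask,
                             statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  stopifnot(identical(dim(pet), dim(reference_mask)))
  vals <- pet[reference_mask != 0]
  if (length(vals) == 0) stop("reference mask is empty")
  ref <- if (statistic == "mean") mean(vals) else median(vals)
  if (!is.finite(ref) || ref <= 0)
    stop("reference uptake is nonpositive; check the reference mask")
  ref
}

#' Tumor-to-brain-ratio parameters
#'
#' @param threshold TBR cutoff; voxels with intensity / reference >= threshold
#'   are tumor-positive. The inclusive comparison treats the threshold as the
#'   lowest tumor-predictive ratio. Default 1.6.
#' @param reference_statistic Statistic over the reference mask.
#' @param min_component_voxels Connected components (26-connectivity) smaller
#'   than this are removed; 0 (default) disables the filter.
#' @return A list of class `tbr_params`.
#' @export
tbr_params <- function(threshold = 1.6,
                       reference_statistic = c("mean", "median"),
                       min_component_voxels = 0L) {
  stopifnot(threshold > 1, min_component_voxels >= 0)
  structure(list(threshold = threshold,
                 reference_statistic = match.arg(reference_statistic),
                 min_component_voxels = as.integer(min_component_voxels)),
            class = "tbr_params")
}

#' Label 3D connected components (26-connectivity)
#' @param mask Logical 3D array.
#' @return Integer array of component labels (0 = background).
#' @export
label_components <- function(mask) {
  stopifnot(length(dim(mask)) == 3L)
  .label_components_cpp(as.logical(mask), as.integer(dim(mask)))
}

#' Segment PET-positive tumor tissue by TBR thresholding
#'
#' Marks in-brain voxels whose intensity divided by the reference uptake is
#' at least the threshold, then optionally removes small 26-connected
#' components. Because the rule is a ratio, the segmentation is invariant to
#' rescaling the PET volume; raising the threshold can only shrink the mask.
#'
#' @param pet Numeric 3D array.
#' @param brain_mask,reference_mask Logical 3D arrays on the PET grid.
#' @param params A [tbr_params()].
#' @param affine 4x4 affine of the PET grid.
#' @param subject_id Subject id for the resulting mask.
#' @return A [lesion_mask()] with `lesion_type = "pet"`.
#' @export
segment_tbr <- function(pet, brain_mask, reference_mask,
                        params = tbr_params(),
                        affine = diag(4), subject_id = "s") {
  if (!identical(dim(pet), dim(brain_mask)) ||
      !identical(dim(pet), dim(reference_mask)))
    stop("pet, brain_mask and reference_mask must share one grid")
  ref <- reference_uptake(pet, reference_mask, params$reference_statistic)
  mask <- (brain_mask != 0) & (pet / ref >= params$threshold)
  if (params$min_component_voxels > 0 && any(mask)) {
    comp <- label_components(mask)
    sizes <- tabulate(comp[comp > 0])
    keep <- which(sizes >= params$min_component_voxels)
    mask <- array(comp %in% keep, dim(mask))
  }
  lesion_mask(mask, affine, "pet", subject_id)
}
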
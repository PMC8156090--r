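#' Write and read atlases and lesion masks as NIfTI
#'
#' Volumes are stored with the affine in both the sform and qform. Region
#' metadata travels in a sidecar CSV (`id,name,hemisphere,network,kind`).
#'
#' @param atlas A [label_atlas()].
#' @param path Output `.nii.gz` path.
#' @param regions_path Sidecar CSV path; defaults to `path` with a
#'   `_regions.csv` suffix.
#' @return The main path, invisibly.
#' @export
write_atlas_nifti <- function(atlas, path,
                              regions_path = sub("\\.nii(\\.gz)?$",
                                                 "_regions.csv", path)) {
  img <- RNifti::asNifti(array(as.integer(atlas$labels),
                               dim(atlas$labels)))
  img <- RNifti::`sform<-`(img, structure(atlas$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(atlas$affine, code = 2L))
  RNifti::writeNifti(img, path)
  write.csv(atlas$regions, regions_path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_atlas_nifti
#' @export
read_atlas_nifti <- function(path,
                             regions_path = sub("\\.nii(\\.gz)?$",
                                                "_regions.csv", path)) {
  img <- RNifti::readNifti(path)
  regions <- read.csv(regions_path, stringsAsFactors = FALSE)
  label_atlas(array(as.integer(img), dim(img)),
              structure(RNifti::xform(img), dimnames = NULL), regions)
}

#' @param mask A [lesion_mask()].
#' @rdname write_atlas_nifti
#' @export
write_mask_nifti <- function(mask, path) {
  img <- RNifti::asNifti(array(as.integer(mask$mask), dim(mask$mask)))
  img <- RNifti::`sform<-`(img, structure(mask$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(mask$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @param lesion_type,subject_id Metadata for the mask being read.
#' @rdname write_atlas_nifti
#' @export
read_mask_nifti <- function(path, lesion_type, subject_id = "s") {
  img <- RNifti::readNifti(path)
  lesion_mask(array(as.integer(img) != 0, dim(img)),
              structure(RNifti::xform(img), dimnames = NULL),
              lesion_type, subject_id)
}

#' @param volume Numeric 3D array (e.g. a PET volume).
#' @param affine 4x4 affine for the volume.
#' @rdname write_atlas_nifti
#' @export
write_volume_nifti <- function(volume, affine, path) {
  img <- RNifti::asNifti(volume)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
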
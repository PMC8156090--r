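#' Label atlas and lesion mask containers
#'
#' A `label_atlas` is an integer-labelled 3D volume (0 = outside brain) with a
#' 4x4 voxel-to-mm affine (0-based voxel indices, NIfTI convention) and a
#' per-region metadata table (`id`, `name`, `hemisphere`, `network`, `kind`).
#' A `lesion_mask` is a logical 3D volume on some grid with the same affine
#' convention, tagged with a lesion type (`cavity`, `t1ce`, `flair`, `pet`)
#' and a subject id.
#'
#' @param labels Integer 3D array.
#' @param affine 4x4 numeric matrix mapping 0-based voxel indices to mm.
#' @param regions Data frame of region metadata.
#' @return An object of class `label_atlas`.
#' @export
label_atlas <- function(labels, affine, regions) {
  stopifnot(length(dim(labels)) == 3L, all(dim(affine) == c(4, 4)))
  stopifnot(all(c("id", "name", "hemisphere", "network", "kind")
                %in% names(regions)))
  if (anyDuplicated(regions$id) > 0) stop("region ids must be unique")
  used <- sort(unique(as.vector(labels)))
  used <- used[used != 0]
  if (!all(used %in% regions$id))
    stop("label grid contains ids missing from the regions table")
  structure(list(labels = labels, affine = affine,
                 regions = as.data.frame(regions)),
            class = "label_atlas")
}

#' @param mask Logical 3D array.
#' @param lesion_type One of `"cavity"`, `"t1ce"`, `"flair"`, `"pet"`.
#' @param subject_id Character subject identifier.
#' @rdname label_atlas
#' @export
lesion_mask <- function(mask, affine, lesion_type, subject_id = "s") {
  stopifnot(length(dim(mask)) == 3L, all(dim(affine) == c(4, 4)))
  lesion_type <- match.arg(lesion_type, c("cavity", "t1ce", "flair", "pet"))
  structure(list(mask = (mask != 0), affine = affine,
                 lesion_type = lesion_type, subject_id = subject_id),
            class = "lesion_mask")
}

#' @export
print.label_atlas <- function(x, ...) {
  cat(sprintf("<label_atlas> %s grid, %d regions (%d nodes, %d tracts)\n",
              paste(dim(x$labels), collapse = "x"), nrow(x$regions),
              sum(x$regions$kind == "node"), sum(x$regions$kind == "tract")))
  invisible(x)
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> %s, type=%s, subject=%s, %d voxels\n",
              paste(dim(x$mask), collapse = "x"), x$lesion_type,
              x$subject_id, sum(x$mask)))
  invisible(x)
}

# centered diagonal affine: world = voxel_size * (index0 - (dim-1)/2)
affine_from_spacing <- function(grid_shape, voxel_size_mm) {
  a <- diag(c(rep(voxel_size_mm, 3), 1))
  a[1:3, 4] <- -voxel_size_mm * (grid_shape - 1) / 2
  a
}

# mm coordinates of all voxel centers; rows in array (column-major) order
voxel_coords_mm <- function(grid_shape, affine) {
  idx <- as.matrix(expand.grid(i = seq_len(grid_shape[1]) - 1,
                               j = seq_len(grid_shape[2]) - 1,
                               k = seq_len(grid_shape[3]) - 1))
  sweep(idx %*% t(affine[1:3, 1:3]), 2, affine[1:3, 4], `+`)
}

#' The seven canonical resting-state network names
#' @return Character vector of length 7.
#' @export
network_names <- function() {
  c("visual", "somato_motor", "dorsal_attention", "ventral_attention",
    "limbic", "fronto_parietal_control", "default_mode")
}

#' Generate a synthetic two-compartment brain atlas
#'
#' Builds an ellipsoidal brain mask on the configured grid, splits it at the
#' mid-sagittal plane (x = 0 mm) into hemispheres and at a configurable
#' normalised radius into a cortical shell and a deep core. The shell is
#' partitioned per hemisphere into `n_nodes_per_hemisphere` functional nodes
#' by nearest-seed (Voronoi) assignment from random seed voxels; the core is
#' partitioned likewise into white-matter tracts. Nodes are assigned
#' round-robin to the seven canonical resting-state networks. Node labels
#' occupy `1..2*n_nodes`, tract labels follow.
#'
#' @param config A [synthetic_config()].
#' @param max_retries Seed-resampling attempts before giving up on a
#'   degenerate partition.
#' @return A [label_atlas()] whose nonzero labels cover the whole brain mask.
#' @export
generate_atlas <- function(config, max_retries = 10L) {
  cfg <- validate_synthetic_config(config)
  with_seed(derive_seed(cfg$seed, "atlas"), {
    dm <- cfg$grid_shape
    affine <- affine_from_spacing(dm, cfg$voxel_size_mm)
    xyz <- voxel_coords_mm(dm, affine)
    semi <- 0.45 * dm * cfg$voxel_size_mm
    rn2 <- (xyz[, 1] / semi[1])^2 + (xyz[, 2] / semi[2])^2 +
      (xyz[, 3] / semi[3])^2
    brain <- rn2 <= 1
    shell <- brain & rn2 > cfg$shell_fraction^2
    core <- brain & !(rn2 > cfg$shell_fraction^2)
    left <- xyz[, 1] < 0
    labels <- integer(prod(dm))

    nn <- cfg$n_nodes_per_hemisphere
    nt <- cfg$n_tracts_per_hemisphere
    for (hemi in c("left", "right")) {
      hsel <- if (hemi == "left") left else !left
      if (sum(shell & hsel) < nn || (nt > 0 && sum(core & hsel) < nt))
        stop("grid too small to host the requested number of regions")
    }

    partition <- function(sel, n, offset) {
      vox <- which(sel)
      for (attempt in seq_len(max_retries)) {
        seeds <- sample(vox, n)
        nearest <- integer(length(vox))
        best <- rep(Inf, length(vox))
        for (s in seq_len(n)) {
          d2 <- (xyz[vox, 1] - xyz[seeds[s], 1])^2 +
            (xyz[vox, 2] - xyz[seeds[s], 2])^2 +
            (xyz[vox, 3] - xyz[seeds[s], 3])^2
          upd <- d2 < best
          nearest[upd] <- s
          best[upd] <- d2[upd]
        }
        if (length(unique(nearest)) == n) {
          labels[vox] <<- offset + nearest
          return(TRUE)
        }
      }
      stop("empty region after Voronoi partition despite retries")
    }

    partition(shell & left, nn, 0L)
    partition(shell & !left, nn, nn)
    if (nt > 0) {
      partition(core & left, nt, 2L * nn)
      partition(core & !left, nt, 2L * nn + nt)
    }

    nets <- network_names()
    node_ids <- seq_len(2 * nn)
    node_hemi <- rep(c("left", "right"), each = nn)
    node_num <- c(seq_len(nn), seq_len(nn))
    regions <- data.frame(
      id = node_ids,
      name = sprintf("node_%s%02d", ifelse(node_hemi == "left", "L", "R"),
                     node_num),
      hemisphere = node_hemi,
      network = nets[(node_ids - 1L) %% 7L + 1L],
      kind = "node", stringsAsFactors = FALSE)
    if (nt > 0) {
      tract_ids <- 2L * nn + seq_len(2 * nt)
      tract_hemi <- rep(c("left", "right"), each = nt)
      tract_num <- c(seq_len(nt), seq_len(nt))
      regions <- rbind(regions, data.frame(
        id = tract_ids,
        name = sprintf("tract_%s%02d", ifelse(tract_hemi == "left", "L", "R"),
                       tract_num),
        hemisphere = tract_hemi,
        network = "white_matter",
        kind = "tract", stringsAsFactors = FALSE))
    }
    dim(labels) <- dm
    label_atlas(labels, affine, regions)
  })
}

#' Brain mask of a synthetic atlas
#'
#' In the synthetic geometry the node and tract compartments jointly tile the
#' brain, so the brain mask is simply the nonzero-label set.
#' @param atlas A `label_atlas`.
#' @return Logical 3D array.
#' @export
atlas_brain_mask <- function(atlas) atlas$labels > 0
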
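# Shared small synthetic fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

tiny_config <- function(seed = 42, n_patients = 20L, n_controls = 20L,
                        grid = 20L, vox = 8, ...) {
  synthetic_config(grid_shape = rep(as.integer(grid), 3L),
                   voxel_size_mm = vox, n_patients = n_patients,
                   n_controls = n_controls, seed = seed, ...)
}

tiny_imaging <- function(seed = 42, n_patients = 20L) {
  key <- sprintf("img_%d_%d", seed, n_patients)
  if (is.null(.fixtures[[key]])) {
    cfg <- tiny_config(seed = seed, n_patients = n_patients,
                       n_controls = n_patients)
    .fixtures[[key]] <- c(list(cfg = cfg), simulate_imaging(cfg))
  }
  .fixtures[[key]]
}

# hand-built 3-region atlas on a small grid (two "nodes", one "tract")
toy_atlas <- function(dm = c(6L, 6L, 6L), vox = 1) {
  labels <- array(0L, dm)
  labels[2:3, 2:3, 2:3] <- 1L
  labels[5, 2:4, 2] <- 2L
  labels[2:5, 5, 4:5] <- 3L
  regions <- data.frame(
    id = 1:3, name = c("node_L01", "node_R01", "tract_L01"),
    hemisphere = c("left", "right", "left"),
    network = c("visual", "visual", "white_matter"),
    kind = c("node", "node", "tract"), stringsAsFactors = FALSE)
  label_atlas(labels, lesioncog:::affine_from_spacing(dm, vox), regions)
}

random_label_atlas <- function(dm = c(20L, 20L, 20L), n_regions = 3L,
                               vox = 1) {
  labels <- array(sample(0:n_regions, prod(dm), replace = TRUE), dm)
  regions <- data.frame(
    id = seq_len(n_regions),
    name = sprintf("region_%02d", seq_len(n_regions)),
    hemisphere = "left", network = "visual", kind = "node",
    stringsAsFactors = FALSE)
  label_atlas(labels, lesioncog:::affine_from_spacing(dm, vox), regions)
}

random_mask_on <- function(atlas, p = 0.2, lesion_type = "flair",
                           subject_id = "s") {
  dm <- dim(atlas$labels)
  lesion_mask(array(runif(prod(dm)) < p, dm), atlas$affine, lesion_type,
              subject_id)
}
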
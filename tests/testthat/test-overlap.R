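test_that("voxel volume follows the affine determinant", {
  expect_equal(voxel_volume_ml(diag(4)), 0.001)
  expect_equal(voxel_volume_ml(diag(c(2, 2, 2, 1))), 0.008)
  # the study's FLAIR grid: 0.9 x 0.9 x 4 mm
  expect_equal(voxel_volume_ml(diag(c(0.9, 0.9, 4, 1))), 0.00324)
  sing <- diag(4); sing[1, 1] <- 0
  expect_error(voxel_volume_ml(sing), "singular")
})

test_that("resampling is identity on matching grids and exact vs oracle", {
  atl <- toy_atlas()
  m <- random_mask_on(atl, 0.3)
  expect_identical(resample_to_grid(m, atl), m)

  # all-ones fine mask stays all ones on a coarser grid
  fine_dim <- c(20L, 20L, 20L)
  fine_aff <- lesioncog:::affine_from_spacing(fine_dim, 1)
  ones <- lesion_mask(array(TRUE, fine_dim), fine_aff, "flair")
  coarse_dim <- c(10L, 10L, 10L)
  coarse <- list(labels = array(1L, coarse_dim),
                 affine = lesioncog:::affine_from_spacing(coarse_dim, 2))
  expect_true(all(resample_to_grid(ones, coarse)$mask))

  # random mask, 1 mm -> 2 mm: per-target-voxel nearest-source oracle
  set.seed(21)
  for (rep in 1:5) {
    rm <- lesion_mask(array(runif(prod(fine_dim)) < 0.4, fine_dim),
                      fine_aff, "flair")
    got <- resample_to_grid(rm, coarse)$mask
    expect_equal(got,
                 oracle_resample(rm$mask, fine_aff, coarse_dim,
                                 coarse$affine))
  }
})

test_that("overlap of an exact region is total and exclusive", {
  atl <- toy_atlas()
  m <- lesion_mask(atl$labels == 1L, atl$affine, "cavity", "sub1")
  ov <- compute_overlap(m, atl)
  expect_equal(nrow(ov), 3)
  r1 <- ov[ov$region_id == 1, ]
  expect_equal(r1$overlap_ml, 8 * 0.001)
  expect_equal(r1$overlap_fraction, 1)
  expect_true(all(ov$overlap_ml[ov$region_id != 1] == 0))
  # empty mask: all-zero rows
  ov0 <- compute_overlap(lesion_mask(array(FALSE, dim(atl$labels)),
                                     atl$affine, "flair"), atl)
  expect_true(all(ov0$overlap_ml == 0))
  expect_true(all(ov0$overlap_fraction == 0))
  # grid mismatch directs to the resampler
  bad <- lesion_mask(array(FALSE, c(4L, 4L, 4L)),
                     lesioncog:::affine_from_spacing(c(4L, 4L, 4L), 1),
                     "flair")
  expect_error(compute_overlap(bad, atl), "resample_to_grid")
})

test_that("overlap rows equal the triple-loop oracle on random instances", {
  set.seed(31)
  for (rep in 1:5) {
    atl <- random_label_atlas(c(12L, 12L, 12L), 3L)
    m <- random_mask_on(atl, runif(1, 0.1, 0.5))
    ov <- compute_overlap(m, atl)
    orc <- oracle_overlap(m$mask, atl$labels, atl$regions$id,
                          voxel_volume_ml(atl$affine))
    expect_equal(ov$overlap_ml, unname(orc$overlap_ml))
    expect_equal(ov$region_volume_ml, unname(orc$region_volume_ml))
    expect_equal(ov$overlap_fraction,
                 unname(orc$overlap_ml / orc$region_volume_ml))
  }
})

test_that("overlap volumes are conserved across regions", {
  fx <- tiny_imaging()
  vvol <- voxel_volume_ml(fx$atlas$affine)
  for (l in fx$lesions) {
    for (type in names(l)) {
      ov <- compute_overlap(l[[type]], fx$atlas)
      unlabeled <- sum(l[[type]]$mask & fx$atlas$labels == 0) * vvol
      expect_equal(sum(ov$overlap_ml) + unlabeled,
                   total_lesion_volume_ml(l[[type]]))
      expect_true(all(ov$overlap_fraction >= 0 &
                        ov$overlap_fraction <= 1))
      expect_true(all(ov$overlap_ml <=
                        pmin(ov$region_volume_ml, ov$lesion_total_ml) +
                        1e-12))
    }
  }
})

test_that("region fraction is 1 exactly when the region is inside the lesion", {
  atl <- toy_atlas()
  m <- lesion_mask(atl$labels == 2L | atl$labels == 1L, atl$affine, "flair")
  ov <- compute_overlap(m, atl)
  expect_equal(ov$overlap_fraction[ov$region_id %in% c(1, 2)], c(1, 1))
  expect_lt(ov$overlap_fraction[ov$region_id == 3], 1)
})

test_that("permuting region ids permutes rows without changing values", {
  set.seed(5)
  atl <- random_label_atlas(c(10L, 10L, 10L), 4L)
  m <- random_mask_on(atl, 0.3)
  ov1 <- compute_overlap(m, atl)
  perm <- c(3L, 1L, 4L, 2L)  # new id for old id i
  labels2 <- array(ifelse(atl$labels > 0, perm[pmax(atl$labels, 1)], 0L),
                   dim(atl$labels))
  regions2 <- atl$regions
  regions2$id <- perm
  atl2 <- label_atlas(labels2, atl$affine, regions2)
  ov2 <- compute_overlap(m, atl2)
  for (i in seq_len(4)) {
    expect_equal(ov2$overlap_ml[ov2$region_id == perm[i]],
                 ov1$overlap_ml[ov1$region_id == i])
  }
})

test_that("total lesion volume is count times voxel volume", {
  dm <- c(10L, 10L, 10L)
  aff <- lesioncog:::affine_from_spacing(dm, 1)
  expect_equal(total_lesion_volume_ml(
    lesion_mask(array(FALSE, dm), aff, "flair")), 0)
  m <- array(FALSE, dm); m[1:1000] <- TRUE
  expect_equal(total_lesion_volume_ml(lesion_mask(m, aff, "flair")), 1)
})
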
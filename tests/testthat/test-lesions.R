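test_that("lesion subset chain holds for every generated subject", {
  fx <- tiny_imaging()
  for (l in fx$lesions) {
    expect_true(all(l$cavity$mask <= l$flair$mask))
    expect_true(all(l$t1ce$mask <= l$flair$mask))
    expect_true(all(l$pet$mask <= l$t1ce$mask))
    brain <- atlas_brain_mask(fx$atlas)
    expect_true(all(l$flair$mask <= brain))
  }
})

test_that("lesion generation is deterministic per subject and seed", {
  fx <- tiny_imaging()
  l1 <- generate_lesions(fx$atlas, fx$cfg, "P001")
  l2 <- generate_lesions(fx$atlas, fx$cfg, "P001")
  expect_identical(l1$flair$mask, l2$flair$mask)
  expect_identical(l1$cavity$mask, l2$cavity$mask)
  l3 <- generate_lesions(fx$atlas, fx$cfg, "P002")
  expect_false(identical(l1$flair$mask, l3$flair$mask))
})

test_that("flair volumes reproduce the configured lognormal median", {
  cfg <- tiny_config(seed = 5, n_patients = 200L)
  atl <- generate_atlas(cfg)
  vols <- vapply(seq_len(200), function(i)
    total_lesion_volume_ml(
      generate_lesions(atl, cfg, sprintf("P%03d", i))$flair),
    numeric(1))
  expect_lt(abs(median(vols) - cfg$flair_median_ml) / cfg$flair_median_ml,
            0.15)
  # bootstrap CI of the sample median covers the configured target
  set.seed(1)
  boot <- replicate(500, median(sample(vols, replace = TRUE)))
  expect_gte(cfg$flair_median_ml, quantile(boot, 0.005))
  expect_lte(cfg$flair_median_ml, quantile(boot, 0.995))
})

test_that("oversized target volumes are truncated at the brain with a note", {
  cfg <- tiny_config(seed = 2, grid = 16L, vox = 6)
  cfg$flair_median_ml <- 1e5
  cfg$flair_sigma <- 0.01
  atl <- generate_atlas(cfg)
  expect_message(l <- generate_lesions(atl, cfg, "P001"), "truncating")
  expect_equal(l$flair$mask, atlas_brain_mask(atl))
})

test_that("disabled cavities stay empty and propagate zero overlap", {
  cfg <- tiny_config(seed = 6, cavity_prob = 0)
  atl <- generate_atlas(cfg)
  l <- generate_lesions(atl, cfg, "P001")
  expect_equal(sum(l$cavity$mask), 0)
  ov <- compute_overlap(l$cavity, atl)
  expect_true(all(ov$overlap_ml == 0))
  expect_true(all(ov$overlap_fraction == 0))
})

test_that("PET tumor masks appear only in recurrent subjects", {
  fx <- tiny_imaging()
  for (id in names(fx$lesions)) {
    if (!fx$recurrent[id])
      expect_equal(sum(fx$lesions[[id]]$pet$mask), 0)
  }
  # forcing recurrence off produces an empty PET mask
  l <- generate_lesions(fx$atlas, fx$cfg, "P001", recurrent = FALSE)
  expect_equal(sum(l$pet$mask), 0)
})

test_that("synthetic PET volumes follow the two-level + noise model", {
  fx <- tiny_imaging()
  atl <- fx$atlas
  brain <- atlas_brain_mask(atl)
  l <- generate_lesions(atl, fx$cfg, "P001", recurrent = TRUE)
  # noiseless: exactly two in-brain intensities
  vol <- generate_pet_volume(atl, l$t1ce, tbr_true = 2, noise_sd = 0,
                             seed = 1)
  expect_setequal(unique(vol[brain]), c(1, 2))
  expect_true(all(vol[!brain] == 0))
  # empty tumor: constant 1 inside the brain
  empty <- lesion_mask(array(FALSE, dim(brain)), atl$affine, "pet", "P001")
  vol0 <- generate_pet_volume(atl, empty, tbr_true = 2, noise_sd = 0,
                              seed = 1)
  expect_true(all(vol0[brain] == 1))
  expect_error(generate_pet_volume(atl, empty, tbr_true = 2,
                                   noise_sd = -0.1), "nonnegative")
  expect_error(generate_pet_volume(atl, empty, tbr_true = 0.9), "exceed")
})

test_that("PET noise tail matches the normal-tail oracle", {
  fx <- tiny_imaging()
  atl <- fx$atlas
  brain <- atlas_brain_mask(atl)
  # a large tumor so the tail fraction is estimated from many voxels
  tumor <- lesion_mask(brain & (seq_along(brain) %% 2 == 0), atl$affine,
                       "pet", "s")
  vol <- generate_pet_volume(atl, tumor, tbr_true = 2, noise_sd = 0.1,
                             seed = 4)
  tv <- vol[tumor$mask]
  n <- length(tv)
  for (cut in c(1.9, 1.6)) {
    expected <- pnorm((cut - 2) / 0.1)
    se <- sqrt(max(expected * (1 - expected), 1 / n) / n)
    expect_lt(abs(mean(tv < cut) - expected), 4 * se + 1e-12)
  }
})
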
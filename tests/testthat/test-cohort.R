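test_that("noise-free null model returns the baselines exactly", {
  cfg <- tiny_config(seed = 8)
  cfg$tests$beta_age <- 0
  cfg$tests$beta_edu <- 0
  cfg$tests$sigma <- 0
  cov <- generate_covariates(10, "patient", cfg, seed = 1)
  sc <- generate_cognition(cov, cfg, seed = 2)
  for (i in seq_len(nrow(cfg$tests)))
    expect_true(all(sc[[cfg$tests$test[i]]] == cfg$tests$mu[i]))
})

test_that("an unknown test direction is rejected", {
  cfg <- tiny_config(seed = 8)
  cfg$tests$direction[3] <- "sideways"
  cov <- generate_covariates(5, "patient", cfg, seed = 1)
  expect_error(generate_cognition(cov, cfg, seed = 2), "direction")
})

test_that("a planted effect induces the expected negative rank correlation", {
  fx <- tiny_imaging(seed = 52, n_patients = 40L)
  cfg <- fx$cfg
  fr <- lesioncog:::overlap_matrix(fx$overlaps, "flair", "fraction")
  region <- as.integer(colnames(fr)[which.max(apply(fr, 2, sd))])
  cfg$planted_effects <- data.frame(region_id = region,
                                    test_name = "wordlist_immediate",
                                    gamma = 60)
  cfg$tests$beta_age <- 0
  cfg$tests$beta_edu <- 0
  cov <- generate_covariates(40, "patient", cfg, seed = 3)
  cov$subject_id <- rownames(fr)
  sc <- generate_cognition(cov, cfg, overlaps = fx$overlaps, seed = 4)
  k <- kendall_tau_b(fr[, as.character(region)], sc$wordlist_immediate)
  expect_lt(k$tau, 0)
  # matches the brute-force pair-counting oracle on the generated table
  orc <- oracle_kendall(fr[, as.character(region)], sc$wordlist_immediate)
  expect_equal(k$tau, orc$tau)
  # on a lower-better test the same effect worsens (raises) the score
  cfg$planted_effects$test_name <- "tmt_a"
  sc2 <- generate_cognition(cov, cfg, overlaps = fx$overlaps, seed = 4)
  k2 <- kendall_tau_b(fr[, as.character(region)], sc2$tmt_a)
  expect_gt(k2$tau, 0)
})

test_that("patients separate from controls when the planted effect is large", {
  fx <- tiny_imaging(seed = 52, n_patients = 40L)
  cfg <- fx$cfg
  fr <- lesioncog:::overlap_matrix(fx$overlaps, "flair", "fraction")
  region <- as.integer(colnames(fr)[which.max(colMeans(fr > 0))])
  cfg$planted_effects <- data.frame(region_id = region,
                                    test_name = "wordlist_immediate",
                                    gamma = 80)
  hits <- 0L
  n_rep <- 200L
  for (r in seq_len(n_rep)) {
    coh <- simulate_cohort(cfg, fx$overlaps,
                           score_seed = derive_seed(cfg$seed,
                                                    paste0("mwrep_", r)))
    p <- mann_whitney(coh$patients$wordlist_immediate,
                      coh$controls$wordlist_immediate)$p
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("matching a pool of duplicates recovers each patient exactly", {
  cfg <- tiny_config(seed = 13)
  pat <- generate_covariates(30, "patient", cfg, seed = 1)
  pool <- pat
  pool$group <- "control"
  pool$subject_id <- sub("P", "C", pool$subject_id)
  m <- match_controls(pat, pool)
  expect_equal(nrow(m), 30)
  for (v in c("age", "education"))
    expect_equal(standardized_mean_difference(pat[[v]], m[[v]]), 0)
  expect_equal(sort(m$age), sort(pat$age))
})

test_that("matching against an older pool moves the mean age toward patients", {
  cfg <- tiny_config(seed = 14)
  pat <- generate_covariates(30, "patient", cfg, seed = 2)
  pool <- generate_covariates(120, "control", cfg, seed = 3)
  pool$age <- pool$age + 15
  m <- match_controls(pat, pool)
  expect_lt(abs(mean(m$age) - mean(pat$age)),
            abs(mean(pool$age) - mean(pat$age)))
  expect_error(match_controls(pat, pool[1:10, ]), "smaller")
})

test_that("matching shrinks the age imbalance in most random pools", {
  cfg <- tiny_config(seed = 15)
  wins <- 0L
  n_rep <- 200L
  for (r in seq_len(n_rep)) {
    pat <- generate_covariates(25, "patient", cfg,
                               seed = derive_seed(1, paste0("pa", r)))
    pool <- generate_covariates(100, "control", cfg,
                                seed = derive_seed(1, paste0("po", r)))
    pool$age <- pool$age + rnorm(1, 8, 2)
    pre <- abs(standardized_mean_difference(pat$age, pool$age))
    m <- match_controls(pat, pool)
    post <- abs(standardized_mean_difference(pat$age, m$age))
    wins <- wins + (post < pre)
  }
  expect_gte(wins / n_rep, 0.95)
})

test_that("planted-gamma calibration hits the target tau", {
  set.seed(99)
  f <- numeric(121)
  f[sample(121, 60)] <- abs(rnorm(60, 0.15, 0.08))
  g <- calibrate_planted_gamma(f, sigma = 2.6, tau_target = 0.3,
                               seed = 2)
  taus <- replicate(300, {
    y <- -g * f + rnorm(121, 0, 2.6)
    kendall_tau_b(f, y)$tau
  })
  expect_lt(abs(mean(abs(taus)) - 0.3), 0.04)
})
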
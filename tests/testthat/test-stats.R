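test_that("tau-b equals the brute-force pair-counting oracle", {
  expect_equal(kendall_tau_b(1:3, 1:3)$tau, 1)
  expect_equal(kendall_tau_b(1:3, 3:1)$tau, -1)
  r <- kendall_tau_b(c(1, 2, 2, 3), c(1, 2, 3, 3))
  orc <- oracle_kendall(c(1, 2, 2, 3), c(1, 2, 3, 3))
  expect_equal(r$tau, orc$tau)
  expect_equal(r$p, orc$p)
  set.seed(17)
  for (rep in 1:200) {
    n <- sample(4:40, 1)
    x <- sample(seq_len(sample(2:8, 1)), n, replace = TRUE)
    y <- sample(seq_len(sample(2:8, 1)), n, replace = TRUE)
    r <- kendall_tau_b(x, y)
    orc <- oracle_kendall(x, y)
    expect_equal(r$tau, orc$tau, tolerance = 1e-12)
    expect_equal(r$p, orc$p, tolerance = 1e-12)
  }
})

test_that("tau-b agrees with the independent cor.test implementation", {
  set.seed(18)
  for (rep in 1:20) {
    x <- sample(0:6, 35, replace = TRUE)
    y <- rnorm(35)
    mine <- kendall_tau_b(x, y)
    ct <- suppressWarnings(cor.test(x, y, method = "kendall",
                                    exact = FALSE, continuity = TRUE))
    expect_equal(mine$tau, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(mine$p, ct$p.value, tolerance = 1e-12)
  }
})

test_that("tau-b is antisymmetric with an identical p-value", {
  set.seed(19)
  x <- sample(1:5, 30, replace = TRUE)
  y <- rnorm(30)
  a <- kendall_tau_b(x, y)
  b <- kendall_tau_b(x, -y)
  expect_equal(a$tau, -b$tau)
  expect_equal(a$p, b$p)
})

test_that("tau-b handles degenerate and undersized input", {
  r <- kendall_tau_b(rep(1, 10), rnorm(10))
  expect_true(is.na(r$tau) && is.na(r$p))
  expect_error(kendall_tau_b(1:2, 1:2), "at least 3")
})

test_that("normal-approximation p is close to the exact permutation p", {
  set.seed(20)
  for (n in c(6, 7)) {
    for (rep in 1:3) {
      x <- sample(n); y <- sample(n)
      approx_p <- kendall_tau_b(x, y)$p
      exact_p <- oracle_kendall_exact_p(x, y)
      expect_lt(abs(approx_p - exact_p), 0.02 + 1e-12)
    }
  }
})

test_that("Spearman rho equals rank-then-Pearson and is rank invariant", {
  expect_equal(spearman_rho(1:10, (1:10)^3)$rho, 1)
  r <- spearman_rho(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(r$rho, cor(rank(c(1, 2, 3, 4)), rank(c(2, 1, 4, 3))))
  set.seed(21)
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(spearman_rho(x, y)$rho, spearman_rho(exp(x), y)$rho)
  expect_true(is.na(spearman_rho(rep(1, 10), rnorm(10))$rho))
})

test_that("Kruskal-Wallis matches the rank-sum oracle and MW equivalence", {
  g <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  expect_equal(kruskal_wallis(g)$h, 0)
  set.seed(22)
  groups <- list(rnorm(10), rnorm(10, 0.5), sample(1:4, 10, TRUE))
  expect_equal(kruskal_wallis(groups)$h, oracle_kruskal(groups),
               tolerance = 1e-12)
  # two groups: H equals the squared tie-corrected MW z (no continuity)
  x <- rnorm(12); y <- rnorm(15, 0.3)
  h <- kruskal_wallis(list(x, y))$h
  n1 <- 12; n2 <- 15; n <- n1 + n2
  u <- sum(rank(c(x, y))[1:n1]) - n1 * (n1 + 1) / 2
  z <- (u - n1 * n2 / 2) / sqrt(n1 * n2 * (n + 1) / 12)
  expect_equal(h, z^2, tolerance = 1e-10)
  expect_error(kruskal_wallis(list(rnorm(3))), "2 groups")
})

test_that("Bonferroni correction caps and validates the family size", {
  expect_equal(bonferroni(0.01, 5), 0.05)
  expect_equal(bonferroni(0.5, 10), 1)
  expect_error(bonferroni(0.1, 0), "m must be")
  expect_error(bonferroni(runif(10), 5), "smaller")
  # familywise error of the corrected rule matches the closed form
  set.seed(23)
  m <- 1000L
  alpha <- 0.05
  fwer <- mean(replicate(5000, any(runif(m) < alpha / m)))
  expect_lt(abs(fwer - (1 - (1 - alpha / m)^m)), 0.01)
})

test_that("a single-cell screen leaves the p-value uncorrected", {
  atl <- toy_atlas()
  atl$regions <- atl$regions[1, , drop = FALSE]
  atl$labels[atl$labels != 1L] <- 0L
  set.seed(24)
  subjects <- sprintf("P%02d", 1:15)
  lesions <- lapply(subjects, function(s)
    list(flair = random_mask_on(atl, runif(1, 0.1, 0.6), "flair", s)))
  names(lesions) <- subjects
  ov <- overlap_table(lesions, atl)
  cohort <- data.frame(subject_id = subjects, group = "patient",
                       wordlist_immediate = rnorm(15))
  scr <- correlation_screen(ov, cohort, atl,
                            tests = "wordlist_immediate",
                            lesion_types = "flair")
  expect_equal(nrow(scr), 1)
  expect_equal(scr$family_size, 1)
  expect_equal(scr$p_bonferroni, scr$p_raw)
})

test_that("the screen is invariant to subject order and flags dead cells", {
  fx <- tiny_imaging()
  coh <- simulate_cohort(fx$cfg, fx$overlaps)
  s1 <- correlation_screen(fx$overlaps, coh$patients, fx$atlas)
  shuffled <- coh$patients[sample(nrow(coh$patients)), ]
  s2 <- correlation_screen(fx$overlaps, shuffled, fx$atlas)
  expect_equal(s1$tau_b, s2$tau_b)
  expect_equal(s1$p_raw, s2$p_raw)
  # regions nobody's lesion touches are reported as not computable
  fr <- lesioncog:::overlap_matrix(fx$overlaps, "cavity", "fraction")
  dead <- as.integer(colnames(fr)[colSums(fr) == 0])
  if (length(dead) > 0) {
    cells <- s1[s1$lesion_type == "cavity" & s1$region_id %in% dead, ]
    expect_true(all(is.na(cells$tau_b)))
    expect_true(all(!cells$significant))
  }
  # family sizes follow the per-atlas rule
  expect_equal(unique(s1$family_size[s1$kind == "node"]), 100 * 11)
  expect_equal(unique(s1$family_size[s1$kind == "tract"]), 48 * 11)
  g <- correlation_screen(fx$overlaps, coh$patients, fx$atlas,
                          family = "global")
  expect_equal(unique(g$family_size), nrow(g))
})

test_that("covariate associations dispatch by declared type", {
  cfg <- tiny_config(seed = 30)
  hits <- 0L
  n_rep <- 100L
  for (r in seq_len(n_rep)) {
    cov <- generate_covariates(121, "patient", cfg,
                               seed = derive_seed(3, paste0("ca", r)))
    sc <- generate_cognition(cov, cfg,
                             seed = derive_seed(4, paste0("cs", r)))
    a <- covariate_associations(sc, c(age = "continuous"),
                                tests = "wordlist_immediate")
    hits <- hits + (a$statistic < 0 && a$p < 0.05)
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("null gender comparisons reject near the nominal rate", {
  set.seed(31)
  n_rep <- 400L
  rej <- 0L
  for (r in seq_len(n_rep)) {
    d <- data.frame(gender = rep(c("m", "f"), each = 40),
                    score = rnorm(80))
    a <- covariate_associations(d, c(gender = "dichotomous"),
                                tests = "score")
    rej <- rej + (a$p < 0.05)
  }
  expect_gt(rej / n_rep, 0.02)
  expect_lt(rej / n_rep, 0.09)
})

test_that("constant covariates yield not-computable rows", {
  d <- data.frame(x = rep(1, 20), score = rnorm(20))
  a <- covariate_associations(d, c(x = "continuous"), tests = "score")
  expect_false(a$computable)
  expect_error(covariate_associations(d, c(x = "weird"), tests = "score"),
               "undeclared")
})
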
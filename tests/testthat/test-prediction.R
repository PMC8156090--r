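test_that("logistic slope on a single binary predictor is the log odds ratio", {
  set.seed(40)
  x <- rep(0:1, each = 50)
  y <- c(rbinom(50, 1, 0.2), rbinom(50, 1, 0.6))
  fit <- fit_logistic(cbind(exposure = x), y)
  tab <- table(factor(x, 0:1), factor(y, 0:1))
  lor <- log(tab[2, 2] * tab[1, 1] / (tab[2, 1] * tab[1, 2]))
  expect_equal(unname(fit$coefficients["exposure"]), lor,
               tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["(Intercept)"]),
               qlogis(mean(y[x == 0])), tolerance = 1e-6)
  expect_equal(fit$flag, "ok")
})

test_that("null predictors give near-logit-prevalence intercepts and |z|<2", {
  set.seed(41)
  z_ok <- c()
  for (r in seq_len(100L)) {
    x <- matrix(rnorm(120 * 3), 120, 3)
    y <- rbinom(120, 1, 0.3)
    if (sum(y) < 2 || sum(y) > 118) next
    fit <- fit_logistic(x, y)
    z <- fit$coefficients[-1] / fit$se[-1]
    z_ok <- c(z_ok, abs(z) < 2)
  }
  expect_gte(mean(z_ok), 0.9)
})

test_that("complete separation is flagged, not silently reported", {
  x <- cbind(v = c(rep(0, 10), rep(1, 10)))
  y <- c(rep(0, 10), rep(1, 10))
  fit <- fit_logistic(x, y)
  expect_equal(fit$flag, "separation")
  fit2 <- fit_logistic(x, y, ridge = TRUE)
  expect_true(all(is.finite(fit2$coefficients)))
  expect_error(fit_logistic(x, rep(1, 20)), "constant")
})

test_that("rank-deficient designs fail naming the aliased column", {
  set.seed(42)
  x <- cbind(a = rnorm(30), b = rnorm(30))
  x <- cbind(x, c = x[, "a"])
  y <- rbinom(30, 1, 0.5)
  expect_error(fit_logistic(x, y), "c")
})

test_that("contingency metrics agree with the hand-counted table", {
  m <- contingency_metrics(c(1, 1, 0, 0, 0), c(0.9, 0.4, 0.6, 0.2, 0.1))
  expect_equal(m$tp, 1); expect_equal(m$fn, 1)
  expect_equal(m$fp, 1); expect_equal(m$tn, 2)
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$specificity, 2 / 3)
  expect_equal(m$ppv, 0.5)
  expect_equal(m$npv, 2 / 3)
  expect_equal(m$accuracy, 0.6)
  # perfect probabilities
  p <- contingency_metrics(c(0, 1, 0, 1), c(0, 1, 0, 1))
  expect_true(all(unlist(p[c("sensitivity", "specificity", "ppv", "npv",
                              "accuracy")]) == 1))
  # all-negative calls: PPV undefined, NPV = 1 - prevalence
  q <- contingency_metrics(c(1, 0, 0, 0), rep(0, 4))
  expect_equal(q$sensitivity, 0)
  expect_equal(q$specificity, 1)
  expect_true(is.na(q$ppv))
  expect_equal(q$npv, 0.75)
  expect_error(contingency_metrics(c(1, 1), c(0.2, 0.6)), "both classes")
})

test_that("contingency metrics recompute from their own 2x2 table", {
  set.seed(43)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    truth <- rbinom(n, 1, 0.4)
    if (sum(truth) %in% c(0, n)) next
    m <- contingency_metrics(truth, runif(n), cutoff = runif(1, 0.2, 0.8))
    with(m, {
      if (tp + fn > 0) expect_equal(sensitivity, tp / (tp + fn))
      if (tn + fp > 0) expect_equal(specificity, tn / (tn + fp))
      expect_equal(accuracy, (tp + tn) / n)
    })
  }
})

test_that("AUC equals both the rank identity and trapezoidal integration", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))$auc, 1)
  set.seed(44)
  for (rep in 1:100) {
    n <- sample(10:80, 1)
    truth <- rbinom(n, 1, 0.4)
    if (sum(truth) %in% c(0, n)) next
    scores <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # with ties
    r <- roc_auc(truth, scores)
    expect_equal(r$auc, oracle_auc_trapezoid(truth, scores),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(rep(1, 5), runif(5)), "both classes")
})

test_that("AUC cross-checks against pROC and survives monotone transforms", {
  skip_if_not_installed("pROC")
  set.seed(45)
  truth <- rbinom(60, 1, 0.4)
  scores <- rnorm(60, truth)
  mine <- roc_auc(truth, scores)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(mine, ref, tolerance = 1e-12)
  expect_equal(roc_auc(truth, exp(scores))$auc, mine)
})

test_that("model comparison reports zero deltas for identical models", {
  set.seed(46)
  x <- matrix(rnorm(80 * 2), 80, 2)
  y <- rbinom(80, 1, plogis(x[, 1]))
  m <- fit_deficit_model(x, y)
  cmp <- compare_models(m, m)
  expect_equal(cmp$d_sensitivity, 0)
  expect_equal(cmp$d_auc, 0)
  expect_false(cmp$improved)
  m2 <- fit_deficit_model(x[1:60, ], y[1:60])
  expect_error(compare_models(m, m2), "different subject")
})

test_that("an all-zero augmentation column surfaces the rank error", {
  set.seed(47)
  x <- cbind(age = rnorm(40), region_overlap = 0)
  expect_error(fit_logistic(x, rbinom(40, 1, 0.4)), "region_overlap")
})

test_that("collinearity check flags duplicates and their negations", {
  set.seed(48)
  base <- rnorm(50)
  x <- cbind(a = base, b = base, c = -base + rnorm(50, 0, 1e-8),
             d = rnorm(50))
  cc <- collinearity_check(x)
  ab <- cc[cc$var1 == "a" & cc$var2 == "b", ]
  expect_equal(ab$r, 1)
  expect_true(ab$collinear)
  ac <- cc[cc$var1 == "a" & cc$var2 == "c", ]
  expect_equal(ac$r, -1, tolerance = 1e-6)
  # zero-variance column: not computable
  cc2 <- collinearity_check(cbind(a = base, z = rep(2, 50)))
  expect_true(is.na(cc2$r))
  expect_error(collinearity_check(cbind(a = base)), "at least 2")
})

test_that("independent columns are rarely flagged as collinear", {
  set.seed(49)
  x <- matrix(rnorm(121 * 40), 121, 40)
  cc <- collinearity_check(x)
  expect_lt(mean(cc$collinear), 0.01)
})
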
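#' Fit a logistic regression for deficit prediction
#'
#' Maximum-likelihood fit (IRLS via [stats::glm()]) of a binary outcome on a
#' numeric design matrix. Complete separation is detected (fitted
#' probabilities numerically 0/1 or exploding coefficients) and flagged; with
#' `ridge = TRUE` a weakly penalised IRLS refit (ridge 1e-6 on the slopes)
#' is returned instead of the diverging estimate.
#'
#' @param x Numeric matrix or data frame of predictors (no intercept
#'   column).
#' @param y Binary outcome (logical or 0/1), same length as `nrow(x)`.
#' @param ridge Use the ridge fallback when separation is detected.
#' @return List with `coefficients`, `se`, `fitted`, `converged` and `flag`
#'   (`"ok"` or `"separation"`).
#' @export
fit_logistic <- function(x, y, ridge = FALSE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.integer(y)
  stopifnot(length(y) == nrow(x), all(y %in% 0:1))
  if (all(y == 0) || all(y == 1))
    stop("outcome is constant (all 0 or all 1)")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  xm <- cbind(`(Intercept)` = 1, x)
  qrx <- qr(xm)
  if (qrx$rank < ncol(xm)) {
    dropped <- colnames(xm)[qrx$pivot[(qrx$rank + 1):ncol(xm)]]
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(dropped, collapse = ", "))
  }
  sep <- FALSE
  fit <- withCallingHandlers(
    glm.fit(xm, y, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- fit$coefficients
  if (any(abs(co) > 15)) sep <- TRUE
  if (sep && ridge) {
    co <- ridge_logistic(xm, y, lambda = 1e-6)
    eta <- as.vector(xm %*% co)
    fitted <- plogis(eta)
    se <- rep(NA_real_, length(co))
  } else {
    fitted <- fit$fitted.values
    w <- fitted * (1 - fitted)
    xtwx <- crossprod(xm * sqrt(w))
    se <- tryCatch(sqrt(diag(solve(xtwx))), error = function(e)
      rep(NA_real_, length(co)))
  }
  names(se) <- names(co) <- colnames(xm)
  list(coefficients = co, se = se, fitted = as.vector(fitted),
       converged = fit$converged && !sep,
       flag = if (sep) "separation" else "ok")
}

# weakly penalised IRLS; the ridge (on slopes only) bounds the diverging
# coefficients under complete separation
ridge_logistic <- function(xm, y, lambda = 1e-6, max_iter = 100L) {
  p <- ncol(xm)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  beta <- rep(0, p)
  for (it in seq_len(max_iter)) {
    eta <- as.vector(xm %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    new <- solve(crossprod(xm * sqrt(w)) + pen,
                 crossprod(xm, w * z))
    if (max(abs(new - beta)) < 1e-10) { beta <- as.vector(new); break }
    beta <- as.vector(new)
  }
  names(beta) <- colnames(xm)
  beta
}

#' Contingency-table classification metrics
#'
#' Thresholds predicted probabilities at `cutoff` (probability at or above
#' the cutoff is a positive call) and reports sensitivity, specificity,
#' positive and negative predictive values and accuracy from the 2x2 table.
#' Predictive values with an empty denominator (e.g. no positive calls) are
#' reported as NA.
#'
#' @param truth Binary true labels.
#' @param prob Predicted probabilities.
#' @param cutoff Classification cutoff on the probability scale.
#' @return List with the 2x2 counts (`tp`, `fp`, `tn`, `fn`) and the five
#'   metrics.
#' @export
contingency_metrics <- function(truth, prob, cutoff = 0.5) {
  truth <- as.integer(truth)
  stopifnot(length(truth) == length(prob), all(truth %in% 0:1))
  if (all(truth == 0) || all(truth == 1))
    stop("both classes must be present in the truth")
  call <- as.integer(prob >= cutoff)
  tp <- sum(call == 1 & truth == 1); fp <- sum(call == 1 & truth == 0)
  tn <- sum(call == 0 & truth == 0); fn <- sum(call == 0 & truth == 1)
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = safe_div(tp, tp + fn),
       specificity = safe_div(tn, tn + fp),
       ppv = safe_div(tp, tp + fp),
       npv = safe_div(tn, tn + fn),
       accuracy = (tp + tn) / length(truth))
}

#' ROC area under the curve with a Mann-Whitney test against 0.5
#'
#' AUC via the Mann-Whitney identity `U / (n1 * n0)` with midrank tie
#' handling (exactly the trapezoidal ROC area). The two-sided p-value tests
#' AUC = 0.5 through the tie-corrected normal approximation of U.
#'
#' @param truth Binary labels.
#' @param scores Numeric scores (higher = more case-like).
#' @return List with `auc`, `p`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(truth, scores) {
  truth <- as.integer(truth)
  stopifnot(length(truth) == length(scores), all(truth %in% 0:1))
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  u <- sum(r[truth == 1]) - n1 * (n1 + 1) / 2
  auc <- u / (n1 * n0)
  n <- n1 + n0
  ties <- table(scores)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  v <- n1 * n0 / 12 * ((n + 1) - tie_term)
  p <- if (v <= 0) NA_real_ else
    2 * pnorm(-abs((u - n1 * n0 / 2) / sqrt(v)))
  list(auc = auc, p = min(1, p), n_pos = n1, n_neg = n0)
}

#' Assemble the modelling data for one cognitive outcome
#'
#' Base covariates are age, education and the total lesion volume (mL) of
#' each of the four lesion types; the augmentation adds one region's overlap
#' measure (T2/FLAIR by default). The outcome is the deficit label from the
#' normative threshold. Rows with a missing score are dropped.
#'
#' @param cohort Patient data frame.
#' @param overlaps Long overlap table.
#' @param thresholds List from [deficit_thresholds()].
#' @param outcome Test name.
#' @param augment_region Optional region id for the augmented model.
#' @param augment_lesion_type Lesion type of the augmentation covariate.
#' @param measure `"fraction"` or `"ml"`.
#' @return List with `x_base`, `x_aug` (or NULL), `y`, `subject_id`.
#' @export
build_model_data <- function(cohort, overlaps, thresholds, outcome,
                             augment_region = NULL,
                             augment_lesion_type = "flair",
                             measure = c("fraction", "ml")) {
  measure <- match.arg(measure)
  patients <- cohort[cohort$group == "patient", , drop = FALSE]
  if (!outcome %in% names(patients)) stop("unknown outcome: ", outcome)
  y <- classify_deficit(patients[[outcome]], thresholds[[outcome]])
  keep <- !is.na(y)
  patients <- patients[keep, , drop = FALSE]
  y <- y[keep]
  totals <- sapply(c("cavity", "t1ce", "flair", "pet"), function(lt) {
    sub <- overlaps[overlaps$lesion_type == lt, ]
    sub$lesion_total_ml[match(patients$subject_id, sub$subject_id)]
  })
  colnames(totals) <- paste0("total_", colnames(totals), "_ml")
  x_base <- cbind(age = patients$age, education = patients$education,
                  totals)
  x_aug <- NULL
  if (!is.null(augment_region)) {
    fr <- overlap_matrix(overlaps, augment_lesion_type, measure,
                         subjects = patients$subject_id)
    key <- as.character(augment_region)
    if (!key %in% colnames(fr))
      stop("augment region ", augment_region, " not in the overlap table")
    aug <- fr[, key]
    x_aug <- cbind(x_base, region_overlap = aug)
  }
  list(x_base = x_base, x_aug = x_aug, y = as.integer(y),
       subject_id = patients$subject_id)
}

#' Fit and evaluate a deficit-prediction model
#'
#' Fits the logistic model, thresholds its apparent (in-sample) predicted
#' probabilities and reports the contingency metrics, AUC and ROC p-value.
#'
#' @param x Design matrix (no intercept).
#' @param y Binary outcome.
#' @param cutoff Probability cutoff for the contingency table.
#' @return List of class `model_report`: coefficients, se, prevalence, the
#'   metrics, `auc`, `p_roc`, `converged`, `flag`, `n`.
#' @export
fit_deficit_model <- function(x, y, cutoff = 0.5) {
  fit <- fit_logistic(x, y, ridge = TRUE)
  cm <- contingency_metrics(y, fit$fitted, cutoff)
  roc <- roc_auc(y, fit$fitted)
  structure(list(coefficients = fit$coefficients, se = fit$se,
                 prevalence = mean(y), cutoff = cutoff,
                 metrics = cm, auc = roc$auc, p_roc = roc$p,
                 converged = fit$converged, flag = fit$flag,
                 n = length(y), fitted = fit$fitted, y = y),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf(paste0("<model_report> n=%d prev=%.2f sens=%.2f spec=%.2f ",
                     "acc=%.2f auc=%.2f p_roc=%.3g [%s]\n"),
              x$n, x$prevalence, x$metrics$sensitivity,
              x$metrics$specificity, x$metrics$accuracy, x$auc, x$p_roc,
              x$flag))
  invisible(x)
}

#' Compare a base and an augmented model report
#'
#' @param base,augmented `model_report`s fitted on the same subjects.
#' @return List with `d_sensitivity`, `d_specificity`, `d_auc` and
#'   `improved` (TRUE when the augmentation raised sensitivity without
#'   lowering the AUC).
#' @export
compare_models <- function(base, augmented) {
  if (base$n != augmented$n || !identical(base$y, augmented$y))
    stop("models were fitted on different subject sets")
  d_sens <- augmented$metrics$sensitivity - base$metrics$sensitivity
  d_spec <- augmented$metrics$specificity - base$metrics$specificity
  d_auc <- augmented$auc - base$auc
  list(d_sensitivity = d_sens, d_specificity = d_spec, d_auc = d_auc,
       improved = isTRUE(d_sens > 0 && d_auc >= 0))
}

#' Pairwise Pearson collinearity check of candidate predictor columns
#'
#' Reports every pairwise Pearson correlation with its two-sided t-test
#' p-value, and which pairs fall below a strong-collinearity p threshold —
#' the justification for augmenting models with a single representative
#' region rather than all correlated ones.
#'
#' @param x Numeric matrix (subjects x regions).
#' @param p_threshold Collinearity flag threshold.
#' @return Data frame of pairs with `r`, `p`, `collinear` (NA rows for
#'   zero-variance columns).
#' @export
collinearity_check <- function(x, p_threshold = 0.001) {
  x <- as.matrix(x)
  if (ncol(x) < 2 || nrow(x) < 3)
    stop("need at least 2 columns and 3 subjects")
  if (is.null(colnames(x))) colnames(x) <- paste0("v", seq_len(ncol(x)))
  pairs <- utils::combn(ncol(x), 2)
  rows <- apply(pairs, 2, function(ij) {
    a <- x[, ij[1]]; b <- x[, ij[2]]
    if (sd(a) == 0 || sd(b) == 0)
      return(data.frame(var1 = colnames(x)[ij[1]], var2 = colnames(x)[ij[2]],
                        r = NA_real_, p = NA_real_, collinear = NA,
                        stringsAsFactors = FALSE))
    ct <- cor.test(a, b, method = "pearson")
    data.frame(var1 = colnames(x)[ij[1]], var2 = colnames(x)[ij[2]],
               r = unname(ct$estimate), p = ct$p.value,
               collinear = ct$p.value < p_threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
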
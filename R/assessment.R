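#' TMT-B / TMT-A ratio
#'
#' Additional executive-function measure; undefined (NA, with a message) when
#' TMT-A is nonpositive.
#'
#' @param tmt_b,tmt_a Completion times in seconds.
#' @return Numeric ratio vector.
#' @export
tmt_ratio <- function(tmt_b, tmt_a) {
  bad <- !is.na(tmt_a) & tmt_a <= 0
  if (any(bad))
    message(sprintf("tmt_ratio: %d nonpositive TMT-A value(s) set to NA",
                    sum(bad)))
  out <- tmt_b / tmt_a
  out[bad] <- NA_real_
  out
}

#' Add the derived TMT ratio column to a cohort table
#' @param cohort Cohort data frame with `tmt_a` and `tmt_b` columns.
#' @return The cohort with a `tmt_ratio` column appended.
#' @export
add_derived_scores <- function(cohort) {
  if (all(c("tmt_a", "tmt_b") %in% names(cohort)))
    cohort$tmt_ratio <- tmt_ratio(cohort$tmt_b, cohort$tmt_a)
  cohort
}

#' Normative deficit threshold for one test
#'
#' Clinically relevant impairment is a score 1.5 control SDs worse than the
#' control mean. For higher-is-better tests the cutoff is
#' `mean - 1.5 * sd`; for lower-is-better tests (TMT times) the rule mirrors
#' to `mean + 1.5 * sd`, the worse tail. Sample SD uses the n-1 denominator.
#'
#' @param control_scores Scores of the healthy controls (NAs dropped).
#' @param direction `"higher_better"` or `"lower_better"`.
#' @param test_name Optional label carried into the result.
#' @return List of class `deficit_threshold` with `control_mean`,
#'   `control_sd`, `cutoff`, `direction`, `n_controls`.
#' @export
deficit_threshold <- function(control_scores,
                              direction = c("higher_better", "lower_better"),
                              test_name = NA_character_) {
  direction <- match.arg(direction)
  x <- control_scores[!is.na(control_scores)]
  if (length(x) < 2) stop("need at least 2 non-missing control scores")
  m <- mean(x); s <- sd(x)
  cutoff <- if (direction == "higher_better") m - 1.5 * s else m + 1.5 * s
  structure(list(test_name = test_name, control_mean = m, control_sd = s,
                 cutoff = cutoff, direction = direction,
                 n_controls = length(x)),
            class = "deficit_threshold")
}

#' Classify scores as clinically relevant deficits
#'
#' Strict comparison: a score exactly at the cutoff is unimpaired ("below"
#' the cutoff means strictly worse). Missing scores give NA labels.
#'
#' @param score Numeric scores.
#' @param threshold A [deficit_threshold()].
#' @return Logical vector (TRUE = deficit).
#' @export
classify_deficit <- function(score, threshold) {
  if (threshold$direction == "higher_better") score < threshold$cutoff
  else score > threshold$cutoff
}

#' Deficit thresholds for a whole battery
#' @param controls Control cohort data frame with score columns.
#' @param tests Data frame with `test` and `direction` columns (the derived
#'   `tmt_ratio` is appended automatically when present in the data).
#' @return Named list of [deficit_threshold()] objects.
#' @export
deficit_thresholds <- function(controls, tests = test_definitions()) {
  defs <- tests[, c("test", "direction")]
  if ("tmt_ratio" %in% names(controls) && !"tmt_ratio" %in% defs$test)
    defs <- rbind(defs, data.frame(test = "tmt_ratio",
                                   direction = "lower_better"))
  out <- lapply(seq_len(nrow(defs)), function(i)
    deficit_threshold(controls[[defs$test[i]]], defs$direction[i],
                      defs$test[i]))
  names(out) <- defs$test
  out
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments,
# with midranks (handles ties); p = 2 * min(P(U <= u), P(U >= u)), capped
mann_whitney_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n, n1)
  u_all <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
  eps <- 1e-9
  p <- 2 * min(mean(u_all <= u_obs + eps), mean(u_all >= u_obs - eps))
  list(u = u_obs, p = min(1, p))
}

#' Two-sided Mann-Whitney U test
#'
#' Exact enumeration of all group assignments (with midranks) when both
#' groups have at most 8 observations; otherwise the tie-corrected normal
#' approximation with continuity correction via [stats::wilcox.test()].
#'
#' @param x,y Numeric samples (NAs dropped).
#' @return List with `u` (statistic for the first sample) and `p`.
#' @export
mann_whitney <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0)
    stop("both groups must be nonempty")
  if (length(x) <= 8 && length(y) <= 8) return(mann_whitney_exact(x, y))
  wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  list(u = unname(wt$statistic), p = wt$p.value)
}

#' Patient-control comparison of cognitive test scores
#'
#' Per test: group means and SDs, the two-sided Mann-Whitney U p-value with
#' significance stars, and (when thresholds are supplied) the number and
#' percentage of patients with a clinically relevant deficit.
#'
#' @param patients,controls Cohort data frames with score columns.
#' @param tests Character vector of test column names; defaults to the
#'   battery plus `tmt_ratio` when present.
#' @param thresholds Optional list from [deficit_thresholds()].
#' @return Summary data frame, one row per test.
#' @export
compare_groups <- function(patients, controls, tests = NULL,
                           thresholds = NULL) {
  if (is.null(tests)) {
    tests <- intersect(c(test_definitions()$test, "tmt_ratio"),
                       names(patients))
  }
  rows <- lapply(tests, function(tn) {
    xp <- patients[[tn]]; xc <- controls[[tn]]
    computable <- sum(!is.na(xp)) > 0 && sum(!is.na(xc)) > 0
    if (computable) mw <- mann_whitney(xp, xc)
    n_def <- pct_def <- NA_real_
    if (!is.null(thresholds) && tn %in% names(thresholds)) {
      lab <- classify_deficit(xp, thresholds[[tn]])
      n_def <- sum(lab, na.rm = TRUE)
      pct_def <- 100 * n_def / sum(!is.na(lab))
    }
    data.frame(
      test = tn,
      control_mean = mean(xc, na.rm = TRUE),
      control_sd = sd(xc, na.rm = TRUE),
      patient_mean = mean(xp, na.rm = TRUE),
      patient_sd = sd(xp, na.rm = TRUE),
      u = if (computable) mw$u else NA_real_,
      p = if (computable) mw$p else NA_real_,
      stars = if (computable) stars_for_p(mw$p) else "",
      n_deficit = n_def, pct_deficit = pct_def,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
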
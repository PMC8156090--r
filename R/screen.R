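#' Kendall tau-b rank correlation with tie-corrected p-value
#'
#' The screen's core statistic:
#' `tau_b = (C - D) / sqrt((n0 - n1)(n0 - n2))` with `n0 = n(n-1)/2` and tie
#' terms `n1 = sum t(t-1)/2`, `n2 = sum u(u-1)/2` over tie groups of x and y.
#' The two-sided p-value comes from the normal approximation of `S = C - D`
#' with the tie-corrected variance and a continuity correction (S is
#' discrete; the correction keeps the approximation within 0.02 of the exact
#' permutation p down to n = 6). Ties are expected and handled exactly:
#' most lesion-region overlaps are zero, so large tie groups in x are the
#' rule, not the exception.
#'
#' @param x,y Paired numeric vectors; incomplete pairs are dropped.
#' @return List with `tau`, `z`, `p`, `n`; `tau` and `p` are `NA` when all
#'   pairs are tied in either variable (tau undefined).
#' @export
kendall_tau_b <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  r <- .kendall_tau_b_cpp(as.numeric(x), as.numeric(y))
  list(tau = r[["tau"]], z = r[["z"]], p = r[["p"]], n = length(x))
}

#' Spearman rank correlation with t-approximation p-value
#' @param x,y Paired numeric vectors; incomplete pairs dropped.
#' @return List with `rho`, `p`, `n`; `NA`s when a rank variance is zero.
#' @export
spearman_rho <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = length(x)))
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Kruskal-Wallis test across groups
#' @param groups List of numeric samples (each nonempty after NA removal).
#' @return List with `h`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(lengths(groups) == 0)) stop("each group must be nonempty")
  kt <- kruskal.test(groups)
  list(h = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Bonferroni correction
#' @param p_values Numeric p-values.
#' @param m Family size; must be at least the number of p-values.
#' @return `pmin(1, m * p)`.
#' @export
bonferroni <- function(p_values, m) {
  if (m < 1) stop("family size m must be >= 1")
  if (m < sum(!is.na(p_values)))
    stop("family size m is smaller than the number of p-values")
  pmin(1, m * p_values)
}

#' Mass-univariate Kendall tau-b screen of overlaps against test scores
#'
#' For every (lesion type, region, test) cell, the Kendall tau-b correlation
#' between the per-patient overlap measure and the test score, over patients
#' with a non-missing score. Patients with zero overlap are retained: they
#' anchor the unaffected end of the ranking. Cells where every patient has
#' the same overlap (typically all-zero) are reported as not computable.
#'
#' Bonferroni families: with `family = "per_atlas"` (default) each lesion
#' type is corrected separately within the node regions and within the tract
#' regions, `m = (#regions of that kind) * (#tests)`, matching a per-heat-map
#' reading of "the total number of tests"; `family = "global"` uses one
#' family spanning all cells of the screen.
#'
#' @param overlaps Long overlap table (see [overlap_table()]).
#' @param cohort Cohort data frame (patients; score columns present).
#' @param atlas A [label_atlas()] providing region kinds.
#' @param tests Character vector of score columns to screen; defaults to the
#'   battery plus `tmt_ratio` when present.
#' @param lesion_types Lesion types to screen.
#' @param alpha Familywise significance level.
#' @param family `"per_atlas"` or `"global"`.
#' @param measure `"fraction"` (region fraction affected) or `"ml"`.
#' @param subgroup `"all"` or `"pet_negative"` (patients whose PET mask is
#'   empty, i.e. no detectable recurrent tumor).
#' @return Data frame of class `screen_result`, sorted by raw p, with
#'   columns `lesion_type`, `region_id`, `region_name`, `kind`, `test_name`,
#'   `n_used`, `tau_b`, `p_raw`, `p_bonferroni`, `family_size`,
#'   `significant`.
#' @export
correlation_screen <- function(overlaps, cohort, atlas, tests = NULL,
                               lesion_types = c("cavity", "t1ce",
                                                "flair", "pet"),
                               alpha = 0.05,
                               family = c("per_atlas", "global"),
                               measure = c("fraction", "ml"),
                               subgroup = c("all", "pet_negative")) {
  family <- match.arg(family)
  measure <- match.arg(measure)
  subgroup <- match.arg(subgroup)
  if (is.null(tests))
    tests <- intersect(c(test_definitions()$test, "tmt_ratio"),
                       names(cohort))
  patients <- cohort[cohort$group == "patient", , drop = FALSE]
  if (subgroup == "pet_negative") {
    pet <- overlaps[overlaps$lesion_type == "pet", ]
    pos <- unique(pet$subject_id[pet$lesion_total_ml > 0])
    patients <- patients[!patients$subject_id %in% pos, , drop = FALSE]
  }
  have <- unique(overlaps$subject_id)
  if (!all(patients$subject_id %in% have))
    stop("every screened patient needs overlap rows")
  y <- as.matrix(patients[, tests, drop = FALSE])
  regions <- atlas$regions
  out <- lapply(lesion_types, function(lt) {
    x <- overlap_matrix(overlaps, lt, measure,
                        subjects = patients$subject_id)
    ids <- as.integer(colnames(x))
    res <- .kendall_screen_cpp(x, y)
    data.frame(
      lesion_type = lt,
      region_id = rep(ids, times = length(tests)),
      test_name = rep(tests, each = length(ids)),
      n_used = as.vector(res$n_used),
      tau_b = as.vector(res$tau),
      p_raw = as.vector(res$p),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$region_name <- regions$name[match(out$region_id, regions$id)]
  out$kind <- regions$kind[match(out$region_id, regions$id)]
  if (family == "global") {
    out$family_size <- nrow(out)
  } else {
    n_tests <- length(tests)
    kind_counts <- table(regions$kind)
    out$family_size <- as.integer(kind_counts[out$kind]) * n_tests
  }
  out$p_bonferroni <- pmin(1, out$family_size * out$p_raw)
  out$significant <- !is.na(out$p_bonferroni) & out$p_bonferroni < alpha
  out <- out[order(out$p_raw), c(
    "lesion_type", "region_id", "region_name", "kind", "test_name",
    "n_used", "tau_b", "p_raw", "p_bonferroni", "family_size",
    "significant")]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "family") <- family
  attr(out, "measure") <- measure
  attr(out, "subgroup") <- subgroup
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Pivot a screen result into heat-map tables
#'
#' One wide table (regions as rows, tests as columns, raw p-values as cells)
#' per lesion type and region kind, mirroring the usual heat-map layout.
#'
#' @param screen A [correlation_screen()] result.
#' @return Named list of data frames.
#' @export
screen_heatmap <- function(screen) {
  out <- list()
  for (lt in unique(screen$lesion_type)) {
    for (kd in unique(screen$kind)) {
      sub <- screen[screen$lesion_type == lt & screen$kind == kd, ]
      if (nrow(sub) == 0) next
      wide <- stats::reshape(
        sub[, c("region_name", "test_name", "p_raw")],
        idvar = "region_name", timevar = "test_name", direction = "wide")
      names(wide) <- sub("^p_raw\\.", "", names(wide))
      wide <- wide[order(wide$region_name), ]
      rownames(wide) <- NULL
      out[[paste(lt, kd, sep = "_")]] <- wide
    }
  }
  out
}

#' Associations of covariates and total lesion volumes with test scores
#'
#' Dispatches by declared variable type: Spearman rank correlation for
#' continuous/ordinal variables, two-sided Mann-Whitney for dichotomous
#' ones, Kruskal-Wallis for categorical variables with more than two levels.
#'
#' @param cohort Patient data frame.
#' @param variables Named character vector mapping variable names to types
#'   (`"continuous"`, `"dichotomous"`, `"categorical"`).
#' @param tests Score columns to relate to.
#' @return Data frame with one row per (variable, test) pair: the statistic,
#'   its name, and p (NA rows marked not computable, e.g. constant
#'   covariates).
#' @export
covariate_associations <- function(cohort,
                                   variables = c(age = "continuous",
                                                 education = "continuous",
                                                 gender = "dichotomous"),
                                   tests = NULL) {
  if (is.null(tests))
    tests <- intersect(c(test_definitions()$test, "tmt_ratio"),
                       names(cohort))
  bad <- setdiff(unname(variables),
                 c("continuous", "dichotomous", "categorical"))
  if (length(bad) > 0)
    stop("undeclared variable type: ", paste(bad, collapse = ", "))
  rows <- list()
  for (v in names(variables)) {
    for (tn in tests) {
      x <- cohort[[v]]; y <- cohort[[tn]]
      type <- variables[[v]]
      stat <- p <- NA_real_
      stat_name <- switch(type, continuous = "spearman_rho",
                          dichotomous = "mann_whitney_u",
                          categorical = "kruskal_wallis_h")
      ok <- length(unique(x[!is.na(x)])) > 1
      if (ok && type == "continuous") {
        r <- spearman_rho(x, y)
        stat <- r$rho; p <- r$p
      } else if (ok && type == "dichotomous") {
        g <- split(y, x)
        if (length(g) == 2) {
          r <- mann_whitney(g[[1]], g[[2]])
          stat <- r$u; p <- r$p
        }
      } else if (ok && type == "categorical") {
        r <- kruskal_wallis(split(y, x))
        stat <- r$h; p <- r$p
      }
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, test = tn, type = type, statistic_name = stat_name,
        statistic = stat, p = p, computable = ok & !is.na(p),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
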
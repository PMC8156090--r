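#' Generate covariates for a synthetic cohort
#'
#' Ages are Gaussian (clamped to `age_range`), gender Bernoulli, and the
#' ISCED-like education score a rounded clamped Gaussian.
#'
#' @param n Number of subjects.
#' @param group `"patient"` or `"control"`.
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @param prefix Subject-id prefix.
#' @return Data frame with `subject_id`, `group`, `age`, `gender`,
#'   `education`.
#' @export
generate_covariates <- function(n, group = c("patient", "control"), config,
                                seed, prefix = NULL) {
  group <- match.arg(group)
  cfg <- validate_synthetic_config(config)
  if (is.null(prefix)) prefix <- if (group == "patient") "P" else "C"
  with_seed(seed, {
    age <- pmin(pmax(rnorm(n, cfg$age_mean, cfg$age_sd),
                     cfg$age_range[1]), cfg$age_range[2])
    gender <- ifelse(runif(n) < cfg$male_prob, "m", "f")
    edu <- round(pmin(pmax(rnorm(n, cfg$edu_mean, cfg$edu_sd),
                           cfg$edu_range[1]), cfg$edu_range[2]))
    data.frame(subject_id = sprintf("%s%03d", prefix, seq_len(n)),
               group = group, age = age, gender = gender, education = edu,
               stringsAsFactors = FALSE)
  })
}

#' Generate cognitive scores for a synthetic cohort
#'
#' Linear-Gaussian generative model per test k and subject i:
#' \deqn{score_{ik} = \mu_k + \beta_{age,k}(age_i - 50) +
#'   \beta_{edu,k}(edu_i - 7) \pm \sum_r \gamma_{kr} f_{ir} + \epsilon_{ik}}
#' where \eqn{f_{ir}} is the subject's T2/FLAIR overlap fraction with planted
#' region r and \eqn{\epsilon_{ik} \sim N(0, \sigma_k^2)}. The lesion term is
#' subtracted for higher-is-better tests and added for lower-is-better tests
#' (TMT), so positive gamma always worsens performance. Controls get the same
#' model with a zero lesion term.
#'
#' @param covariates Covariate data frame from [generate_covariates()].
#' @param config A [synthetic_config()]; `config$planted_effects` supplies
#'   the gammas.
#' @param overlaps Overlap table covering every patient (ignored for
#'   controls); required when planted effects are present.
#' @param seed Integer seed for the noise.
#' @return The covariate data frame with one numeric column per test.
#' @export
generate_cognition <- function(covariates, config, overlaps = NULL,
                               seed = derive_seed(config$seed, "cognition")) {
  cfg <- validate_synthetic_config(config)
  tests <- cfg$tests
  if (!all(tests$direction %in% c("higher_better", "lower_better")))
    stop("unknown test direction")
  pe <- cfg$planted_effects
  is_patient <- covariates$group == "patient"
  if (!is.null(pe) && nrow(pe) > 0 && any(is_patient)) {
    if (is.null(overlaps)) stop("overlaps required when effects are planted")
    have <- unique(overlaps$subject_id[overlaps$lesion_type == "flair"])
    if (!all(covariates$subject_id[is_patient] %in% have))
      stop("every patient needs flair overlap rows")
    fr <- overlap_matrix(overlaps, "flair", "fraction",
                         subjects = covariates$subject_id[is_patient])
    if (!all(as.character(pe$region_id) %in% colnames(fr)))
      stop("planted region ids missing from the overlap table")
  }
  out <- covariates
  with_seed(seed, {
    for (t in seq_len(nrow(tests))) {
      tk <- tests[t, ]
      worse <- if (tk$direction == "lower_better") 1 else -1
      score <- tk$mu + tk$beta_age * (covariates$age - 50) +
        tk$beta_edu * (covariates$education - 7)
      if (!is.null(pe) && nrow(pe) > 0 && any(is_patient)) {
        rows <- pe[pe$test_name == tk$test, , drop = FALSE]
        if (nrow(rows) > 0) {
          lesion_term <- as.vector(
            fr[, as.character(rows$region_id), drop = FALSE] %*% rows$gamma)
          score[is_patient] <- score[is_patient] + worse * lesion_term
        }
      }
      out[[tk$test]] <- score + rnorm(nrow(covariates), 0, tk$sigma)
    }
  })
  out
}

#' Calibrate a planted effect size for a target Kendall tau
#'
#' Given the fixed overlap-fraction vector of the planted region and the
#' test's noise SD, finds the gamma for which the expected Kendall tau-b
#' between fraction and score reaches `tau_target`, by bisection over quick
#' Monte-Carlo estimates. This pins "an effect sized for tau = 0.3" to the
#' actual generative conditions (zero-inflated fractions, Gaussian noise)
#' instead of a bivariate-normal approximation.
#'
#' @param fractions Overlap fractions of the planted region across patients.
#' @param sigma Noise SD of the test score.
#' @param tau_target Target absolute tau-b.
#' @param n_sim Monte-Carlo replicates per candidate gamma.
#' @param seed Integer seed.
#' @return Positive gamma (score units per unit overlap fraction).
#' @export
calibrate_planted_gamma <- function(fractions, sigma, tau_target = 0.3,
                                    n_sim = 60L, seed = 1L) {
  stopifnot(sd(fractions) > 0, sigma > 0, tau_target > 0, tau_target < 1)
  mean_tau <- function(gamma) {
    taus <- vapply(seq_len(n_sim), function(r) {
      y <- -gamma * fractions + rnorm(length(fractions), 0, sigma)
      abs(.kendall_tau_b_cpp(fractions, y)[["tau"]])
    }, numeric(1))
    mean(taus, na.rm = TRUE)
  }
  with_seed(seed, {
    lo <- 0.01 * sigma / sd(fractions)
    hi <- 50 * sigma / sd(fractions)
    for (it in seq_len(25L)) {
      mid <- sqrt(lo * hi)
      if (mean_tau(mid) < tau_target) lo <- mid else hi <- mid
      if (hi / lo < 1.05) break
    }
    sqrt(lo * hi)
  })
}

#' Propensity-score matching of healthy controls to patients
#'
#' Fits a logistic propensity model of patient status on the stated
#' covariates over the pooled sample, then matches each patient to the
#' nearest unused control on the logit scale (greedy 1:1 nearest neighbour
#' without replacement, patients processed in order of decreasing propensity).
#'
#' @param patients,pool Covariate data frames (pool rows are candidate
#'   controls); `pool` must be at least as large as `patients`.
#' @param covariates Matching covariates.
#' @return The matched controls, one row per patient, with columns
#'   `matched_to` (patient id) and `propensity`.
#' @export
match_controls <- function(patients, pool,
                           covariates = c("age", "gender", "education")) {
  if (nrow(pool) < nrow(patients))
    stop("control pool is smaller than the patient group")
  stacked <- rbind(
    cbind(patients[covariates], .treat = 1),
    cbind(pool[covariates], .treat = 0))
  for (v in covariates)
    if (is.character(stacked[[v]])) stacked[[v]] <- factor(stacked[[v]])
  fit <- glm(.treat ~ ., data = stacked, family = binomial())
  lp <- fit$linear.predictors
  lp_pat <- lp[seq_len(nrow(patients))]
  lp_pool <- lp[-seq_len(nrow(patients))]
  take <- integer(nrow(patients))
  used <- logical(nrow(pool))
  for (i in order(lp_pat, decreasing = TRUE)) {
    d <- abs(lp_pool - lp_pat[i])
    d[used] <- Inf
    j <- which.min(d)
    take[i] <- j
    used[j] <- TRUE
  }
  out <- pool[take, , drop = FALSE]
  out$matched_to <- patients$subject_id
  out$propensity <- plogis(lp_pool[take])
  rownames(out) <- NULL
  out
}

#' Standardized mean difference of a covariate between two groups
#' @param x,y Numeric vectors.
#' @return `(mean(x) - mean(y)) / pooled SD`; 0 when both SDs are 0.
#' @export
standardized_mean_difference <- function(x, y) {
  s <- sqrt((var(x) + var(y)) / 2)
  if (!is.finite(s) || s == 0) return(0)
  (mean(x) - mean(y)) / s
}
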
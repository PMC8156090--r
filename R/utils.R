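#' Derive a stage-specific random seed
#'
#' All stochastic stages of the pipeline derive their own seed from the single
#' run seed plus a text label (stage name, subject id, replicate index), so
#' every stage is independently reproducible and no stage consumes another
#' stage's random stream.
#'
#' @param seed Integer master seed (< 2^31).
#' @param label Character label naming the stage.
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 1013904223
  as.integer((abs(seed) %% 2147483647 * 48271 + h) %% 2147483629)
}

# run `expr` under a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Dice similarity of two binary arrays on the same grid
#' Dice coefficient of two binary masks
#' @param a,b Logical arrays of identical shape.
#' @return Dice similarity in `[0, 1]`; `NA` when both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(NA_real_)
  2 * sum(a & b) / (na + nb)
}

affines_match <- function(a, b, tol = 1e-6) {
  is.matrix(a) && is.matrix(b) && all(dim(a) == c(4, 4)) &&
    all(dim(b) == c(4, 4)) && max(abs(a - b)) < tol
}

stars_for_p <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***",
    ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "n.s."))))
}
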
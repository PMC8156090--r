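# Brute-force oracles, deliberately simple and independent of the package's
# computational paths.

# O(n^2) pair classification + tie-corrected formulas
oracle_kendall <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[i] - x[j]; dy <- y[i] - y[j]
      if (dx != 0 && dy != 0) {
        if (sign(dx) == sign(dy)) C <- C + 1 else D <- D + 1
      }
    }
  }
  tie <- function(v) {
    t <- as.numeric(table(v))
    list(s1 = sum(t * (t - 1) / 2), s2 = sum(t * (t - 1) * (2 * t + 5)),
         s3 = sum(t * (t - 1)), s4 = sum(t * (t - 1) * (t - 2)))
  }
  tx <- tie(x); ty <- tie(y)
  n0 <- n * (n - 1) / 2
  den <- (n0 - tx$s1) * (n0 - ty$s1)
  if (den <= 0) return(list(tau = NA_real_, p = NA_real_))
  S <- C - D
  v <- (n * (n - 1) * (2 * n + 5) - tx$s2 - ty$s2) / 18 +
    tx$s3 * ty$s3 / (2 * n * (n - 1)) +
    tx$s4 * ty$s4 / (9 * n * (n - 1) * (n - 2))
  s_cc <- max(abs(S) - 1, 0)  # continuity correction for discrete S
  list(tau = S / sqrt(den), p = min(1, 2 * pnorm(-s_cc / sqrt(v))))
}

# exact permutation p for S = C - D (no ties assumed), all n! permutations
oracle_kendall_exact_p <- function(x, y) {
  n <- length(x)
  s_of <- function(yy) {
    s <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      s <- s + sign(x[i] - x[j]) * sign(yy[i] - yy[j])
    s
  }
  s_obs <- s_of(y)
  perms <- gtools_permutations(n)
  s_all <- apply(perms, 1, function(p) s_of(y[p]))
  mean(abs(s_all) >= abs(s_obs))
}

# all permutations of 1..n (small n only)
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(nrow(sub))) {
      rest <- seq_len(n)[-k]
      out[r, ] <- c(k, rest[sub[i, ]])
      r <- r + 1
    }
  }
  out
}

# triple-loop voxel counting
oracle_overlap <- function(mask_arr, labels, ids, vvol) {
  dm <- dim(labels)
  hit <- setNames(numeric(length(ids)), as.character(ids))
  regv <- hit
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    l <- labels[i, j, k]
    if (l > 0) {
      key <- as.character(l)
      regv[key] <- regv[key] + 1
      if (mask_arr[i, j, k]) hit[key] <- hit[key] + 1
    }
  }
  list(overlap_ml = hit * vvol, region_volume_ml = regv * vvol)
}

# naive per-voxel TBR threshold
oracle_tbr <- function(pet, brain, ref_mask, threshold, statistic = "mean") {
  vals <- pet[ref_mask]
  ref <- if (statistic == "mean") mean(vals) else median(vals)
  out <- array(FALSE, dim(pet))
  dm <- dim(pet)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3]))
    out[i, j, k] <- brain[i, j, k] && (pet[i, j, k] / ref >= threshold)
  out
}

# 26-connectivity flood fill in plain R
oracle_components <- function(mask) {
  dm <- dim(mask)
  lab <- array(0L, dm)
  nxt <- 0L
  for (s in which(mask & lab == 0)) {
    if (lab[s] != 0) next
    nxt <- nxt + 1L
    queue <- s
    lab[s] <- nxt
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      ijk <- arrayInd(v, dm)[1, ]
      for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
        if (di == 0 && dj == 0 && dk == 0) next
        w <- ijk + c(di, dj, dk)
        if (any(w < 1) || any(w > dm)) next
        wl <- w[1] + dm[1] * (w[2] - 1 + dm[2] * (w[3] - 1))
        if (mask[wl] && lab[wl] == 0) {
          lab[wl] <- nxt
          queue <- c(queue, wl)
        }
      }
    }
  }
  lab
}

# per-target-voxel nearest-source lookup
oracle_resample <- function(mask_arr, src_affine, tgt_dim, tgt_affine) {
  m <- solve(src_affine) %*% tgt_affine
  out <- array(FALSE, tgt_dim)
  sdim <- dim(mask_arr)
  for (i in seq_len(tgt_dim[1])) for (j in seq_len(tgt_dim[2])) {
    for (k in seq_len(tgt_dim[3])) {
      src <- round(m %*% c(i - 1, j - 1, k - 1, 1))[1:3]
      if (all(src >= 0) && all(src < sdim))
        out[i, j, k] <- mask_arr[src[1] + 1, src[2] + 1, src[3] + 1]
    }
  }
  out
}

# trapezoidal ROC integration
oracle_auc_trapezoid <- function(truth, scores) {
  th <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  sens <- vapply(th, function(t) mean(scores[truth == 1] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(scores[truth == 0] >= t), numeric(1))
  sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
}

# tie-corrected Kruskal-Wallis from the rank-sum formula
oracle_kruskal <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  r <- rank(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, sum)^2 / lengths(groups)) - 3 * (n + 1)
  t <- as.numeric(table(x))
  h / (1 - sum(t^3 - t) / (n^3 - n))
}
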
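# Independent brute-force oracles. These deliberately share no code with the
# package: GLCM counts come from exhaustive voxel-pair enumeration with
# explicit loops, and every feature is evaluated term by term from its
# definition.

oracle_glcm_counts <- function(q, offset, ng) {
  dm <- dim(q)
  counts <- matrix(0L, ng, ng)
  for (x in seq_len(dm[1])) {
    for (y in seq_len(dm[2])) {
      for (z in seq_len(dm[3])) {
        a <- q[x, y, z]
        if (a == 0) next
        xx <- x + offset[1]; yy <- y + offset[2]; zz <- z + offset[3]
        if (xx < 1 || xx > dm[1] || yy < 1 || yy > dm[2] || zz < 1 || zz > dm[3]) next
        b <- q[xx, yy, zz]
        if (b == 0) next
        counts[a, b] <- counts[a, b] + 1L # forward order
        counts[b, a] <- counts[b, a] + 1L # reverse order (symmetric)
      }
    }
  }
  counts
}

oracle_glcm_features <- function(p, ng, homogeneity_kind = "inverse_difference") {
  stopifnot(abs(sum(p) - 1) < 1e-9)
  energy <- 0; entropy <- 0; contrast <- 0; homogeneity <- 0
  dissimilarity <- 0; sum_avg <- 0
  px <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) px[i] <- px[i] + p[i, j]
  mu_x <- 0
  for (i in 1:ng) mu_x <- mu_x + i * px[i]
  var_x <- 0
  for (i in 1:ng) var_x <- var_x + (i - mu_x)^2 * px[i]
  corr_num <- 0
  variance <- 0
  for (i in 1:ng) {
    for (j in 1:ng) {
      pij <- p[i, j]
      energy <- energy + pij^2
      if (pij > 0) entropy <- entropy - pij * log2(pij)
      contrast <- contrast + (i - j)^2 * pij
      dissimilarity <- dissimilarity + abs(i - j) * pij
      homogeneity <- homogeneity + if (homogeneity_kind == "inverse_difference") {
        pij / (1 + abs(i - j))
      } else {
        pij / (1 + (i - j)^2)
      }
      corr_num <- corr_num + i * j * pij
      variance <- variance + (i - mu_x)^2 * pij
    }
  }
  # sum average via the explicit diagonal sum distribution p_{x+y}(k)
  p_sum <- numeric(2 * ng)
  for (i in 1:ng) for (j in 1:ng) p_sum[i + j] <- p_sum[i + j] + p[i, j]
  for (k in 2:(2 * ng)) sum_avg <- sum_avg + k * p_sum[k]
  correlation <- if (var_x > 0) (corr_num - mu_x^2) / var_x else NA_real_
  c(
    energy = energy, entropy = entropy, contrast = contrast,
    homogeneity = homogeneity, correlation = correlation,
    sum_average = sum_avg, variance_glcm = variance,
    dissimilarity = dissimilarity
  )
}

# raw-sample central moments (population denominators)
oracle_moments <- function(v) {
  n <- length(v)
  mu <- sum(v) / n
  m2 <- sum((v - mu)^2) / n
  m3 <- sum((v - mu)^3) / n
  m4 <- sum((v - mu)^4) / n
  list(
    variance = m2,
    skewness = if (m2 > 0) m3 / m2^1.5 else NA_real_,
    kurtosis = if (m2 > 0) m4 / m2^2 - 3 else NA_real_
  )
}

# random quantized volume with a random mask, ng levels; 0 outside mask
random_quantized_volume <- function(dm, ng, p_mask = 0.7) {
  q <- array(sample.int(ng, prod(dm), replace = TRUE), dm)
  msk <- array(runif(prod(dm)) < p_mask, dm)
  q[!msk] <- 0L
  storage.mode(q) <- "integer"
  attr(q, "ng") <- as.integer(ng)
  q
}

# all 48 signed axis permutations applied to a 3D array
signed_permutations <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  flips <- expand.grid(f1 = c(FALSE, TRUE), f2 = c(FALSE, TRUE), f3 = c(FALSE, TRUE))
  out <- list()
  for (pm in perms) {
    for (r in seq_len(nrow(flips))) {
      out[[length(out) + 1]] <- list(perm = pm, flip = unlist(flips[r, ]))
    }
  }
  out
}

apply_signed_permutation <- function(q, op) {
  x <- aperm(q, op$perm)
  for (ax in 1:3) {
    if (op$flip[ax]) {
      idx <- rev(seq_len(dim(x)[ax]))
      x <- switch(ax,
        x[idx, , , drop = FALSE],
        x[, idx, , drop = FALSE],
        x[, , idx, drop = FALSE]
      )
    }
  }
  storage.mode(x) <- "integer"
  attr(x, "ng") <- attr(q, "ng")
  x
}
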
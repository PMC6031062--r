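# Brute-force reference implementations used as independent oracles.
# They work on small dense matrices with explicit loops and share no code
# with the package internals they check.

toy_layout <- function(...) genome_layout(c(...))

# contact matrix from a dense symmetric matrix on one uniform-bin chromosome
cm_from_dense <- function(D, bin_size = 10, chrom = "chrA") {
  n <- nrow(D)
  bins <- make_fixed_bins(genome_layout(stats::setNames(n * bin_size, chrom)),
                          bin_size)
  pix <- list()
  for (i in 1:n) for (j in i:n) {
    if (D[i, j] != 0) pix[[length(pix) + 1]] <- c(i, j, D[i, j])
  }
  pix <- if (length(pix)) do.call(rbind, pix) else matrix(0, 0, 3)
  contact_matrix(bins, data.frame(bin1 = pix[, 1], bin2 = pix[, 2],
                                  value = pix[, 3]))
}

random_dense <- function(n, seed, density = 0.7, max_count = 20) {
  set.seed(seed)
  D <- matrix(0, n, n)
  for (i in 1:n) for (j in i:n) {
    if (runif(1) < density) D[i, j] <- D[j, i] <- sample.int(max_count, 1)
  }
  D
}

oracle_merge_dense <- function(D, k) {
  n <- nrow(D)
  groups <- split(1:n, (0:(n - 1)) %/% k)
  m <- length(groups)
  out <- matrix(0, m, m)
  for (a in 1:m) for (b in 1:m) {
    out[a, b] <- sum(D[groups[[a]], groups[[b]], drop = FALSE])
  }
  out
}

oracle_expected <- function(D) {
  n <- nrow(D)
  sapply(0:(n - 1), function(d) {
    vals <- c()
    for (i in 1:n) for (j in i:n) if (j - i == d) vals <- c(vals, D[i, j])
    mean(vals)
  })
}

oracle_obs_exp <- function(D) {
  e <- oracle_expected(D)
  n <- nrow(D)
  out <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    ed <- e[abs(j - i) + 1]
    out[i, j] <- if (!is.na(ed) && ed > 0) D[i, j] / ed else 0
  }
  out
}

oracle_pearson_cov <- function(B) {
  n <- nrow(B)
  P <- matrix(NA_real_, n, n)
  C <- matrix(NA_real_, n, n)
  for (i in 1:n) for (j in 1:n) {
    x <- B[i, ]; y <- B[j, ]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) >= 2) {
      C[i, j] <- sum((x[ok] - mean(x[ok])) * (y[ok] - mean(y[ok]))) /
        (sum(ok) - 1)
      sx <- sqrt(sum((x[ok] - mean(x[ok]))^2) / (sum(ok) - 1))
      sy <- sqrt(sum((y[ok] - mean(y[ok]))^2) / (sum(ok) - 1))
      P[i, j] <- if (sx > 0 && sy > 0) C[i, j] / (sx * sy) else NA_real_
    }
  }
  list(pearson = P, covariance = C)
}

# dense iterative correction from the definition
oracle_ice <- function(D, tol = 1e-10, max_iter = 2000) {
  n <- nrow(D)
  W <- D
  bias <- rep(1, n)
  total0 <- sum(W[upper.tri(W, diag = TRUE)])
  for (it in 1:max_iter) {
    s <- rowSums(W)
    delta <- s / mean(s)
    for (i in 1:n) for (j in 1:n) W[i, j] <- W[i, j] / (delta[i] * delta[j])
    bias <- bias * delta
    if (max(abs(delta - 1)) < tol) break
  }
  W <- W * total0 / sum(W[upper.tri(W, diag = TRUE)])
  list(matrix = W, bias = bias / mean(bias), iterations = it)
}

# per-distance z-scores of log1p then the diamond mean, all explicit loops
oracle_diamond <- function(D, boundary_b, w) {
  n <- nrow(D)
  L <- log(1 + D)
  Z <- matrix(NA_real_, n, n)
  for (d in 0:(n - 1)) {
    vals <- c()
    for (i in 1:(n - d)) vals <- c(vals, L[i, i + d])
    mu <- mean(vals); sg <- stats::sd(vals)
    for (i in 1:(n - d)) {
      z <- if (!is.na(sg) && sg > 0) (L[i, i + d] - mu) / sg else 0
      Z[i, i + d] <- Z[i + d, i] <- z
    }
  }
  vals <- c()
  for (i in (boundary_b - w):(boundary_b - 1)) {
    for (j in boundary_b:(boundary_b + w - 1)) vals <- c(vals, Z[i, j])
  }
  mean(vals)
}
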
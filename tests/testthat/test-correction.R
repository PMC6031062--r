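test_that("coverage totals match hand-summed dense rows", {
  D <- matrix(c(2, 1, 0,
                1, 4, 3,
                0, 3, 6), 3, 3, byrow = TRUE)
  m <- cm_from_dense(D)
  d <- coverage_diagnostics(m)
  expect_equal(d$totals, c(3, 8, 9))
})

test_that("uniform coverage flags nothing; an empty bin is always flagged", {
  D <- matrix(1, 5, 5)
  m <- cm_from_dense(D)
  d <- coverage_diagnostics(m)
  expect_false(any(d$flagged))

  D2 <- matrix(1, 5, 5); D2[3, ] <- D2[, 3] <- 0
  d2 <- coverage_diagnostics(cm_from_dense(D2))
  expect_true(d2$flagged[3])
  expect_false(any(d2$flagged[-3]))
})

test_that("an all-zero matrix yields empty diagnostics, not a crash", {
  bins <- make_fixed_bins(toy_layout(chrA = 40), 10)
  d <- coverage_diagnostics(contact_matrix(bins))
  expect_true(all(is.na(c(d$lower, d$upper))))
  expect_true(all(d$flagged))
})

test_that("masking respects thresholds, is idempotent and refuses to mask all", {
  D <- matrix(1, 6, 6); D[2, ] <- D[, 2] <- 0
  m <- cm_from_dense(D)
  m1 <- mask_bins(m, -Inf, Inf)
  expect_equal(which(m1$masked), 2L)        # zero bins always masked (mad units)
  m2 <- mask_bins(m1, -3, 3)
  expect_equal(m2$masked, m1$masked)        # idempotent
  Dm <- densify(m1)
  expect_true(all(is.na(Dm[2, ])))

  mc <- mask_bins(m, lower = 3, upper = 10, units = "count")
  expect_equal(which(mc$masked), 2L)        # count units keep the 5-count rows
  expect_error(mask_bins(m, lower = 100, upper = 200, units = "count"),
               "every bin")
})

test_that("ICE leaves a balanced matrix untouched and converges at once", {
  # circulant matrix: all row sums equal by construction
  n <- 6
  D <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) D[i, j] <- 1 + (abs(i - j) %in% c(0, 3))
  stopifnot(length(unique(rowSums(D))) == 1)
  m <- cm_from_dense(D)
  res <- ice_correct(m)
  expect_equal(res$iterations, 1)
  expect_true(res$converged)
  expect_equal(unname(res$bias), rep(1, n))
  expect_equal(densify(res$matrix), D)
})

test_that("a rank-one biased 2-bin matrix yields the analytic bias ratio", {
  # [[1,2],[2,4]] = outer(c(1,2), c(1,2)): bias ratio must be 2
  m <- cm_from_dense(matrix(c(1, 2, 2, 4), 2, 2))
  res <- ice_correct(m, tol = 1e-12)
  expect_true(res$converged)
  expect_equal(res$bias[2] / res$bias[1], 2, tolerance = 1e-8)
  s <- rowSums(densify(res$matrix))
  expect_equal(s[1], s[2], tolerance = 1e-8)
  expect_equal(total_counts(res$matrix), total_counts(m))
})

test_that("ICE agrees with a brute-force dense implementation on small toys", {
  for (s in c(4, 8, 15)) {
    D <- random_dense(10, s, density = 1)
    res <- ice_correct(cm_from_dense(D), tol = 1e-12, max_iter = 5000)
    ora <- oracle_ice(D, tol = 1e-12, max_iter = 5000)
    un <- !res$matrix$masked
    expect_equal(res$bias[un], ora$bias[un], tolerance = 1e-8)
    expect_equal(densify(res$matrix), ora$matrix, tolerance = 1e-8)
  }
})

test_that("ICE recovers planted log-normal biases on a balanced base", {
  spec <- hic_truth(layout = toy_layout(chr1 = 5e5), comp_strength = 0,
                    n_anchors = 0, bias_sdlog = 0, n_tad_boundaries = 2,
                    seed = 19)
  base <- ice_correct(simulate_truth_matrix(spec))$matrix
  base$meta$corrected <- FALSE
  base$meta$bias <- NULL
  b <- hicmat:::with_seed(77, {
    x <- stats::rlnorm(nrow(base$bins), 0, 0.25); x / mean(x)
  })
  biased <- base
  biased$pixels$value <- base$pixels$value *
    b[base$pixels$bin1] * b[base$pixels$bin2]
  res <- ice_correct(biased, tol = 1e-8)
  un <- !res$matrix$masked
  expect_gt(stats::cor(res$bias[un], b[un]), 0.99)
  s <- hicmat:::bin_coverage(res$matrix)[un]
  expect_lt(stats::sd(s) / mean(s), 1e-4)
})

test_that("correction is scale invariant and preserves symmetry", {
  D <- random_dense(8, 23, density = 1)
  m <- cm_from_dense(D)
  m10 <- cm_from_dense(10 * D)
  r1 <- ice_correct(m, tol = 1e-10)
  r10 <- ice_correct(m10, tol = 1e-10)
  expect_equal(r1$bias, r10$bias, tolerance = 1e-6)
  expect_equal(10 * densify(r1$matrix), densify(r10$matrix),
               tolerance = 1e-6)
  Dc <- densify(r1$matrix)
  expect_equal(Dc, t(Dc))
})

test_that("non-convergence returns the matrix with a warning, not an error", {
  D <- random_dense(8, 3, density = 1)
  expect_warning(res <- ice_correct(cm_from_dense(D), tol = 1e-14,
                                    max_iter = 2),
                 "not converged")
  expect_false(res$converged)
  expect_equal(res$iterations, 2)
  expect_true(is.finite(res$residual))
})
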
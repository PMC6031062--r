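test_that("expected profile and O/E match dense double-loop oracles", {
  for (s in c(2, 6)) {
    D <- random_dense(9, s, density = 0.8)
    m <- cm_from_dense(D)
    pr <- expected_profile(m, "chrA")
    expect_equal(pr$mean, oracle_expected(D))
    OE <- densify(obs_exp(m), masked_as = 0)
    expect_equal(OE, oracle_obs_exp(D))
  }
})

test_that("a constant-by-diagonal matrix has O/E of exactly one", {
  n <- 7
  D <- outer(1:n, 1:n, function(i, j) 10 / (abs(i - j) + 1))
  m <- cm_from_dense(D)
  oe <- obs_exp(m)
  expect_true(all(abs(oe$pixels$value - 1) < 1e-12))
})

test_that("O/E re-averaged per distance is one wherever defined", {
  D <- random_dense(10, 44, density = 0.9)
  oe <- obs_exp(cm_from_dense(D))
  pr <- expected_profile(oe, "chrA")
  defined <- !is.na(pr$mean) & pr$mean > 0
  expect_true(all(abs(pr$mean[defined] - 1) < 1e-12))
})

test_that("a pixel at twice the mean of its diagonal gets O/E of 2", {
  # distance-1 values 1,1,1,3: mean 1.5; the 3 must map to 2.0
  D <- matrix(0, 5, 5)
  vals <- c(1, 1, 1, 3)
  for (i in 1:4) D[i, i + 1] <- D[i + 1, i] <- vals[i]
  oe <- obs_exp(cm_from_dense(D))
  p <- oe$pixels
  expect_equal(p$value[p$bin1 == 4 & p$bin2 == 5], 3 / 1.5)
})

test_that("inter-chromosomal pixels are dropped by the O/E transform", {
  bins <- make_fixed_bins(toy_layout(cA = 20, cB = 20), 10)
  m <- contact_matrix(bins, data.frame(bin1 = c(1, 1), bin2 = c(2, 3),
                                       value = c(4, 9)))
  oe <- obs_exp(m)
  expect_true(all(bins$chrom[oe$pixels$bin1] == bins$chrom[oe$pixels$bin2]))
})

test_that("Pearson and covariance agree with the brute-force double loop", {
  D <- random_dense(10, 12, density = 0.8)
  m <- cm_from_dense(D)
  oe <- obs_exp(m)
  pc <- pearson_and_covariance(oe)[["chrA"]]
  ora <- oracle_pearson_cov(densify(oe, masked_as = 0))
  expect_equal(pc$pearson, ora$pearson, tolerance = 1e-10)
  expect_equal(pc$covariance, ora$covariance, tolerance = 1e-10)
  expect_equal(unname(diag(pc$pearson)), rep(1, 10), tolerance = 1e-12)
})

test_that("a two-block checkerboard O/E yields a +/-1 Pearson pattern", {
  B <- matrix(c(2, 2, .5, .5,
                2, 2, .5, .5,
                .5, .5, 2, 2,
                .5, .5, 2, 2), 4, 4, byrow = TRUE)
  P <- oracle_pearson_cov(B)$pearson
  parity <- c(1, 1, -1, -1)
  expect_equal(P, outer(parity, parity), tolerance = 1e-12)
  m <- cm_from_dense(B)
  oe <- m; oe$meta$transform <- "obs_exp"   # feed the block as O/E directly
  pc <- pearson_and_covariance(oe)[["chrA"]]
  expect_equal(pc$pearson, outer(parity, parity), tolerance = 1e-12)
})

test_that("distance decay is flat for a uniform matrix and equal for copies", {
  D <- matrix(3, 8, 8)
  m <- cm_from_dense(D)
  tab <- distance_decay(list(a = m, b = m))
  expect_true(all(tab$mean_count == 3))
  a <- tab[tab$sample == "a", -1]
  b <- tab[tab$sample == "b", -1]
  expect_equal(a, b, ignore_attr = TRUE)
  expect_error(distance_decay(list(m, cm_from_dense(D, bin_size = 20))),
               "bin size")
})

test_that("the fitted log-log slope recovers a planted unit decay exponent", {
  spec <- hic_truth(layout = toy_layout(chr1 = 2e6), tad_enrichment = 1,
                    comp_strength = 0, n_anchors = 0, bias_sdlog = 0,
                    alpha = 1, seed = 3)
  m <- simulate_counts(spec, 5e5, seed = 103)
  slope <- decay_slope(distance_decay(m), 1e5, 1e6)
  expect_lt(abs(slope - (-1)), 0.05)
})

test_that("matrix comparison identities hold", {
  D <- random_dense(8, 5)
  m <- cm_from_dense(D)
  self <- compare_matrices(m, m, "log2ratio")
  expect_true(all(self$pixels$value == 0))

  # depth normalization cancels a global scale factor
  m2 <- cm_from_dense(2 * D)
  rat <- compare_matrices(m, m2, "ratio")
  expect_true(all(abs(rat$pixels$value - 1) < 1e-12))

  # disjoint single pixels: difference gives opposite signs
  bins <- make_fixed_bins(toy_layout(cA = 40), 10)
  a <- contact_matrix(bins, data.frame(bin1 = 1, bin2 = 2, value = 5))
  b <- contact_matrix(bins, data.frame(bin1 = 3, bin2 = 4, value = 5))
  d <- compare_matrices(a, b, "difference")
  expect_setequal(d$pixels$value, c(5, -5))

  expect_error(compare_matrices(m, cm_from_dense(random_dense(9, 5))),
               "incompatib")
})

test_that("difference comparison is antisymmetric", {
  m1 <- cm_from_dense(random_dense(7, 1))
  m2 <- cm_from_dense(random_dense(7, 2))
  d12 <- compare_matrices(m1, m2, "difference")
  d21 <- compare_matrices(m2, m1, "difference")
  expect_equal(d12$pixels$bin1, d21$pixels$bin1)
  expect_equal(d12$pixels$value, -d21$pixels$value)
})

test_that("matrix correlation is 1 on itself and drops under perturbation", {
  m <- cm_from_dense(random_dense(10, 9, density = 0.9))
  expect_equal(correlate_matrices(m, m)$coefficient, 1)
  expect_equal(correlate_matrices(m, m, method = "spearman")$coefficient, 1)

  m2 <- m
  m2$pixels$value[5] <- m2$pixels$value[5] + 50
  expect_lt(correlate_matrices(m, m2)$coefficient, 1)

  # Spearman is invariant under a monotone transform of one input
  m3 <- m
  m3$pixels$value <- m3$pixels$value^1.7 + 2
  expect_equal(correlate_matrices(m, m3, method = "spearman")$coefficient,
               correlate_matrices(m, m, method = "spearman")$coefficient)
})

test_that("distance windows restrict the correlated pixels", {
  m <- cm_from_dense(random_dense(10, 9, density = 1), bin_size = 10)
  all_r <- correlate_matrices(m, m)
  near <- correlate_matrices(m, m, d_min = 0, d_max = 20)
  expect_lt(near$n, all_r$n)
  out <- correlate_matrices(m, m, d_min = 1e6, d_max = 2e6)
  expect_identical(out$status, "undefined")
  expect_true(is.na(out$coefficient))
})

test_that("sample-set correlation produces a clusterable matrix", {
  ms <- lapply(c(1, 2, 3), function(s) cm_from_dense(random_dense(8, s)))
  names(ms) <- c("wt1", "wt2", "kd")
  cs <- correlate_matrix_set(ms)
  expect_equal(dim(cs$matrix), c(3, 3))
  expect_equal(unname(diag(cs$matrix)), rep(1, 3))
  expect_equal(cs$matrix, t(cs$matrix))
  expect_s3_class(cs$hclust, "hclust")
})
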
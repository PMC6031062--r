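test_that("contact-matrix container round-trips exactly", {
  bins <- make_fixed_bins(toy_layout(chrA = 20, chrB = 10), 10)
  # empty matrix
  m0 <- contact_matrix(bins)
  pre <- withr::local_tempfile()
  m0b <- read_matrix(write_matrix(m0, pre))
  expect_equal(nrow(m0b$pixels), 0)
  expect_equal(as.data.frame(m0b$bins), as.data.frame(m0$bins))

  # counts, mask, metadata and bias vector
  m <- contact_matrix(bins,
                      data.frame(bin1 = c(1, 1, 2), bin2 = c(1, 2, 2),
                                 value = c(2, 1, 4)),
                      masked = c(FALSE, FALSE, TRUE),
                      meta = list(total_valid_pairs = 7,
                                  bias = c(0.5, 2, NA)))
  m2 <- read_matrix(write_matrix(m, withr::local_tempfile()))
  expect_identical(m2$pixels$value, m$pixels$value)
  expect_identical(m2$pixels$bin1, m$pixels$bin1)
  expect_equal(m2$masked, m$masked)
  expect_equal(m2$meta$total_valid_pairs, 7)
  expect_equal(m2$meta$bias, c(0.5, 2, NA))
  expect_equal(attr(m2$bins, "bin_size"), 10)

  # fractional values survive within 1e-12 relative
  mf <- contact_matrix(bins, data.frame(bin1 = 1, bin2 = 3,
                                        value = pi * 1e-7))
  mf2 <- read_matrix(write_matrix(mf, withr::local_tempfile()))
  expect_identical(mf2$pixels$value, pi * 1e-7)
})

test_that("pixel indices outside the bin table raise an integrity error", {
  bins <- make_fixed_bins(toy_layout(chrA = 30), 10)
  expect_error(contact_matrix(bins, data.frame(bin1 = 1, bin2 = 100,
                                               value = 1)),
               "integrity")
  expect_error(read_matrix(file.path(tempdir(), "does-not-exist")),
               "missing")
})

test_that("merging bins block-sums pixels and conserves totals", {
  # 4 bins, k = 2: derived expectation from a dense block-sum oracle
  D <- matrix(0, 4, 4)
  D[1, 2] <- D[2, 1] <- 3
  D[3, 4] <- D[4, 3] <- 5
  D[2, 3] <- D[3, 2] <- 7
  m <- cm_from_dense(D)
  mm <- merge_bins(m, 2)
  O <- oracle_merge_dense(D, 2)
  # merged diagonal pixel = sum of within-block upper-triangle pixels
  expect_equal(densify(mm)[1, 1], D[1, 2])
  expect_equal(mm$pixels$value[mm$pixels$bin1 == 1 & mm$pixels$bin2 == 2], 7)
  expect_equal(densify(mm) + diag(diag(densify(mm))), O)
  expect_equal(total_counts(mm), total_counts(m))

  expect_identical(merge_bins(m, 1), m)

  set.seed(5)
  r <- cm_from_dense(random_dense(9, 21))
  expect_equal(total_counts(merge_bins(r, 4)), total_counts(r))
})

test_that("merge composition: two k=2 merges equal one k=4 merge", {
  D <- random_dense(8, 13)
  m <- cm_from_dense(D)
  a <- merge_bins(merge_bins(m, 2), 2)
  b <- merge_bins(m, 4)
  expect_equal(a$pixels, b$pixels)
  expect_equal(as.data.frame(a$bins), as.data.frame(b$bins))
})

test_that("merging a corrected matrix is refused", {
  m <- cm_from_dense(random_dense(6, 2, density = 1))
  res <- ice_correct(m)
  expect_error(merge_bins(res$matrix, 2), "corrected")
})

test_that("summing matrices is elementwise and validates bin tables", {
  m <- cm_from_dense(random_dense(5, 31))
  m$meta$total_valid_pairs <- total_counts(m)
  zero <- contact_matrix(m$bins)
  expect_equal(sum_matrices(list(m))$pixels, m$pixels)
  expect_equal(sum_matrices(list(m, zero))$pixels, m$pixels)
  dbl <- sum_matrices(list(m, m))
  expect_equal(dbl$pixels$value, 2 * m$pixels$value)
  expect_equal(dbl$meta$total_valid_pairs, 2 * m$meta$total_valid_pairs)

  other <- cm_from_dense(random_dense(6, 31))
  expect_error(sum_matrices(list(m, other)), "incompatib")
})

test_that("summing is associative and commutative on a shared bin table", {
  ms <- lapply(1:3, function(s) cm_from_dense(random_dense(7, s)))
  abc <- sum_matrices(list(sum_matrices(ms[1:2]), ms[[3]]))
  bca <- sum_matrices(list(ms[[3]], sum_matrices(ms[2:1])))
  expect_equal(abc$pixels, bca$pixels)
})

test_that("densified matrices are exactly symmetric", {
  for (s in 1:5) {
    D <- densify(cm_from_dense(random_dense(8, s)))
    expect_identical(D, t(D))
  }
})

test_that("region extraction returns mirrored dense blocks", {
  D <- random_dense(6, 9)
  m <- cm_from_dense(D, bin_size = 10)
  full <- extract_region(m, "chrA")
  expect_equal(full$matrix, D)

  one <- extract_region(m, "chrA", 20, 30)
  expect_equal(one$matrix, D[3, 3, drop = FALSE])

  two <- extract_region(m, "chrA", 15, 25)
  expect_equal(two$matrix, D[2:3, 2:3])
  expect_equal(two$matrix[1, 2], two$matrix[2, 1])

  expect_error(extract_region(m, "nope", 0, 10), "unknown")
})

test_that("masked bins surface as missing rows but keep their pixels stored", {
  D <- random_dense(5, 17, density = 1)
  m <- cm_from_dense(D)
  m$masked[2] <- TRUE
  Dm <- densify(m)
  expect_true(all(is.na(Dm[2, ])) && all(is.na(Dm[, 2])))
  expect_equal(Dm[-2, -2], D[-2, -2])
  # storage retains the masked pixels; totals exclude them
  expect_true(any(m$pixels$bin1 == 2 | m$pixels$bin2 == 2))
  expect_equal(total_counts(m),
               sum(D[-2, -2][upper.tri(D[-2, -2], diag = TRUE)]))
})
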
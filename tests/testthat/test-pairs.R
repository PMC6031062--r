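# a tiny genome with 10-bp fragments for geometry-sensitive classification
frag_fixture <- function() {
  lay <- toy_layout(cA = 100, cB = 60)
  frags <- hicmat:::uniform_fragments(lay, 10, "GATC")
  bins <- make_fixed_bins(lay, 20)
  list(layout = lay, frags = frags, bins = bins)
}

mk_pair <- function(id, c1, p1, s1, c2, p2, s2, q1 = 60, q2 = 60,
                    seq1 = "AAAA", seq2 = "AAAA") {
  data.frame(id = id, chrom1 = c1, pos1 = p1, strand1 = s1, mapq1 = q1,
             seq1 = seq1, chrom2 = c2, pos2 = p2, strand2 = s2, mapq2 = q2,
             seq2 = seq2, stringsAsFactors = FALSE)
}

test_that("classification follows the precedence order", {
  fx <- frag_fixture()
  pairs <- rbind(
    mk_pair("unm", "cA", 5, "+", NA, NA, "+"),                  # unmapped
    mk_pair("low", "cA", 5, "+", "cA", 50, "-", q2 = 3),        # low mapq
    mk_pair("dangle_seq", "cA", 5, "+", "cA", 50, "-", seq1 = "GATC"),
    mk_pair("same_in", "cA", 31, "+", "cA", 38, "-"),           # one fragment, inward
    mk_pair("same_out", "cA", 31, "-", "cA", 38, "+"),          # one fragment, outward
    mk_pair("selflig", "cA", 45, "+", "cA", 52, "-"),           # adjacent, inward
    mk_pair("adj_out", "cA", 45, "-", "cA", 52, "+"),           # adjacent, outward: fine
    mk_pair("valid", "cA", 5, "+", "cA", 75, "-"),
    mk_pair("inter", "cA", 5, "+", "cB", 30, "+"))
  cl <- classify_pairs(pairs, fx$frags)
  expect_equal(as.character(cl$category),
               c("unmapped", "low_mapq", "same_fragment_dangling",
                 "same_fragment_dangling", "self_circle", "self_ligation",
                 "valid", "valid", "valid"))
})

test_that("a pair identical to an earlier one is a duplicate, even swapped", {
  fx <- frag_fixture()
  a <- mk_pair("a", "cA", 5, "+", "cA", 75, "-")
  b <- mk_pair("b", "cA", 5, "+", "cA", 75, "-")          # exact copy
  c <- mk_pair("c", "cA", 75, "-", "cA", 5, "+")          # mates swapped
  d <- mk_pair("d", "cA", 5, "+", "cA", 75, "+")          # strand differs
  cl <- classify_pairs(rbind(a, b, c, d), fx$frags)
  expect_equal(as.character(cl$category),
               c("valid", "duplicate", "duplicate", "valid"))
  # low-mapq copies are filtered before duplicate detection
  e <- mk_pair("e", "cA", 5, "+", "cA", 75, "-", q1 = 1)
  cl2 <- classify_pairs(rbind(e, a), fx$frags)
  expect_equal(as.character(cl2$category), c("low_mapq", "valid"))
})

test_that("fragment-free classification skips fragment-dependent classes", {
  pairs <- rbind(mk_pair("x", "cA", 31, "+", "cA", 38, "-"),
                 mk_pair("y", "cA", 5, "+", NA, NA, "+"))
  cl <- classify_pairs(pairs, frags = NULL)
  expect_equal(as.character(cl$category), c("valid", "unmapped"))
})

test_that("dangling-end checking without leading sequences is refused", {
  fx <- frag_fixture()
  p <- mk_pair("x", "cA", 5, "+", "cA", 75, "-", seq1 = NA, seq2 = NA)
  p$seq1 <- NA_character_; p$seq2 <- NA_character_
  expect_error(classify_pairs(p, fx$frags), "configuration")
})

test_that("matrix building tabulates valid pairs and splits distances", {
  fx <- frag_fixture()
  lay <- toy_layout(cA = 1e5)
  bins <- make_fixed_bins(lay, 1e4)
  frags <- hicmat:::uniform_fragments(lay, 100, "GATC")
  pairs <- rbind(
    mk_pair("p1", "cA", 1000, "+", "cA", 16000, "-"),   # 15 kb: short range
    mk_pair("p2", "cA", 1000, "-", "cA", 26000, "-"),   # 25 kb: long range
    mk_pair("p3", "cA", 1500, "+", "cA", 16500, "+"),   # same bin pair as p1
    mk_pair("p4", "cA", 50000, "+", "cA", 70000, "-"))  # exactly 20 kb: long
  res <- build_matrix(pairs, bins, frags)
  expect_equal(res$qc$counts$intra_short_range, 2)   # the two 15-kb pairs
  expect_equal(res$qc$counts$intra_long_range, 2)    # 25 kb, and exactly 20 kb
  expect_equal(res$qc$counts$valid, 4)
  px <- res$matrix$pixels
  expect_equal(px$value[px$bin1 == 1 & px$bin2 == 2], 2)
  expect_equal(total_counts(res$matrix), 4)

  bad <- mk_pair("oops", "cA", 99999999, "+", "cA", 10, "-")
  expect_error(build_matrix(rbind(pairs, bad), bins, frags), "oops")
})

test_that("category counts partition the stream and orientation sums check out", {
  spec <- hic_truth(seed = 31)
  sim <- simulate_pairs(spec, 4000, seed = 13)
  res <- build_matrix(sim$pairs, spec$bins, sim$frags)
  cnt <- res$qc$counts
  cats <- c("unmapped", "low_mapq", "duplicate", "same_fragment_dangling",
            "self_circle", "self_ligation", "valid")
  expect_equal(sum(unlist(cnt[cats])), cnt$total)
  expect_equal(cnt$total, nrow(sim$pairs))
  # orientation tallied over all intra-chromosomal both-mapped pairs
  intra <- !is.na(sim$pairs$chrom1) & !is.na(sim$pairs$chrom2) &
    sim$pairs$chrom1 == sim$pairs$chrom2
  expect_equal(sum(res$qc$orientation), sum(intra))
})

test_that("simulated category labels are recovered exactly", {
  spec <- hic_truth(seed = 8)
  sim <- simulate_pairs(spec, 5000, seed = 80)
  res <- build_matrix(sim$pairs, spec$bins, sim$frags)
  side <- sim$sidecar$counts
  expect_identical(res$qc$counts$unmapped, side$unmapped)
  expect_identical(res$qc$counts$low_mapq, side$low_mapq)
  expect_identical(res$qc$counts$duplicate, side$duplicate)
  expect_identical(res$qc$counts$same_fragment_dangling,
                   side$same_fragment_dangling)
  expect_identical(res$qc$counts$self_circle, side$self_circle)
  expect_identical(res$qc$counts$self_ligation, side$self_ligation)
  expect_identical(res$qc$counts$valid, side$valid)
})

test_that("shuffling the stream changes nothing; duplicating it only adds duplicates", {
  spec <- hic_truth(seed = 9, fragments = list(duplicate = 0, dangling = 0.05,
                                               self_circle = 0.02,
                                               unmapped = 0.02,
                                               low_mapq = 0.02))
  sim <- simulate_pairs(spec, 3000, seed = 90)
  res1 <- build_matrix(sim$pairs, spec$bins, sim$frags)
  set.seed(1)
  shuf <- sim$pairs[sample.int(nrow(sim$pairs)), ]
  res2 <- build_matrix(shuf, spec$bins, sim$frags)
  expect_equal(res1$matrix$pixels, res2$matrix$pixels)
  expect_equal(unlist(res1$qc$counts), unlist(res2$qc$counts))

  doubled <- rbind(sim$pairs, sim$pairs)
  res3 <- build_matrix(doubled, spec$bins, sim$frags)
  expect_equal(res3$matrix$pixels, res1$matrix$pixels)
  n_pass_filters <- res1$qc$counts$total - res1$qc$counts$unmapped -
    res1$qc$counts$low_mapq
  expect_equal(res3$qc$counts$duplicate, n_pass_filters)
})

test_that(".pairs and SAM round trips preserve classification", {
  spec <- hic_truth(seed = 14)
  sim <- simulate_pairs(spec, 2000, seed = 41)
  ref <- build_matrix(sim$pairs, spec$bins, sim$frags)

  pf <- withr::local_tempfile()
  write_pairs(sim$pairs, pf, spec$layout)
  from_pairs <- build_matrix(read_pairs(pf), spec$bins, sim$frags)
  expect_equal(unlist(from_pairs$qc$counts), unlist(ref$qc$counts))
  expect_equal(from_pairs$matrix$pixels, ref$matrix$pixels)

  sf <- withr::local_tempfile()
  write_sam(sim$pairs, sf, spec$layout)
  from_sam <- build_matrix(read_sam_pairs(sf, seq_length = 4), spec$bins,
                           sim$frags)
  expect_equal(unlist(from_sam$qc$counts), unlist(ref$qc$counts))
  expect_equal(from_sam$matrix$pixels, ref$matrix$pixels)
})

test_that("QC reports merge into one row per sample with sane fractions", {
  spec <- hic_truth(seed = 3)
  sim <- simulate_pairs(spec, 1000, seed = 5)
  qc <- build_matrix(sim$pairs, spec$bins, sim$frags)$qc
  tab <- merge_qc(list(a = qc, b = qc))
  expect_equal(nrow(tab), 2)
  expect_equal(tab[1, -1], tab[2, -1], ignore_attr = TRUE)
  expect_equal(tab$frac_valid[1], qc$counts$valid / qc$counts$total)

  empty <- hicmat:::new_qc_report(
    counts = list(total = 0, valid = 0),
    orientation = c(inward = 0, outward = 0, same_strand_forward = 0,
                    same_strand_reverse = 0),
    params = list())
  tab0 <- merge_qc(list(z = empty))
  expect_true(is.na(tab0$frac_valid))
  expect_equal(tab0$total, 0)

  pre <- withr::local_tempfile()
  write_qc(list(a = qc), pre)
  expect_true(file.exists(paste0(pre, ".html")))
  expect_true(file.exists(paste0(pre, ".tsv")))
  expect_true(any(grepl("frac_valid", readLines(paste0(pre, ".json")))))
})
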
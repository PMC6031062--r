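#' Per-chromosome expected contact profile
#'
#' Mean pixel value over all unmasked bin pairs at each genomic distance
#' (in bins) of one chromosome. Absent pixels count as zeros: the
#' denominator is the full number of unmasked pairs at that distance, so
#' sparse storage does not bias the expectation.
#'
#' @param m A `contact_matrix`.
#' @param chrom Chromosome name.
#' @return Data frame with `distance` (bins), `mean`, `n_pairs`.
#' @export
expected_profile <- function(m, chrom) {
  rows <- bins_of_chrom(m$bins, chrom)
  if (!length(rows)) stop("expected_profile: unknown chromosome ", chrom)
  nb <- length(rows)
  un <- which(!m$masked[rows])
  p <- active_pixels(m)
  p <- p[p$bin1 %in% rows & p$bin2 %in% rows, , drop = FALSE]
  d <- p$bin2 - p$bin1
  sums <- numeric(nb)
  if (nrow(p)) {
    agg <- rowsum(p$value, d)
    sums[as.integer(rownames(agg)) + 1L] <- agg
  }
  # number of unmasked (i, j), j - i == d pairs, by distance
  npairs <- vapply(0:(nb - 1), function(dd) {
    if (!length(un)) 0L else sum((un + dd) %in% un)
  }, 0L)
  data.frame(distance = 0:(nb - 1),
             mean = ifelse(npairs > 0, sums / npairs, NA_real_),
             n_pairs = npairs)
}

#' Distance-decay table
#'
#' Average contact value at each genomic distance, per chromosome and
#' genome-wide ("all" rows, weighted by the number of bin pairs), for one or
#' several samples sharing a bin size. Plot `mean_count` against
#' `distance_bp` on log-log axes for the classic decay curve.
#'
#' @param ms A `contact_matrix` or list of them.
#' @param per_chromosome Keep per-chromosome rows (default TRUE).
#' @return Data frame: `sample`, `chrom`, `distance_bp`, `mean_count`,
#'   `n_pairs`.
#' @export
distance_decay <- function(ms, per_chromosome = TRUE) {
  if (inherits(ms, "contact_matrix")) ms <- list(ms)
  if (is.null(names(ms)) || any(names(ms) == "")) {
    names(ms) <- paste0("sample", seq_along(ms))
  }
  bs <- vapply(ms, function(m) attr(m$bins, "bin_size"), 0)
  if (anyNA(bs) || length(unique(bs)) != 1) {
    stop("distance_decay: matrices must share one uniform bin size")
  }
  bin_size <- bs[1]
  out <- list()
  for (nm in names(ms)) {
    m <- ms[[nm]]
    profs <- lapply(names(bin_layout(m$bins)), function(ch) {
      pr <- expected_profile(m, ch)
      data.frame(sample = nm, chrom = ch, distance_bp = pr$distance * bin_size,
                 mean_count = pr$mean, n_pairs = pr$n_pairs)
    })
    percr <- do.call(rbind, profs)
    w <- percr[!is.na(percr$mean_count), , drop = FALSE]
    allrows <- do.call(rbind, lapply(split(w, w$distance_bp), function(g) {
      data.frame(sample = nm, chrom = "all", distance_bp = g$distance_bp[1],
                 mean_count = sum(g$mean_count * g$n_pairs) / sum(g$n_pairs),
                 n_pairs = sum(g$n_pairs))
    }))
    out[[nm]] <- rbind(if (per_chromosome) percr else NULL, allrows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fit the log-log slope of a distance-decay curve
#'
#' Least-squares slope of `log(mean_count)` on `log(distance_bp)` over a
#' distance window, on the genome-wide ("all") rows of one sample.
#'
#' @param decay Output of [distance_decay()].
#' @param d_min,d_max Distance window in bp.
#' @param sample Sample to use (default first).
#' @return Numeric slope.
#' @export
decay_slope <- function(decay, d_min, d_max, sample = NULL) {
  if (is.null(sample)) sample <- decay$sample[1]
  g <- decay[decay$sample == sample & decay$chrom == "all" &
               decay$distance_bp >= d_min & decay$distance_bp <= d_max &
               !is.na(decay$mean_count) & decay$mean_count > 0, ]
  if (nrow(g) < 3) stop("decay_slope: fewer than 3 usable distances in window")
  unname(stats::coef(stats::lm(log(mean_count) ~ log(distance_bp), g))[2])
}

#' Observed/expected transform
#'
#' Divides every intra-chromosomal pixel by the expected (per-distance mean)
#' value of its chromosome. Pixels at distances with zero expectation are
#' dropped (undefined); inter-chromosomal pixels are dropped.
#'
#' @param m A `contact_matrix` (raw or corrected).
#' @return A `contact_matrix` of O/E values (`meta$transform = "obs_exp"`).
#' @export
obs_exp <- function(m) {
  first <- chrom_first_index(m$bins)
  chrom_of <- m$bins$chrom
  p <- active_pixels(m)
  intra <- chrom_of[p$bin1] == chrom_of[p$bin2]
  p <- p[intra, , drop = FALSE]
  newp <- list()
  for (ch in names(bin_layout(m$bins))) {
    rows <- bins_of_chrom(m$bins, ch)
    sel <- p[chrom_of[p$bin1] == ch, , drop = FALSE]
    if (!nrow(sel)) next
    exp_ <- expected_profile(m, ch)
    ev <- exp_$mean[sel$bin2 - sel$bin1 + 1L]
    ok <- !is.na(ev) & ev > 0
    sel <- sel[ok, , drop = FALSE]
    sel$value <- sel$value / ev[ok]
    newp[[ch]] <- sel
  }
  meta <- m$meta
  meta$transform <- "obs_exp"
  pixels <- if (length(newp)) do.call(rbind, newp) else
    data.frame(bin1 = integer(), bin2 = integer(), value = numeric())
  contact_matrix(m$bins, pixels, masked = m$masked, meta = meta)
}

#' Pearson and covariance matrices of an O/E matrix
#'
#' For each chromosome, the dense O/E block is formed (absent pixels as 0,
#' masked bins as `NA`); `pearson[i, j]` is the Pearson correlation of rows
#' `i` and `j` with pairwise exclusion of missing values, and `covariance`
#' the analogous covariance. Constant rows yield missing correlations.
#'
#' @param m_oe An O/E `contact_matrix` (see [obs_exp()]).
#' @param chroms Chromosomes to process (default all).
#' @return Named list per chromosome: `pearson`, `covariance`, `bin_index`.
#' @export
pearson_and_covariance <- function(m_oe, chroms = NULL) {
  if (is.null(chroms)) chroms <- names(bin_layout(m_oe$bins))
  out <- list()
  for (ch in chroms) {
    B <- densify(m_oe, ch)
    P <- suppressWarnings(stats::cor(B, use = "pairwise.complete.obs"))
    C <- stats::cov(B, use = "pairwise.complete.obs")
    out[[ch]] <- list(pearson = P, covariance = C,
                      bin_index = bins_of_chrom(m_oe$bins, ch))
  }
  out
}

#' Compare two contact matrices
#'
#' Depth-normalizes both matrices to the smaller total count, then applies
#' an element-wise operation on the union of their pixels (absent pixels
#' count as 0). Ratio and log2ratio pixels with an undefined result (zero
#' denominator, or zero numerator for log2ratio) are emitted as missing,
#' i.e. dropped from the sparse result and counted in
#' `meta$n_undefined_pixels`.
#'
#' @param m1,m2 `contact_matrix` objects on identical bin tables.
#' @param mode `"difference"`, `"ratio"` or `"log2ratio"`.
#' @return A `contact_matrix` of comparison values (may contain negatives).
#' @export
compare_matrices <- function(m1, m2,
                             mode = c("difference", "ratio", "log2ratio")) {
  mode <- match.arg(mode)
  if (!bins_identical(m1$bins, m2$bins)) {
    diffs <- if (nrow(m1$bins) != nrow(m2$bins)) "bin counts differ" else
      which(m1$bins$chrom != m2$bins$chrom | m1$bins$start != m2$bins$start |
              m1$bins$end != m2$bins$end)[1]
    stop("compare_matrices: incompatible bin tables; first differing bin: ",
         diffs)
  }
  t1 <- total_counts(m1); t2 <- total_counts(m2)
  tmin <- min(t1, t2)
  p1 <- active_pixels(m1); p2 <- active_pixels(m2)
  if (t1 > 0) p1$value <- p1$value * tmin / t1
  if (t2 > 0) p2$value <- p2$value * tmin / t2
  nb <- nrow(m1$bins)
  k1 <- (p1$bin1 - 1) * nb + p1$bin2
  k2 <- (p2$bin1 - 1) * nb + p2$bin2
  keys <- sort(unique(c(k1, k2)))
  a <- numeric(length(keys)); b <- numeric(length(keys))
  a[match(k1, keys)] <- p1$value
  b[match(k2, keys)] <- p2$value
  v <- switch(mode,
              difference = a - b,
              ratio = ifelse(b == 0, NA_real_, a / b),
              log2ratio = ifelse(b == 0 | a == 0, NA_real_, log2(a / b)))
  ok <- !is.na(v)
  pix <- data.frame(bin1 = (keys[ok] - 1) %/% nb + 1,
                    bin2 = (keys[ok] - 1) %% nb + 1, value = v[ok])
  meta <- list(corrected = m1$meta$corrected, comparison = mode,
               n_undefined_pixels = sum(!ok))
  out <- contact_matrix(m1$bins, data.frame(bin1 = integer(),
                                            bin2 = integer(),
                                            value = numeric()),
                        masked = m1$masked | m2$masked, meta = meta)
  # bypass the non-negativity check of the constructor: comparison values
  # may legitimately be negative
  pix <- pix[order(keys[ok]), ]
  rownames(pix) <- NULL
  out$pixels <- pix
  out
}

#' Correlate two contact matrices
#'
#' Pearson or Spearman correlation over intra-chromosomal pixel pairs within
#' a genomic-distance window (union of pixels, absent values as 0). For
#' Pearson, `log1p` is applied by default to tame the dynamic range.
#'
#' @param m1,m2 `contact_matrix` objects on identical bin tables.
#' @param method `"pearson"` or `"spearman"`.
#' @param d_min,d_max Distance window in bp (defaults: all distances).
#' @param log_transform Apply `log(1 + x)` before Pearson (default: TRUE for
#'   Pearson, FALSE for Spearman, which is rank-invariant to it).
#' @return List: `coefficient`, `n`, `table` (paired values), `method`,
#'   `status` (`"ok"` or `"undefined"`).
#' @export
correlate_matrices <- function(m1, m2, method = c("pearson", "spearman"),
                               d_min = 0, d_max = Inf, log_transform = NULL) {
  method <- match.arg(method)
  if (is.null(log_transform)) log_transform <- method == "pearson"
  if (!bins_identical(m1$bins, m2$bins)) {
    stop("correlate_matrices: incompatible bin tables")
  }
  if (d_min > d_max) stop("correlate_matrices: d_min > d_max")
  bins <- m1$bins
  nb <- nrow(bins)
  chrom_of <- bins$chrom
  mid <- (bins$start + bins$end) / 2
  collect <- function(m) {
    p <- active_pixels(m)
    p[chrom_of[p$bin1] == chrom_of[p$bin2], , drop = FALSE]
  }
  p1 <- collect(m1); p2 <- collect(m2)
  k1 <- (p1$bin1 - 1) * nb + p1$bin2
  k2 <- (p2$bin1 - 1) * nb + p2$bin2
  keys <- sort(unique(c(k1, k2)))
  i <- (keys - 1) %/% nb + 1
  j <- (keys - 1) %% nb + 1
  dist_bp <- abs(mid[j] - mid[i])
  keep <- dist_bp >= d_min & dist_bp <= d_max
  keys <- keys[keep]; i <- i[keep]; j <- j[keep]
  x <- numeric(length(keys)); y <- numeric(length(keys))
  mx <- match(k1, keys); sel <- !is.na(mx); x[mx[sel]] <- p1$value[sel]
  my <- match(k2, keys); sel <- !is.na(my); y[my[sel]] <- p2$value[sel]
  if (log_transform && method == "pearson") { x <- log1p(x); y <- log1p(y) }
  tab <- data.frame(bin1 = i, bin2 = j, value1 = x, value2 = y)
  if (length(x) < 2 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(coefficient = NA_real_, n = length(x), table = tab,
                method = method, status = "undefined"))
  }
  r <- stats::cor(x, y, method = method)
  list(coefficient = r, n = length(x), table = tab, method = method,
       status = "ok")
}

#' Correlation matrix over a set of samples
#'
#' All-pairs [correlate_matrices()] plus average-linkage clustering of
#' `1 - r`, the data behind a sample-correlation heatmap.
#'
#' @param ms Named list of `contact_matrix` objects.
#' @param ... Passed to [correlate_matrices()].
#' @return List: `matrix` (N x N correlations), `hclust`.
#' @export
correlate_matrix_set <- function(ms, ...) {
  n <- length(ms)
  if (is.null(names(ms))) names(ms) <- paste0("sample", seq_len(n))
  R <- matrix(1, n, n, dimnames = list(names(ms), names(ms)))
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    r <- correlate_matrices(ms[[a]], ms[[b]], ...)$coefficient
    R[a, b] <- R[b, a] <- r
  }
  hc <- if (n >= 3 && !anyNA(R)) {
    stats::hclust(stats::as.dist(1 - R), method = "average")
  } else NULL
  list(matrix = R, hclust = hc)
}
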
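#' Virtual 4C viewpoint track
#'
#' Sums, for every bin within `flank` bp of a reference region, the contacts
#' between that bin and the bin(s) overlapping the reference — the Hi-C
#' analogue of a 4C-seq profile around the viewpoint. The reference's own
#' bins are included.
#'
#' @param m A `contact_matrix` (raw or corrected; flag is propagated).
#' @param chrom Reference chromosome.
#' @param start,end 0-based half-open reference region.
#' @param flank Flank in bp on each side of the reference.
#' @return Data frame `chrom`, `start`, `end`, `value` (`NA` on masked
#'   bins), with the reference bins in `attr(, "reference_bins")`.
#' @export
viewpoint <- function(m, chrom, start, end, flank) {
  layout <- bin_layout(m$bins)
  if (!chrom %in% names(layout)) stop("viewpoint: unknown chromosome ", chrom)
  rows <- bins_of_chrom(m$bins, chrom)
  ref <- rows[m$bins$end[rows] > start & m$bins$start[rows] < end]
  if (!length(ref)) stop("viewpoint: reference overlaps no bin")
  lo <- max(0, start - flank)
  hi <- min(layout[[chrom]], end + flank)
  targ <- rows[m$bins$end[rows] > lo & m$bins$start[rows] < hi]
  D <- densify(m, chrom)
  off <- rows[1] - 1L
  vals <- colSums(D[ref - off, targ - off, drop = FALSE], na.rm = FALSE)
  if (length(ref) > 1) {
    # additive over reference bins, NA only where the target bin is masked
    vals <- colSums(D[ref - off, targ - off, drop = FALSE], na.rm = TRUE)
    vals[m$masked[targ]] <- NA_real_
  }
  out <- data.frame(chrom = chrom, start = m$bins$start[targ],
                    end = m$bins$end[targ], value = unname(vals),
                    stringsAsFactors = FALSE)
  attr(out, "reference_bins") <- ref
  attr(out, "corrected") <- isTRUE(m$meta$corrected)
  out
}

#' Aggregate contacts around anchor pairs
#'
#' Extracts the `(2 * half_width + 1)` square submatrix centered on every
#' qualifying anchor pair and averages them element-wise (missing values
#' excluded per cell) — the aggregate-peak view of, e.g., loop anchors.
#' Operates on an observed/expected matrix by default so the distance decay
#' does not dominate the average.
#'
#' @param m A `contact_matrix`; transformed with [obs_exp()] first unless
#'   `raw = TRUE` or it already is an O/E matrix.
#' @param anchors Data frame `chrom`, `start`, `end` (0-based); each anchor
#'   is reduced to the bin containing its midpoint.
#' @param pairs Optional explicit BEDPE-style data frame (`chrom1`,
#'   `start1`, `end1`, `chrom2`, `start2`, `end2`); default: all
#'   intra-chromosomal anchor pairs with separation in `[d_min, d_max]`.
#' @param d_min,d_max Separation window in bp for all-vs-all pairing.
#' @param half_width Half-width of the extracted block, in bins (>= 1).
#' @param raw Skip the O/E transform.
#' @return List: `aggregate` (dense mean block), `n_pairs`, `n_skipped`
#'   (blocks crossing a chromosome edge), `status`.
#' @export
aggregate_contacts <- function(m, anchors, pairs = NULL, d_min = 0,
                               d_max = Inf, half_width = 5, raw = FALSE) {
  stopifnot(half_width >= 1)
  if (!raw && !identical(m$meta$transform, "obs_exp")) m <- obs_exp(m)
  if (is.null(pairs)) {
    if (!nrow(anchors)) stop("aggregate_contacts: no anchors given")
    mid <- (anchors$start + anchors$end) / 2
    ctr <- locate_bin(m$bins, anchors$chrom, pmin(mid, bin_layout(m$bins)[anchors$chrom] - 1))
    idx <- expand.grid(a = seq_along(ctr), b = seq_along(ctr))
    idx <- idx[idx$a < idx$b, , drop = FALSE]
    same <- anchors$chrom[idx$a] == anchors$chrom[idx$b]
    sep <- abs(mid[idx$b] - mid[idx$a])
    idx <- idx[same & sep >= d_min & sep <= d_max, , drop = FALSE]
    centers <- cbind(ctr[idx$a], ctr[idx$b])
  } else {
    c1 <- locate_bin(m$bins, pairs$chrom1, (pairs$start1 + pairs$end1) / 2)
    c2 <- locate_bin(m$bins, pairs$chrom2, (pairs$start2 + pairs$end2) / 2)
    keep <- pairs$chrom1 == pairs$chrom2
    centers <- cbind(pmin(c1, c2)[keep], pmax(c1, c2)[keep])
  }
  h <- as.integer(half_width)
  sz <- 2L * h + 1L
  if (!nrow(centers)) {
    return(list(aggregate = matrix(NA_real_, sz, sz), n_pairs = 0L,
                n_skipped = 0L, status = "empty: no qualifying anchor pairs"))
  }
  acc <- matrix(0, sz, sz)
  cnt <- matrix(0, sz, sz)
  used <- 0L; skipped <- 0L
  dense_cache <- list()
  for (r in seq_len(nrow(centers))) {
    bi <- centers[r, 1]; bj <- centers[r, 2]
    ch <- m$bins$chrom[bi]
    rows <- bins_of_chrom(m$bins, ch)
    li <- bi - rows[1] + 1L; lj <- bj - rows[1] + 1L
    nb <- length(rows)
    if (li - h < 1 || li + h > nb || lj - h < 1 || lj + h > nb) {
      skipped <- skipped + 1L
      next
    }
    if (is.null(dense_cache[[ch]])) dense_cache[[ch]] <- densify(m, ch)
    blk <- dense_cache[[ch]][(li - h):(li + h), (lj - h):(lj + h)]
    ok <- !is.na(blk)
    acc[ok] <- acc[ok] + blk[ok]
    cnt <- cnt + ok
    used <- used + 1L
  }
  if (used == 0L) {
    return(list(aggregate = matrix(NA_real_, sz, sz), n_pairs = 0L,
                n_skipped = skipped,
                status = "empty: no qualifying anchor pairs"))
  }
  list(aggregate = ifelse(cnt > 0, acc / cnt, NA_real_), n_pairs = used,
       n_skipped = skipped, status = "ok")
}

#' Rotate a matrix block for 45-degree triangle rendering
#'
#' Maps every upper-triangle cell `(i, j)` of a square symmetric block to
#' the coordinates used when the matrix diagonal is drawn horizontally:
#' `x` = genomic midpoint of bins `i` and `j`, `y = (j - i) * bin_size / 2`.
#'
#' @param block Dense square symmetric matrix (e.g. from
#'   [extract_region()]).
#' @param bins The matching bin-table slice.
#' @return Data frame `x`, `y`, `value`, one row per upper-triangle cell.
#' @export
rotate45 <- function(block, bins) {
  if (nrow(block) != ncol(block)) stop("rotate45: block must be square")
  stopifnot(nrow(bins) == nrow(block))
  mid <- (bins$start + bins$end) / 2
  bin_size <- stats::median(bins$end - bins$start)
  ut <- which(upper.tri(block, diag = TRUE), arr.ind = TRUE)
  i <- ut[, 1]; j <- ut[, 2]
  data.frame(x = (mid[i] + mid[j]) / 2, y = (j - i) * bin_size / 2,
             value = block[ut])
}

#' Read BED3(+) intervals
#'
#' @param path File path.
#' @return Data frame `chrom`, `start`, `end` (plus `name` when present).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|#|browser)", lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  out <- data.frame(chrom = vapply(f, `[`, "", 1),
                    start = as.numeric(vapply(f, `[`, "", 2)),
                    end = as.numeric(vapply(f, `[`, "", 3)),
                    stringsAsFactors = FALSE)
  if (all(lengths(f) >= 4)) out$name <- vapply(f, `[`, "", 4)
  out
}
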
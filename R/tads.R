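#' TAD-separation score
#'
#' For every bin boundary of every chromosome, the mean distance-normalized
#' contact between the `w` bins on either side (a "diamond" across the
#' boundary), at several window sizes plus their average. Contacts are first
#' `log(1 + x)`-transformed and z-scored per genomic distance (up to
#' `z_depth`), which removes the distance decay and makes scores comparable
#' along the genome; local minima of the averaged score mark insulation
#' points, i.e. candidate TAD boundaries.
#'
#' @param m A corrected `contact_matrix` on uniform bins.
#' @param windows Window sizes in bp, each a multiple of the bin size
#'   (default `c(2, 4, 6, 8, 10, 12) * bin_size`).
#' @param z_depth Maximum distance (bp) used for the z-score normalization
#'   (default `5 * max(windows)`).
#' @return A `tad_score` data frame: `chrom`, `pos` (boundary bp), `bin`
#'   (global index of the bin right of the boundary), one `score_w*` column
#'   per window and `avg_score` (defined only where every window fits).
#' @export
tad_separation_score <- function(m, windows = NULL, z_depth = NULL) {
  bin_size <- attr(m$bins, "bin_size")
  if (is.na(bin_size)) stop("tad_separation_score: uniform bins required")
  if (is.null(windows)) windows <- c(2, 4, 6, 8, 10, 12) * bin_size
  if (any(windows %% bin_size != 0) || any(windows < bin_size)) {
    stop("tad_separation_score: windows must be positive multiples of the ",
         "bin size")
  }
  if (is.null(z_depth)) z_depth <- 5 * max(windows)
  wb <- sort(unique(as.integer(windows / bin_size)))
  zb <- max(as.integer(z_depth / bin_size), 2L * max(wb))
  bins <- m$bins
  out <- list()
  for (ch in names(bin_layout(bins))) {
    rows <- bins_of_chrom(bins, ch)
    nb <- length(rows)
    usable_w <- wb[wb < nb]
    if (length(usable_w) < length(wb)) {
      warning("tad_separation_score: window(s) larger than ", ch,
              " skipped for that chromosome")
    }
    if (!length(usable_w) || nb < 3) next
    D <- densify(m, ch)            # masked bins NA
    Z <- matrix(NA_real_, nb, nb)
    L <- log1p(D)
    for (d in 0:min(zb, nb - 1)) {
      idx <- cbind(1:(nb - d), (1 + d):nb)
      vals <- L[idx]
      mu <- mean(vals, na.rm = TRUE)
      sg <- stats::sd(vals, na.rm = TRUE)
      z <- if (!is.na(sg) && sg > 0) (vals - mu) / sg else
        ifelse(is.na(vals), NA_real_, 0)
      Z[idx] <- z
      Z[idx[, c(2, 1), drop = FALSE]] <- z
    }
    score <- matrix(NA_real_, nb + 1, length(usable_w))
    for (k in seq_along(usable_w)) {
      w <- usable_w[k]
      for (b in (w + 1):(nb - w + 1)) {   # boundary before local bin b
        blk <- Z[(b - w):(b - 1), b:(b + w - 1), drop = FALSE]
        score[b, k] <- mean(blk, na.rm = TRUE)
      }
    }
    all_fit <- rowSums(!is.na(score)) == length(usable_w)
    avg <- ifelse(all_fit, rowMeans(score), NA_real_)
    b_local <- seq_len(nb + 1)
    keep <- b_local >= 2 & b_local <= nb   # internal boundaries only
    df <- data.frame(chrom = ch,
                     pos = bins$start[rows[1]] + (b_local[keep] - 1) * bin_size,
                     bin = rows[b_local[keep]],
                     stringsAsFactors = FALSE)
    sc <- score[keep, , drop = FALSE]
    colnames(sc) <- paste0("score_w", usable_w * bin_size)
    df <- cbind(df, sc)
    df$avg_score <- avg[keep]
    out[[ch]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, windows = wb * bin_size, bin_size = bin_size,
            class = c("tad_score", "data.frame"))
}

# climb from index p toward lower indices until the value stops increasing
climb <- function(v, p, dir) {
  k <- p
  repeat {
    nxt <- k + dir
    if (nxt < 1 || nxt > length(v) || is.na(v[nxt]) || v[nxt] <= v[k]) break
    k <- nxt
  }
  k
}

#' Call TAD boundaries and domains from a separation-score track
#'
#' Candidate boundaries are local minima of the averaged score, strictly
#' lower than every neighbor within `min_boundary_distance` positions
#' (plateaus take the leftmost position). Each candidate must (1) be at
#' least `min_delta` below the mean of its two flanking local maxima, and
#' (2) have its per-window diamond scores significantly lower than those at
#' the flanking maxima (one-sided Wilcoxon rank-sum, Benjamini-Hochberg
#' corrected per chromosome at `significance_alpha`). Consecutive surviving
#' boundaries delimit domains.
#'
#' @param track A `tad_score` from [tad_separation_score()].
#' @param min_delta Minimum depth below the flanking maxima, in z-score
#'   units (default 1).
#' @param significance_alpha BH-adjusted p-value threshold (default 0.05).
#' @param min_boundary_distance Neighborhood half-width, in bins, defining a
#'   local minimum (default 2).
#' @return List: `boundaries` (chrom, pos, score, delta, pvalue, padj),
#'   `domains` (chrom, start, end), `track`.
#' @export
find_boundaries <- function(track, min_delta = 1, significance_alpha = 0.05,
                            min_boundary_distance = 2) {
  score_cols <- grep("^score_w", names(track), value = TRUE)
  bnd <- list(); dom <- list()
  if (is.null(track) || !nrow(track)) {
    return(list(boundaries = data.frame(), domains = data.frame(),
                track = track))
  }
  for (ch in unique(track$chrom)) {
    tr <- track[track$chrom == ch, , drop = FALSE]
    v <- tr$avg_score
    n <- length(v)
    cand <- integer()
    for (p in seq_len(n)) {
      if (is.na(v[p])) next
      lo <- max(1, p - min_boundary_distance)
      hi <- min(n, p + min_boundary_distance)
      left <- if (p > lo) v[lo:(p - 1)] else numeric()
      right <- if (p < hi) v[(p + 1):hi] else numeric()
      left <- left[!is.na(left)]; right <- right[!is.na(right)]
      if (!length(left) || !length(right)) next
      # strictly below the left flank, at-or-below the right flank: a tied
      # plateau yields only its leftmost position
      if (all(v[p] < left) && all(v[p] <= right)) cand <- c(cand, p)
    }
    if (!length(cand)) next
    rec <- lapply(cand, function(p) {
      kL <- climb(v, p, -1L)
      kR <- climb(v, p, +1L)
      delta <- mean(c(v[kL], v[kR])) - v[p]
      at_min <- unlist(tr[p, score_cols])
      at_max <- c(unlist(tr[kL, score_cols]), unlist(tr[kR, score_cols]))
      at_min <- at_min[!is.na(at_min)]; at_max <- at_max[!is.na(at_max)]
      pv <- if (length(at_min) && length(at_max)) {
        suppressWarnings(stats::wilcox.test(at_min, at_max,
                                            alternative = "less",
                                            exact = FALSE)$p.value)
      } else NA_real_
      data.frame(chrom = ch, pos = tr$pos[p], score = v[p], delta = delta,
                 pvalue = pv, stringsAsFactors = FALSE)
    })
    rec <- do.call(rbind, rec)
    rec$padj <- stats::p.adjust(rec$pvalue, method = "BH")
    keep <- !is.na(rec$delta) & rec$delta >= min_delta &
      !is.na(rec$padj) & rec$padj < significance_alpha
    rec <- rec[keep, , drop = FALSE]
    if (!nrow(rec)) next
    bnd[[ch]] <- rec
    if (nrow(rec) >= 2) {
      dom[[ch]] <- data.frame(chrom = ch, start = rec$pos[-nrow(rec)],
                              end = rec$pos[-1], stringsAsFactors = FALSE)
    }
  }
  boundaries <- if (length(bnd)) do.call(rbind, bnd) else
    data.frame(chrom = character(), pos = numeric(), score = numeric(),
               delta = numeric(), pvalue = numeric(), padj = numeric())
  domains <- if (length(dom)) do.call(rbind, dom) else
    data.frame(chrom = character(), start = numeric(), end = numeric())
  rownames(boundaries) <- rownames(domains) <- NULL
  list(boundaries = boundaries, domains = domains, track = track)
}

#' Write TAD calls as BED / bedGraph files
#'
#' @param calls Output of [find_boundaries()].
#' @param prefix Path prefix; writes `<prefix>_boundaries.bed` (score in
#'   column 5), `<prefix>_domains.bed`, `<prefix>_score.bedgraph` and
#'   `<prefix>_score_windows.tsv`.
#' @export
write_tads <- function(calls, prefix) {
  b <- calls$boundaries
  bs <- attr(calls$track, "bin_size")
  writeLines(if (nrow(b)) {
    sprintf("%s\t%d\t%d\tboundary_%d\t%.6g", b$chrom,
            as.integer(b$pos), as.integer(b$pos) + 1L,
            seq_len(nrow(b)), b$score)
  } else character(), paste0(prefix, "_boundaries.bed"))
  d <- calls$domains
  writeLines(if (nrow(d)) {
    sprintf("%s\t%d\t%d\tdomain_%d", d$chrom, as.integer(d$start),
            as.integer(d$end), seq_len(nrow(d)))
  } else character(), paste0(prefix, "_domains.bed"))
  tr <- calls$track
  gr <- data.frame(chrom = tr$chrom, start = pmax(0, tr$pos - bs / 2),
                   end = tr$pos + bs / 2, value = tr$avg_score)
  write_bedgraph(gr, "value", paste0(prefix, "_score.bedgraph"))
  utils::write.table(as.data.frame(tr), paste0(prefix, "_score_windows.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
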
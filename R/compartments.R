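#' A/B compartment eigenvector tracks
#'
#' Per chromosome: observed/expected transform, Pearson correlation matrix
#' of the O/E block, then (by default) the covariance of that Pearson
#' matrix, whose eigenvectors — ordered by decreasing absolute eigenvalue —
#' give the compartment signal. The sign of the leading eigenvector
#' partitions bins into the A/B checkerboard pattern; the sign itself is
#' arbitrary until oriented against a guide track (see [orient_track()]).
#'
#' @param m A corrected `contact_matrix`.
#' @param method Decompose `"covariance"` of the Pearson matrix (default) or
#'   the `"pearson"` matrix directly.
#' @param min_bins Chromosomes with fewer unmasked bins are skipped with a
#'   warning (default 3).
#' @return Data frame track: `chrom`, `start`, `end`, `ev1`, `ev2` (`NA` on
#'   masked/skipped bins), with per-chromosome eigenvalues in
#'   `attr(, "eigenvalues")`.
#' @export
ab_compartments <- function(m, method = c("covariance", "pearson"),
                            min_bins = 3) {
  method <- match.arg(method)
  oe <- if (identical(m$meta$transform, "obs_exp")) m else obs_exp(m)
  bins <- m$bins
  ev1 <- rep(NA_real_, nrow(bins))
  ev2 <- rep(NA_real_, nrow(bins))
  evals <- list()
  for (ch in names(bin_layout(bins))) {
    rows <- bins_of_chrom(bins, ch)
    un <- rows[!m$masked[rows]]
    if (length(un) < min_bins) {
      warning("ab_compartments: skipping ", ch, " (", length(un),
              " unmasked bins)")
      next
    }
    pc <- pearson_and_covariance(oe, ch)[[ch]]
    P <- pc$pearson[!m$masked[rows], !m$masked[rows], drop = FALSE]
    # rows that were entirely undefined (e.g. constant O/E) are excluded
    ok <- rowSums(is.na(P)) < ncol(P)
    P <- P[ok, ok, drop = FALSE]
    use <- un[ok]
    if (length(use) < min_bins) {
      warning("ab_compartments: skipping ", ch, " (degenerate correlations)")
      next
    }
    P[is.na(P)] <- 0
    M <- if (method == "covariance") stats::cov(P) else P
    eg <- eigen(M, symmetric = TRUE)
    ord <- order(-abs(eg$values))
    v1 <- eg$vectors[, ord[1]]
    v2 <- if (length(ord) >= 2) eg$vectors[, ord[2]] else rep(NA_real_, length(use))
    ev1[use] <- v1
    ev2[use] <- v2
    evals[[ch]] <- eg$values[ord]
  }
  out <- data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
                    ev1 = ev1, ev2 = ev2, stringsAsFactors = FALSE)
  attr(out, "eigenvalues") <- evals
  out
}

#' Orient an eigenvector track against a guide
#'
#' The sign of a compartment eigenvector is arbitrary; given a per-bin guide
#' (e.g. GC content or gene density binned to matrix resolution), the track
#' is flipped per chromosome whenever its correlation with the guide is
#' negative. Orientations with `|r|` below `reliability_r` are flagged
#' unreliable; a zero-variance guide refuses orientation and returns the
#' input unchanged.
#'
#' @param track Data frame with `chrom`, `start`, `end` and a value column.
#' @param guide Numeric vector, one value per track row (NA allowed).
#' @param value_col Column to orient (default `"ev1"`).
#' @param reliability_r Threshold on `|r|` below which the orientation is
#'   flagged unreliable (default 0.1).
#' @return List: `track` (possibly flipped), `correlation` (per chromosome),
#'   `flipped`, `reliable`, `status`.
#' @export
orient_track <- function(track, guide, value_col = "ev1",
                         reliability_r = 0.1) {
  stopifnot(length(guide) == nrow(track))
  v <- track[[value_col]]
  covered <- !is.na(guide) & !is.na(v)
  if (sum(!is.na(guide)) < nrow(track) / 2) {
    stop("orient_track: guide covers fewer than half of the bins")
  }
  if (sum(covered) < 2 || stats::sd(guide[covered]) == 0) {
    return(list(track = track, correlation = NA_real_, flipped = NULL,
                reliable = FALSE, status = "zero-variance guide"))
  }
  cors <- c(); flips <- c(); reliable <- c()
  for (ch in unique(track$chrom)) {
    sel <- track$chrom == ch & covered
    r <- if (sum(sel) >= 2 && stats::sd(v[sel]) > 0 &&
             stats::sd(guide[sel]) > 0) {
      stats::cor(v[sel], guide[sel])
    } else NA_real_
    fl <- !is.na(r) && r < 0
    if (fl) {
      chsel <- track$chrom == ch
      track[[value_col]][chsel] <- -track[[value_col]][chsel]
    }
    cors[ch] <- r; flips[ch] <- fl
    reliable[ch] <- !is.na(r) && abs(r) >= reliability_r
  }
  list(track = track, correlation = cors, flipped = flips,
       reliable = reliable, status = "ok")
}

#' Bin a bedGraph-style track to a bin table
#'
#' Overlap-weighted mean of interval values within each bin.
#'
#' @param bins A `bin_table`.
#' @param bedgraph Data frame `chrom`, `start`, `end`, `value` (0-based
#'   half-open).
#' @return Numeric vector, one value per bin (`NA` where uncovered).
#' @export
bin_track <- function(bins, bedgraph) {
  out <- rep(NA_real_, nrow(bins))
  for (i in seq_len(nrow(bins))) {
    g <- bedgraph[bedgraph$chrom == bins$chrom[i] &
                    bedgraph$end > bins$start[i] &
                    bedgraph$start < bins$end[i], , drop = FALSE]
    if (!nrow(g)) next
    w <- pmin(g$end, bins$end[i]) - pmax(g$start, bins$start[i])
    out[i] <- sum(g$value * w) / sum(w)
  }
  out
}

#' Write a per-bin track as bedGraph
#'
#' Rows with missing values are skipped, so the intervals tile exactly the
#' bins carrying a value.
#'
#' @param track Data frame with `chrom`, `start`, `end` and `value_col`.
#' @param value_col Name of the value column.
#' @param path Output path.
#' @param track_name Optional `track` header line name.
#' @export
write_bedgraph <- function(track, value_col, path, track_name = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(track_name)) {
    writeLines(sprintf("track type=bedGraph name=\"%s\"", track_name), con)
  }
  keep <- !is.na(track[[value_col]])
  writeLines(sprintf("%s\t%d\t%d\t%.10g", track$chrom[keep],
                     as.integer(track$start[keep]),
                     as.integer(track$end[keep]),
                     track[[value_col]][keep]), con)
  invisible(path)
}

#' Read a bedGraph file
#'
#' @param path File path.
#' @return Data frame `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|#|browser)", lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(chrom = vapply(f, `[`, "", 1),
             start = as.numeric(vapply(f, `[`, "", 2)),
             end = as.numeric(vapply(f, `[`, "", 3)),
             value = as.numeric(vapply(f, `[`, "", 4)),
             stringsAsFactors = FALSE)
}
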
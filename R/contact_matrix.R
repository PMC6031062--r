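#' Contact matrix container
#'
#' A symmetric sparse matrix of interaction values over a shared bin table.
#' Only the upper triangle (`bin1 <= bin2`, 1-based global indices) is stored;
#' off-diagonal pixels represent unordered bin pairs and the diagonal is
#' counted once in totals. Masked bins stay in the bin table (indices never
#' shift); their pixels are retained in storage but excluded from every
#' downstream computation.
#'
#' @param bins A `bin_table` shared by all pixels.
#' @param pixels Data frame with columns `bin1`, `bin2`, `value` (1-based
#'   global indices; any orientation, duplicates are summed).
#' @param masked Logical vector of length `nrow(bins)`, or integer indices.
#' @param meta List of metadata (`corrected`, `bias`, `total_valid_pairs`, ...).
#' @return A `contact_matrix` object.
#' @export
contact_matrix <- function(bins,
                           pixels = data.frame(bin1 = integer(),
                                               bin2 = integer(),
                                               value = numeric()),
                           masked = NULL, meta = list()) {
  stopifnot(inherits(bins, "bin_table"))
  nb <- nrow(bins)
  if (is.null(masked)) masked <- rep(FALSE, nb)
  if (is.numeric(masked) && !is.logical(masked)) {
    m <- rep(FALSE, nb); m[masked] <- TRUE; masked <- m
  }
  stopifnot(length(masked) == nb)
  pixels <- as.data.frame(pixels)
  pixels$bin1 <- as.integer(pixels$bin1)
  pixels$bin2 <- as.integer(pixels$bin2)
  pixels$value <- as.numeric(pixels$value)
  if (nrow(pixels)) {
    if (anyNA(pixels$bin1) || anyNA(pixels$bin2) ||
        any(pixels$bin1 < 1) || any(pixels$bin2 < 1) ||
        any(pixels$bin1 > nb) || any(pixels$bin2 > nb)) {
      stop("contact_matrix: integrity error: pixel references a bin outside ",
           "the ", nb, "-bin table")
    }
    if (any(pixels$value < 0, na.rm = TRUE)) {
      stop("contact_matrix: negative pixel value")
    }
    swap <- pixels$bin1 > pixels$bin2
    if (any(swap)) {
      tmp <- pixels$bin1[swap]
      pixels$bin1[swap] <- pixels$bin2[swap]
      pixels$bin2[swap] <- tmp
    }
    key <- (pixels$bin1 - 1) * nb + pixels$bin2
    if (anyDuplicated(key)) {
      agg <- rowsum(pixels$value, key)
      k <- as.numeric(rownames(agg))
      pixels <- data.frame(bin1 = (k - 1) %/% nb + 1, bin2 = (k - 1) %% nb + 1,
                           value = as.numeric(agg))
      key <- k
    }
    pixels <- pixels[order(key), c("bin1", "bin2", "value")]
    rownames(pixels) <- NULL
  }
  if (is.null(meta$corrected)) meta$corrected <- FALSE
  structure(list(bins = bins, pixels = pixels, masked = masked, meta = meta),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact matrix: %d bins, %d stored pixels, total %.6g\n",
              nrow(x$bins), nrow(x$pixels), total_counts(x)))
  cat(sprintf("  masked bins: %d; corrected: %s\n",
              sum(x$masked), x$meta$corrected))
  invisible(x)
}

#' Total counts of a contact matrix
#'
#' Diagonal pixels are counted once; off-diagonal pixels once per unordered
#' pair. Pixels touching masked bins are excluded.
#'
#' @param m A `contact_matrix`.
#' @param use_masked Include pixels on masked bins.
#' @return Numeric scalar.
#' @export
total_counts <- function(m, use_masked = FALSE) {
  p <- m$pixels
  if (!use_masked && any(m$masked)) {
    keep <- !m$masked[p$bin1] & !m$masked[p$bin2]
    p <- p[keep, , drop = FALSE]
  }
  sum(p$value)
}

active_pixels <- function(m) {
  p <- m$pixels
  if (any(m$masked)) p <- p[!m$masked[p$bin1] & !m$masked[p$bin2], , drop = FALSE]
  p
}

#' Densify a contact matrix (or one chromosome of it)
#'
#' @param m A `contact_matrix`.
#' @param chrom Optional chromosome name; default whole genome.
#' @param masked_as Value used for rows/columns of masked bins (`NA` default).
#' @return Dense symmetric numeric matrix.
#' @export
densify <- function(m, chrom = NULL, masked_as = NA_real_) {
  rows <- if (is.null(chrom)) seq_len(nrow(m$bins)) else bins_of_chrom(m$bins, chrom)
  if (!is.null(chrom) && !length(rows)) stop("densify: unknown chromosome ", chrom)
  n <- length(rows)
  D <- matrix(0, n, n)
  p <- m$pixels
  keep <- p$bin1 %in% rows & p$bin2 %in% rows
  p <- p[keep, , drop = FALSE]
  off <- rows[1] - 1L
  i <- p$bin1 - off; j <- p$bin2 - off
  D[cbind(i, j)] <- p$value
  D[cbind(j, i)] <- p$value
  msk <- m$masked[rows]
  if (any(msk)) { D[msk, ] <- masked_as; D[, msk] <- masked_as }
  dimnames(D) <- NULL
  D
}

# dense symmetric matrix (one chromosome slice) back to pixel triplets
dense_to_pixels <- function(D, rows) {
  ut <- which(upper.tri(D, diag = TRUE) & D != 0 & !is.na(D), arr.ind = TRUE)
  data.frame(bin1 = rows[ut[, 1]], bin2 = rows[ut[, 2]], value = D[ut])
}

bins_identical <- function(a, b) {
  nrow(a) == nrow(b) && all(a$chrom == b$chrom) &&
    all(a$start == b$start) && all(a$end == b$end)
}

#' Write / read the plain-text contact-matrix container
#'
#' The container is two tab-separated files sharing a path prefix:
#' `<prefix>.bins.tsv` (chrom, start, end, 0-based bin id, masked flag,
#' bias or NA) and `<prefix>.pixels.tsv` (0-based bin1 id, bin2 id, value)
#' whose `#meta` header line carries the remaining metadata as JSON.
#' `read_matrix(write_matrix(m, p))` reproduces bins, pixels, mask and meta;
#' values survive bit-exactly (`%.17g`).
#'
#' @param m A `contact_matrix`.
#' @param prefix Path prefix for the two files.
#' @return `prefix`, invisibly.
#' @export
write_matrix <- function(m, prefix) {
  bias <- m$meta$bias
  if (is.null(bias)) bias <- rep(NA_real_, nrow(m$bins))
  bins_df <- data.frame(chrom = m$bins$chrom, start = m$bins$start,
                        end = m$bins$end, id = seq_len(nrow(m$bins)) - 1L,
                        masked = as.integer(m$masked),
                        bias = sprintf("%.17g", bias))
  utils::write.table(bins_df, paste0(prefix, ".bins.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  meta <- m$meta
  meta$bias <- NULL
  layout <- bin_layout(m$bins)
  header <- jsonlite::toJSON(list(
    kind = attr(m$bins, "kind"), bin_size = attr(m$bins, "bin_size"),
    chrom_names = names(layout), chrom_lengths = as.numeric(layout),
    recognition_seq = attr(m$bins, "recognition_seq"),
    dangling_seq = attr(m$bins, "dangling_seq"),
    meta = meta), auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(paste0(prefix, ".pixels.tsv"), "w")
  on.exit(close(con))
  writeLines(paste0("#meta\t", header), con)
  if (nrow(m$pixels)) {
    writeLines(sprintf("%d\t%d\t%.17g", m$pixels$bin1 - 1L,
                       m$pixels$bin2 - 1L, m$pixels$value), con)
  }
  invisible(prefix)
}

#' @rdname write_matrix
#' @param prefix Path prefix used by [write_matrix()].
#' @export
read_matrix <- function(prefix) {
  bins_path <- paste0(prefix, ".bins.tsv")
  pix_path <- paste0(prefix, ".pixels.tsv")
  for (p in c(bins_path, pix_path)) {
    if (!file.exists(p)) stop("read_matrix: missing container file ", p)
  }
  bins_df <- tryCatch(
    utils::read.table(bins_path, sep = "\t", stringsAsFactors = FALSE,
                      col.names = c("chrom", "start", "end", "id", "masked",
                                    "bias"),
                      colClasses = c("character", "numeric", "numeric",
                                     "integer", "integer", "numeric"),
                      na.strings = c("NA", "nan")),
    error = function(e) stop("read_matrix: malformed bins file ", bins_path,
                             ": ", conditionMessage(e)))
  first <- readLines(pix_path, n = 1)
  if (!startsWith(first, "#meta\t")) {
    stop("read_matrix: malformed pixels file ", pix_path,
         ": line 1 must be a '#meta' header")
  }
  hdr <- jsonlite::fromJSON(sub("^#meta\t", "", first), simplifyVector = TRUE)
  layout <- genome_layout(structure(hdr$chrom_lengths, names = hdr$chrom_names))
  bins <- new_bin_table(bins_df[, c("chrom", "start", "end")], layout,
                        hdr$kind,
                        if (is.null(hdr$bin_size)) NA_real_ else hdr$bin_size)
  if (!is.null(hdr$recognition_seq)) {
    attr(bins, "recognition_seq") <- hdr$recognition_seq
    attr(bins, "dangling_seq") <- hdr$dangling_seq
  }
  pix <- tryCatch(
    utils::read.table(pix_path, sep = "\t", comment.char = "#",
                      col.names = c("bin1", "bin2", "value"),
                      colClasses = c("integer", "integer", "numeric")),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) {
        data.frame(bin1 = integer(), bin2 = integer(), value = numeric())
      } else {
        stop("read_matrix: malformed pixels file ", pix_path, ": ",
             conditionMessage(e))
      }
    })
  meta <- hdr$meta
  if (any(!is.na(bins_df$bias))) meta$bias <- bins_df$bias
  m <- contact_matrix(bins, data.frame(bin1 = pix$bin1 + 1L,
                                       bin2 = pix$bin2 + 1L,
                                       value = pix$value),
                      masked = bins_df$masked == 1L, meta = meta)
  m
}

#' Merge neighboring bins
#'
#' Lowers matrix resolution by summing consecutive runs of `k` bins per
#' chromosome (the trailing run may be shorter). Pixel values are summed, so
#' total counts are conserved; the operation is only defined on uncorrected
#' count matrices. A merged bin is masked only if all its constituents were.
#'
#' @param m An uncorrected `contact_matrix`.
#' @param k Number of neighboring bins to merge (>= 1).
#' @return A `contact_matrix` on the merged bin table.
#' @export
merge_bins <- function(m, k) {
  if (isTRUE(m$meta$corrected)) {
    stop("merge_bins: refusing to merge a corrected matrix; merge counts ",
         "before correction")
  }
  stopifnot(k >= 1)
  k <- as.integer(round(k))
  if (k == 1) return(m)
  bins <- m$bins
  layout <- bin_layout(bins)
  map <- integer(nrow(bins))
  pieces <- list()
  nxt <- 1L
  for (ch in names(layout)) {
    rows <- bins_of_chrom(bins, ch)
    grp <- (seq_along(rows) - 1L) %/% k
    for (g in unique(grp)) {
      sel <- rows[grp == g]
      map[sel] <- nxt
      pieces[[nxt]] <- data.frame(chrom = ch, start = bins$start[sel[1]],
                                  end = bins$end[sel[length(sel)]],
                                  masked = all(m$masked[sel]))
      nxt <- nxt + 1L
    }
  }
  newdf <- do.call(rbind, pieces)
  newbins <- new_bin_table(newdf[, c("chrom", "start", "end")], layout,
                           attr(bins, "kind"),
                           if (attr(bins, "kind") == "uniform")
                             attr(bins, "bin_size") * k else NA_real_)
  contact_matrix(newbins,
                 data.frame(bin1 = map[m$pixels$bin1],
                            bin2 = map[m$pixels$bin2],
                            value = m$pixels$value),
                 masked = newdf$masked, meta = m$meta)
}

#' Sum contact matrices
#'
#' Element-wise sum of matrices sharing one bin table (e.g. replicates);
#' `total_valid_pairs` metadata is summed and masks are unioned.
#'
#' @param ms List of `contact_matrix` objects on identical bin tables.
#' @return A `contact_matrix`.
#' @export
sum_matrices <- function(ms) {
  stopifnot(length(ms) >= 1)
  b0 <- ms[[1]]$bins
  for (i in seq_along(ms)[-1]) {
    b <- ms[[i]]$bins
    if (!bins_identical(b0, b)) {
      what <- if (nrow(b0) != nrow(b)) "bin counts differ" else
        which(b0$chrom != b$chrom | b0$start != b$start |
                b0$end != b$end)[1]
      stop("sum_matrices: incompatible bin tables; first differing bin: ",
           what)
    }
  }
  pix <- do.call(rbind, lapply(ms, function(m) m$pixels))
  masked <- Reduce(`|`, lapply(ms, function(m) m$masked))
  tvp <- vapply(ms, function(m) {
    v <- m$meta$total_valid_pairs
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, 0)
  meta <- ms[[1]]$meta
  meta$total_valid_pairs <- if (all(is.na(tvp))) NULL else sum(tvp, na.rm = TRUE)
  contact_matrix(b0, pix, masked = masked, meta = meta)
}

#' Extract a dense region of a contact matrix
#'
#' @param m A `contact_matrix`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open region; default the whole chromosome.
#' @return List with `matrix` (dense symmetric block; masked bins as `NA`)
#'   and `bins` (the corresponding bin-table slice).
#' @export
extract_region <- function(m, chrom, start = 0, end = NULL) {
  layout <- bin_layout(m$bins)
  if (!chrom %in% names(layout)) stop("extract_region: unknown chromosome ",
                                      chrom)
  if (is.null(end)) end <- layout[[chrom]]
  rows <- bins_of_chrom(m$bins, chrom)
  rows <- rows[m$bins$end[rows] > start & m$bins$start[rows] < end]
  if (!length(rows)) stop("extract_region: region overlaps no bin")
  n <- length(rows)
  D <- matrix(0, n, n)
  p <- m$pixels
  keep <- p$bin1 >= rows[1] & p$bin1 <= rows[n] &
    p$bin2 >= rows[1] & p$bin2 <= rows[n]
  p <- p[keep, , drop = FALSE]
  i <- p$bin1 - rows[1] + 1L; j <- p$bin2 - rows[1] + 1L
  D[cbind(i, j)] <- p$value
  D[cbind(j, i)] <- p$value
  msk <- m$masked[rows]
  if (any(msk)) { D[msk, ] <- NA_real_; D[, msk] <- NA_real_ }
  list(matrix = D, bins = m$bins[rows, , drop = FALSE],
       bin_index = rows)
}

#' Heatmap of (part of) a contact matrix
#'
#' Convenience log-scale image of a chromosome block.
#'
#' @param x A `contact_matrix`.
#' @param chrom Chromosome (default first).
#' @param log Plot `log10(1 + value)`.
#' @param ... Passed to [graphics::image()].
#' @exportS3Method graphics::plot
plot.contact_matrix <- function(x, chrom = NULL, log = TRUE, ...) {
  if (is.null(chrom)) chrom <- x$bins$chrom[1]
  D <- densify(x, chrom)
  if (log) D <- log10(1 + D)
  n <- ncol(D)
  graphics::image(seq_len(n), seq_len(n), D[, n:1, drop = FALSE],
                  col = grDevices::hcl.colors(64, "Reds", rev = TRUE),
                  xlab = paste(chrom, "bin"), ylab = paste(chrom, "bin"),
                  useRaster = TRUE, ...)
  invisible(x)
}
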
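pair_categories <- c("unmapped", "low_mapq", "duplicate",
                     "same_fragment_dangling", "self_circle",
                     "self_ligation", "valid")

# Put the lower (chrom order, pos) mate first for every fully mapped pair.
canonicalize_pairs <- function(pairs, chrom_order) {
  rank1 <- match(pairs$chrom1, chrom_order)
  rank2 <- match(pairs$chrom2, chrom_order)
  swap <- !is.na(rank1) & !is.na(rank2) &
    (rank1 > rank2 | (rank1 == rank2 & pairs$pos1 > pairs$pos2))
  if (any(swap)) {
    for (col in c("chrom", "pos", "strand", "mapq", "seq")) {
      a <- paste0(col, 1); b <- paste0(col, 2)
      tmp <- pairs[[a]][swap]
      pairs[[a]][swap] <- pairs[[b]][swap]
      pairs[[b]][swap] <- tmp
    }
  }
  pairs
}

#' Classify Hi-C read pairs
#'
#' Assigns every pair to exactly one category with the precedence
#' `unmapped > low_mapq > duplicate > same_fragment_dangling > self_circle >
#' self_ligation > valid`. Pairs are first put in canonical mate order
#' (lower (chromosome order, position) mate first). A duplicate is any pair
#' after the first with an identical canonical
#' (chrom1,pos1,strand1,chrom2,pos2,strand2) key, detected over the stream
#' among pairs passing the mapping filters. With a fragment table, a mate
#' whose leading sequence equals the dangling-end sequence, and any
#' same-fragment pair that is not read-outward, is `same_fragment_dangling`;
#' same-fragment outward-facing pairs are `self_circle`; adjacent-fragment
#' inward-facing pairs are `self_ligation`. Without fragments the
#' fragment-dependent classes are skipped.
#'
#' @param pairs A pairs data frame (see [pairs_format]).
#' @param frags Fragment `bin_table` from [digest_genome()], or `NULL`.
#' @param min_mapq Minimum mapping quality for both mates (default 15).
#' @param dangling_seq Override of the dangling-end sequence (default: the
#'   fragment table's).
#' @return List with `category` (factor per pair) and the canonicalized
#'   `pairs`.
#' @export
classify_pairs <- function(pairs, frags = NULL, min_mapq = 15,
                           dangling_seq = NULL) {
  stopifnot(min_mapq >= 0)
  n <- nrow(pairs)
  chrom_order <- if (!is.null(frags)) names(bin_layout(frags)) else
    unique(c(pairs$chrom1, pairs$chrom2))
  chrom_order <- chrom_order[!is.na(chrom_order)]
  pairs <- canonicalize_pairs(pairs, chrom_order)
  cat_ <- rep(NA_character_, n)

  unmapped <- is.na(pairs$chrom1) | is.na(pairs$chrom2)
  cat_[unmapped] <- "unmapped"
  low <- !unmapped & (pairs$mapq1 < min_mapq | pairs$mapq2 < min_mapq)
  cat_[low] <- "low_mapq"

  open <- is.na(cat_)
  key <- paste(pairs$chrom1, pairs$pos1, pairs$strand1,
               pairs$chrom2, pairs$pos2, pairs$strand2, sep = "\r")
  dup <- open & duplicated(ifelse(open, key, paste0("closed", seq_len(n))))
  cat_[dup] <- "duplicate"
  open <- is.na(cat_)

  if (!is.null(frags) && any(open)) {
    if (is.null(dangling_seq)) dangling_seq <- attr(frags, "dangling_seq")
    if (is.null(dangling_seq)) {
      stop("classify_pairs: fragment table carries no dangling-end sequence")
    }
    s1 <- toupper(pairs$seq1[open]); s2 <- toupper(pairs$seq2[open])
    if (all(is.na(s1)) && all(is.na(s2)) && sum(open) > 0) {
      stop("classify_pairs: configuration error: dangling-end checking is ",
           "enabled but no pair carries a leading sequence")
    }
    dang_seq <- (!is.na(s1) & s1 == dangling_seq) |
      (!is.na(s2) & s2 == dangling_seq)
    f1 <- locate_bin(frags, pairs$chrom1[open], pairs$pos1[open])
    f2 <- locate_bin(frags, pairs$chrom2[open], pairs$pos2[open])
    same_chrom <- pairs$chrom1[open] == pairs$chrom2[open]
    inward <- pairs$strand1[open] == "+" & pairs$strand2[open] == "-"
    outward <- pairs$strand1[open] == "-" & pairs$strand2[open] == "+"
    same_frag <- same_chrom & f1 == f2
    cls <- rep("valid", sum(open))
    cls[same_chrom & abs(f2 - f1) == 1 & inward] <- "self_ligation"
    cls[same_frag & outward] <- "self_circle"
    cls[same_frag & !outward] <- "same_fragment_dangling"
    cls[dang_seq] <- "same_fragment_dangling"
    cat_[open] <- cls
  } else {
    cat_[open] <- "valid"
  }
  list(category = factor(cat_, levels = pair_categories), pairs = pairs)
}

new_qc_report <- function(counts, orientation, params) {
  structure(list(counts = counts, orientation = orientation, params = params),
            class = "hic_qc")
}

#' Build a contact matrix from read pairs
#'
#' Classifies the pairs (see [classify_pairs()]), drops every non-valid
#' category, and tabulates each valid pair into the bin pair containing the
#' two 5' mate positions. The QC report counts every category, splits valid
#' pairs into inter-chromosomal / intra short-range (< `short_range` bp) /
#' intra long-range, and tallies mate orientation (inward, outward,
#' same-strand forward/reverse) over all intra-chromosomal mapped pairs.
#'
#' @param pairs A pairs data frame.
#' @param bins Target `bin_table`.
#' @param frags Optional fragment table enabling the fragment filters.
#' @param min_mapq Minimum mapping quality (default 15).
#' @param short_range Short/long-range split in bp (default 20000).
#' @param dangling_seq Optional dangling-end sequence override.
#' @return List with `matrix` (a [contact_matrix()]) and `qc` (a `hic_qc`).
#' @export
build_matrix <- function(pairs, bins, frags = NULL, min_mapq = 15,
                         short_range = 20000, dangling_seq = NULL) {
  layout <- bin_layout(bins)
  for (side in 1:2) {
    ch <- pairs[[paste0("chrom", side)]]
    p <- pairs[[paste0("pos", side)]]
    mapped <- !is.na(ch)
    if (any(mapped & !(ch %in% names(layout)))) {
      stop("build_matrix: integrity error: pair ",
           pairs$id[mapped & !(ch %in% names(layout))][1],
           " maps to a chromosome absent from the bin table")
    }
    over <- mapped & p >= layout[ifelse(mapped, ch, names(layout)[1])]
    if (any(over, na.rm = TRUE)) {
      stop("build_matrix: integrity error: pair ", pairs$id[which(over)[1]],
           " has a position beyond its chromosome length")
    }
  }
  cl <- classify_pairs(pairs, frags, min_mapq, dangling_seq)
  pairs <- cl$pairs
  category <- cl$category
  counts <- as.list(table(category))
  counts <- c(list(total = nrow(pairs)), counts)

  valid <- category == "valid"
  inter <- valid & pairs$chrom1 != pairs$chrom2
  dist <- abs(pairs$pos2 - pairs$pos1)
  intra_short <- valid & !inter & dist < short_range
  intra_long <- valid & !inter & dist >= short_range
  counts$inter_chromosomal <- sum(inter)
  counts$intra_short_range <- sum(intra_short)
  counts$intra_long_range <- sum(intra_long)

  mapped_intra <- !is.na(pairs$chrom1) & !is.na(pairs$chrom2) &
    pairs$chrom1 == pairs$chrom2
  s1 <- pairs$strand1[mapped_intra]; s2 <- pairs$strand2[mapped_intra]
  orientation <- c(
    inward = sum(s1 == "+" & s2 == "-"),
    outward = sum(s1 == "-" & s2 == "+"),
    same_strand_forward = sum(s1 == "+" & s2 == "+"),
    same_strand_reverse = sum(s1 == "-" & s2 == "-"))

  vp <- pairs[valid, , drop = FALSE]
  pixels <- if (nrow(vp)) {
    data.frame(bin1 = locate_bin(bins, vp$chrom1, vp$pos1),
               bin2 = locate_bin(bins, vp$chrom2, vp$pos2),
               value = 1)
  } else data.frame(bin1 = integer(), bin2 = integer(), value = numeric())
  m <- contact_matrix(bins, pixels,
                      meta = list(total_valid_pairs = sum(valid)))
  qc <- new_qc_report(counts, orientation,
                      list(min_mapq = min_mapq, short_range = short_range,
                           fragment_filters = !is.null(frags)))
  list(matrix = m, qc = qc)
}

#' @export
print.hic_qc <- function(x, ...) {
  cat("Hi-C pair QC report\n")
  for (k in names(x$counts)) cat(sprintf("  %-24s %d\n", k, x$counts[[k]]))
  cat("  orientation:", paste(names(x$orientation), x$orientation,
                              collapse = ", "), "\n")
  invisible(x)
}

#' Merge QC reports into one table
#'
#' One row per sample with raw counts plus fractions of total; a zero-total
#' report yields missing fractions, not an error.
#'
#' @param reports Named list of `hic_qc` reports (names become sample ids).
#' @return Data frame, one row per report.
#' @export
merge_qc <- function(reports) {
  stopifnot(length(reports) >= 1)
  if (is.null(names(reports)) || any(names(reports) == "")) {
    names(reports) <- paste0("sample", seq_along(reports))
  }
  keys <- c("total", pair_categories, "inter_chromosomal",
            "intra_short_range", "intra_long_range")
  rows <- lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    cnt <- vapply(keys, function(k) {
      v <- r$counts[[k]]; if (is.null(v)) 0 else as.numeric(v)
    }, 0)
    tot <- cnt[["total"]]
    frac <- if (tot > 0) cnt / tot else rep(NA_real_, length(cnt))
    names(frac) <- paste0("frac_", keys)
    ori <- r$orientation
    names(ori) <- paste0("orient_", names(ori))
    data.frame(sample = nm, t(cnt), t(frac[-1]), t(ori),
               stringsAsFactors = FALSE, check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write QC outputs
#'
#' Writes the merged table as TSV, as structured JSON, and as a minimal
#' standalone HTML table.
#'
#' @param reports Named list of `hic_qc` reports.
#' @param prefix Output path prefix (`.tsv`, `.json`, `.html` appended).
#' @return The merged data frame, invisibly.
#' @export
write_qc <- function(reports, prefix) {
  tab <- merge_qc(reports)
  utils::write.table(tab, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(tab, paste0(prefix, ".json"), dataframe = "rows",
                       na = "null", digits = NA)
  esc <- function(s) gsub("<", "&lt;", gsub("&", "&amp;", s))
  cells <- function(v, tag) paste0("<", tag, ">", esc(as.character(v)),
                                   "</", tag, ">", collapse = "")
  html <- c("<!DOCTYPE html><html><head><title>Hi-C pair QC</title></head>",
            "<body><h1>Hi-C pair QC</h1><table border='1'>",
            paste0("<tr>", cells(names(tab), "th"), "</tr>"),
            vapply(seq_len(nrow(tab)), function(i) {
              paste0("<tr>", cells(unlist(lapply(tab[i, ], function(x)
                if (is.numeric(x)) signif(x, 6) else x)), "td"), "</tr>")
            }, ""),
            "</table></body></html>")
  writeLines(html, paste0(prefix, ".html"))
  invisible(tab)
}
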
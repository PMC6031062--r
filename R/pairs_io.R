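#' @name pairs_format
#' @title Read-pair records
#' @description
#' Read pairs are plain data frames with one row per mate pair and columns
#' `id`, `chrom1`, `pos1`, `strand1`, `mapq1`, `seq1`, `chrom2`, `pos2`,
#' `strand2`, `mapq2`, `seq2`. Positions are 0-based 5' mapping positions;
#' an unmapped mate has `chrom = NA`. `seq*` is the leading (5') read
#' sequence used for dangling-end detection, or `NA` when unavailable.
NULL

empty_pairs <- function() {
  data.frame(id = character(), chrom1 = character(), pos1 = numeric(),
             strand1 = character(), mapq1 = numeric(), seq1 = character(),
             chrom2 = character(), pos2 = numeric(), strand2 = character(),
             mapq2 = numeric(), seq2 = character(), stringsAsFactors = FALSE)
}

#' Read a 4DN-style .pairs file
#'
#' Header lines start with `#`. The mandatory columns are
#' `readID chr1 pos1 chr2 pos2 strand1 strand2`; this reader also takes the
#' optional extended columns `mapq1 mapq2 seq1 seq2` written by
#' [write_pairs()]. File positions are 1-based (converted to 0-based
#' internally); an unmapped mate is encoded as `!` with position 0.
#'
#' @param path Path to the .pairs file.
#' @param default_mapq Mapping quality assumed when the file has no mapq
#'   columns.
#' @return A pairs data frame (see [pairs_format]).
#' @export
read_pairs <- function(path, default_mapq = 60) {
  if (!file.exists(path)) stop("read_pairs: no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) return(empty_pairs())
  f <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(f)
  if (any(ncol < 7)) {
    stop("read_pairs: line ", which(ncol < 7)[1],
         " has fewer than the 7 mandatory columns")
  }
  get <- function(k) vapply(f, function(x) if (length(x) >= k) x[k] else NA_character_, "")
  df <- data.frame(id = get(1), chrom1 = get(2), pos1 = as.numeric(get(3)),
                   chrom2 = get(4), pos2 = as.numeric(get(5)),
                   strand1 = get(6), strand2 = get(7),
                   stringsAsFactors = FALSE)
  ext <- max(ncol) >= 9
  df$mapq1 <- if (ext) as.numeric(get(8)) else default_mapq
  df$mapq2 <- if (ext) as.numeric(get(9)) else default_mapq
  df$seq1 <- if (max(ncol) >= 11) get(10) else NA_character_
  df$seq2 <- if (max(ncol) >= 11) get(11) else NA_character_
  for (side in 1:2) {
    ch <- df[[paste0("chrom", side)]]
    un <- ch == "!" | ch == "."
    df[[paste0("chrom", side)]][un] <- NA
    df[[paste0("pos", side)]] <- df[[paste0("pos", side)]] - 1  # to 0-based
    df[[paste0("pos", side)]][un] <- NA
    df[[paste0("seq", side)]][!is.na(df[[paste0("seq", side)]]) &
                                df[[paste0("seq", side)]] == "."] <- NA
  }
  df[, names(empty_pairs())]
}

#' Write pairs in the 4DN .pairs dialect
#'
#' Columns: `readID chr1 pos1 chr2 pos2 strand1 strand2 mapq1 mapq2 seq1
#' seq2` (1-based positions; unmapped mate as `! 0 +`; missing sequence as
#' `.`).
#'
#' @param pairs A pairs data frame.
#' @param path Output path.
#' @param layout Optional [genome_layout()] written as `#chromsize` headers.
#' @export
write_pairs <- function(pairs, path, layout = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("## pairs format v1.0", con)
  if (!is.null(layout)) {
    writeLines(sprintf("#chromsize: %s %d", names(layout), as.numeric(layout)),
               con)
  }
  writeLines(paste("#columns: readID chr1 pos1 chr2 pos2 strand1 strand2",
                   "mapq1 mapq2 seq1 seq2"), con)
  enc <- function(side) {
    ch <- pairs[[paste0("chrom", side)]]
    pos <- pairs[[paste0("pos", side)]] + 1
    pos[is.na(ch)] <- 0
    sq <- pairs[[paste0("seq", side)]]
    sq[is.na(sq)] <- "."
    list(chrom = ifelse(is.na(ch), "!", ch), pos = pos,
         strand = pairs[[paste0("strand", side)]],
         mapq = pairs[[paste0("mapq", side)]], seq = sq)
  }
  if (nrow(pairs)) {
    a <- enc(1); b <- enc(2)
    writeLines(sprintf("%s\t%s\t%d\t%s\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                       pairs$id, a$chrom, as.integer(a$pos), b$chrom,
                       as.integer(b$pos), a$strand, b$strand,
                       as.integer(a$mapq), as.integer(b$mapq), a$seq, b$seq),
               con)
  }
  invisible(path)
}

revcomp <- function(s) {
  out <- chartr("ACGTacgt", "TGCAtgca", s)
  vapply(strsplit(out, NULL), function(x) paste(rev(x), collapse = ""), "")
}

#' Write pairs as a minimal SAM file
#'
#' Two records per pair (FLAG bits for paired/mate number/strand/unmapped).
#' Reads are given a fully matching CIGAR; for minus-strand mates the stored
#' POS is the leftmost base and SEQ is reverse-complemented, so the 5'
#' position and leading sequence round-trip through [read_sam_pairs()].
#'
#' @param pairs A pairs data frame.
#' @param path Output path.
#' @param layout A [genome_layout()] for the `@SQ` header lines.
#' @param read_length Length used for mates without a stored sequence.
#' @export
write_sam <- function(pairs, path, layout, read_length = 20) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(layout), as.numeric(layout)),
             con)
  rec <- function(i, side) {
    other <- 3 - side
    ch <- pairs[[paste0("chrom", side)]][i]
    och <- pairs[[paste0("chrom", other)]][i]
    strand <- pairs[[paste0("strand", side)]][i]
    ostrand <- pairs[[paste0("strand", other)]][i]
    sq <- pairs[[paste0("seq", side)]][i]
    if (is.na(sq)) sq <- strrep("N", read_length)
    L <- nchar(sq)
    flag <- 1L + if (side == 1) 64L else 128L
    if (is.na(ch)) flag <- flag + 4L
    if (is.na(och)) flag <- flag + 8L
    if (!is.na(ch) && strand == "-") flag <- flag + 16L
    if (!is.na(och) && ostrand == "-") flag <- flag + 32L
    if (is.na(ch)) {
      return(sprintf("%s\t%d\t*\t0\t0\t*\t*\t0\t0\t%s\t*",
                     pairs$id[i], flag, sq))
    }
    fivep <- pairs[[paste0("pos", side)]][i]
    left <- if (strand == "-") fivep - L + 1 else fivep
    seq_out <- if (strand == "-") revcomp(sq) else sq
    sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*",
            pairs$id[i], flag, ch, as.integer(left) + 1L,
            as.integer(pairs[[paste0("mapq", side)]][i]), L, seq_out)
  }
  for (i in seq_len(nrow(pairs))) {
    writeLines(c(rec(i, 1), rec(i, 2)), con)
  }
  invisible(path)
}

#' Read paired alignments from a SAM text file
#'
#' Parses the 11 mandatory columns, pairs records by query name, and ignores
#' secondary (0x100) and supplementary (0x800) alignments. The reported
#' position is the 5' mapping position (POS for `+`, rightmost aligned base
#' for `-`, from the CIGAR reference span) and the reported sequence is the
#' leading read sequence in original orientation, truncated to `seq_length`.
#'
#' @param path SAM file path.
#' @param seq_length Number of leading bases to retain (`Inf` for all).
#' @return A pairs data frame (see [pairs_format]).
#' @export
read_sam_pairs <- function(path, seq_length = Inf) {
  if (!file.exists(path)) stop("read_sam_pairs: no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) return(empty_pairs())
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) < 11)
  if (length(bad)) stop("read_sam_pairs: line ", bad[1],
                        " has fewer than 11 mandatory columns")
  qname <- vapply(f, `[`, "", 1)
  flag <- as.integer(vapply(f, `[`, "", 2))
  keep <- bitwAnd(flag, 0x100) == 0 & bitwAnd(flag, 0x800) == 0
  f <- f[keep]; qname <- qname[keep]; flag <- flag[keep]
  rname <- vapply(f, `[`, "", 3)
  pos <- as.numeric(vapply(f, `[`, "", 4)) - 1  # to 0-based leftmost
  mapq <- as.numeric(vapply(f, `[`, "", 5))
  cigar <- vapply(f, `[`, "", 6)
  seqs <- vapply(f, `[`, "", 10)
  ref_span <- function(cg) {
    if (cg == "*") return(0)
    toks <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    sum(vapply(toks, function(t) {
      op <- substr(t, nchar(t), nchar(t))
      n <- as.numeric(substr(t, 1, nchar(t) - 1))
      if (op %in% c("M", "D", "N", "=", "X")) n else 0
    }, 0))
  }
  unmapped <- bitwAnd(flag, 0x4) != 0
  minus <- bitwAnd(flag, 0x10) != 0
  fivep <- pos
  span <- vapply(cigar, ref_span, 0)
  fivep[minus] <- pos[minus] + span[minus] - 1
  lead <- seqs
  lead[minus] <- revcomp(seqs[minus])
  lead[lead == "*"] <- NA_character_
  if (is.finite(seq_length)) {
    lead <- ifelse(is.na(lead), lead, substr(lead, 1, seq_length))
  }
  mate1 <- bitwAnd(flag, 0x40) != 0
  make_side <- function(sel) {
    o <- sel[order(qname[sel])]
    data.frame(id = qname[o],
               chrom = ifelse(unmapped[o], NA_character_, rname[o]),
               pos = ifelse(unmapped[o], NA_real_, fivep[o]),
               strand = ifelse(minus[o], "-", "+"),
               mapq = mapq[o], seq = lead[o], stringsAsFactors = FALSE)
  }
  s1 <- make_side(which(mate1))
  s2 <- make_side(which(!mate1))
  if (nrow(s1) != nrow(s2) || any(s1$id != s2$id)) {
    stop("read_sam_pairs: unpaired records (mate missing for some query)")
  }
  data.frame(id = s1$id,
             chrom1 = s1$chrom, pos1 = s1$pos, strand1 = s1$strand,
             mapq1 = s1$mapq, seq1 = s1$seq,
             chrom2 = s2$chrom, pos2 = s2$pos, strand2 = s2$strand,
             mapq2 = s2$mapq, seq2 = s2$seq, stringsAsFactors = FALSE)
}
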
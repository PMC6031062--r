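#' Genome layout
#'
#' A `genome_layout` is an ordered named integer vector of chromosome lengths
#' in base pairs. The order is significant: it defines the global ordering of
#' bins in every matrix built on top of it.
#'
#' @param chroms Named numeric vector of chromosome lengths (bp, >= 1).
#' @return A `genome_layout` object (named integer vector).
#' @examples
#' genome_layout(c(chr1 = 2e6, chr2 = 2e6))
#' @export
genome_layout <- function(chroms) {
  if (length(chroms) == 0) stop("genome_layout: no chromosomes given")
  nm <- names(chroms)
  if (is.null(nm) || any(nm == "") || anyNA(nm)) {
    stop("genome_layout: chromosome lengths must be named")
  }
  if (anyDuplicated(nm)) stop("genome_layout: duplicated chromosome name: ",
                              nm[duplicated(nm)][1])
  len <- as.numeric(chroms)
  if (anyNA(len) || any(len < 1)) stop("genome_layout: lengths must be >= 1")
  out <- structure(round(len), names = nm, class = "genome_layout")
  out
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome layout:", length(x), "chromosome(s),",
      format(sum(x), big.mark = ","), "bp\n")
  for (i in seq_along(x)) cat(" ", names(x)[i], x[[i]], "\n")
  invisible(x)
}

as_layout <- function(x) {
  if (inherits(x, "genome_layout")) x else genome_layout(x)
}

new_bin_table <- function(df, layout, kind, bin_size = NA_real_, ...) {
  rownames(df) <- NULL
  structure(df,
            layout = layout, kind = kind, bin_size = bin_size, ...,
            class = c("bin_table", "data.frame"))
}

#' Fixed-size genomic bins
#'
#' Partitions every chromosome of a layout into consecutive bins of
#' `bin_size` bp; the last bin of a chromosome may be shorter. Coordinates
#' are 0-based half-open; the row number is the global (1-based) bin index.
#'
#' @param layout A [genome_layout()] (or named length vector).
#' @param bin_size Bin width in bp (>= 1).
#' @return A `bin_table` data frame with columns `chrom`, `start`, `end`.
#' @examples
#' make_fixed_bins(genome_layout(c(chrA = 11)), 5)
#' @export
make_fixed_bins <- function(layout, bin_size) {
  layout <- as_layout(layout)
  if (!is.numeric(bin_size) || length(bin_size) != 1 || is.na(bin_size) ||
      bin_size < 1) {
    stop("make_fixed_bins: bin_size must be a positive number")
  }
  bin_size <- round(bin_size)
  pieces <- lapply(names(layout), function(ch) {
    len <- layout[[ch]]
    starts <- seq(0, len - 1, by = bin_size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + bin_size, len),
               stringsAsFactors = FALSE)
  })
  new_bin_table(do.call(rbind, pieces), layout, "uniform", bin_size)
}

#' In-silico restriction digestion
#'
#' Cuts each chromosome sequence at the start offset of every (possibly
#' overlapping) occurrence of the recognition sequence on the forward strand.
#' Matching is case-insensitive; ambiguous bases in the genome never match.
#' Fragment boundaries are the cut positions plus the chromosome ends, so the
#' fragments partition each chromosome.
#'
#' @param sequences Named character vector of chromosome sequences, or a
#'   `Biostrings::DNAStringSet`.
#' @param recognition_seq Enzyme recognition sequence (ACGT only).
#' @param dangling_seq Sequence marking unligated (dangling-end) reads;
#'   defaults to the recognition sequence.
#' @return A `bin_table` of kind `"fragment"` carrying the enzyme and
#'   dangling-end sequences as attributes.
#' @examples
#' digest_genome(c(chrA = "AAAAGATCAAAA"), "GATC")
#' @export
digest_genome <- function(sequences, recognition_seq,
                          dangling_seq = recognition_seq) {
  if (inherits(sequences, "DNAStringSet")) {
    sequences <- as.character(sequences)
  }
  if (length(sequences) == 0) stop("digest_genome: empty sequence set")
  if (is.null(names(sequences))) stop("digest_genome: sequences must be named")
  recognition_seq <- toupper(recognition_seq)
  if (!nzchar(recognition_seq) || grepl("[^ACGT]", recognition_seq)) {
    stop("digest_genome: recognition_seq must be a non-empty ACGT string")
  }
  layout <- genome_layout(vapply(sequences, nchar, 0))
  pat <- Biostrings::DNAString(recognition_seq)
  pieces <- lapply(names(sequences), function(ch) {
    subj <- Biostrings::DNAString(toupper(sequences[[ch]]))
    hits <- Biostrings::matchPattern(pat, subj, fixed = TRUE)
    cuts <- Biostrings::start(hits) - 1L   # 0-based cut offsets
    cuts <- cuts[cuts > 0]                 # a cut at 0 gives no leading fragment
    bnd <- unique(c(0, cuts, layout[[ch]]))
    data.frame(chrom = ch, start = bnd[-length(bnd)], end = bnd[-1],
               stringsAsFactors = FALSE)
  })
  new_bin_table(do.call(rbind, pieces), layout, "fragment",
                recognition_seq = recognition_seq,
                dangling_seq = toupper(dangling_seq))
}

n_bins <- function(bins) nrow(bins)

bin_layout <- function(bins) attr(bins, "layout")

# first global index of each chromosome's bins
chrom_first_index <- function(bins) {
  idx <- which(!duplicated(bins$chrom))
  structure(idx, names = bins$chrom[idx])
}

bins_of_chrom <- function(bins, chrom) which(bins$chrom == chrom)

#' Locate the bin containing a position
#'
#' Maps genomic positions (0-based) to global bin indices (1-based row
#' numbers of the bin table). Vectorized over `chrom`/`pos`.
#'
#' @param bins A `bin_table`.
#' @param chrom Chromosome name(s).
#' @param pos 0-based position(s); must satisfy `0 <= pos < length`.
#' @return Integer vector of global bin indices.
#' @export
locate_bin <- function(bins, chrom, pos) {
  layout <- bin_layout(bins)
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n)
  pos <- rep_len(pos, n)
  bad <- !(chrom %in% names(layout))
  if (any(bad)) stop("locate_bin: unknown chromosome: ", chrom[bad][1])
  if (anyNA(pos) || any(pos < 0) || any(pos >= layout[chrom])) {
    stop("locate_bin: position out of range for its chromosome")
  }
  out <- integer(n)
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    rows <- bins_of_chrom(bins, ch)
    # bins tile the chromosome, so findInterval on starts is exact
    out[sel] <- rows[findInterval(pos[sel], bins$start[rows])]
  }
  out
}

#' Read a chromosome-sizes table
#'
#' Two whitespace-separated columns: chromosome name, length in bp.
#'
#' @param path File path.
#' @return A [genome_layout()].
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("read_chrom_sizes: no such file: ", path)
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  genome_layout(structure(df$length, names = df$chrom))
}

#' Read a (possibly line-wrapped, multi-record) FASTA genome
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercase sequences.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("read_genome_fasta: no such file: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  # drop FASTA description after first whitespace
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' Write a bin or fragment table as BED3(+index)
#'
#' @param bins A `bin_table`.
#' @param path Output path.
#' @param index Add the 0-based global bin index as a fourth column.
#' @export
write_bins_bed <- function(bins, path, index = TRUE) {
  df <- data.frame(bins$chrom, bins$start, bins$end)
  if (index) df$idx <- seq_len(nrow(bins)) - 1L
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.bin_table <- function(x, ...) {
  cat(sprintf("bin table: %d bins (%s", nrow(x), attr(x, "kind")))
  if (!is.na(attr(x, "bin_size"))) cat(",", attr(x, "bin_size"), "bp")
  cat("),", length(bin_layout(x)), "chromosome(s)\n")
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("...\n")
  invisible(x)
}
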
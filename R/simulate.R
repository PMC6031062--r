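with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

#' Ground-truth specification for the synthetic Hi-C generator
#'
#' Defines a genome with every structural feature the pipeline is meant to
#' recover: a power-law distance decay, planted TAD blocks, a checkerboard
#' compartment pattern, multiplicative per-bin biases, point enrichment at
#' anchor pairs, and the artifact read classes the pair classifier filters.
#' All stochastic ingredients (boundary placement, compartment labels,
#' biases, anchors) are drawn once here from `seed`, so a spec fully
#' determines the expectation of every downstream statistic.
#'
#' @param layout A [genome_layout()]; default two 2-Mb chromosomes.
#' @param bin_size Bin width in bp (default 5000).
#' @param alpha Distance-decay exponent: intensity proportional to
#'   `(d + 1)^-alpha` in bins (default 1).
#' @param amplitude Intensity at distance 0 before modulation (default 100).
#' @param n_tad_boundaries Planted boundaries per chromosome (default 5);
#'   ignored when `tad_boundaries` is given.
#' @param tad_boundaries Optional list (per chromosome) of local bin indices
#'   `b` meaning a boundary between bins `b - 1` and `b`.
#' @param tad_enrichment Within-TAD multiplicative factor `t` (default 3).
#' @param comp_block_bins Checkerboard block size in bins (default 25).
#' @param comp_strength Checkerboard strength `c` in `[0, 1)`: same-label
#'   pairs scaled by `1 + c`, opposite by `1 - c` (default 0.3).
#' @param comp_labels Optional list (per chromosome) of +/-1 labels.
#' @param bias_sdlog Log-normal sd of planted per-bin biases (default 0.25);
#'   biases are normalized to mean 1.
#' @param biases Optional explicit per-bin bias vector.
#' @param inter_level Constant intensity of inter-chromosomal pairs before
#'   bias modulation, as a fraction of `amplitude` (default 1e-3).
#' @param n_anchors Planted anchor bins per chromosome (default 6).
#' @param anchor_enrichment Multiplicative enrichment at every
#'   intra-chromosomal anchor-pair pixel (default 3).
#' @param fragments Artifact fractions, a named list with elements
#'   `duplicate`, `dangling`, `self_circle`, `unmapped`, `low_mapq`
#'   (fractions of the read stream; must sum to < 1).
#' @param fragment_size Synthetic restriction-fragment size in bp
#'   (default 500).
#' @param recognition_seq Enzyme site used for the synthetic fragment table
#'   (default "GATC").
#' @param seed Seed fixing the spec's stochastic ingredients (default 1).
#' @return A `hic_truth` object.
#' @export
hic_truth <- function(layout = genome_layout(c(chr1 = 2e6, chr2 = 2e6)),
                      bin_size = 5000, alpha = 1, amplitude = 100,
                      n_tad_boundaries = 5, tad_boundaries = NULL,
                      tad_enrichment = 3, comp_block_bins = 25,
                      comp_strength = 0.3, comp_labels = NULL,
                      bias_sdlog = 0.25, biases = NULL, inter_level = 1e-3,
                      n_anchors = 6, anchor_enrichment = 3,
                      fragments = list(duplicate = 0.05, dangling = 0.05,
                                       self_circle = 0.02, unmapped = 0.03,
                                       low_mapq = 0.05),
                      fragment_size = 500, recognition_seq = "GATC",
                      seed = 1) {
  layout <- as_layout(layout)
  if (alpha <= 0) stop("hic_truth: alpha must be > 0")
  if (comp_strength < 0 || comp_strength >= 1) {
    stop("hic_truth: comp_strength must be in [0, 1)")
  }
  if (sum(unlist(fragments)) >= 1) {
    stop("hic_truth: artifact fractions must sum to < 1")
  }
  bins <- make_fixed_bins(layout, bin_size)
  nb_per <- table(factor(bins$chrom, levels = names(layout)))
  spec <- with_seed(seed, {
    tb <- tad_boundaries
    if (is.null(tb)) {
      tb <- lapply(names(layout), function(ch) {
        nb <- nb_per[[ch]]
        if (n_tad_boundaries == 0) return(integer())
        # boundaries well inside the chromosome; margins and the minimum
        # separation scale down on short chromosomes
        margin <- min(15L, max(1L, nb %/% 8))
        lo <- margin + 1L; hi <- nb - margin
        if (hi - lo + 1L < n_tad_boundaries) {
          stop("hic_truth: chromosome ", ch, " is too short for ",
               n_tad_boundaries, " TAD boundaries")
        }
        minsep <- min(20L, max(1L, (hi - lo) %/% max(1L, n_tad_boundaries)))
        repeat {
          b <- sort(sample(lo:hi, n_tad_boundaries))
          if (n_tad_boundaries < 2 || min(diff(b)) >= minsep) break
        }
        b
      })
      names(tb) <- names(layout)
    }
    cl <- comp_labels
    if (is.null(cl)) {
      cl <- lapply(names(layout), function(ch) {
        nb <- nb_per[[ch]]
        blk <- ((seq_len(nb) - 1) %/% comp_block_bins) %% 2
        ifelse(blk == 0, 1, -1)
      })
      names(cl) <- names(layout)
    }
    b <- biases
    if (is.null(b)) {
      b <- stats::rlnorm(nrow(bins), 0, bias_sdlog)
      b <- b / mean(b)
    }
    anch <- lapply(names(layout), function(ch) {
      nb <- nb_per[[ch]]
      if (n_anchors == 0) return(integer())
      margin <- min(10L, max(1L, nb %/% 8))
      pool <- seq(margin, nb - margin)
      if (length(pool) < n_anchors) {
        stop("hic_truth: chromosome ", ch, " is too short for ", n_anchors,
             " anchors")
      }
      sort(sample(pool, n_anchors))
    })
    names(anch) <- names(layout)
    list(tad_boundaries = tb, comp_labels = cl, biases = b, anchors = anch)
  })
  structure(list(layout = layout, bins = bins, bin_size = bin_size,
                 alpha = alpha, amplitude = amplitude,
                 tad_boundaries = spec$tad_boundaries,
                 tad_enrichment = tad_enrichment,
                 comp_labels = spec$comp_labels,
                 comp_strength = comp_strength,
                 biases = spec$biases, inter_level = inter_level,
                 anchors = spec$anchors,
                 anchor_enrichment = anchor_enrichment,
                 fractions = fragments, fragment_size = fragment_size,
                 recognition_seq = recognition_seq, seed = seed),
            class = "hic_truth")
}

#' @export
print.hic_truth <- function(x, ...) {
  cat("synthetic Hi-C ground truth:", length(x$layout), "chromosome(s),",
      nrow(x$bins), "bins of", x$bin_size, "bp\n")
  cat(sprintf("  alpha=%g, TAD t=%g, checkerboard c=%g, bias sd(log)=%.3g, seed=%d\n",
              x$alpha, x$tad_enrichment, x$comp_strength,
              stats::sd(log(x$biases)), x$seed))
  invisible(x)
}

#' Expected-intensity matrix of a ground truth
#'
#' Deterministic real-valued expected contact intensities:
#' `amplitude * (d + 1)^-alpha`, multiplied by `tad_enrichment` for
#' same-TAD pairs, by `1 +/- comp_strength` for same/opposite compartment
#' labels, by `anchor_enrichment` at anchor-pair pixels, and by
#' `bias_i * bias_j` throughout; inter-chromosomal pairs get the constant
#' `inter_level * amplitude` (bias-modulated).
#'
#' @param spec A [hic_truth()].
#' @return A real-valued `contact_matrix` over the spec's bins.
#' @export
simulate_truth_matrix <- function(spec) {
  bins <- spec$bins
  layout <- spec$layout
  pix <- list()
  for (ch in names(layout)) {
    rows <- bins_of_chrom(bins, ch)
    nb <- length(rows)
    ut <- which(upper.tri(diag(nb), diag = TRUE), arr.ind = TRUE)
    i <- ut[, 1]; j <- ut[, 2]
    d <- j - i
    v <- spec$amplitude * (d + 1)^(-spec$alpha)
    tb <- spec$tad_boundaries[[ch]]
    tad <- findInterval(seq_len(nb), tb)
    v <- v * ifelse(tad[i] == tad[j], spec$tad_enrichment, 1)
    lab <- spec$comp_labels[[ch]]
    v <- v * (1 + spec$comp_strength * lab[i] * lab[j])
    anch <- spec$anchors[[ch]]
    if (length(anch) >= 2) {
      ap <- utils::combn(anch, 2)
      key <- (i - 1) * nb + j
      akey <- (ap[1, ] - 1) * nb + ap[2, ]
      v[key %in% akey] <- v[key %in% akey] * spec$anchor_enrichment
    }
    pix[[ch]] <- data.frame(bin1 = rows[i], bin2 = rows[j], value = v)
  }
  if (spec$inter_level > 0 && length(layout) > 1) {
    chroms <- names(layout)
    for (a in seq_along(chroms)[-length(chroms)]) {
      for (b in (a + 1):length(chroms)) {
        ra <- bins_of_chrom(bins, chroms[a])
        rb <- bins_of_chrom(bins, chroms[b])
        g <- expand.grid(bin1 = ra, bin2 = rb)
        g$value <- spec$inter_level * spec$amplitude
        pix[[paste(chroms[a], chroms[b])]] <- g
      }
    }
  }
  p <- do.call(rbind, pix)
  p$value <- p$value * spec$biases[p$bin1] * spec$biases[p$bin2]
  contact_matrix(bins, p, meta = list(total_valid_pairs = NULL,
                                      simulated = TRUE))
}

#' Sample a contact-count matrix from a ground truth
#'
#' Multinomial sample of `n_pairs` valid contacts over the expected
#' intensities — what [build_matrix()] would produce from the valid reads of
#' [simulate_pairs()], without going through read records.
#'
#' @param spec A [hic_truth()].
#' @param n_pairs Number of contacts to sample.
#' @param seed Seed for the multinomial draw.
#' @param truth Optional precomputed [simulate_truth_matrix()] output.
#' @return An integer-count `contact_matrix`.
#' @export
simulate_counts <- function(spec, n_pairs, seed = 1, truth = NULL) {
  if (is.null(truth)) truth <- simulate_truth_matrix(spec)
  cnt <- with_seed(seed, {
    as.numeric(stats::rmultinom(1, n_pairs, truth$pixels$value))
  })
  keep <- cnt > 0
  contact_matrix(truth$bins,
                 data.frame(bin1 = truth$pixels$bin1[keep],
                            bin2 = truth$pixels$bin2[keep],
                            value = cnt[keep]),
                 meta = list(total_valid_pairs = n_pairs, simulated = TRUE))
}

# synthetic uniform fragment table carrying the enzyme annotation
uniform_fragments <- function(layout, fragment_size, recognition_seq,
                              dangling_seq = recognition_seq) {
  fb <- make_fixed_bins(layout, fragment_size)
  new_bin_table(as.data.frame(fb)[, c("chrom", "start", "end")], layout,
                "fragment", recognition_seq = recognition_seq,
                dangling_seq = toupper(dangling_seq))
}

#' Simulate classified Hi-C read pairs with a ground-truth sidecar
#'
#' Samples valid mate pairs proportional to the expected intensities
#' (positions uniform within bins, strands random but never matching an
#' artifact geometry), then injects artifact pairs at the spec's fractions
#' with exactly the signatures the classifier tests for: duplicates are
#' exact copies of sampled pairs, dangling ends sit inward on one fragment
#' with the dangling-end sequence as leading bases, self-circles sit
#' outward on one fragment, unmapped/low-mapq pairs fail the mapping
#' filters. Artifact counts are exact (injected, not expected), and all
#' non-duplicate pair keys are unique, so the sidecar predicts every QC
#' category count exactly.
#'
#' @param spec A [hic_truth()].
#' @param n_pairs Total number of read pairs (>= 1).
#' @param seed Seed for all sampling.
#' @param truth Optional precomputed truth matrix.
#' @return List: `pairs` (shuffled pairs data frame), `sidecar` (realized
#'   per-category counts, valid-pair distance split, parameters), `frags`
#'   (the synthetic fragment table), `truth`.
#' @export
simulate_pairs <- function(spec, n_pairs, seed = 1, truth = NULL) {
  stopifnot(n_pairs >= 1)
  if (is.null(truth)) truth <- simulate_truth_matrix(spec)
  frags <- uniform_fragments(spec$layout, spec$fragment_size,
                             spec$recognition_seq)
  bins <- spec$bins
  fr <- spec$fractions
  n_art <- vapply(c("duplicate", "dangling", "self_circle", "unmapped",
                    "low_mapq"),
                  function(k) {
    v <- fr[[k]]; if (is.null(v)) 0L else as.integer(round(v * n_pairs))
  }, 0L)
  n_valid <- n_pairs - sum(n_art)
  if (n_valid < 1) stop("simulate_pairs: artifact fractions leave no valid pairs")
  dang <- attr(frags, "dangling_seq")
  filler <- if (dang == strrep("A", nchar(dang))) {
    strrep("C", nchar(dang))
  } else strrep("A", nchar(dang))
  fs <- spec$fragment_size

  with_seed(seed, {
    ## ---- valid pairs -------------------------------------------------
    px <- sample.int(nrow(truth$pixels), n_valid, replace = TRUE,
                     prob = truth$pixels$value)
    b1 <- truth$pixels$bin1[px]; b2 <- truth$pixels$bin2[px]
    draw_pos <- function(b) {
      bins$start[b] + floor(stats::runif(length(b)) *
                              (bins$end[b] - bins$start[b]))
    }
    p1 <- draw_pos(b1); p2 <- draw_pos(b2)
    s1 <- sample(c("+", "-"), n_valid, replace = TRUE)
    s2 <- sample(c("+", "-"), n_valid, replace = TRUE)
    ch1 <- bins$chrom[b1]; ch2 <- bins$chrom[b2]
    # canonical mate order within a chromosome
    swap <- ch1 == ch2 & p1 > p2
    tmp <- p1[swap]; p1[swap] <- p2[swap]; p2[swap] <- tmp
    tmp <- s1[swap]; s1[swap] <- s2[swap]; s2[swap] <- tmp
    frag_of <- function(ch, p) locate_bin(frags, ch, p)
    for (round in 1:50) {
      intra <- ch1 == ch2
      f1 <- frag_of(ch1, p1); f2 <- frag_of(ch2, p2)
      same_frag <- intra & f1 == f2
      adj_in <- intra & abs(f2 - f1) == 1 & s1 == "+" & s2 == "-"
      bad <- same_frag | adj_in
      if (!any(bad)) break
      # resample positions of offending pairs within their bins
      p1[bad] <- draw_pos(b1[bad]); p2[bad] <- draw_pos(b2[bad])
      sw <- bad & ch1 == ch2 & p1 > p2
      tmp <- p1[sw]; p1[sw] <- p2[sw]; p2[sw] <- tmp
      tmp <- s1[sw]; s1[sw] <- s2[sw]; s2[sw] <- tmp
    }
    valid <- data.frame(chrom1 = ch1, pos1 = p1, strand1 = s1, mapq1 = 60,
                        seq1 = filler, chrom2 = ch2, pos2 = p2, strand2 = s2,
                        mapq2 = 60, seq2 = filler, stringsAsFactors = FALSE)

    ## ---- artifact pairs ---------------------------------------------
    rand_frag <- function(n) sample.int(nrow(frags), n, replace = TRUE)
    same_frag_pair <- function(n, inward) {
      f <- rand_frag(n)
      lo <- frags$start[f]; w <- frags$end[f] - frags$start[f]
      a <- lo + floor(stats::runif(n) * (w - 1))
      b <- a + 1 + floor(stats::runif(n) * (lo + w - a - 1))
      data.frame(chrom1 = frags$chrom[f], pos1 = a,
                 strand1 = if (inward) "+" else "-", mapq1 = 60,
                 seq1 = if (inward) dang else filler,
                 chrom2 = frags$chrom[f], pos2 = b,
                 strand2 = if (inward) "-" else "+", mapq2 = 60,
                 seq2 = filler, stringsAsFactors = FALSE)
    }
    dangling <- if (n_art[["dangling"]] > 0) {
      same_frag_pair(n_art[["dangling"]], inward = TRUE)
    }
    circles <- if (n_art[["self_circle"]] > 0) {
      same_frag_pair(n_art[["self_circle"]], inward = FALSE)
    }
    rand_loc <- function(n) {
      b <- sample.int(nrow(bins), n, replace = TRUE)
      list(chrom = bins$chrom[b], pos = draw_pos(b))
    }
    unmapped <- if (n_art[["unmapped"]] > 0) {
      n <- n_art[["unmapped"]]
      l <- rand_loc(n)
      data.frame(chrom1 = l$chrom, pos1 = l$pos,
                 strand1 = sample(c("+", "-"), n, TRUE), mapq1 = 60,
                 seq1 = filler, chrom2 = NA_character_, pos2 = NA_real_,
                 strand2 = "+", mapq2 = 0, seq2 = filler,
                 stringsAsFactors = FALSE)
    }
    lowq <- if (n_art[["low_mapq"]] > 0) {
      n <- n_art[["low_mapq"]]
      a <- rand_loc(n); b <- rand_loc(n)
      data.frame(chrom1 = a$chrom, pos1 = a$pos,
                 strand1 = sample(c("+", "-"), n, TRUE), mapq1 = 60,
                 seq1 = filler, chrom2 = b$chrom, pos2 = b$pos,
                 strand2 = sample(c("+", "-"), n, TRUE), mapq2 = 5,
                 seq2 = filler, stringsAsFactors = FALSE)
    }

    ## ---- uniqueness of non-duplicate keys ----------------------------
    ## Any accidental key collision among mapped, good-mapq originals would
    ## be counted as a duplicate by the classifier, so the offending rows
    ## are regenerated until all keys are unique.
    key <- function(df) paste(df$chrom1, df$pos1, df$strand1, df$chrom2,
                              df$pos2, df$strand2)
    nv <- nrow(valid)
    for (round in 1:100) {
      dupidx <- which(duplicated(key(valid)))
      if (!length(dupidx)) break
      p1n <- draw_pos(b1[dupidx]); p2n <- draw_pos(b2[dupidx])
      sw <- valid$chrom1[dupidx] == valid$chrom2[dupidx] & p1n > p2n
      tmp <- p1n[sw]; p1n[sw] <- p2n[sw]; p2n[sw] <- tmp
      f1n <- frag_of(valid$chrom1[dupidx], p1n)
      f2n <- frag_of(valid$chrom2[dupidx], p2n)
      intra_n <- valid$chrom1[dupidx] == valid$chrom2[dupidx]
      ok <- !(intra_n & (f1n == f2n |
                           (abs(f2n - f1n) == 1 &
                              valid$strand1[dupidx] == "+" &
                              valid$strand2[dupidx] == "-")))
      valid$pos1[dupidx[ok]] <- p1n[ok]
      valid$pos2[dupidx[ok]] <- p2n[ok]
    }
    ensure_unique <- function(df, regen, prior_keys) {
      if (is.null(df)) return(df)
      for (round in 1:100) {
        bad <- which(duplicated(c(prior_keys, key(df)))[-seq_along(prior_keys)])
        if (!length(bad)) break
        df[bad, ] <- regen(length(bad))
      }
      df
    }
    dangling <- ensure_unique(dangling,
                              function(n) same_frag_pair(n, inward = TRUE),
                              key(valid))
    circles <- ensure_unique(circles,
                             function(n) same_frag_pair(n, inward = FALSE),
                             c(key(valid), if (!is.null(dangling)) key(dangling)))

    dups <- if (n_art[["duplicate"]] > 0) {
      valid[sample.int(nv, n_art[["duplicate"]], replace = TRUE), ]
    }

    all_pairs <- rbind(valid, dangling, circles, dups, unmapped, lowq)
    all_pairs <- all_pairs[sample.int(nrow(all_pairs)), ]
    all_pairs <- cbind(id = sprintf("sim%07d", seq_len(nrow(all_pairs))),
                       all_pairs, stringsAsFactors = FALSE)
    rownames(all_pairs) <- NULL

    intra <- valid$chrom1 == valid$chrom2
    dist <- abs(valid$pos2 - valid$pos1)
    sidecar <- list(
      seed = seed, n_pairs = n_pairs,
      counts = list(total = n_pairs, unmapped = n_art[["unmapped"]],
                    low_mapq = n_art[["low_mapq"]],
                    duplicate = n_art[["duplicate"]],
                    same_fragment_dangling = n_art[["dangling"]],
                    self_circle = n_art[["self_circle"]],
                    self_ligation = 0L, valid = nv),
      valid_split = list(inter_chromosomal = sum(!intra),
                         intra_short_range = sum(intra & dist < 20000),
                         intra_long_range = sum(intra & dist >= 20000)),
      fractions = spec$fractions, fragment_size = spec$fragment_size,
      recognition_seq = spec$recognition_seq)
    list(pairs = all_pairs[, names(empty_pairs())], sidecar = sidecar,
         frags = frags, truth = truth)
  })
}

#' Write a simulation to disk
#'
#' Writes the read pairs as 4DN `.pairs` and minimal SAM, the ground-truth
#' expected matrix in the standard container, and the sidecar as JSON.
#'
#' @param sim Output of [simulate_pairs()].
#' @param prefix Path prefix.
#' @param layout The spec's [genome_layout()].
#' @export
write_simulation <- function(sim, prefix, layout) {
  write_pairs(sim$pairs, paste0(prefix, ".pairs"), layout)
  write_sam(sim$pairs, paste0(prefix, ".sam"), layout)
  write_matrix(sim$truth, paste0(prefix, "_truth"))
  jsonlite::write_json(sim$sidecar, paste0(prefix, "_sidecar.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(prefix)
}
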
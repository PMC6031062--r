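#' Per-bin coverage diagnostics
#'
#' Computes the per-bin coverage (row sums of the implied dense matrix) and
#' suggests pruning thresholds as median +/- 3 MAD of the log coverage of
#' nonzero bins, the standard first step before iterative correction.
#' Zero-coverage bins are always flagged.
#'
#' @param m An uncorrected `contact_matrix`.
#' @param n_mad Width of the suggested band in MAD-score units (default 3).
#' @return List: `totals` (per bin), `log_median`, `log_mad`, `mad_score`
#'   (per-bin score; `-Inf` for zero bins), suggested `lower`/`upper`
#'   thresholds in counts, `flagged` (logical per bin), and `histogram`
#'   (a [graphics::hist()] object of the nonzero log totals, not plotted).
#' @export
coverage_diagnostics <- function(m, n_mad = 3) {
  if (isTRUE(m$meta$corrected)) {
    stop("coverage_diagnostics: expects an uncorrected count matrix")
  }
  totals <- bin_coverage(m)
  nz <- totals > 0
  if (!any(nz)) {
    return(list(totals = totals, log_median = NA_real_, log_mad = NA_real_,
                mad_score = rep(NA_real_, length(totals)),
                lower = NA_real_, upper = NA_real_,
                flagged = totals == 0, histogram = NULL))
  }
  lt <- log(totals[nz])
  med <- stats::median(lt)
  md <- stats::mad(lt)
  score <- rep(-Inf, length(totals))
  score[nz] <- if (md > 0) (log(totals[nz]) - med) / md else 0
  lower <- exp(med - n_mad * md)
  upper <- exp(med + n_mad * md)
  flagged <- totals == 0 | score < -n_mad | score > n_mad
  hist_obj <- graphics::hist(lt, breaks = "FD", plot = FALSE)
  list(totals = totals, log_median = med, log_mad = md, mad_score = score,
       lower = lower, upper = upper, flagged = flagged, histogram = hist_obj)
}

# row sums of the dense symmetric matrix, masked bins excluded (0)
bin_coverage <- function(m, respect_mask = TRUE) {
  n <- nrow(m$bins)
  p <- if (respect_mask) active_pixels(m) else m$pixels
  s <- numeric(n)
  if (nrow(p)) {
    s <- s + unname(rowsum_vec(p$value, p$bin1, n))
    off <- p$bin1 != p$bin2
    if (any(off)) s <- s + unname(rowsum_vec(p$value[off], p$bin2[off], n))
  }
  s
}

rowsum_vec <- function(v, idx, n) {
  out <- numeric(n)
  agg <- rowsum(v, idx)
  out[as.integer(rownames(agg))] <- agg
  out
}

#' Mask low/high-coverage bins
#'
#' Masks bins whose coverage falls outside `[lower, upper]`, given either in
#' MAD-score units of the log coverage (as suggested by
#' [coverage_diagnostics()]) or in absolute counts. In MAD units,
#' zero-coverage bins are always masked. Pixels of masked bins stay in
#' storage; masking is idempotent and never deletes bins.
#'
#' @param m A `contact_matrix`.
#' @param lower,upper Thresholds (`-Inf`/`Inf` to disable a side).
#' @param units `"mad"` (default) or `"count"`.
#' @return The matrix with an updated mask.
#' @export
mask_bins <- function(m, lower = -3, upper = 3, units = c("mad", "count")) {
  units <- match.arg(units)
  if (lower > upper) stop("mask_bins: lower > upper")
  totals <- bin_coverage(m, respect_mask = FALSE)
  if (units == "mad") {
    d <- coverage_diagnostics(m)
    bad <- totals == 0 | d$mad_score < lower | d$mad_score > upper
  } else {
    bad <- totals < lower | totals > upper
  }
  new_mask <- m$masked | bad
  if (all(new_mask)) {
    stop("mask_bins: thresholds would mask every bin (coverage range ",
         signif(min(totals), 4), "-", signif(max(totals), 4), ")")
  }
  m$masked <- new_mask
  m
}

#' Iterative correction (ICE) of a contact matrix
#'
#' Estimates multiplicative per-bin biases by iterative proportional fitting:
#' at each step the unmasked row sums `s` are computed, each pixel is divided
#' by `delta_i * delta_j` where `delta = s / mean(s)`, and the bias estimate
#' is multiplied by `delta`, until `max |delta - 1| < tol`. On success all
#' unmasked row sums are equal (to within the tolerance); the corrected
#' matrix is rescaled so its total equals the input total and the returned
#' bias vector is normalized to mean 1 over unmasked bins. Unmasked
#' zero-coverage bins are masked first (with a warning) since their bias is
#' undefined.
#'
#' @param m A masked, uncorrected `contact_matrix`.
#' @param tol Convergence tolerance on `max |delta - 1|` (default 1e-5).
#' @param max_iter Iteration cap (default 500).
#' @return List: `matrix` (corrected), `bias` (per-bin, `NA` where masked),
#'   `iterations`, `converged`, `residual`.
#' @export
ice_correct <- function(m, tol = 1e-5, max_iter = 500) {
  if (isTRUE(m$meta$corrected)) stop("ice_correct: matrix already corrected")
  n <- nrow(m$bins)
  cov0 <- bin_coverage(m)
  dead <- !m$masked & cov0 == 0
  if (any(dead)) {
    warning("ice_correct: masking ", sum(dead), " unmasked zero-coverage bin(s)")
    m$masked <- m$masked | dead
  }
  if (all(m$masked)) stop("ice_correct: no unmasked bins")
  p <- active_pixels(m)
  total0 <- sum(p$value)
  un <- which(!m$masked)
  bias <- rep(1, n)
  val <- p$value
  off <- p$bin1 != p$bin2
  converged <- FALSE
  residual <- NA_real_
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    s <- rowsum_vec(val, p$bin1, n)
    s <- s + rowsum_vec(val[off], p$bin2[off], n)
    delta <- rep(1, n)
    delta[un] <- s[un] / mean(s[un])
    residual <- max(abs(delta[un] - 1))
    bias <- bias * delta
    val <- val / (delta[p$bin1] * delta[p$bin2])
    if (residual < tol) { converged <- TRUE; break }
  }
  val <- val * (total0 / sum(val))
  bias_out <- rep(NA_real_, n)
  bias_out[un] <- bias[un] / mean(bias[un])
  out <- m
  key_all <- paste(m$pixels$bin1, m$pixels$bin2)
  key_act <- paste(p$bin1, p$bin2)
  newval <- m$pixels$value
  newval[match(key_act, key_all)] <- val
  out$pixels$value <- newval
  out$meta$corrected <- TRUE
  out$meta$bias <- bias_out
  if (!converged) {
    warning(sprintf("ice_correct: not converged after %d iterations (residual %.3g)",
                    iter, residual))
  }
  list(matrix = out, bias = bias_out, iterations = iter,
       converged = converged, residual = residual)
}
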
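#' Two-cluster k-medians deconvolution of one sample
#'
#' The default LINCS L1000 approach: partition the bead intensities of a
#' color into two clusters and report the cluster medians as the two peak
#' positions. In one dimension the optimal two-cluster L1 partition is
#' contiguous in sorted order, so the fit is computed exactly by scanning
#' every cut point of the sorted intensities and minimizing the total
#' absolute deviation from the cluster medians; no iterative refinement
#' (and hence no local optimum or run-to-run variation) is involved.
#'
#' `lambda` is reported as the proportion of beads assigned to the
#' higher-median cluster, matching the convention of the mixture methods
#' where `lambda` weights the higher peak.
#'
#' @param x Numeric vector of bead intensities, length >= 4, at least two
#'   distinct values.
#' @param sample_id,color_id Identifiers copied into the result.
#' @param n_outliers_removed Bookkeeping count copied into the result.
#' @return A one-row peak-call data frame ([peak_call()]) with
#'   `method = "kmedians"` and `sigma = NA`; the cluster assignment is
#'   attached as attribute `"assignment"` (1 = low cluster, 2 = high).
#' @export
#' @examples
#' kmedians_deconv(c(0, 1, 2, 10, 11, 12))[, c("mu_high", "mu_low")]
kmedians_deconv <- function(x, sample_id = "sample", color_id = "color",
                            n_outliers_removed = 0L) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 4L)
    stop("k-medians needs at least 4 beads", call. = FALSE)
  if (length(unique(x)) < 2L)
    stop("k-medians needs at least 2 distinct values", call. = FALSE)
  ord <- order(x)
  xs <- x[ord]
  # L1 cost of a sorted block = sum(upper half) - sum(lower half); scan
  # all cuts in O(n) with prefix sums
  S <- c(0, cumsum(xs))
  block_cost <- function(l, r) {
    h <- (r - l + 1L) %/% 2L
    (S[r + 1L] - S[r - h + 1L]) - (S[l + h] - S[l])
  }
  ks <- seq_len(n - 1L)
  costs <- block_cost(1L, ks) + block_cost(ks + 1L, n)
  k <- which.min(costs)
  m_lo <- stats::median(xs[1:k])
  m_hi <- stats::median(xs[(k + 1L):n])
  # the upper block always has the (weakly) larger median
  lambda <- (n - k) / n
  assignment <- integer(n)
  assignment[ord] <- rep(c(1L, 2L), c(k, n - k))
  out <- peak_call(sample_id, color_id, "kmedians",
                   mu_high = m_hi, mu_low = m_lo, lambda = lambda,
                   sigma = NA_real_, n_used = n,
                   n_outliers_removed = n_outliers_removed)
  attr(out, "assignment") <- assignment
  out
}
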
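#' Gaussian probability density
#'
#' The normal density `f(x; mu, sigma) = exp(-(x-mu)^2/(2 sigma^2)) /
#' (sqrt(2 pi) sigma)`, the building block of both mixture models. Thin
#' checked wrapper around [stats::dnorm()].
#'
#' @param x Numeric vector of evaluation points.
#' @param mu Mean.
#' @param sigma Standard deviation, strictly positive.
#' @param log Return the log-density instead.
#' @return Numeric vector of densities.
#' @export
gaussian_pdf <- function(x, mu, sigma, log = FALSE) {
  if (!is.finite(sigma) || sigma <= 0)
    stop("'sigma' must be strictly positive", call. = FALSE)
  stats::dnorm(x, mean = mu, sd = sigma, log = log)
}

#' Naive two-component Gaussian mixture deconvolution of one sample
#'
#' Fits the shared-variance two-component mixture
#' `lambda f(x; mu1, sigma) + (1 - lambda) f(x; mu2, sigma)` to the bead
#' intensities of one color in one sample by EM, independently of any
#' other sample. This is the per-sample baseline the aggregate model
#' extends.
#'
#' Initialization is deterministic: the two k-medians cluster medians give
#' the component means, `lambda` starts at 0.5, and `sigma` starts at the
#' pooled within-cluster SD (floored at 1e-3, the same floor applied in
#' every M-step to prevent variance collapse). EM stops when the
#' log-likelihood improves by less than `tol` or after `max_iter`
#' iterations.
#'
#' @param x Numeric vector of bead intensities, length >= 4.
#' @param max_iter Maximum EM iterations.
#' @param tol Absolute log-likelihood convergence tolerance.
#' @param sample_id,color_id Identifiers copied into the result.
#' @param n_outliers_removed Bookkeeping count copied into the result.
#' @return A one-row peak-call data frame with `method = "gmm"`; the
#'   log-likelihood trace is attached as attribute `"loglik_trace"` and
#'   the final log-likelihood as attribute `"loglik"`.
#' @export
gmm_deconv <- function(x, max_iter = 500L, tol = 1e-8,
                       sample_id = "sample", color_id = "color",
                       n_outliers_removed = 0L) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 4L)
    stop("GMM needs at least 4 beads", call. = FALSE)
  km <- kmedians_deconv(x, sample_id, color_id)
  assign <- attr(km, "assignment")
  mu1 <- km$mu_high
  mu2 <- km$mu_low
  dev <- ifelse(assign == 2L, x - mu1, x - mu2)
  sigma <- max(sqrt(mean(dev^2)), 1e-3)
  lambda <- 0.5
  ll_old <- -Inf
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    l1 <- log(lambda) + stats::dnorm(x, mu1, sigma, log = TRUE)
    l2 <- log1p(-lambda) + stats::dnorm(x, mu2, sigma, log = TRUE)
    m <- pmax(l1, l2)
    ls <- m + log(exp(l1 - m) + exp(l2 - m))
    ll <- sum(ls)
    if (!is.finite(ll))
      stop("GMM fit failed: non-finite likelihood", call. = FALSE)
    trace <- c(trace, ll)
    if (ll - ll_old < tol && it > 1L) break
    ll_old <- ll
    r1 <- exp(l1 - ls)
    r2 <- 1 - r1
    s1 <- sum(r1)
    s2 <- n - s1
    mu1 <- sum(r1 * x) / s1
    mu2 <- sum(r2 * x) / s2
    sigma <- max(sqrt(sum(r1 * (x - mu1)^2 + r2 * (x - mu2)^2) / n), 1e-3)
    lambda <- min(max(s1 / n, 1e-6), 1 - 1e-6)
  }
  if (mu1 < mu2) {
    tmp <- mu1; mu1 <- mu2; mu2 <- tmp
    lambda <- 1 - lambda
  }
  lambda <- min(max(lambda, 1e-6), 1 - 1e-6)
  out <- peak_call(sample_id, color_id, "gmm", mu_high = mu1,
                   mu_low = mu2, lambda = lambda, sigma = sigma,
                   n_used = n, n_outliers_removed = n_outliers_removed)
  attr(out, "loglik") <- ll
  attr(out, "loglik_trace") <- trace
  out
}
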
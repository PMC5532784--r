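#' Log-likelihood of the aggregate Gaussian mixture model
#'
#' The AGMM treats the m replicate bead vectors of one color jointly. In
#' each sample i the intensities follow a two-component shared-variance
#' Gaussian mixture whose peaks are written through the midpoint/
#' separation reparametrization `mu1_i = mu_i + delta_i/2`,
#' `mu2_i = mu_i - delta_i/2`. The mixing proportion `lambda` (weight of
#' the higher peak) and the within-peak SD `sigma` are shared across
#' samples, and the box constraint `delta_i >= 0` forces the peak order to
#' be consistent within the color — the mechanism that rules out
#' within-color order flips. The log-likelihood is
#' `sum_i sum_j log( lambda f(x_ij; mu_i + delta_i/2, sigma) +
#' (1 - lambda) f(x_ij; mu_i - delta_i/2, sigma) )`,
#' evaluated with log-sum-exp protection.
#'
#' @param group A [color_group()] (or plain list of numeric vectors, one
#'   per sample).
#' @param mu Numeric vector of per-sample peak midpoints, length m.
#' @param delta Numeric vector of per-sample peak separations, length m,
#'   all >= 0.
#' @param sigma Shared within-peak SD, > 0.
#' @param lambda Shared mixing proportion of the higher peak, in (0, 1).
#' @return The log-likelihood (scalar).
#' @export
agmm_loglik <- function(group, mu, delta, sigma, lambda) {
  xs <- group_intensities(group)
  m <- length(xs)
  if (length(mu) != m || length(delta) != m)
    stop("'mu' and 'delta' must have one entry per sample", call. = FALSE)
  if (any(delta < 0))
    stop("'delta' must be non-negative (sign constraint)", call. = FALSE)
  if (!is.finite(sigma) || sigma <= 0)
    stop("'sigma' must be strictly positive", call. = FALSE)
  if (!is.finite(lambda) || lambda <= 0 || lambda >= 1)
    stop("'lambda' must lie strictly in (0, 1)", call. = FALSE)
  x <- unlist(xs, use.names = FALSE)
  idx <- rep.int(seq_len(m), lengths(xs))
  a <- (mu + delta / 2)[idx]
  b <- (mu - delta / 2)[idx]
  l1 <- log(lambda) + stats::dnorm(x, a, sigma, log = TRUE)
  l2 <- log1p(-lambda) + stats::dnorm(x, b, sigma, log = TRUE)
  mx <- pmax(l1, l2)
  sum(mx + log(exp(l1 - mx) + exp(l2 - mx)))
}

group_intensities <- function(group) {
  if (inherits(group, "color_group"))
    return(lapply(group$samples, `[[`, "intensities"))
  if (is.numeric(group)) return(list(as.numeric(group)))
  if (is.list(group)) return(lapply(group, as.numeric))
  stop("'group' must be a color_group or a list of numeric vectors",
       call. = FALSE)
}

# loglik and analytic gradient in the packed parameter order
# (mu_1..mu_m, delta_1..delta_m, sigma, lambda), for the optimizer
agmm_obj <- function(theta, x, idx, m) {
  mu <- theta[1:m]
  delta <- theta[(m + 1):(2 * m)]
  sigma <- theta[2 * m + 1]
  lambda <- theta[2 * m + 2]
  a <- (mu + delta / 2)[idx]
  b <- (mu - delta / 2)[idx]
  l1 <- log(lambda) + stats::dnorm(x, a, sigma, log = TRUE)
  l2 <- log1p(-lambda) + stats::dnorm(x, b, sigma, log = TRUE)
  mx <- pmax(l1, l2)
  ls <- mx + log(exp(l1 - mx) + exp(l2 - mx))
  r1 <- exp(l1 - ls)
  r2 <- 1 - r1
  za <- (x - a) / sigma^2
  zb <- (x - b) / sigma^2
  gmu_pt <- r1 * za + r2 * zb
  gdelta_pt <- (r1 * za - r2 * zb) / 2
  gsig <- sum(r1 * (za^2 * sigma - 1 / sigma) +
                r2 * (zb^2 * sigma - 1 / sigma))
  glam <- sum(r1 / lambda - r2 / (1 - lambda))
  list(value = sum(ls),
       gradient = c(rowsum_by(gmu_pt, idx, m), rowsum_by(gdelta_pt, idx, m),
                    gsig, glam))
}

rowsum_by <- function(v, idx, m) {
  out <- numeric(m)
  s <- rowsum(v, idx)
  out[as.integer(rownames(s))] <- s
  out
}

#' Fit the aggregate Gaussian mixture model to one color
#'
#' The main fitting function of the package. Given the bead vectors of
#' one color across m replicate samples it (optionally) removes outlier
#' beads per sample with the density-gap detector, then maximizes the
#' AGMM log-likelihood ([agmm_loglik()]) over the per-sample midpoints
#' `mu`, the per-sample separations `delta >= 0`, and the shared `sigma`
#' and `lambda`, using L-BFGS-B with analytic gradients under the box
#' constraints `delta_i >= 0`, `sigma >= 1e-3`,
#' `lambda` in `[0.01, 0.99]`.
#'
#' Initial values come from a deterministic per-sample 2-means step
#' (itself started at the 25th/75th intensity percentiles): the two
#' cluster centers give `mu_i` (midpoint) and `delta_i` (separation),
#' `sigma` starts at the pooled within-cluster SD and `lambda` at the
#' pooled fraction of beads in the upper clusters, clipped to
#' `[0.05, 0.95]`. If the optimizer reports failure, one restart is
#' attempted from a perturbed start (`delta` scaled by 1.05,
#' `lambda = 0.5`).
#'
#' Samples retaining fewer than 4 beads after outlier removal are dropped
#' from the fit and listed in `dropped_samples`; a two-peak model with
#' per-sample means is not identifiable below that.
#'
#' @param group A [color_group()], or a list of numeric bead-intensity
#'   vectors (one per replicate sample).
#' @param outlier_filter Apply density-gap outlier removal first
#'   (default TRUE). Disabling it reproduces the "AGMM without outlier
#'   detection" ablation.
#' @param config An [outlier_config()].
#' @param max_iter Maximum L-BFGS-B iterations.
#' @param factr L-BFGS-B relative convergence tolerance (see
#'   [stats::optim()]).
#' @param single_peak_delta Separations below this (in every sample) flag
#'   the color as effectively single-peaked in diagnostics.
#' @return An object of class `agmm` with components `color_id`,
#'   `sample_ids`, `mu`, `delta`, `sigma`, `lambda`, `loglik`,
#'   `converged`, `n_used`, `n_outliers_removed`, `dropped_samples`,
#'   `single_peak`, the kept intensities (`data`), and the initial
#'   parameter vector (`init`).
#' @seealso [peak_calls()] to extract the per-sample peak table;
#'   [gmm_deconv()] and [kmedians_deconv()] for the per-sample baselines.
#' @export
#' @examples
#' set.seed(1)
#' g <- lapply(1:3, function(i) c(rnorm(40, 8, 0.2), rnorm(20, 6, 0.2)))
#' fit <- agmm(g)
#' fit
#' coef(fit)
agmm <- function(group, outlier_filter = TRUE, config = outlier_config(),
                 max_iter = 500L, factr = 1e7, single_peak_delta = 0.02) {
  xs <- group_intensities(group)
  color_id <- if (inherits(group, "color_group")) group$color_id else "color"
  sample_ids <- if (inherits(group, "color_group"))
    names(group$samples) else sprintf("sample%d", seq_along(xs))

  n_out <- integer(length(xs))
  if (outlier_filter) {
    for (i in seq_along(xs)) {
      oc <- detect_outliers(xs[[i]], config)
      n_out[i] <- length(oc$outliers)
      xs[[i]] <- xs[[i]][oc$kept]
    }
  }
  usable <- lengths(xs) >= 4L
  if (!any(usable))
    stop("AGMM fit for color '", color_id,
         "': no sample retains >= 4 beads", call. = FALSE)
  dropped <- sample_ids[!usable]
  xs_fit <- xs[usable]
  ids_fit <- sample_ids[usable]
  n_out_fit <- n_out[usable]
  m <- length(xs_fit)

  init <- agmm_init(xs_fit)
  x <- unlist(xs_fit, use.names = FALSE)
  idx <- rep.int(seq_len(m), lengths(xs_fit))
  lower <- c(rep(-Inf, m), rep(0, m), 1e-3, 0.01)
  upper <- c(rep(Inf, 2 * m + 1), 0.99)

  run_optim <- function(theta0) {
    # optim() evaluates fn and gr separately at the same point; cache the
    # last objective evaluation so each point is computed once
    last <- list(theta = NULL, obj = NULL)
    eval_obj <- function(th) {
      if (is.null(last$theta) || !identical(th, last$theta))
        last <<- list(theta = th, obj = agmm_obj(th, x, idx, m))
      last$obj
    }
    stats::optim(theta0,
                 fn = function(th) eval_obj(th)$value,
                 gr = function(th) eval_obj(th)$gradient,
                 method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(fnscale = -1, maxit = max_iter,
                                factr = factr))
  }
  opt <- run_optim(init)
  if (opt$convergence != 0) {
    restart <- init
    restart[(m + 1):(2 * m)] <- restart[(m + 1):(2 * m)] * 1.05
    restart[2 * m + 2] <- 0.5
    opt2 <- run_optim(restart)
    if (opt2$convergence == 0 || opt2$value > opt$value) opt <- opt2
    if (opt$convergence != 0 && !is.finite(opt$value))
      stop("AGMM fit for color '", color_id, "' failed: ", opt$message,
           call. = FALSE)
  }
  theta <- opt$par
  mu <- theta[1:m]
  delta <- theta[(m + 1):(2 * m)]
  structure(list(color_id = color_id, sample_ids = ids_fit,
                 mu = mu, delta = delta,
                 sigma = theta[2 * m + 1], lambda = theta[2 * m + 2],
                 loglik = opt$value, converged = opt$convergence == 0,
                 n_used = lengths(xs_fit),
                 n_outliers_removed = n_out_fit,
                 dropped_samples = dropped,
                 single_peak = all(delta < single_peak_delta),
                 outlier_filter = outlier_filter,
                 data = xs_fit, init = init),
            class = "agmm")
}

# deterministic 2-means per sample (started at the 25th/75th percentiles)
# -> packed initial parameter vector
agmm_init <- function(xs) {
  m <- length(xs)
  mu0 <- delta0 <- numeric(m)
  n_hi <- n_tot <- 0
  ssq <- 0
  for (i in seq_len(m)) {
    x <- xs[[i]]
    cen <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
    if (cen[1] == cen[2]) cen <- cen + c(-1, 1) * 1e-6
    km <- tryCatch(
      stats::kmeans(x, centers = matrix(cen, ncol = 1), iter.max = 50L),
      error = function(e) NULL)
    if (is.null(km) || length(unique(km$cluster)) < 2L) {
      c_lo <- c_hi <- mean(x)
      hi_n <- length(x) / 2
      dev2 <- sum((x - mean(x))^2)
    } else {
      cs <- sort(as.numeric(km$centers))
      c_lo <- cs[1]; c_hi <- cs[2]
      hi_cl <- which.max(km$centers)
      hi_n <- sum(km$cluster == hi_cl)
      fit_mean <- as.numeric(km$centers)[km$cluster]
      dev2 <- sum((x - fit_mean)^2)
    }
    mu0[i] <- (c_hi + c_lo) / 2
    delta0[i] <- c_hi - c_lo
    n_hi <- n_hi + hi_n
    n_tot <- n_tot + length(x)
    ssq <- ssq + dev2
  }
  sigma0 <- max(sqrt(ssq / n_tot), 1e-3)
  lambda0 <- min(max(n_hi / n_tot, 0.05), 0.95)
  c(mu0, delta0, sigma0, lambda0)
}

#' Extract per-sample peak calls
#'
#' @param fit A fitted object.
#' @param ... Passed to methods.
#' @return A peak-call data frame, one row per sample.
#' @export
peak_calls <- function(fit, ...) UseMethod("peak_calls")

#' @rdname peak_calls
#' @export
peak_calls.agmm <- function(fit, ...) {
  rows <- lapply(seq_along(fit$sample_ids), function(i)
    peak_call(fit$sample_ids[i], fit$color_id, "agmm",
              mu_high = fit$mu[i] + fit$delta[i] / 2,
              mu_low = fit$mu[i] - fit$delta[i] / 2,
              lambda = fit$lambda, sigma = fit$sigma,
              n_used = fit$n_used[i],
              n_outliers_removed = fit$n_outliers_removed[i]))
  do.call(rbind, rows)
}

#' @export
print.agmm <- function(x, ...) {
  cat(sprintf("Aggregate Gaussian mixture fit: color '%s', %d sample(s)\n",
              x$color_id, length(x$sample_ids)))
  cat(sprintf("  shared sigma = %.4f, lambda = %.4f, logLik = %.2f%s\n",
              x$sigma, x$lambda, x$loglik,
              if (x$converged) "" else " (NOT converged)"))
  cat(sprintf("  mean separation delta = %.4f%s\n", mean(x$delta),
              if (x$single_peak) " [flagged single-peak]" else ""))
  if (length(x$dropped_samples))
    cat("  dropped samples:", paste(x$dropped_samples, collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
summary.agmm <- function(object, ...) {
  out <- peak_calls(object)
  out$n_beads <- object$n_used
  structure(list(fit = object, peaks = out), class = "summary.agmm")
}

#' @export
print.summary.agmm <- function(x, ...) {
  print(x$fit)
  cat("\nPer-sample peaks:\n")
  print(x$peaks[, c("sample_id", "mu_high", "mu_low", "n_used",
                    "n_outliers_removed")], row.names = FALSE)
  invisible(x)
}

#' @export
coef.agmm <- function(object, ...) {
  c(stats::setNames(object$mu, paste0("mu.", object$sample_ids)),
    stats::setNames(object$delta, paste0("delta.", object$sample_ids)),
    sigma = object$sigma, lambda = object$lambda)
}

#' @export
logLik.agmm <- function(object, ...) {
  val <- object$loglik
  attr(val, "df") <- 2 * length(object$mu) + 2
  attr(val, "nobs") <- sum(object$n_used)
  class(val) <- "logLik"
  val
}

#' Posterior component membership for an AGMM fit
#'
#' @param object An `agmm` fit.
#' @param newdata Optional list of numeric vectors (one per fitted
#'   sample); defaults to the beads the model was fitted on.
#' @param type `"class"` for hard labels (`"high"`/`"low"`) or `"prob"`
#'   for the posterior probability of the high peak.
#' @param ... Ignored.
#' @return A list (one element per sample) of labels or probabilities.
#' @export
predict.agmm <- function(object, newdata = NULL,
                         type = c("class", "prob"), ...) {
  type <- match.arg(type)
  xs <- if (is.null(newdata)) object$data else group_intensities(newdata)
  if (length(xs) != length(object$mu))
    stop("'newdata' must supply one vector per fitted sample",
         call. = FALSE)
  out <- lapply(seq_along(xs), function(i) {
    x <- xs[[i]]
    l1 <- log(object$lambda) +
      stats::dnorm(x, object$mu[i] + object$delta[i] / 2, object$sigma,
                   log = TRUE)
    l2 <- log1p(-object$lambda) +
      stats::dnorm(x, object$mu[i] - object$delta[i] / 2, object$sigma,
                   log = TRUE)
    p <- 1 / (1 + exp(l2 - l1))
    if (type == "prob") p else ifelse(p >= 0.5, "high", "low")
  })
  names(out) <- object$sample_ids
  out
}

#' @export
fitted.agmm <- function(object, ...) {
  cls <- predict(object, type = "class")
  out <- lapply(seq_along(cls), function(i)
    ifelse(cls[[i]] == "high", object$mu[i] + object$delta[i] / 2,
           object$mu[i] - object$delta[i] / 2))
  names(out) <- object$sample_ids
  out
}

#' @export
residuals.agmm <- function(object, ...) {
  f <- fitted(object)
  out <- lapply(seq_along(f), function(i) object$data[[i]] - f[[i]])
  names(out) <- object$sample_ids
  out
}

#' Simulate bead intensities from a fitted AGMM
#'
#' @param object An `agmm` fit.
#' @param nsim Number of replicate datasets.
#' @param seed Optional integer seed.
#' @param ... Ignored.
#' @return A list of `nsim` datasets, each a list of per-sample numeric
#'   vectors with the fitted bead counts.
#' @export
simulate.agmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  replicate(nsim, simplify = FALSE, {
    out <- lapply(seq_along(object$mu), function(i) {
      n <- object$n_used[i]
      hi <- stats::rbinom(1, n, object$lambda)
      x <- c(stats::rnorm(hi, object$mu[i] + object$delta[i] / 2,
                          object$sigma),
             stats::rnorm(n - hi, object$mu[i] - object$delta[i] / 2,
                          object$sigma))
      sample(x)
    })
    names(out) <- object$sample_ids
    out
  })
}

#' Plot an AGMM fit over the bead-intensity histograms
#'
#' Draws, for each fitted sample, the kept-bead histogram with the fitted
#' mixture density and the two peak locations.
#'
#' @param x An `agmm` fit.
#' @param samples Indices or names of samples to draw (default: up to 9).
#' @param breaks Histogram breaks (passed to [graphics::hist()]).
#' @param ... Further arguments passed to [graphics::hist()].
#' @return Invisibly, `x`.
#' @export
plot.agmm <- function(x, samples = NULL, breaks = 20, ...) {
  idx <- seq_along(x$sample_ids)
  if (!is.null(samples))
    idx <- if (is.character(samples)) match(samples, x$sample_ids)
      else samples
  idx <- idx[seq_len(min(length(idx), 9L))]
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(idx)))
  on.exit(graphics::par(old))
  for (i in idx) {
    xi <- x$data[[i]]
    h <- graphics::hist(xi, breaks = breaks, freq = FALSE,
                        main = paste(x$color_id, x$sample_ids[i]),
                        xlab = "intensity", ...)
    gx <- seq(min(xi) - 3 * x$sigma, max(xi) + 3 * x$sigma,
              length.out = 256)
    gy <- x$lambda *
      stats::dnorm(gx, x$mu[i] + x$delta[i] / 2, x$sigma) +
      (1 - x$lambda) *
      stats::dnorm(gx, x$mu[i] - x$delta[i] / 2, x$sigma)
    graphics::lines(gx, gy, col = "red", lwd = 2)
    graphics::abline(v = x$mu[i] + c(-0.5, 0.5) * x$delta[i],
                     col = "red", lty = 2)
  }
  invisible(x)
}
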
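#' Pair predicted peaks with ground truth by rank
#'
#' Joins a peak-call table to a truth table on (color_id, sample_id) and
#' unrolls each match into two rows: the predicted `mu_high` paired with
#' `true_mu_high` and the predicted `mu_low` with `true_mu_low`. Pairing
#' by rank means a flipped prediction (the two peaks swapped relative to
#' truth) shows up as two large errors rather than being silently
#' re-matched.
#'
#' @param truth Truth data frame (`color_id`, `sample_id`,
#'   `true_mu_high`, `true_mu_low`).
#' @param calls Peak-call data frame.
#' @return A data frame of class `paired_peaks` with columns `color_id`,
#'   `sample_id`, `method`, `peak_rank` (`"high"`/`"low"`),
#'   `true_value`, `predicted_value`.
#' @export
pair_predictions <- function(truth, calls) {
  validate_peak_calls(calls)
  key_t <- paste(truth$color_id, truth$sample_id, sep = "\r")
  key_c <- paste(calls$color_id, calls$sample_id, sep = "\r")
  hit <- match(key_c, key_t)
  if (anyNA(hit)) {
    miss <- unique(paste0("(", calls$color_id, ", ", calls$sample_id,
                          ")")[is.na(hit)])
    stop("peak calls without a truth row: ",
         paste(utils::head(miss, 5L), collapse = ", "),
         if (length(miss) > 5L) ", ..." else "", call. = FALSE)
  }
  n <- nrow(calls)
  out <- data.frame(
    color_id = rep(calls$color_id, each = 2L),
    sample_id = rep(calls$sample_id, each = 2L),
    method = rep(calls$method, each = 2L),
    peak_rank = rep(c("high", "low"), n),
    true_value = as.vector(rbind(truth$true_mu_high[hit],
                                 truth$true_mu_low[hit])),
    predicted_value = as.vector(rbind(calls$mu_high, calls$mu_low)),
    stringsAsFactors = FALSE)
  class(out) <- c("paired_peaks", "data.frame")
  out
}

#' Pearson correlation between two vectors
#'
#' Checked wrapper around [stats::cor()]: requires at least 3 paired
#' observations and non-degenerate variance on both sides.
#'
#' @param a,b Numeric vectors of equal length >= 3.
#' @return The Pearson product-moment correlation.
#' @export
pcc <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b) || length(a) < 3L)
    stop("'a' and 'b' must have equal length >= 3", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  stats::cor(a, b)
}

#' Williams's test for two dependent correlations sharing a variable
#'
#' Tests whether `r13 = cor(truth, method A)` differs from
#' `r23 = cor(truth, method B)` when both correlations are computed on
#' the same n observations and the two methods correlate `r12` with each
#' other. The statistic is
#' \deqn{t = (r13 - r23) \sqrt{\frac{(n-1)(1+r12)}
#'   {2K(n-1)/(n-3) + \bar r^2 (1-r12)^3}}}
#' with `K = 1 - r12^2 - r13^2 - r23^2 + 2 r12 r13 r23` (the determinant
#' of the 3x3 correlation matrix) and `rbar = (r13 + r23)/2`, referred to
#' a Student t distribution on `n - 3` degrees of freedom (two-sided).
#'
#' @param r13,r23 Correlations of the shared variable with methods A and
#'   B.
#' @param r12 Correlation between the two methods.
#' @param n Number of paired observations, >= 4.
#' @return A list with `t`, `p` and `df`.
#' @export
#' @examples
#' williams_test(0.97, 0.89, 0.85, 10000)
williams_test <- function(r13, r23, r12, n) {
  n <- as.integer(n)
  if (is.na(n) || n < 4L)
    stop("'n' must be an integer >= 4", call. = FALSE)
  rs <- c(r13 = r13, r23 = r23, r12 = r12)
  if (any(!is.finite(rs)) || any(abs(rs) >= 1))
    stop("correlations must lie strictly in (-1, 1)", call. = FALSE)
  K <- 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23
  if (K <= 0)
    stop("inconsistent correlation matrix (determinant <= 0)",
         call. = FALSE)
  rbar <- (r13 + r23) / 2
  t <- (r13 - r23) *
    sqrt((n - 1) * (1 + r12) /
           (2 * K * (n - 1) / (n - 3) + rbar^2 * (1 - r12)^3))
  p <- 2 * stats::pt(abs(t), df = n - 3, lower.tail = FALSE)
  list(t = t, p = p, df = n - 3L)
}

#' Count true predictions
#'
#' A true prediction is a predicted peak whose absolute difference from
#' its true value is strictly less than `thr` (0.05 by default, on the
#' analysis intensity scale).
#'
#' @param paired A [pair_predictions()] table.
#' @param thr Threshold (strict inequality).
#' @return Integer count.
#' @export
true_predictions <- function(paired, thr = 0.05) {
  stopifnot(nrow(paired) > 0L)
  sum(abs(paired$predicted_value - paired$true_value) < thr)
}

#' Mean absolute error of paired peak predictions
#'
#' @param paired A [pair_predictions()] table.
#' @return Mean of `|predicted - true|` over all rows.
#' @export
mean_absolute_error <- function(paired) {
  stopifnot(nrow(paired) > 0L)
  mean(abs(paired$predicted_value - paired$true_value))
}

#' Count peak-order flips per color
#'
#' A flip is a deconvolution error in which the two genes' peaks are
#' assigned in the wrong order relative to truth. Gene identity of a
#' prediction is taken from the mixing proportion: the component carrying
#' the majority of the beads (`lambda >= 0.5` means the higher predicted
#' peak) is the majority gene, which in the 2:1 bead design identifies a
#' gene a priori. A sample is flipped when the majority gene's predicted
#' mean lies strictly on the opposite side of the minority gene's
#' predicted mean relative to the truth ordering.
#'
#' @param calls Peak-call data frame (must carry `lambda`).
#' @param truth Truth data frame.
#' @param majority_gene Which gene carries the 2:1 bead majority in
#'   truth: `"high"` (the higher-expressed gene, the simulator's
#'   convention) or `"low"`.
#' @return Named integer vector: flips per color, over that color's
#'   samples.
#' @export
count_flips <- function(calls, truth, majority_gene = c("high", "low")) {
  majority_gene <- match.arg(majority_gene)
  validate_peak_calls(calls)
  key_t <- paste(truth$color_id, truth$sample_id, sep = "\r")
  key_c <- paste(calls$color_id, calls$sample_id, sep = "\r")
  hit <- match(key_c, key_t)
  if (anyNA(hit))
    stop("peak calls without a truth row; cannot count flips",
         call. = FALSE)
  sep_true <- truth$true_mu_high[hit] - truth$true_mu_low[hit]
  # predicted majority-minus-minority mean difference
  d_pred <- ifelse(calls$lambda >= 0.5, 1, -1) *
    (calls$mu_high - calls$mu_low)
  d_true <- if (majority_gene == "high") sep_true else -sep_true
  flipped <- sign(d_pred) * sign(d_true) < 0
  counts <- tapply(flipped, calls$color_id, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Benchmark the deconvolution methods on a simulated dataset
#'
#' Runs each requested method over every color of a simulated dataset and
#' computes the full comparison: pooled Pearson correlation between true
#' and predicted peaks, number of true predictions, mean absolute error,
#' per-color flip counts, and pairwise Williams tests of the pooled
#' correlations against the reference method (the last one listed,
#' AGMM-with-filter by default). `"agmm_nofilter"` denotes the ablation
#' that skips outlier removal.
#'
#' @param dataset A [simulate_dataset()] result.
#' @param methods Character vector drawn from `"kmedians"`, `"gmm"`,
#'   `"agmm_nofilter"`, `"agmm"`.
#' @param config An [outlier_config()].
#' @param thr True-prediction threshold.
#' @return An object of class `benchmark_report`: per-method metrics
#'   (`$methods`), Williams tests (`$williams`), the simulation
#'   parameters (`$params`) and seed, and per-method paired tables
#'   (`$paired`).
#' @export
benchmark <- function(dataset,
                      methods = c("kmedians", "gmm", "agmm_nofilter",
                                  "agmm"),
                      config = outlier_config(), thr = 0.05) {
  stopifnot(inherits(dataset, "sim_dataset"))
  methods <- match.arg(methods, several.ok = TRUE)
  paired <- list()
  metrics <- list()
  for (meth in methods) {
    base <- if (meth == "agmm_nofilter") "agmm" else meth
    filt <- switch(meth, kmedians = FALSE, gmm = FALSE,
                   agmm_nofilter = FALSE, agmm = TRUE)
    calls <- suppressWarnings(
      deconv_beads(dataset$beads, base, config, outlier_filter = filt))
    pp <- pair_predictions(dataset$truth, calls)
    metrics[[meth]] <- list(
      pcc = pcc(pp$true_value, pp$predicted_value),
      n_true_predictions = true_predictions(pp, thr),
      mean_absolute_error = mean_absolute_error(pp),
      flips_per_color = count_flips(calls, dataset$truth),
      n_failed_colors = attr(calls, "n_failed_colors"))
    paired[[meth]] <- pp
  }
  ref <- methods[length(methods)]
  williams <- NULL
  if (length(methods) > 1L) {
    rows <- lapply(setdiff(methods, ref), function(meth) {
      key_r <- paste(paired[[ref]]$color_id, paired[[ref]]$sample_id,
                     paired[[ref]]$peak_rank, sep = "\r")
      key_m <- paste(paired[[meth]]$color_id, paired[[meth]]$sample_id,
                     paired[[meth]]$peak_rank, sep = "\r")
      common <- intersect(key_r, key_m)
      ir <- match(common, key_r); im <- match(common, key_m)
      tv <- paired[[ref]]$true_value[ir]
      wt <- williams_test(
        r13 = pcc(tv, paired[[ref]]$predicted_value[ir]),
        r23 = pcc(tv, paired[[meth]]$predicted_value[im]),
        r12 = pcc(paired[[ref]]$predicted_value[ir],
                  paired[[meth]]$predicted_value[im]),
        n = length(common))
      data.frame(reference = ref, method = meth, t = wt$t, p = wt$p,
                 df = wt$df, n = length(common),
                 stringsAsFactors = FALSE)
    })
    williams <- do.call(rbind, rows)
  }
  structure(list(methods = metrics, williams = williams,
                 params = dataset$params, seed = dataset$params$seed,
                 thr = thr, paired = paired),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("Deconvolution benchmark (seed %d, %d colors x %d samples)\n\n",
              x$seed, x$params$n_colors, x$params$n_samples))
  tab <- benchmark_table(x)
  print(tab, row.names = FALSE, digits = 4)
  if (!is.null(x$williams)) {
    cat(sprintf("\nWilliams tests vs '%s':\n", x$williams$reference[1]))
    print(x$williams[, c("method", "t", "df", "p")], row.names = FALSE,
          digits = 4)
  }
  invisible(x)
}

#' Tabulate a benchmark report
#'
#' @param report A `benchmark_report`.
#' @return Data frame with one row per method: pooled PCC, true
#'   predictions, MAE, total flips.
#' @export
benchmark_table <- function(report) {
  rows <- lapply(names(report$methods), function(meth) {
    m <- report$methods[[meth]]
    data.frame(method = meth, pcc = m$pcc,
               n_true_predictions = m$n_true_predictions,
               mean_absolute_error = m$mean_absolute_error,
               total_flips = sum(m$flips_per_color),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
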
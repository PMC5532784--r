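#' Deconvolve one color group with a chosen method
#'
#' Runs one of the three peak callers on the m replicate bead vectors of a
#' color. `kmedians` and `gmm` are fitted independently per sample; `agmm`
#' is fitted jointly across the samples (a single shared `sigma` and
#' `lambda`). When `outlier_filter` is TRUE the density-gap detector is
#' applied per sample first and only kept beads enter the fit; every
#' returned row records `n_used` and `n_outliers_removed`. Running
#' `method = "agmm"` with `outlier_filter = FALSE` is the
#' AGMM-without-outlier-detection ablation.
#'
#' For the per-sample methods, a sample left with fewer than 4 beads (or
#' fewer than 2 distinct values) is skipped with a warning rather than
#' fitted.
#'
#' @param group A [color_group()].
#' @param method `"kmedians"`, `"gmm"` or `"agmm"`.
#' @param config An [outlier_config()].
#' @param outlier_filter Apply outlier removal before fitting.
#' @param ... Passed on to the underlying fitter ([agmm()] or
#'   [gmm_deconv()]).
#' @return A peak-call data frame with one row per (fitted) sample.
#' @export
deconv_group <- function(group, method = c("agmm", "gmm", "kmedians"),
                         config = outlier_config(), outlier_filter = TRUE,
                         ...) {
  method <- match.arg(method)
  stopifnot(inherits(group, "color_group"))
  if (method == "agmm") {
    fit <- agmm(group, outlier_filter = outlier_filter, config = config,
                ...)
    return(peak_calls(fit))
  }
  rows <- list()
  for (s in group$samples) {
    x <- s$intensities
    n_rm <- 0L
    if (outlier_filter) {
      oc <- detect_outliers(x, config)
      n_rm <- length(oc$outliers)
      x <- x[oc$kept]
    }
    if (length(x) < 4L || length(unique(x)) < 2L) {
      warning("skipping color '", group$color_id, "' sample '",
              s$sample_id, "': too few usable beads", call. = FALSE)
      next
    }
    row <- tryCatch(
      if (method == "kmedians")
        kmedians_deconv(x, s$sample_id, group$color_id, n_rm)
      else gmm_deconv(x, sample_id = s$sample_id,
                      color_id = group$color_id,
                      n_outliers_removed = n_rm, ...),
      error = function(e)
        stop("deconvolution failed for color '", group$color_id,
             "' sample '", s$sample_id, "': ", conditionMessage(e),
             call. = FALSE))
    attributes(row)[c("assignment", "loglik", "loglik_trace")] <- NULL
    rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows))
    stop("no sample of color '", group$color_id, "' could be fitted",
         call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Deconvolve every color of a bead dataset
#'
#' Applies [deconv_group()] to each color group, collecting all peak
#' calls. Colors whose fit fails are dropped with a warning and counted
#' in the `"n_failed_colors"` attribute.
#'
#' @param groups A list of [color_group()] objects (e.g. from
#'   [read_beads()] or [simulate_dataset()]).
#' @param method,config,outlier_filter,... See [deconv_group()].
#' @return A peak-call data frame covering all successfully fitted colors.
#' @export
deconv_beads <- function(groups, method = c("agmm", "gmm", "kmedians"),
                         config = outlier_config(), outlier_filter = TRUE,
                         ...) {
  method <- match.arg(method)
  res <- vector("list", length(groups))
  failed <- 0L
  for (k in seq_along(groups)) {
    res[[k]] <- tryCatch(
      deconv_group(groups[[k]], method, config, outlier_filter, ...),
      error = function(e) {
        warning(conditionMessage(e), call. = FALSE)
        failed <<- failed + 1L
        NULL
      })
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    stop("every color failed to deconvolve", call. = FALSE)
  rownames(out) <- NULL
  attr(out, "n_failed_colors") <- failed
  out
}
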
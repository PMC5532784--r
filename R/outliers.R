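#' Kernel density estimate of bead intensities
#'
#' Gaussian-kernel KDE with the rule-of-thumb bandwidth
#' h = 0.9 min(sd, IQR/1.34) n^(-1/5), evaluated on `grid_size` equally
#' spaced points spanning `[min(x) - 3h, max(x) + 3h]` and renormalized to
#' integrate (trapezoidal rule) to exactly 1. This is the density the gap
#' detector scans for data-free regions.
#'
#' @param x Numeric vector, length >= 2, not all values identical.
#' @param config An [outlier_config()].
#' @return A list of class `density_curve` with elements `grid`,
#'   `density` and `bw`.
#' @export
estimate_density <- function(x, config = outlier_config()) {
  x <- as.numeric(x)
  if (length(x) < 2L || !all(is.finite(x)))
    stop("density estimation needs >= 2 finite intensities", call. = FALSE)
  if (max(x) == min(x))
    stop("density estimation needs non-zero spread", call. = FALSE)
  bw <- stats::bw.nrd0(x)
  d <- stats::density(x, bw = bw, kernel = "gaussian",
                      n = config$grid_size, cut = 3)
  auc <- trapz(d$x, d$y)
  structure(list(grid = d$x, density = d$y / auc, bw = bw),
            class = "density_curve")
}

trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1L] - x[-n]) * (y[-1L] + y[-n])) / 2
}

#' Split intensities at data-free density gaps
#'
#' Maximal runs of consecutive grid points whose estimated density falls
#' below `dy_thr` are declared data-free gaps; beads are assigned to the
#' same cluster exactly when no gap interval lies strictly between them.
#' With no gap, a single cluster holds every bead.
#'
#' @param x The intensities the curve was computed from.
#' @param curve A `density_curve` from [estimate_density()].
#' @param dy_thr Density threshold defining a gap.
#' @return A list of class `cluster_split` with `clusters` (list of index
#'   vectors into `x`, ordered by minimum intensity) and `gap_intervals`
#'   (two-column matrix of gap bounds, possibly zero rows).
#' @export
split_by_gaps <- function(x, curve, dy_thr = 1e-4) {
  stopifnot(inherits(curve, "density_curve"))
  x <- as.numeric(x)
  low <- curve$density < dy_thr
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  gap_lo <- curve$grid[starts[r$values]]
  gap_hi <- curve$grid[ends[r$values]]
  gaps <- cbind(lo = gap_lo, hi = gap_hi)
  # cluster id of a bead = number of gaps lying entirely below it; a bead
  # sitting inside a gap (possible only at extreme thresholds) joins the
  # cluster on its left
  cid <- vapply(x, function(p) sum(gap_hi <= p), integer(1))
  ids <- sort(unique(cid))
  clusters <- lapply(ids, function(k) which(cid == k))
  # drop empty gap-separated ranges and order clusters by min intensity
  ord <- order(vapply(clusters, function(ix) min(x[ix]), numeric(1)))
  structure(list(clusters = clusters[ord], gap_intervals = gaps),
            class = "cluster_split")
}

#' Detect outlier beads by density gaps
#'
#' Applies the density-gap rule per sample per color: estimate the kernel
#' density of the bead intensities, declare regions with density below
#' `dy_thr` data-free gaps, split the beads into gap-separated clusters,
#' and flag every cluster smaller than `clustersize_thr` beads as
#' outliers. If every cluster falls below the size threshold, the largest
#' cluster is retained so that downstream fitting always has data.
#' Degenerate input (fewer than 2 beads, or zero spread) skips detection
#' and keeps everything, with `degenerate = TRUE`.
#'
#' @param x Numeric vector of bead intensities.
#' @param config An [outlier_config()].
#' @return A list of class `outlier_call`: `kept` and `outliers` (disjoint
#'   index vectors whose union is `seq_along(x)`), `clusters`, and a
#'   `degenerate` flag.
#' @export
#' @examples
#' x <- c(rnorm(40, 8, 0.2), rnorm(20, 6, 0.2), 30)
#' detect_outliers(x)$outliers   # the stray bead at 30
detect_outliers <- function(x, config = outlier_config()) {
  x <- as.numeric(x)
  idx <- seq_along(x)
  if (length(x) < 2L || max(x) == min(x)) {
    return(structure(list(kept = idx, outliers = integer(0),
                          clusters = list(idx), degenerate = TRUE),
                     class = "outlier_call"))
  }
  curve <- estimate_density(x, config)
  split <- split_by_gaps(x, curve, config$dy_thr)
  sizes <- lengths(split$clusters)
  small <- sizes < config$clustersize_thr
  if (all(small)) {
    keep_cl <- which.max(sizes)   # never return an empty kept set
    small <- rep(TRUE, length(sizes))
    small[keep_cl] <- FALSE
  }
  outliers <- sort(unlist(split$clusters[small], use.names = FALSE))
  if (is.null(outliers)) outliers <- integer(0)
  kept <- setdiff(idx, outliers)
  structure(list(kept = kept, outliers = outliers,
                 clusters = split$clusters, degenerate = FALSE),
            class = "outlier_call")
}
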
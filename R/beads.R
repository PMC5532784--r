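#' Construct a bead vector
#'
#' A bead vector holds the fluorescence intensities of all beads of one
#' color (analyte channel) measured in one sample. Intensities are taken
#' as-is on whatever scale the caller supplies (typically log scale); the
#' package never transforms them.
#'
#' @param sample_id Sample identifier (scalar character).
#' @param color_id Color/analyte identifier (scalar character).
#' @param intensities Numeric vector of bead intensities, all finite,
#'   length at least 1.
#' @return An object of class `bead_vector`: a list with elements
#'   `sample_id`, `color_id` and `intensities`.
#' @export
#' @examples
#' bead_vector("s01", "c001", c(6.4, 6.5, 7.9))
bead_vector <- function(sample_id, color_id, intensities) {
  sample_id <- as.character(sample_id)
  color_id <- as.character(color_id)
  intensities <- as.numeric(intensities)
  if (length(sample_id) != 1L || is.na(sample_id))
    stop("'sample_id' must be a single non-missing string", call. = FALSE)
  if (length(color_id) != 1L || is.na(color_id))
    stop("'color_id' must be a single non-missing string", call. = FALSE)
  if (length(intensities) < 1L)
    stop("a bead vector needs at least one intensity", call. = FALSE)
  if (!all(is.finite(intensities)))
    stop("all bead intensities must be finite", call. = FALSE)
  structure(
    list(sample_id = sample_id, color_id = color_id,
         intensities = intensities),
    class = "bead_vector"
  )
}

#' Construct a color group
#'
#' A color group collects the bead vectors of one color across the m
#' replicate samples of a condition. It is the unit the aggregate Gaussian
#' mixture model is fitted on.
#'
#' @param color_id Color identifier shared by all members.
#' @param samples List of [bead_vector()] objects, all with this
#'   `color_id` and pairwise-distinct `sample_id`s.
#' @return An object of class `color_group`.
#' @export
color_group <- function(color_id, samples) {
  color_id <- as.character(color_id)
  if (length(samples) < 1L)
    stop("a color group needs at least one sample", call. = FALSE)
  if (!all(vapply(samples, inherits, logical(1), "bead_vector")))
    stop("'samples' must be a list of bead_vector objects", call. = FALSE)
  ids <- vapply(samples, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids))
    stop("sample_ids within a color group must be distinct", call. = FALSE)
  cols <- vapply(samples, `[[`, character(1), "color_id")
  if (!all(cols == color_id))
    stop("all members of a color group must share its color_id",
         call. = FALSE)
  names(samples) <- ids
  structure(list(color_id = color_id, samples = samples),
            class = "color_group")
}

#' @export
print.color_group <- function(x, ...) {
  n <- vapply(x$samples, function(s) length(s$intensities), integer(1))
  cat(sprintf("Color group '%s': %d sample(s), %s beads\n",
              x$color_id, length(x$samples),
              paste(n, collapse = "/")))
  invisible(x)
}

#' Outlier-detection configuration
#'
#' Bundles the tuning parameters of the density-gap outlier detector.
#' `dy_thr` is the kernel-density level below which a region of the
#' intensity axis is declared a data-free gap; `clustersize_thr` is the
#' minimum number of beads a gap-separated cluster must contain to be
#' kept, smaller clusters being flagged as outliers.
#'
#' @param dy_thr Density threshold, positive (default 1e-4).
#' @param clustersize_thr Minimum cluster size, integer >= 1 (default 3).
#' @param grid_size Number of KDE grid points, integer >= 64 (default 512).
#' @param bandwidth_rule Bandwidth selector; only `"rule-of-thumb"`
#'   (0.9 min(sd, IQR/1.34) n^-1/5) is available.
#' @return An object of class `outlier_config`.
#' @export
outlier_config <- function(dy_thr = 1e-4, clustersize_thr = 3L,
                           grid_size = 512L,
                           bandwidth_rule = "rule-of-thumb") {
  if (!is.numeric(dy_thr) || length(dy_thr) != 1L || dy_thr <= 0)
    stop("'dy_thr' must be a single positive number", call. = FALSE)
  clustersize_thr <- as.integer(clustersize_thr)
  if (is.na(clustersize_thr) || clustersize_thr < 1L)
    stop("'clustersize_thr' must be an integer >= 1", call. = FALSE)
  grid_size <- as.integer(grid_size)
  if (is.na(grid_size) || grid_size < 64L)
    stop("'grid_size' must be an integer >= 64", call. = FALSE)
  bandwidth_rule <- match.arg(bandwidth_rule, "rule-of-thumb")
  structure(list(dy_thr = dy_thr, clustersize_thr = clustersize_thr,
                 grid_size = grid_size, bandwidth_rule = bandwidth_rule),
            class = "outlier_config")
}

peak_call_columns <- c("sample_id", "color_id", "method", "mu_high",
                       "mu_low", "lambda", "sigma", "n_used",
                       "n_outliers_removed")

#' Assemble a peak-call table row
#'
#' One row of the package's peak-call table: the deconvolution result for
#' one color in one sample. `mu_high`/`mu_low` are the two peak means
#' sorted so that `mu_high >= mu_low`; `lambda` is the estimated
#' proportion of beads belonging to the higher peak; `sigma` is the shared
#' within-peak standard deviation (NA for k-medians, which estimates no
#' spread).
#'
#' @param sample_id,color_id Identifiers.
#' @param method One of `"kmedians"`, `"gmm"`, `"agmm"`.
#' @param mu_high,mu_low Peak means, `mu_high >= mu_low`.
#' @param lambda Mixing proportion of the higher peak, in (0, 1) for the
#'   mixture methods.
#' @param sigma Shared within-peak SD (> 0), or NA for k-medians.
#' @param n_used Number of beads used in the fit.
#' @param n_outliers_removed Number of beads removed as outliers.
#' @return A one-row data frame with the standard peak-call columns.
#' @export
peak_call <- function(sample_id, color_id, method, mu_high, mu_low,
                      lambda, sigma = NA_real_, n_used,
                      n_outliers_removed = 0L) {
  method <- match.arg(method, c("kmedians", "gmm", "agmm"))
  if (!is.finite(mu_high) || !is.finite(mu_low) || mu_high < mu_low)
    stop("peak means must be finite with mu_high >= mu_low", call. = FALSE)
  if (method != "kmedians" && (!is.finite(lambda) || lambda <= 0 || lambda >= 1))
    stop("'lambda' must lie strictly in (0, 1)", call. = FALSE)
  if (!is.na(sigma) && sigma <= 0)
    stop("'sigma' must be positive when present", call. = FALSE)
  data.frame(sample_id = as.character(sample_id),
             color_id = as.character(color_id),
             method = method, mu_high = mu_high, mu_low = mu_low,
             lambda = lambda, sigma = sigma,
             n_used = as.integer(n_used),
             n_outliers_removed = as.integer(n_outliers_removed),
             stringsAsFactors = FALSE)
}

validate_peak_calls <- function(calls) {
  if (!is.data.frame(calls) || nrow(calls) == 0L)
    stop("'calls' must be a non-empty data frame of peak calls",
         call. = FALSE)
  missing <- setdiff(peak_call_columns, names(calls))
  if (length(missing))
    stop("peak-call table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(calls$mu_high < calls$mu_low))
    stop("invalid peak calls: mu_high < mu_low", call. = FALSE)
  mix <- calls$method != "kmedians"
  if (any(mix & (!is.finite(calls$lambda) | calls$lambda <= 0 |
                   calls$lambda >= 1)))
    stop("invalid peak calls: lambda outside (0, 1)", call. = FALSE)
  invisible(calls)
}

#' Read a bead-level intensity table
#'
#' Reads the package's native long-format bead table: delimited text with
#' a header row and columns `sample_id`, `color_id`, `intensity`, one row
#' per bead. Rows are grouped into one [color_group()] per distinct color;
#' bead order within a sample follows file order.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return A named list of `color_group` objects, one per color.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' df <- data.frame(sample_id = "s1", color_id = "c1",
#'                  intensity = c(6.1, 6.2, 7.9))
#' write_beads(tf, df)
#' groups <- read_beads(tf)
#' groups[["c1"]]
read_beads <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep,
                      colClasses = "character",
                      stringsAsFactors = FALSE, quote = "",
                      comment.char = ""),
    error = function(e) stop("cannot read bead table '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  missing <- setdiff(c("sample_id", "color_id", "intensity"), names(df))
  if (length(missing))
    stop("bead table '", path, "' lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L)
    stop("bead table '", path, "' contains no data rows", call. = FALSE)
  suppressWarnings(x <- as.numeric(df$intensity))
  bad <- which(is.na(x) | !is.finite(x))
  if (length(bad))
    stop("non-numeric or non-finite intensity at data line ", bad[1L],
         " of '", path, "'", call. = FALSE)
  df$intensity <- x
  beads_to_groups(df)
}

#' Convert a long bead table to color groups
#'
#' @param df Data frame with columns `sample_id`, `color_id`, `intensity`.
#' @return Named list of [color_group()] objects keyed by color.
#' @export
beads_to_groups <- function(df) {
  stopifnot(all(c("sample_id", "color_id", "intensity") %in% names(df)))
  # split preserving first-appearance order of colors and samples
  col_levels <- unique(df$color_id)
  out <- lapply(col_levels, function(cid) {
    sub <- df[df$color_id == cid, , drop = FALSE]
    sids <- unique(sub$sample_id)
    bvs <- lapply(sids, function(sid)
      bead_vector(sid, cid, sub$intensity[sub$sample_id == sid]))
    color_group(cid, bvs)
  })
  names(out) <- col_levels
  out
}

#' Flatten color groups back to a long bead table
#'
#' @param groups A `color_group` or list of them.
#' @return Data frame with columns `sample_id`, `color_id`, `intensity`.
#' @export
groups_to_beads <- function(groups) {
  if (inherits(groups, "color_group")) groups <- list(groups)
  parts <- lapply(groups, function(g) {
    do.call(rbind, lapply(g$samples, function(s)
      data.frame(sample_id = s$sample_id, color_id = s$color_id,
                 intensity = s$intensities, stringsAsFactors = FALSE)))
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Write a bead table
#'
#' @param path Output path.
#' @param beads Long data frame (`sample_id`, `color_id`, `intensity`) or
#'   a list of [color_group()] objects.
#' @param dialect `"tsv"` or `"csv"`.
#' @return Invisibly, the path.
#' @export
write_beads <- function(path, beads, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!is.data.frame(beads)) beads <- groups_to_beads(beads)
  stopifnot(all(c("sample_id", "color_id", "intensity") %in% names(beads)))
  sep <- if (dialect == "tsv") "\t" else ","
  df <- beads[, c("sample_id", "color_id", "intensity")]
  df$intensity <- formatC(df$intensity, digits = 10, format = "g")
  tryCatch(
    utils::write.table(df, path, sep = sep, quote = FALSE,
                       row.names = FALSE),
    error = function(e) stop("cannot write bead table '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Write a peak-call table
#'
#' Writes deconvolution results as tab-separated text with the standard
#' peak-call columns; floats carry 10 significant digits so a read-back
#' reproduces the values to well below 1e-6.
#'
#' @param path Output path.
#' @param calls Peak-call data frame (see [peak_call()]).
#' @return Invisibly, the path.
#' @export
write_peaks <- function(path, calls) {
  validate_peak_calls(calls)
  df <- calls[, peak_call_columns]
  for (col in c("mu_high", "mu_low", "lambda", "sigma"))
    df[[col]] <- formatC(df[[col]], digits = 10, format = "g")
  tryCatch(
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE),
    error = function(e) stop("cannot write peak table '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read a peak-call table written by [write_peaks()]
#'
#' @param path Path to the TSV file.
#' @return Peak-call data frame.
#' @export
read_peaks <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(sample_id = "character",
                                         color_id = "character"))
  df$sigma <- suppressWarnings(as.numeric(df$sigma))
  validate_peak_calls(df)
  df
}
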
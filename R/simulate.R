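#' Hyperparameters of the hierarchical bead simulator
#'
#' The simulator emulates the structure of a LINCS L1000 plate: m
#' replicate samples x ~500 colors x ~60 beads per color, two latent
#' expression peaks per color at a 2:1 bead ratio, plus sparse uniform
#' outliers. Per color, the peak separation is drawn from a Gamma
#' distribution and the peak average from a Gaussian, mirroring the
#' empirical distributions of real deconvolved expression values; beads
#' are then drawn from the induced two-component Gaussian mixture and a
#' Poisson-distributed number of uniform outliers is added per sample.
#'
#' Defaults give a typical separation-to-noise ratio around 5
#' (`Gamma(4, 4)` separations, mean 1; bead SD 0.2) with a left tail of
#' barely separated colors, and exactly 40 + 20 beads per color per
#' sample.
#'
#' @param n_samples Number of replicate samples m (default 10).
#' @param n_colors Number of colors (default 500).
#' @param beads_high Beads of the majority (higher-expressed) gene per
#'   sample (default 40).
#' @param beads_low Beads of the minority gene (default 20).
#' @param diff_shape,diff_rate Gamma shape/rate of the peak separation
#'   (defaults 4, 4).
#' @param avg_mean,avg_sd Gaussian mean/SD of the peak average
#'   (defaults 7, 1).
#' @param bead_sd Within-peak bead SD (default 0.2).
#' @param outlier_poisson_mean Poisson mean of the per-sample outlier
#'   count (default 2).
#' @param outlier_margin Widening of the uniform outlier support beyond
#'   the peak range (default 2).
#' @param sample_jitter_sd SD of optional per-sample jitter of the two
#'   peak means (default 0: peaks common to all samples).
#' @param count_jitter Add Poisson jitter to the per-gene bead counts
#'   instead of exact counts (default FALSE).
#' @param seed Integer seed; all randomness derives from it.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n_samples = 10L, n_colors = 500L,
                       beads_high = 40L, beads_low = 20L,
                       diff_shape = 4, diff_rate = 4,
                       avg_mean = 7, avg_sd = 1, bead_sd = 0.2,
                       outlier_poisson_mean = 2, outlier_margin = 2,
                       sample_jitter_sd = 0, count_jitter = FALSE,
                       seed = 1L) {
  p <- list(n_samples = as.integer(n_samples),
            n_colors = as.integer(n_colors),
            beads_high = as.integer(beads_high),
            beads_low = as.integer(beads_low),
            diff_shape = diff_shape, diff_rate = diff_rate,
            avg_mean = avg_mean, avg_sd = avg_sd, bead_sd = bead_sd,
            outlier_poisson_mean = outlier_poisson_mean,
            outlier_margin = outlier_margin,
            sample_jitter_sd = sample_jitter_sd,
            count_jitter = isTRUE(count_jitter),
            seed = as.integer(seed))
  stopifnot(p$n_samples >= 1L, p$n_colors >= 1L, p$beads_high >= 1L,
            p$beads_low >= 1L, p$diff_shape > 0, p$diff_rate > 0,
            p$avg_sd > 0, p$bead_sd > 0, p$outlier_poisson_mean >= 0,
            p$sample_jitter_sd >= 0, !is.na(p$seed))
  structure(p, class = "sim_params")
}

#' Estimate simulator hyperparameters from a peak-call table
#'
#' Method-of-moments fit of the simulator's Gamma/Gaussian layer to real
#' (or simulated) deconvolution results: the Gamma shape and rate are
#' matched to the mean and variance of the peak separations
#' `mu_high - mu_low` (shape = mean^2/var, rate = mean/var), and the
#' Gaussian layer to the sample mean and SD of the peak averages
#' `(mu_high + mu_low)/2`. All other fields keep their defaults.
#'
#' @param peaks A peak-call data frame with at least 10 rows.
#' @param ... Overrides passed through to [sim_params()].
#' @return A `sim_params` object.
#' @export
fit_hyperparams_from_peaks <- function(peaks, ...) {
  validate_peak_calls(peaks)
  if (nrow(peaks) < 10L)
    stop("need at least 10 peak calls to fit hyperparameters",
         call. = FALSE)
  d <- peaks$mu_high - peaks$mu_low
  a <- (peaks$mu_high + peaks$mu_low) / 2
  v <- stats::var(d)
  if (!is.finite(v) || v <= 0)
    stop("peak separations have zero variance; cannot fit a Gamma",
         call. = FALSE)
  sim_params(diff_shape = mean(d)^2 / v, diff_rate = mean(d) / v,
             avg_mean = mean(a), avg_sd = stats::sd(a), ...)
}

# independent RNG substream per color so that changing n_colors never
# perturbs the draws of earlier colors
color_seed <- function(seed, c) {
  (as.numeric(seed) %% 100000 * 10007 + c * 97 + 11) %% 2147483629
}

#' Simulate a bead-level benchmark dataset
#'
#' Draws a full synthetic plate from the hierarchical model described in
#' [sim_params()] and returns both the bead tables and the ground-truth
#' peak table used for scoring. Per color c: separation
#' `diff_c ~ Gamma(diff_shape, diff_rate)` and average
#' `avg_c ~ N(avg_mean, avg_sd^2)` give `mu_high = avg_c + diff_c/2`,
#' `mu_low = avg_c - diff_c/2`; per sample, `beads_high` beads are drawn
#' around `mu_high` and `beads_low` around `mu_low` (SD `bead_sd`), a
#' `Poisson(outlier_poisson_mean)` number of outliers is drawn uniformly
#' on `[mu_low - diff_c - outlier_margin, mu_high + diff_c +
#' outlier_margin]`, and the bead order is shuffled. Each color uses its
#' own RNG substream derived from `seed`, so the dataset is reproducible
#' and adding colors leaves earlier colors unchanged.
#'
#' @param params A [sim_params()] object.
#' @return A list of class `sim_dataset` with `beads` (named list of
#'   [color_group()]s), `truth` (data frame `color_id`, `sample_id`,
#'   `true_mu_high`, `true_mu_low`, `n_outliers_injected`) and `params`.
#' @export
#' @examples
#' d <- simulate_dataset(sim_params(n_colors = 3, seed = 7))
#' d$truth[1:3, ]
simulate_dataset <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  wid <- max(2L, nchar(p$n_colors))
  sids <- sprintf("s%02d", seq_len(p$n_samples))
  groups <- vector("list", p$n_colors)
  truth <- vector("list", p$n_colors)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv))
  for (c in seq_len(p$n_colors)) {
    set.seed(color_seed(p$seed, c))
    cid <- sprintf("c%0*d", wid, c)
    diff_c <- stats::rgamma(1, p$diff_shape, rate = p$diff_rate)
    avg_c <- stats::rnorm(1, p$avg_mean, p$avg_sd)
    hi_c <- avg_c + diff_c / 2
    lo_c <- avg_c - diff_c / 2
    bvs <- vector("list", p$n_samples)
    trows <- vector("list", p$n_samples)
    for (i in seq_len(p$n_samples)) {
      jit <- if (p$sample_jitter_sd > 0)
        stats::rnorm(2, 0, p$sample_jitter_sd) else c(0, 0)
      hi <- hi_c + jit[1]
      lo <- lo_c + jit[2]
      nh <- if (p$count_jitter) stats::rpois(1, p$beads_high)
        else p$beads_high
      nl <- if (p$count_jitter) stats::rpois(1, p$beads_low)
        else p$beads_low
      k <- stats::rpois(1, p$outlier_poisson_mean)
      x <- c(stats::rnorm(nh, hi, p$bead_sd),
             stats::rnorm(nl, lo, p$bead_sd),
             stats::runif(k, lo - diff_c - p$outlier_margin,
                          hi + diff_c + p$outlier_margin))
      bvs[[i]] <- bead_vector(sids[i], cid, sample(x))
      trows[[i]] <- data.frame(color_id = cid, sample_id = sids[i],
                               true_mu_high = hi, true_mu_low = lo,
                               n_outliers_injected = k,
                               stringsAsFactors = FALSE)
    }
    groups[[c]] <- color_group(cid, bvs)
    truth[[c]] <- do.call(rbind, trows)
  }
  names(groups) <- vapply(groups, `[[`, character(1), "color_id")
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  structure(list(beads = groups, truth = truth, params = p),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  p <- x$params
  cat(sprintf(paste0("Simulated bead dataset: %d colors x %d samples, ",
                     "%d+%d beads/color, seed %d\n"),
              p$n_colors, p$n_samples, p$beads_high, p$beads_low, p$seed))
  cat(sprintf("  separation ~ Gamma(%.3g, %.3g), average ~ N(%.3g, %.3g^2), bead SD %.3g, outliers ~ Pois(%.3g)\n",
              p$diff_shape, p$diff_rate, p$avg_mean, p$avg_sd, p$bead_sd,
              p$outlier_poisson_mean))
  invisible(x)
}

#' Write the ground-truth peak table of a simulated dataset
#'
#' @param path Output path (TSV).
#' @param truth The `truth` data frame of a `sim_dataset`.
#' @return Invisibly, the path.
#' @export
write_truth <- function(path, truth) {
  df <- truth
  for (col in c("true_mu_high", "true_mu_low"))
    df[[col]] <- formatC(df[[col]], digits = 10, format = "g")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a ground-truth peak table
#'
#' @param path Path to a TSV written by [write_truth()].
#' @return The truth data frame.
#' @export
read_truth <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c(color_id = "character",
                                   sample_id = "character"))
}
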
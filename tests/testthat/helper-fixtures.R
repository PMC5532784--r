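# Small in-code fixtures shared across test files.

# a color group with well-separated peaks and optional far outliers
make_group <- function(m = 3, n_high = 40, n_low = 20, mu_high = 8,
                       mu_low = 6, sd = 0.2, outliers = numeric(0),
                       color_id = "cX", seed = 42) {
  set.seed(seed)
  bvs <- lapply(seq_len(m), function(i)
    bead_vector(sprintf("s%02d", i), color_id,
                c(rnorm(n_high, mu_high, sd), rnorm(n_low, mu_low, sd),
                  outliers)))
  color_group(color_id, bvs)
}

# long bead data frame for IO tests
make_bead_df <- function(n_colors = 2, n_samples = 2, n_beads = 2,
                         seed = 7) {
  set.seed(seed)
  expand <- expand.grid(bead = seq_len(n_beads),
                        sample_id = sprintf("s%02d", seq_len(n_samples)),
                        color_id = sprintf("c%02d", seq_len(n_colors)),
                        stringsAsFactors = FALSE)
  data.frame(sample_id = expand$sample_id, color_id = expand$color_id,
             intensity = round(rnorm(nrow(expand), 7, 1), 6),
             stringsAsFactors = FALSE)
}

# brute-force two-component shared-sigma mixture log-likelihood,
# independent of the package's vectorized/log-sum-exp code path
brute_loglik <- function(xs, mu1, mu2, sigma, lambda) {
  total <- 0
  for (i in seq_along(xs)) {
    for (x in xs[[i]]) {
      f1 <- exp(-(x - mu1[i])^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
      f2 <- exp(-(x - mu2[i])^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
      total <- total + log(lambda * f1 + (1 - lambda) * f2)
    }
  }
  total
}

# exhaustive optimal 1-D 2-cluster L1 partition over all 2^n - 2
# non-trivial assignments (oracle for the k-medians fitter)
brute_kmedians <- function(x) {
  n <- length(x)
  best <- NULL
  best_cost <- Inf
  for (mask in 1:(2^n - 2)) {
    inA <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    a <- x[inA]; b <- x[!inA]
    cost <- sum(abs(a - median(a))) + sum(abs(b - median(b)))
    if (cost < best_cost - 1e-12) {
      best_cost <- cost
      best <- sort(c(median(a), median(b)), decreasing = TRUE)
    }
  }
  list(mu_high = best[1], mu_low = best[2], cost = best_cost)
}
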
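test_that("agmm_loglik reduces to a single Gaussian when delta = 0", {
  set.seed(41)
  x <- rnorm(30, 7, 0.5)
  single <- sum(dnorm(x, 7, 0.5, log = TRUE))
  for (lam in c(0.1, 0.5, 0.9))
    expect_equal(agmm_loglik(list(x), mu = 7, delta = 0, sigma = 0.5,
                             lambda = lam), single, tolerance = 1e-12)
})

test_that("the midpoint/separation reparametrization is exact", {
  set.seed(42)
  for (rep in 1:20) {
    m <- sample(1:4, 1)
    xs <- lapply(seq_len(m), function(i) rnorm(sample(5:20, 1), 7, 1))
    mu <- rnorm(m, 7, 0.5)
    delta <- rexp(m)
    sigma <- runif(1, 0.1, 1)
    lambda <- runif(1, 0.05, 0.95)
    expect_equal(agmm_loglik(xs, mu, delta, sigma, lambda),
                 brute_loglik(xs, mu + delta / 2, mu - delta / 2,
                              sigma, lambda),
                 tolerance = 1e-10)
  }
})

test_that("agmm_loglik rejects parameters outside the box", {
  x <- list(rnorm(10))
  expect_error(agmm_loglik(x, 0, -0.1, 1, 0.5), "non-negative")
  expect_error(agmm_loglik(x, 0, 0.1, 0, 0.5), "positive")
  expect_error(agmm_loglik(x, 0, 0.1, 1, 1), "lambda")
  expect_error(agmm_loglik(x, c(0, 1), c(0.1, 0.2), 1, 0.5), "per sample")
})

test_that("AGMM recovers the generating peaks on clean replicates", {
  g <- make_group(m = 3, mu_high = 8, mu_low = 6, sd = 0.2, seed = 43)
  fit <- agmm(g)
  expect_s3_class(fit, "agmm")
  expect_true(fit$converged)
  pc <- peak_calls(fit)
  expect_equal(nrow(pc), 3L)
  expect_true(all(abs(pc$mu_high - 8) < 0.1))
  expect_true(all(abs(pc$mu_low - 6) < 0.1))
  expect_equal(fit$lambda, 2 / 3, tolerance = 0.1)
  expect_equal(fit$sigma, 0.2, tolerance = 0.05)
  # ascent: the optimum is at least as good as the starting point
  m <- length(fit$mu)
  init <- fit$init
  ll0 <- agmm_loglik(fit$data, init[1:m], init[(m + 1):(2 * m)],
                     init[2 * m + 1], init[2 * m + 2])
  expect_gte(fit$loglik, ll0)
  # stored loglik is recomputable from the stored parameters
  expect_equal(fit$loglik,
               agmm_loglik(fit$data, fit$mu, fit$delta, fit$sigma,
                           fit$lambda),
               tolerance = 1e-8)
})

test_that("the sign constraint orders every sample's peaks consistently", {
  set.seed(44)
  for (rep in 1:5) {
    sep <- runif(1, 0.1, 2)
    g <- make_group(m = 5, mu_high = 7 + sep / 2, mu_low = 7 - sep / 2,
                    sd = 0.2, seed = 44 + rep,
                    outliers = runif(2, 4, 10))
    pc <- peak_calls(agmm(g))
    expect_true(all(pc$mu_high >= pc$mu_low))
    expect_length(unique(pc$lambda), 1L)  # shared mixing proportion
    expect_length(unique(pc$sigma), 1L)   # shared SD
  }
})

test_that("with m = 1 AGMM agrees with the per-sample GMM", {
  set.seed(45)
  x <- c(rnorm(40, 8, 0.15), rnorm(20, 6, 0.15))  # separation 13 sigma
  fit <- agmm(list(x), outlier_filter = FALSE)
  ref <- gmm_deconv(x)
  expect_equal(fit$mu[1] + fit$delta[1] / 2, ref$mu_high,
               tolerance = 0.05)
  expect_equal(fit$mu[1] - fit$delta[1] / 2, ref$mu_low,
               tolerance = 0.05)
})

test_that("samples left with too few beads are dropped and flagged", {
  bv_ok <- bead_vector("s1", "c9", c(rnorm(30, 8, 0.1), rnorm(15, 6, 0.1)))
  bv_tiny <- bead_vector("s2", "c9", c(7.0, 7.1))
  g <- color_group("c9", list(bv_ok, bv_tiny))
  fit <- agmm(g)
  expect_equal(fit$dropped_samples, "s2")
  expect_equal(fit$sample_ids, "s1")
  g_bad <- color_group("c9", list(bv_tiny))
  expect_error(agmm(g_bad), "no sample retains")
})

test_that("agmm methods expose the fit coherently", {
  g <- make_group(m = 2, seed = 46)
  fit <- agmm(g)
  cf <- coef(fit)
  expect_named(cf, c("mu.s01", "mu.s02", "delta.s01", "delta.s02",
                     "sigma", "lambda"))
  ll <- logLik(fit)
  expect_s3_class(ll, "logLik")
  expect_equal(attr(ll, "df"), 6)
  cls <- predict(fit)
  expect_equal(lengths(cls), fit$n_used, ignore_attr = TRUE)
  expect_setequal(unique(unlist(cls)), c("high", "low"))
  # posterior probabilities in [0, 1] and consistent with labels
  pr <- predict(fit, type = "prob")
  expect_true(all(unlist(pr) >= 0 & unlist(pr) <= 1))
  expect_equal(unlist(cls) == "high", unlist(pr) >= 0.5,
               ignore_attr = TRUE)
  res <- residuals(fit)
  expect_equal(lengths(res), fit$n_used, ignore_attr = TRUE)
  expect_lt(max(abs(unlist(res))), 6 * fit$sigma)
  sim <- simulate(fit, nsim = 2, seed = 9)
  expect_length(sim, 2L)
  expect_equal(lengths(sim[[1]]), fit$n_used, ignore_attr = TRUE)
  expect_output(print(summary(fit)), "Per-sample peaks")
})

test_that("deconv_group returns per-sample calls with bookkeeping", {
  g <- make_group(m = 4, seed = 47, outliers = c(15, 15.2))
  for (meth in c("kmedians", "gmm")) {
    pc <- deconv_group(g, meth, outlier_filter = FALSE)
    expect_equal(nrow(pc), 4L)
    expect_length(unique(pc$mu_high), 4L)  # independent per-sample fits
    expect_true(all(pc$n_outliers_removed == 0L))
  }
  pc <- deconv_group(g, "agmm", outlier_filter = TRUE)
  expect_equal(nrow(pc), 4L)
  expect_length(unique(pc$lambda), 1L)
  expect_true(all(pc$n_outliers_removed == 2L))
  expect_true(all(pc$n_used == 60L))
})

test_that("the outlier filter shields AGMM from injected far outliers", {
  g_clean <- make_group(m = 3, seed = 48)
  g_dirty <- make_group(m = 3, seed = 48, outliers = numeric(0))
  # inject 2 far outliers into the first sample only
  g_dirty$samples[[1]]$intensities <-
    c(g_dirty$samples[[1]]$intensities, 16, 16.5)
  clean <- peak_calls(agmm(g_clean, outlier_filter = TRUE))
  filt <- peak_calls(agmm(g_dirty, outlier_filter = TRUE))
  gmm_dirty <- deconv_group(g_dirty, "gmm", outlier_filter = FALSE)
  # gmm on the contaminated sample moves; filtered agmm does not
  expect_lt(abs(filt$mu_high[1] - clean$mu_high[1]), 0.05)
  expect_gt(abs(gmm_dirty$mu_high[1] - clean$mu_high[1]), 0.05)
})
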
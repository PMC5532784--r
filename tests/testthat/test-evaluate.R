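test_that("rank pairing turns a swapped prediction into two equal errors", {
  truth <- data.frame(color_id = "c1", sample_id = "s1",
                      true_mu_high = 8, true_mu_low = 6,
                      n_outliers_injected = 0L)
  ok <- peak_call("s1", "c1", "gmm", 8, 6, 0.6, 0.2, 60L)
  pp <- pair_predictions(truth, ok)
  expect_equal(nrow(pp), 2L)
  expect_equal(pp$predicted_value, pp$true_value)

  # a collapsed prediction sitting on the low peak: the high-rank error
  # equals the true separation (the off-diagonal arm of a flip)
  swapped <- peak_call("s1", "c1", "gmm", 8, 6, 0.4, 0.2, 60L)
  swapped$mu_high <- 6 + 1e-9
  swapped$mu_low <- 6
  pp2 <- pair_predictions(truth, swapped)
  err <- abs(pp2$predicted_value - pp2$true_value)
  expect_equal(err, c(2, 0), tolerance = 1e-6)

  bad <- peak_call("s9", "c9", "gmm", 8, 6, 0.6, 0.2, 60L)
  expect_error(pair_predictions(truth, bad), "without a truth row")
})

test_that("pcc matches its definitional oracle", {
  set.seed(61)
  a <- rnorm(20)
  expect_equal(pcc(a, 2 * a + 1), 1)
  expect_equal(pcc(a, -a), -1)
  b <- rnorm(20)
  oracle <- mean((a - mean(a)) * (b - mean(b))) /
    (sqrt(mean((a - mean(a))^2)) * sqrt(mean((b - mean(b))^2)))
  expect_equal(pcc(a, b), oracle, tolerance = 1e-12)
  expect_error(pcc(a, rep(1, 20)), "zero variance")
  expect_error(pcc(1:2, 1:2), "length")
})

test_that("Williams's test matches hand computation and its symmetries", {
  # hand-computed example, n = 10: every quantity written out from the
  # formula with plain arithmetic
  r13 <- 0.8; r23 <- 0.6; r12 <- 0.5; n <- 10
  K <- 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23
  rbar <- (r13 + r23) / 2
  t_hand <- (r13 - r23) *
    sqrt((n - 1) * (1 + r12) /
           (2 * K * (n - 1) / (n - 3) + rbar^2 * (1 - r12)^3))
  wt <- williams_test(0.8, 0.6, 0.5, 10)
  expect_equal(wt$t, t_hand, tolerance = 1e-10)
  expect_identical(wt$df, 7L)
  expect_equal(wt$p, 2 * pt(abs(t_hand), 7, lower.tail = FALSE),
               tolerance = 1e-10)

  # symmetric null: equal correlations give t = 0, p = 1 exactly
  wt0 <- williams_test(0.7, 0.7, 0.3, 50)
  expect_identical(wt0$t, 0)
  expect_identical(wt0$p, 1)

  # a published-benchmark-scale contrast is overwhelming at n = 10000
  expect_lt(williams_test(0.97, 0.89, 0.85, 10000)$p, 1e-20)

  # sign follows the correlation difference; p decreases in |r13 - r23|
  set.seed(62)
  p_prev <- 1
  for (gap in c(0.02, 0.05, 0.1, 0.2)) {
    wt <- williams_test(0.6 + gap, 0.6, 0.4, 100)
    expect_gt(wt$t, 0)
    expect_lt(wt$p, p_prev)
    p_prev <- wt$p
    expect_lt(williams_test(0.6, 0.6 + gap, 0.4, 100)$t, 0)
  }
  expect_error(williams_test(0.99, -0.99, 0.99, 10), "inconsistent")
  expect_error(williams_test(1, 0.5, 0.5, 10), "strictly")
})

test_that("true predictions use a strict 0.05 rule and conserve rows", {
  truth <- data.frame(color_id = "c1", sample_id = sprintf("s%d", 1:4),
                      true_mu_high = 8, true_mu_low = 6,
                      n_outliers_injected = 0L)
  errs <- c(0.01, 0.049, 0.05, 0.2)
  calls <- do.call(rbind, lapply(1:4, function(i)
    peak_call(sprintf("s%d", i), "c1", "gmm", 8 + errs[i], 6, 0.6, 0.2,
              60L)))
  pp <- pair_predictions(truth, calls)
  # low peaks are exact (4 true) plus high-peak errors {0.01, 0.049} -> 2
  expect_identical(true_predictions(pp), 6L)
  expect_identical(true_predictions(pp) +
                     sum(abs(pp$predicted_value - pp$true_value) >= 0.05),
                   nrow(pp))
  expect_equal(mean_absolute_error(pp), mean(c(errs, 0, 0, 0, 0)))
  # MAE against an independent summation
  expect_equal(mean_absolute_error(pp),
               sum(abs(pp$predicted_value - pp$true_value)) / nrow(pp),
               tolerance = 1e-12)
})

test_that("flips are counted by majority-gene identity", {
  truth <- data.frame(color_id = rep(c("c1", "c2"), each = 2),
                      sample_id = rep(c("s1", "s2"), 2),
                      true_mu_high = 8, true_mu_low = 6,
                      n_outliers_injected = 0L)
  mk <- function(sid, cid, lam) peak_call(sid, cid, "gmm", 8, 6, lam,
                                          0.2, 60L)
  calls <- rbind(mk("s1", "c1", 0.65), mk("s2", "c1", 0.4),  # one flip
                 mk("s1", "c2", 0.7), mk("s2", "c2", 0.7))   # none
  fl <- count_flips(calls, truth)
  expect_identical(fl[["c1"]], 1L)
  expect_identical(fl[["c2"]], 0L)
  # when the bead majority sits on the LOW gene, the roles reverse
  fl2 <- count_flips(calls, truth, majority_gene = "low")
  expect_identical(fl2[["c1"]], 1L)
  expect_identical(fl2[["c2"]], 2L)
})

test_that("benchmark assembles all metrics for every method", {
  d <- simulate_dataset(sim_params(n_colors = 6, n_samples = 3,
                                   seed = 71))
  rep <- benchmark(d)
  expect_named(rep$methods,
               c("kmedians", "gmm", "agmm_nofilter", "agmm"))
  for (m in rep$methods) {
    expect_true(is.finite(m$pcc))
    expect_true(m$n_true_predictions <= 2 * 6 * 3)
    expect_gte(m$mean_absolute_error, 0)
    expect_length(m$flips_per_color, 6L)
  }
  expect_equal(nrow(rep$williams), 3L)
  expect_equal(rep$williams$reference, rep("agmm", 3))
  tab <- benchmark_table(rep)
  expect_equal(dim(tab), c(4L, 5L))
  expect_output(print(rep), "Williams tests")
  expect_identical(rep$seed, 71L)
})
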
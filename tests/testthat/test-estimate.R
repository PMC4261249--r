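# Concentration estimation from partition counts: closed-form values,
# boundary behaviour and replicate combination.

test_that("single-replicate estimator matches the closed form", {
  # -log(500/1000) = log 2
  est <- estimate_lambda(partition_counts(1000, 500))
  expect_equal(est$lambda_hat, log(2), tolerance = 1e-12)
  expect_identical(est$method, "single")

  # -log(7358/20000), computed independently: 0.9999441
  est2 <- estimate_lambda(partition_counts(20000, 7358))
  expect_equal(est2$lambda_hat, 0.9999441, tolerance = 1e-6)
  expect_equal(est2$se, sqrt((exp(est2$lambda_hat) - 1) / 20000), tolerance = 1e-12)
  expect_true(est2$ci_low <= est2$lambda_hat && est2$lambda_hat <= est2$ci_high)
})

test_that("estimator is strictly decreasing in the negative count", {
  n <- 5000L
  ks <- seq(100L, 4900L, by = 400L)
  lams <- vapply(ks, function(k) estimate_lambda(partition_counts(n, k))$lambda_hat,
                 numeric(1))
  expect_true(all(diff(lams) < 0))
})

test_that("boundary counts are handled as contracted", {
  # saturated: no negative partition -> typed error, not +Inf
  expect_error(estimate_lambda(partition_counts(20000, 0)),
               class = "dpcr_boundary_error")
  expect_error(estimate_lambda(partition_counts(20000, 0)), "all .* positive")

  # all negative: zero estimate with a one-sided rule-of-three interval
  est <- estimate_lambda(partition_counts(20000, 20000))
  expect_identical(est$lambda_hat, 0)
  expect_identical(est$ci_low, 0)
  expect_equal(est$ci_high, -log1p(-3 / 20000), tolerance = 1e-12)
  expect_true("at_lower_boundary" %in% est$flags)
})

test_that("asymptotic variance has the delta-method form and limits", {
  expect_equal(asymptotic_variance(1, 20000), 8.591409e-05, tolerance = 1e-6)

  # small-lambda Poisson limit: var -> lambda/n
  lam <- 1e-3
  expect_equal(asymptotic_variance(lam, 1000) / (lam / 1000), 1, tolerance = 1e-3)

  # precision scales as 1/sqrt(n): losing 6000 of 20000 partitions costs ~19.5%
  sd_ratio <- sqrt(asymptotic_variance(1, 14000) / asymptotic_variance(1, 20000))
  expect_equal(sd_ratio, sqrt(20000 / 14000), tolerance = 1e-12)

  expect_true(all(diff(asymptotic_variance(seq(0.1, 4, by = 0.1), 1000)) > 0))
  expect_error(asymptotic_variance(-1, 1000), class = "dpcr_parameter_error")
})

test_that("Wald interval is z-quantile symmetric and floored at zero", {
  expect_equal(wald_ci(1, 0.01), c(0.9804004, 1.0196), tolerance = 1e-6)
  expect_equal(wald_ci(1, 0), c(1, 1))
  expect_identical(wald_ci(0.01, 0.01)[1], 0)
  expect_error(wald_ci(1, 0.01, level = 1.2), class = "dpcr_parameter_error")
  expect_error(wald_ci(1, -0.1), class = "dpcr_parameter_error")
})

test_that("pooled estimate sums counts before estimating", {
  # m = 1: identical to the single-replicate estimator
  one <- replicate_set(12000, 4000)
  single <- estimate_lambda(partition_counts(12000, 4000))
  pooled <- pooled_estimate(one)
  expect_identical(pooled$lambda_hat, single$lambda_hat)
  expect_identical(pooled$se, single$se)

  # asymmetric negatives pool to -log(10000/20000) with variance (e^log2 - 1)/20000
  reps <- replicate_set(c(10000, 10000), c(4000, 6000))
  est <- pooled_estimate(reps)
  expect_equal(est$lambda_hat, log(2), tolerance = 1e-12)
  expect_equal(est$se^2, 5e-5, tolerance = 1e-12)
  expect_identical(est$method, "pooled")
})

test_that("replicate-based estimate uses the empirical t-interval", {
  # per-replicate estimates log 2 and log 4; expected moments computed
  # directly from those two numbers
  reps <- replicate_set(c(1000, 1000), c(500, 250))
  per <- -log(c(0.5, 0.25))
  est <- replicate_based_estimate(reps)
  expect_equal(est$lambda_hat, mean(per), tolerance = 1e-12)
  expect_equal(est$se, sd(per) / sqrt(2), tolerance = 1e-12)
  expect_equal(est$ci_high, mean(per) + qt(0.975, 1) * sd(per) / sqrt(2),
               tolerance = 1e-9)

  # identical replicates: degenerate interval
  same <- replicate_set(c(1000, 1000, 1000), c(400, 400, 400))
  est0 <- replicate_based_estimate(same)
  expect_identical(est0$se, 0)
  expect_equal(est0$ci_low, est0$ci_high)

  expect_error(replicate_based_estimate(replicate_set(1000, 400)),
               class = "dpcr_parameter_error")
  expect_error(replicate_based_estimate(replicate_set(c(1000, 1000), c(400, 0))),
               class = "dpcr_boundary_error")
})

test_that("volume conversion rescales estimate and interval", {
  est <- estimate_lambda(partition_counts(20000, 7358))
  out <- to_concentration(est, volume_spec(0.868))
  expect_equal(out$theta_hat, est$lambda_hat / 0.868, tolerance = 1e-12)
  expect_equal(out$theta_ci_high, est$ci_high / 0.868, tolerance = 1e-12)

  # trivial identity: lambda 0.89 in 0.89-nL partitions is 1 copy/nL
  est89 <- estimate_lambda(partition_counts(100000, round(100000 * exp(-0.89))))
  expect_equal(to_concentration(est89, volume_spec(0.89))$theta_hat,
               est89$lambda_hat / 0.89, tolerance = 1e-12)
  expect_error(volume_spec(0), class = "dpcr_parameter_error")
})

test_that("replicate-planning widths follow t(m-1)/sqrt(m) normalised to m = 2", {
  tab <- relative_ci_width_table(c(2, 3, 8))
  expect_equal(tab$width[1], 1, tolerance = 1e-12)
  expect_equal(tab$width[2], (qt(0.975, 2) / sqrt(3)) / (qt(0.975, 1) / sqrt(2)),
               tolerance = 1e-12)
  expect_equal(round(tab$width[3], 3), 0.093)
  expect_true(is.na(tab$improvement_pct[1]))
  expect_error(relative_ci_width_table(1:3), class = "dpcr_parameter_error")
})

test_that("estimates export as flat rows", {
  df <- as.data.frame(estimate_lambda(partition_counts(1000, 500)))
  expect_identical(names(df),
                   c("method", "lambda_hat", "se", "ci_low", "ci_high",
                     "theta_hat", "flags"))
  expect_identical(nrow(df), 1L)
})

test_that("count containers validate their invariants", {
  expect_error(partition_counts(100, 101), class = "dpcr_parameter_error")
  expect_error(partition_counts(0, 0), class = "dpcr_parameter_error")
  expect_error(replicate_set(c(100, 100), c(10, 10), c("a", "a")),
               class = "dpcr_parameter_error")
  expect_identical(n_replicates(replicate_set(c(100, 200), c(10, 20))), 2L)
})
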
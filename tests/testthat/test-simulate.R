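# Generator components: each variance component in isolation, then the
# composed experiment and the fluorescence stand-in.

test_that("pipette factor is centred at 1 with the requested CV", {
  expect_identical(draw_pipette_factor(0, 5), rep(1, 5))
  set.seed(101)
  fac <- draw_pipette_factor(0.05, 10000)
  expect_true(all(fac > 0))
  expect_equal(mean(fac), 1, tolerance = 0.002)
  expect_equal(sd(fac), 0.05, tolerance = 0.02)   # relative: +/- 0.001
})

test_that("partition sizes are lognormal with sample mean exactly 1", {
  expect_identical(draw_partition_sizes(7, 0), rep(1, 7))
  set.seed(202)
  s <- draw_partition_sizes(1e6, 0.1)
  expect_equal(mean(s), 1, tolerance = 1e-12)   # rescaled, exact
  # lognormal CV = sqrt(exp(sigma^2) - 1) = 0.10025 at sigma = 0.1
  expect_equal(sd(s), sqrt(exp(0.01) - 1), tolerance = 0.002)
})

test_that("copy seeding is Poisson proportional to size", {
  expect_identical(draw_copies(0, rep(1, 10)), rep(0L, 10))
  set.seed(303)
  copies <- draw_copies(1.59, rep(1, 2e5))
  # 4 binomial SEs on the zero fraction, relative to exp(-1.59)
  expect_equal(mean(copies == 0), exp(-1.59), tolerance = 0.018)
  set.seed(304)
  total <- sum(draw_copies(1, rep(1, 20000)))
  expect_true(abs(total - 20000) < 4 * sqrt(20000))
})

test_that("partition loss is MCAR and respects its moments", {
  set.seed(404)
  # no-loss identity
  full <- apply_loss(5000, 5000, 0)
  expect_identical(full$n_returned, 5000L)
  expect_identical(full$keep, seq_len(5000))

  draws <- replicate(1000, apply_loss(20000, 14000, 1800)$n_returned)
  expect_equal(mean(draws), 14000, tolerance = 170 / 14000 * 3)
  expect_true(all(draws >= 1 & draws <= 20000))

  # retained positive fraction is unbiased for the full set's
  copies <- rep(c(0L, 1L), c(12000, 8000))
  fracs <- replicate(400, {
    keep <- apply_loss(20000, 14000, 1800)$keep
    mean(copies[keep] > 0)
  })
  expect_equal(mean(fracs), 0.4, tolerance = 0.002)
})

test_that("classification applies the false rates per partition", {
  copies <- c(0L, 0L, 3L, 1L, 0L, 2L)
  expect_identical(classify(copies, 0, 0), copies >= 1L)
  expect_identical(classify(copies, 0, 1), rep(FALSE, 6))
  expect_identical(classify(copies, 1, 1), copies == 0L)

  # expected observed-negative fraction at lambda = 1, fpr 1e-4, fnr 1e-2:
  # exp(-1)*0.9999 + (1 - exp(-1))*0.01 = 0.3741639
  set.seed(505)
  copies <- rpois(4e5, 1)
  obs_neg <- mean(!classify(copies, 1e-4, 0.01))
  expect_equal(obs_neg, 0.3741639, tolerance = 0.004)
})

test_that("experiments compose reproducibly and respect theory", {
  cfg <- theory_cfg(0, n = 1000, m = 2)
  reps <- simulate_experiment(cfg)
  expect_identical(reps$k_negative, reps$n_returned)

  cfg <- sim_config(lambda_true = 1.25, pipette_cv = 0.05,
                    loss_mean = 14000, loss_sd = 1800, seed = 42)
  expect_identical(simulate_experiment(cfg), simulate_experiment(cfg))
  # per-partition path is seeded the same way
  expect_identical(simulate_experiment(cfg, fast = FALSE),
                   simulate_experiment(cfg, fast = FALSE))

  # pure Poisson: estimate within 3 asymptotic SDs of the truth
  est <- replicate_based_estimate(simulate_experiment(theory_cfg(1, seed = 7)))
  expect_true(abs(est$lambda_hat - 1) < 3 * sqrt((exp(1) - 1) / 20000 / 8))
})

test_that("realizations carry consistent per-partition state", {
  cfg <- sim_config(lambda_true = 1, n_created = 2000, m = 2,
                    size_sigma = 0.1, loss_mean = 1400, loss_sd = 180, seed = 9)
  reps <- simulate_experiment(cfg, keep_realizations = TRUE)
  reals <- attr(reps, "realizations")
  expect_length(reals, 2)
  r <- reals[[1]]
  expect_identical(length(r$sizes), length(r$copies))
  expect_identical(r$counts$n_returned, length(r$copies))
  expect_identical(r$counts$k_negative, sum(!r$observed_positive))
  expect_identical(r$true_positive, r$copies >= 1L)
  expect_identical(reps$n_returned[1], r$counts$n_returned)
})

test_that("fluorescence model thresholds reproduce the intended rates", {
  cfg <- sim_config(lambda_true = 1, n_created = 5000, m = 1, seed = 11)
  r <- simulate_replicate(cfg)

  # widely separated clusters, no rain, midpoint cutoff: perfect calls
  clean <- fluorescence_model(mu_neg = 1000, sigma_neg = 50,
                              mu_pos = 9000, sigma_pos = 50, rain_fraction = 0)
  intens <- draw_fluorescence(r, clean)
  res <- apply_threshold(intens, r$true_positive, 5000)
  expect_identical(res$fpr, 0)
  expect_identical(res$fnr, 0)
  expect_identical(res$observed_positive, r$true_positive)

  # cutoff below all intensities: everything positive, no false negatives
  res_lo <- apply_threshold(intens, r$true_positive, min(intens) - 1)
  expect_true(all(res_lo$observed_positive))
  expect_identical(res_lo$fnr, 0)
  expect_true("all_one_class" %in% res_lo$flags)

  # with rain, the realized false-negative rate is non-decreasing in the cutoff
  rainy <- fluorescence_model(rain_fraction = 0.06)
  set.seed(12)
  intens_r <- draw_fluorescence(r, rainy)
  cuts <- seq(2500, 5800, length.out = 12)
  fnrs <- vapply(cuts, function(ct) apply_threshold(intens_r, r$true_positive, ct)$fnr,
                 numeric(1))
  expect_true(all(diff(fnrs) >= 0))
})

test_that("configuration validation rejects out-of-range parameters", {
  expect_error(sim_config(-1), class = "dpcr_parameter_error")
  expect_error(sim_config(1, fpr = 1.5), class = "dpcr_parameter_error")
  expect_error(sim_config(1, loss_mean = 30000), class = "dpcr_parameter_error")
  expect_error(sim_config(1, pipette_cv = -0.1), class = "dpcr_parameter_error")
})
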
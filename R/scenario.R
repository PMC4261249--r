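# Monte-Carlo scenario engine: sweeps a concentration grid, simulates
# many experiments per condition, and summarises bias, spread, RMSE and
# confidence-interval coverage for the competing estimators.

#' Scenario configuration
#'
#' A base simulation configuration plus the sweep dimensions: the
#' concentration grid, the number of simulated experiments per grid
#' point and the estimation methods to compare.
#'
#' @param base A [sim_config()]; its `lambda_true` is overridden by the
#'   grid and its `seed` (or the `seed` argument) anchors the whole
#'   sweep.
#' @param lambda_grid Concentrations to sweep (copies/partition); the
#'   default is log-spaced over the working range 1e-4 to 5.
#' @param n_sims Simulated experiments per grid point (default 1000,
#'   enough for stable coverage and RMSE summaries).
#' @param methods Estimators to evaluate, a subset of `"pooled"`,
#'   `"replicate_based"`, `"single"` (`"single"` uses the first
#'   replicate only).
#' @param seed Optional root seed overriding `base$seed`.
#' @return A list of class `"dpcr_scenario_config"`.
#' @export
scenario_config <- function(base,
                            lambda_grid = exp(seq(log(1e-4), log(5), length.out = 12)),
                            n_sims = 1000L,
                            methods = c("pooled", "replicate_based"),
                            seed = NULL) {
  stopifnot(inherits(base, "dpcr_sim_config"))
  if (length(lambda_grid) < 1 || any(lambda_grid < 0))
    stop_dpcr("`lambda_grid` must be non-empty and non-negative", "dpcr_parameter_error")
  if (!is_count(n_sims) || n_sims < 1)
    stop_dpcr("`n_sims` must be a positive integer", "dpcr_parameter_error")
  methods <- match.arg(methods, c("pooled", "replicate_based", "single"),
                       several.ok = TRUE)
  if (is.null(seed)) seed <- base$seed
  structure(
    list(base = base, lambda_grid = lambda_grid, n_sims = as.integer(n_sims),
         methods = methods, seed = seed),
    class = "dpcr_scenario_config"
  )
}

estimate_by_method <- function(reps, method) {
  switch(method,
    pooled = pooled_estimate(reps),
    replicate_based = replicate_based_estimate(reps),
    single = estimate_lambda(partition_counts(reps$n_returned[1], reps$k_negative[1]))
  )
}

#' Confidence-interval coverage
#'
#' Fraction of estimates whose interval contains the true
#' concentration, the standard yardstick for interval calibration in a
#' simulation study.
#'
#' @param estimates Data frame with columns `ci_low` and `ci_high` (one
#'   row per simulated experiment), or a list of `"dpcr_estimate"`s.
#' @param lambda_true True concentration.
#' @return Proportion in [0, 1].
#' @export
coverage <- function(estimates, lambda_true) {
  if (is.list(estimates) && !is.data.frame(estimates))
    estimates <- do.call(rbind, lapply(estimates, as.data.frame))
  if (nrow(estimates) < 1)
    stop_dpcr("no estimates supplied", "dpcr_parameter_error")
  mean(estimates$ci_low <= lambda_true & lambda_true <= estimates$ci_high)
}

#' Relative root-mean-squared error of a set of estimates
#'
#' `sqrt(relVar + relBias^2)` with `relBias = mean(lambda_hat/lambda -
#' 1)` and `relVar` the empirical variance of `lambda_hat/lambda`:
#' accuracy and precision combined on the relative scale, so different
#' dilutions of the same sample are directly comparable.
#'
#' @param lambda_hats Numeric vector of point estimates (>= 2).
#' @param lambda_true True concentration (> 0).
#' @return Relative RMSE (dimensionless).
#' @examples
#' relative_rmse(c(0.98, 1.01, 1.03), 1)
#' @export
relative_rmse <- function(lambda_hats, lambda_true) {
  if (length(lambda_hats) < 2)
    stop_dpcr("relative RMSE needs >= 2 estimates", "dpcr_parameter_error")
  rel <- lambda_hats / lambda_true
  sqrt(stats::var(rel) + (mean(rel) - 1)^2)
}

#' Run a Monte-Carlo scenario sweep
#'
#' For every concentration on the grid, simulates `n_sims` experiments
#' from the base configuration, applies each requested estimator, and
#' summarises relative bias, relative SD, relative RMSE and CI
#' coverage.  Saturated runs (a replicate with zero negative
#' partitions, increasingly common at high concentration) cannot be
#' estimated; they are excluded from the moments and counted in
#' `n_boundary` so the censoring is visible.  Each grid point uses a
#' seed derived deterministically from the root seed, so sweeps that
#' share a root seed are paired across scenario variants.
#'
#' @param cfg A [scenario_config()].
#' @param fast Use the aggregated simulator path when valid.
#' @return Data frame of class `"dpcr_scenario_summary"`, one row per
#'   (lambda, method): columns `lambda`, `method`, `n_used`,
#'   `n_boundary`, `rel_bias`, `rel_sd`, `rel_rmse`, `coverage`,
#'   `undefined`.
#' @examples
#' cfg <- scenario_config(sim_config(1, n_created = 2000, m = 4),
#'                        lambda_grid = c(0.5, 1), n_sims = 50, seed = 3)
#' run_scenario(cfg)
#' @export
run_scenario <- function(cfg, fast = TRUE) {
  stopifnot(inherits(cfg, "dpcr_scenario_config"))
  base <- cfg$base
  base$seed <- NULL
  rows <- list()
  for (j in seq_along(cfg$lambda_grid)) {
    lam <- cfg$lambda_grid[j]
    if (!is.null(cfg$seed)) set.seed((cfg$seed + 7919L * j) %% 2147483647L)
    base$lambda_true <- lam
    # plain pre-allocated vectors: this loop runs n_sims times per
    # grid point and must stay allocation-light
    lh <- lo <- hi <- matrix(NA_real_, nrow = cfg$n_sims,
                             ncol = length(cfg$methods),
                             dimnames = list(NULL, cfg$methods))
    for (s in seq_len(cfg$n_sims)) {
      reps <- simulate_experiment(base, fast = fast)
      for (mth in cfg$methods) {
        est <- tryCatch(estimate_by_method(reps, mth),
                        dpcr_boundary_error = function(e) NULL)
        if (!is.null(est)) {
          lh[s, mth] <- est$lambda_hat
          lo[s, mth] <- est$ci_low
          hi[s, mth] <- est$ci_high
        }
      }
    }
    for (mth in cfg$methods) {
      ok <- which(!is.na(lh[, mth]))
      n_boundary <- cfg$n_sims - length(ok)
      if (length(ok) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          lambda = lam, method = mth, n_used = 0L,
          n_boundary = n_boundary, rel_bias = NA_real_,
          rel_sd = NA_real_, rel_rmse = NA_real_, coverage = NA_real_,
          undefined = TRUE, stringsAsFactors = FALSE)
        next
      }
      rel <- lh[ok, mth] / lam
      two <- length(ok) >= 2  # spread needs at least two usable runs
      rows[[length(rows) + 1L]] <- data.frame(
        lambda = lam, method = mth, n_used = length(ok),
        n_boundary = n_boundary,
        rel_bias = mean(rel) - 1,
        rel_sd = if (two) stats::sd(rel) else NA_real_,
        rel_rmse = if (two) relative_rmse(lh[ok, mth], lam) else NA_real_,
        coverage = mean(lo[ok, mth] <= lam & lam <= hi[ok, mth]),
        undefined = FALSE, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("dpcr_scenario_summary", "data.frame")
  attr(out, "n_sims") <- cfg$n_sims
  out
}

#' Concentration minimising the relative RMSE
#'
#' Grid argmin of the relative RMSE per estimation method — the
#' dilution with the best combined accuracy and precision in the
#' scenario studied.  When adjacent grid points tie (within `tie_tol`
#' relative difference) the tie is reported as an interval.
#'
#' @param summary A `"dpcr_scenario_summary"` from [run_scenario()]
#'   with at least 3 defined grid points per method.
#' @param tie_tol Relative RMSE difference below which adjacent grid
#'   points are treated as tied; default 0 (strict argmin).
#' @return Data frame with one row per method: `method`, `lambda_min`,
#'   `lambda_lo`, `lambda_hi` (tie interval; equal to `lambda_min` when
#'   unique), `rel_rmse_min`.
#' @export
rmse_minimizer <- function(summary, tie_tol = 0) {
  stopifnot(inherits(summary, "dpcr_scenario_summary"))
  out <- lapply(split(summary, summary$method), function(d) {
    d <- d[!d$undefined & is.finite(d$rel_rmse), ]
    if (nrow(d) < 3)
      stop_dpcr("rmse_minimizer needs >= 3 defined grid points", "dpcr_domain_error")
    d <- d[order(d$lambda), ]
    i <- which.min(d$rel_rmse)
    tied <- which(d$rel_rmse <= d$rel_rmse[i] * (1 + tie_tol))
    # only extend through grid points adjacent to the argmin
    lo <- i; while ((lo - 1) %in% tied) lo <- lo - 1
    hi <- i; while ((hi + 1) %in% tied) hi <- hi + 1
    data.frame(method = d$method[1], lambda_min = d$lambda[i],
               lambda_lo = d$lambda[lo], lambda_hi = d$lambda[hi],
               rel_rmse_min = d$rel_rmse[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Sequential variance-component report
#'
#' Reruns a scenario while switching variance components on
#' cumulatively in the order loss of partitions, pipette error, unequal
#' partition size, misclassification — so each stage's increment shows
#' the marginal effect of one component.  All stages share the root
#' seed (paired comparison).
#'
#' @param cfg A [scenario_config()]; its `base` holds the component
#'   parameters used when each component switches on.
#' @param loss_mean,loss_sd Loss stage parameters (defaults 14000,
#'   1800) used if `base` has loss disabled.
#' @return A `"dpcr_scenario_summary"` data frame with an extra `stage`
#'   column (`none`, `+loss`, `+pipette`, `+size`, `+misclass`).
#' @export
sequential_components_report <- function(cfg, loss_mean = 14000, loss_sd = 1800) {
  stopifnot(inherits(cfg, "dpcr_scenario_config"))
  full <- cfg$base
  if (is.null(full$loss_mean)) {
    full$loss_mean <- loss_mean
    full$loss_sd <- loss_sd
  }
  stage_cfgs <- list(
    none = list(loss = FALSE, pipette = FALSE, size = FALSE, mis = FALSE),
    `+loss` = list(loss = TRUE, pipette = FALSE, size = FALSE, mis = FALSE),
    `+pipette` = list(loss = TRUE, pipette = TRUE, size = FALSE, mis = FALSE),
    `+size` = list(loss = TRUE, pipette = TRUE, size = TRUE, mis = FALSE),
    `+misclass` = list(loss = TRUE, pipette = TRUE, size = TRUE, mis = TRUE)
  )
  rows <- lapply(names(stage_cfgs), function(nm) {
    on <- stage_cfgs[[nm]]
    b <- full
    if (!on$loss) { b$loss_mean <- NULL; b$loss_sd <- 0 }
    if (!on$pipette) b$pipette_cv <- 0
    if (!on$size) b$size_sigma <- 0
    if (!on$mis) { b$fpr <- 0; b$fnr <- 0 }
    sc <- cfg
    sc$base <- b
    res <- run_scenario(sc)
    res$stage <- nm
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("dpcr_scenario_summary", "data.frame")
  out
}
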
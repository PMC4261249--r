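# Poisson estimation from partition counts.
#
# With X the number of target copies in a partition and lambda the
# expected copies per partition, P(X = 0) = exp(-lambda).  Observing K
# negative partitions out of n_r returned gives
#   lambda_hat = -log(K / n_r),
# and the delta method on the binomial proportion gives
#   Var(lambda_hat) = (exp(lambda_hat) - 1) / n_r.

new_estimate <- function(lambda_hat, se, ci_low, ci_high, method,
                         theta_hat = NULL, flags = character(), level = 0.95) {
  structure(
    list(lambda_hat = lambda_hat, se = se, ci_low = ci_low, ci_high = ci_high,
         method = method, theta_hat = theta_hat, flags = flags, level = level),
    class = "dpcr_estimate"
  )
}

#' Asymptotic variance of the Poisson concentration estimator
#'
#' Delta-method variance of `lambda_hat = -log(K/n)`:
#' `(exp(lambda_hat) - 1) / n_returned`.  For small `lambda_hat` this
#' reduces to the familiar Poisson limit `lambda_hat / n_returned`; it
#' grows without bound as the positive-partition fraction approaches 1.
#'
#' @param lambda_hat Estimated copies per partition (>= 0).
#' @param n_returned Number of partitions with a returned readout.
#' @return The variance of `lambda_hat` (copies/partition squared).
#' @examples
#' asymptotic_variance(1, 20000)   # (e - 1)/20000
#' @export
asymptotic_variance <- function(lambda_hat, n_returned) {
  if (any(lambda_hat < 0))
    stop_dpcr("`lambda_hat` must be non-negative", "dpcr_parameter_error")
  if (any(n_returned < 1))
    stop_dpcr("`n_returned` must be >= 1", "dpcr_parameter_error")
  (exp(lambda_hat) - 1) / n_returned
}

#' Wald confidence interval on the concentration scale
#'
#' Symmetric normal-quantile interval `lambda_hat +/- z * se`, with the
#' lower bound floored at 0 since a concentration cannot be negative.
#'
#' @param lambda_hat Point estimate (copies/partition).
#' @param se Standard error of `lambda_hat`.
#' @param level Confidence level in (0, 1); default 0.95.
#' @return Numeric vector `c(ci_low, ci_high)`.
#' @examples
#' wald_ci(1, 0.01)
#' @export
wald_ci <- function(lambda_hat, se, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop_dpcr("`level` must be in (0, 1)", "dpcr_parameter_error")
  if (any(se < 0))
    stop_dpcr("`se` must be non-negative", "dpcr_parameter_error")
  z <- stats::qnorm((1 + level) / 2)
  c(max(0, lambda_hat - z * se), lambda_hat + z * se)
}

#' Estimate the target concentration from one replicate
#'
#' The standard dPCR estimator: `lambda_hat = -log(k_negative /
#' n_returned)` copies per partition, with asymptotic standard error and
#' a Wald confidence interval.
#'
#' Boundary cases: when no partition is negative the estimator is
#' undefined (the sample is saturated) and a boundary error of class
#' `"dpcr_boundary_error"` is raised.  When every partition is negative
#' the point estimate is 0 and a one-sided interval is returned whose
#' upper bound uses the rule of three, `-log(1 - 3/n)`; the estimate
#' carries the flag `"at_lower_boundary"`.
#'
#' @param counts A [partition_counts()] object.
#' @param level Confidence level; default 0.95.
#' @return A `"dpcr_estimate"` with fields `lambda_hat`, `se`, `ci_low`,
#'   `ci_high`, `method = "single"`, `flags`.
#' @examples
#' estimate_lambda(partition_counts(1000, 500))   # log(2)
#' @export
estimate_lambda <- function(counts, level = 0.95) {
  stopifnot(inherits(counts, "dpcr_counts"))
  n <- counts$n_returned
  k <- counts$k_negative
  if (k == 0)
    stop_dpcr(
      sprintf("all %d partitions positive: concentration estimate undefined (saturated sample); dilute and re-run", n),
      "dpcr_boundary_error")
  if (k == n) {
    upper <- -log1p(-min(3 / n, 1 - .Machine$double.eps))
    return(new_estimate(0, 0, 0, upper, "single",
                        flags = "at_lower_boundary", level = level))
  }
  lambda_hat <- -log(k / n)
  se <- sqrt(asymptotic_variance(lambda_hat, n))
  ci <- wald_ci(lambda_hat, se, level)
  new_estimate(lambda_hat, se, ci[1], ci[2], "single", level = level)
}

#' Pooled estimate over technical replicates
#'
#' Pools the partitions of all replicates into one virtual reaction
#' (summing returned and negative counts) and applies the single-sample
#' estimator.  Pooling ignores between-replicate technical variation:
#' in the presence of pipette error its interval is too narrow and its
#' coverage collapses, which is why [replicate_based_estimate()] is
#' preferred whenever replicates exist.
#'
#' @param reps A [replicate_set()].
#' @param level Confidence level; default 0.95.
#' @return A `"dpcr_estimate"` with `method = "pooled"`.
#' @examples
#' reps <- replicate_set(c(10000, 10000), c(4000, 6000))
#' pooled_estimate(reps)   # -log(0.5)
#' @export
pooled_estimate <- function(reps, level = 0.95) {
  stopifnot(inherits(reps, "dpcr_replicates"))
  est <- estimate_lambda(
    partition_counts(sum(reps$n_returned), sum(reps$k_negative)), level)
  est$method <- "pooled"
  est
}

#' Replicate-based estimate with empirical uncertainty
#'
#' Estimates the concentration separately in each replicate, then
#' reports the empirical mean with a t-interval based on the empirical
#' standard deviation across replicates: `mean +/- t(m-1) * sd/sqrt(m)`.
#' Unlike pooling, the empirical variance captures both Poisson
#' (within-replicate) and technical (between-replicate) variation, so
#' the interval keeps nominal coverage under pipette error.
#'
#' @param reps A [replicate_set()] with at least two replicates, none
#'   saturated.
#' @param level Confidence level; default 0.95.
#' @return A `"dpcr_estimate"` with `method = "replicate_based"`.
#' @examples
#' reps <- replicate_set(c(14000, 13900, 14100, 14050),
#'                       c(5100, 5030, 5210, 5150))
#' replicate_based_estimate(reps)
#' @export
replicate_based_estimate <- function(reps, level = 0.95) {
  stopifnot(inherits(reps, "dpcr_replicates"))
  m <- nrow(reps)
  if (m < 2)
    stop_dpcr("replicate-based variance requires >= 2 replicates",
              "dpcr_parameter_error")
  per_rep <- vapply(seq_len(m), function(i) {
    estimate_lambda(partition_counts(reps$n_returned[i], reps$k_negative[i]))$lambda_hat
  }, numeric(1))
  lambda_hat <- mean(per_rep)
  se <- stats::sd(per_rep) / sqrt(m)
  tq <- stats::qt((1 + level) / 2, df = m - 1)
  new_estimate(lambda_hat, se,
               max(0, lambda_hat - tq * se), lambda_hat + tq * se,
               "replicate_based", level = level)
}

#' Convert an estimate to copies per nanoliter
#'
#' Divides the copies-per-partition estimate and its interval by the
#' mean partition volume: `theta_hat = lambda_hat / v`.  If the assumed
#' volume deviates from the true mean volume the reported concentration
#' is systematically biased; see [volume_bias()].
#'
#' @param est A `"dpcr_estimate"`.
#' @param vol A [volume_spec()].
#' @return The estimate with `theta_hat` filled in and volume-scale
#'   fields `theta_se`, `theta_ci_low`, `theta_ci_high` attached.
#' @examples
#' est <- estimate_lambda(partition_counts(20000, 7358))
#' to_concentration(est, volume_spec(0.89))
#' @export
to_concentration <- function(est, vol) {
  stopifnot(inherits(est, "dpcr_estimate"))
  if (!inherits(vol, "dpcr_volume")) vol <- volume_spec(vol)
  v <- vol$v_assumed
  est$theta_hat <- est$lambda_hat / v
  est$theta_se <- est$se / v
  est$theta_ci_low <- est$ci_low / v
  est$theta_ci_high <- est$ci_high / v
  est$v_assumed <- v
  est
}

#' Replicate-number planning table
#'
#' Width of a replicate-based confidence interval, relative to a
#' constant standard deviation, as a function of the number of
#' technical replicates `m`: proportional to `t(m-1) / sqrt(m)`.
#' Widths are normalised to `m = 2` and each row reports the percentage
#' improvement over one fewer replicate, showing the diminishing return
#' of additional replicates (4 or more are worthwhile, beyond 8 the
#' gain is marginal).
#'
#' @param m_values Integer vector of replicate counts, all >= 2.
#' @param level Confidence level; default 0.95.
#' @return Data frame with columns `m`, `width` (relative to the
#'   smallest `m` requested when it is 2, otherwise to m = 2) and
#'   `improvement_pct` (percentage width decrease versus `m - 1`; `NA`
#'   at `m = 2`).
#' @examples
#' relative_ci_width_table(2:12)
#' @export
relative_ci_width_table <- function(m_values, level = 0.95) {
  if (any(m_values < 2) || any(m_values != round(m_values)))
    stop_dpcr("all `m_values` must be integers >= 2", "dpcr_parameter_error")
  m_values <- as.integer(m_values)
  half_width <- function(m) stats::qt((1 + level) / 2, df = m - 1) / sqrt(m)
  ref <- half_width(2L)
  data.frame(
    m = m_values,
    width = vapply(m_values, half_width, numeric(1)) / ref,
    improvement_pct = vapply(m_values, function(m) {
      if (m == 2L) return(NA_real_)
      100 * (1 - half_width(m) / half_width(m - 1L))
    }, numeric(1))
  )
}

#' @export
print.dpcr_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("dPCR concentration estimate (%s method)\n", x$method))
  cat(sprintf("  lambda_hat: %.*f copies/partition (se %.*f)\n",
              digits, x$lambda_hat, digits, x$se))
  cat(sprintf("  %d%% CI: [%.*f, %.*f]\n", round(100 * x$level),
              digits, x$ci_low, digits, x$ci_high))
  if (!is.null(x$theta_hat))
    cat(sprintf("  theta_hat: %.*f copies/nL (v = %.3f nL)\n",
                digits, x$theta_hat, x$v_assumed))
  if (length(x$flags))
    cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.dpcr_estimate <- function(x, ...) {
  data.frame(
    method = x$method,
    lambda_hat = x$lambda_hat,
    se = x$se,
    ci_low = x$ci_low,
    ci_high = x$ci_high,
    theta_hat = if (is.null(x$theta_hat)) NA_real_ else x$theta_hat,
    flags = paste(x$flags, collapse = ";"),
    stringsAsFactors = FALSE
  )
}
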
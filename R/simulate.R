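# Stochastic generator of dPCR experiments.  One replicate is built in
# workflow order: pipette draw -> partitioning (sizes) -> copy seeding
# (Poisson, mean proportional to size) -> random partition loss (MCAR)
# -> endpoint classification (false positives/negatives).  Every
# component can be switched off to recover the textbook Poisson model.

#' Simulation configuration for the dPCR data-generating process
#'
#' Collects every parameter of the generator.  Defaults describe a
#' droplet-type system with 20 000 created partitions and 8 technical
#' replicates; all variance components default to "off" so that
#' `sim_config(lambda_true = 1)` is the pure Poisson model.
#'
#' @param lambda_true Expected target copies per partition (the
#'   quantity being estimated); typical working range 1e-4 to 5.
#' @param n_created Partitions created per replicate (default 20000).
#' @param m Number of technical replicates (default 8, matching the
#'   8-well column of a 96-well plate).
#' @param pipette_cv Coefficient of variation of the pipetted amount of
#'   template; one multiplicative Normal(1, cv) factor per replicate on
#'   the effective concentration.  0 disables.  Realistic range 0-0.10.
#' @param size_sigma Lognormal sigma of relative partition size
#'   (volume); sizes are rescaled to mean exactly 1 within a replicate.
#'   0.1 corresponds to roughly 10% volume CV; 0 gives equal partitions.
#' @param loss_mean,loss_sd Mean and SD of the number of partitions
#'   returned after random (MCAR) loss, e.g. 14000 and 1800 for a ~30%
#'   droplet loss.  `loss_mean = NULL` disables loss entirely.
#' @param fpr Probability an empty partition reads positive
#'   (1 - specificity).
#' @param fnr Probability an occupied partition reads negative
#'   (1 - sensitivity).
#' @param seed Optional integer seed; when set, [simulate_experiment()]
#'   is fully reproducible.
#' @return A list of class `"dpcr_sim_config"`.
#' @examples
#' cfg <- sim_config(lambda_true = 1.59, pipette_cv = 0.05, seed = 7)
#' @export
sim_config <- function(lambda_true,
                       n_created = 20000L,
                       m = 8L,
                       pipette_cv = 0,
                       size_sigma = 0,
                       loss_mean = NULL,
                       loss_sd = 0,
                       fpr = 0,
                       fnr = 0,
                       seed = NULL) {
  if (!is.numeric(lambda_true) || lambda_true < 0)
    stop_dpcr("`lambda_true` must be >= 0", "dpcr_parameter_error")
  if (!is_count(n_created) || n_created < 1)
    stop_dpcr("`n_created` must be a positive integer", "dpcr_parameter_error")
  if (!is_count(m) || m < 1)
    stop_dpcr("`m` must be a positive integer", "dpcr_parameter_error")
  if (pipette_cv < 0 || size_sigma < 0)
    stop_dpcr("`pipette_cv` and `size_sigma` must be >= 0", "dpcr_parameter_error")
  if (fpr < 0 || fpr > 1 || fnr < 0 || fnr > 1)
    stop_dpcr("`fpr` and `fnr` must lie in [0, 1]", "dpcr_parameter_error")
  if (!is.null(loss_mean)) {
    if (loss_mean <= 0 || loss_mean > n_created)
      stop_dpcr("`loss_mean` must be in (0, n_created]", "dpcr_parameter_error")
    if (loss_sd < 0)
      stop_dpcr("`loss_sd` must be >= 0", "dpcr_parameter_error")
  }
  structure(
    list(lambda_true = lambda_true, n_created = as.integer(n_created),
         m = as.integer(m), pipette_cv = pipette_cv, size_sigma = size_sigma,
         loss_mean = loss_mean, loss_sd = loss_sd, fpr = fpr, fnr = fnr,
         seed = seed),
    class = "dpcr_sim_config"
  )
}

#' @export
print.dpcr_sim_config <- function(x, ...) {
  cat("dPCR simulation config\n")
  cat(sprintf("  lambda_true = %g copies/partition, n_created = %d, m = %d\n",
              x$lambda_true, x$n_created, x$m))
  cat(sprintf("  pipette_cv = %g, size_sigma = %g, fpr = %g, fnr = %g\n",
              x$pipette_cv, x$size_sigma, x$fpr, x$fnr))
  if (is.null(x$loss_mean)) cat("  partition loss: none\n")
  else cat(sprintf("  partition loss: Normal(%g, %g) returned\n",
                   x$loss_mean, x$loss_sd))
  if (!is.null(x$seed)) cat(sprintf("  seed = %d\n", x$seed))
  invisible(x)
}

#' Draw the per-replicate pipette factor
#'
#' One multiplicative factor per replicate for the amount of template
#' that actually entered the reaction mix: Normal with mean 1 and SD
#' `pipette_cv`, redrawn on the (physically impossible) non-positive
#' tail.  The factor multiplies the replicate's effective concentration
#' and is the model for pipette error plus other lumped between-replicate
#' technical variation.
#'
#' @param pipette_cv Coefficient of variation (>= 0); 0 returns exactly 1.
#' @param n Number of factors to draw (default 1).
#' @return Numeric vector of positive scale factors.
#' @export
draw_pipette_factor <- function(pipette_cv, n = 1L) {
  if (pipette_cv < 0)
    stop_dpcr("`pipette_cv` must be >= 0", "dpcr_parameter_error")
  if (pipette_cv == 0) return(rep(1, n))
  fac <- stats::rnorm(n, mean = 1, sd = pipette_cv)
  while (any(bad <- fac <= 0))
    fac[bad] <- stats::rnorm(sum(bad), mean = 1, sd = pipette_cv)
  fac
}

#' Draw relative partition sizes
#'
#' I.i.d. lognormal relative volumes, rescaled so the sample mean is
#' exactly 1 within the replicate.  The rescaling keeps within-replicate
#' size heterogeneity from leaking into between-replicate variation
#' (which the pipette factor models separately).  `size_sigma = 0.1` is
#' approximately a 10% volume CV.
#'
#' @param n Number of partitions.
#' @param size_sigma Lognormal sigma (>= 0); 0 gives all ones.
#' @return Numeric vector of length `n` with mean exactly 1.
#' @export
draw_partition_sizes <- function(n, size_sigma) {
  if (size_sigma < 0)
    stop_dpcr("`size_sigma` must be >= 0", "dpcr_parameter_error")
  if (size_sigma == 0) return(rep(1, n))
  s <- stats::rlnorm(n, meanlog = 0, sdlog = size_sigma)
  s / mean(s)
}

#' Seed partitions with target copies
#'
#' Independent Poisson counts with per-partition mean
#' `lambda_eff * size`, so larger partitions are proportionally more
#' likely to capture copies.
#'
#' @param lambda_eff Effective copies per unit-size partition (>= 0).
#' @param sizes Relative partition sizes.
#' @return Integer vector of copy numbers.
#' @export
draw_copies <- function(lambda_eff, sizes) {
  if (lambda_eff < 0)
    stop_dpcr("`lambda_eff` must be >= 0", "dpcr_parameter_error")
  stats::rpois(length(sizes), lambda_eff * sizes)
}

#' Random partition loss (missing completely at random)
#'
#' Draws the number of partitions returned from a rounded
#' Normal(`loss_mean`, `loss_sd`) clamped to `[1, n_created]`, then
#' retains a uniformly random subset of that many partitions.  Because
#' the loss is MCAR it leaves the negative fraction unbiased and only
#' costs precision.
#'
#' @param n_created Number of partitions before loss.
#' @param loss_mean,loss_sd Mean and SD of the returned count.
#' @return A list with `n_returned` and `keep`, the indices of the
#'   retained partitions.
#' @export
apply_loss <- function(n_created, loss_mean, loss_sd) {
  if (loss_mean <= 0 || loss_mean > n_created)
    stop_dpcr("`loss_mean` must be in (0, n_created]", "dpcr_parameter_error")
  n_ret <- as.integer(max(1, min(n_created, round(stats::rnorm(1, loss_mean, loss_sd)))))
  keep <- if (n_ret == n_created) seq_len(n_created)
          else sample.int(n_created, n_ret)
  list(n_returned = n_ret, keep = keep)
}

#' Misclassify endpoint labels
#'
#' Occupied partitions (copies >= 1) read positive with probability
#' `1 - fnr`; empty partitions read positive with probability `fpr`;
#' independent Bernoulli per partition.
#'
#' @param copies Integer vector of per-partition copy numbers.
#' @param fpr False positive rate (empty partition reads positive).
#' @param fnr False negative rate (occupied partition reads negative).
#' @return Logical vector: observed positive labels.
#' @export
classify <- function(copies, fpr, fnr) {
  if (fpr < 0 || fpr > 1 || fnr < 0 || fnr > 1)
    stop_dpcr("`fpr` and `fnr` must lie in [0, 1]", "dpcr_parameter_error")
  occupied <- copies >= 1L
  if (fpr == 0 && fnr == 0) return(occupied)  # no RNG draw needed
  p_pos <- ifelse(occupied, 1 - fnr, fpr)
  stats::runif(length(copies)) < p_pos
}

# Probability a returned partition reads negative, for the fast path:
# empty and correctly read, or occupied and missed.
observed_negative_prob <- function(lambda_eff, fpr, fnr) {
  p0 <- exp(-lambda_eff)
  p0 * (1 - fpr) + (1 - p0) * fnr
}

#' Simulate one technical replicate
#'
#' Composes the generator stages in workflow order for a single
#' replicate and returns the full per-partition realization.  For large
#' scenario sweeps prefer [simulate_experiment()], which can use an
#' aggregated fast path.
#'
#' @param cfg A [sim_config()].
#' @param pipette_factor Optional pre-drawn pipette factor (drawn from
#'   `cfg$pipette_cv` when `NULL`).
#' @return A list of class `"dpcr_realization"` with per-partition
#'   `sizes`, `copies`, `true_positive`, `observed_positive` (returned
#'   partitions only) and the `counts` summary as [partition_counts()].
#' @export
simulate_replicate <- function(cfg, pipette_factor = NULL) {
  stopifnot(inherits(cfg, "dpcr_sim_config"))
  if (is.null(pipette_factor))
    pipette_factor <- draw_pipette_factor(cfg$pipette_cv)
  lambda_eff <- cfg$lambda_true * pipette_factor
  sizes <- draw_partition_sizes(cfg$n_created, cfg$size_sigma)
  copies <- draw_copies(lambda_eff, sizes)
  if (!is.null(cfg$loss_mean)) {
    loss <- apply_loss(cfg$n_created, cfg$loss_mean, cfg$loss_sd)
    sizes <- sizes[loss$keep]
    copies <- copies[loss$keep]
  }
  observed_positive <- classify(copies, cfg$fpr, cfg$fnr)
  structure(
    list(sizes = sizes, copies = copies,
         true_positive = copies >= 1L,
         observed_positive = observed_positive,
         pipette_factor = pipette_factor,
         counts = partition_counts(length(copies), sum(!observed_positive))),
    class = "dpcr_realization"
  )
}

# Aggregated fast path: valid when size_sigma = 0, in which case each
# returned partition reads negative independently with the same
# probability, so k_negative | n_returned is a single binomial draw.
simulate_replicate_fast <- function(cfg, pipette_factor) {
  lambda_eff <- cfg$lambda_true * pipette_factor
  if (is.null(cfg$loss_mean)) {
    n_ret <- cfg$n_created
  } else {
    n_ret <- as.integer(round(stats::rnorm(1, cfg$loss_mean, cfg$loss_sd)))
    n_ret <- max(1L, min(cfg$n_created, n_ret))
  }
  k <- stats::rbinom(1L, n_ret, observed_negative_prob(lambda_eff, cfg$fpr, cfg$fnr))
  c(n_ret, k)
}

#' Simulate a full dPCR experiment
#'
#' Generates `cfg$m` independent technical replicates and returns their
#' partition counts as a [replicate_set()], ready for the estimators.
#' When `cfg$seed` is set the result is reproducible.
#'
#' Two execution paths produce statistically identical counts when
#' partition sizes are equal (`size_sigma = 0`): the per-partition path
#' (`fast = FALSE`), which realizes every partition and is kept as the
#' reference, and an aggregated path drawing `k_negative` directly from
#' its binomial distribution, roughly three orders of magnitude faster
#' for scenario sweeps.  With `size_sigma > 0` the per-partition path is
#' always used.
#'
#' @param cfg A [sim_config()].
#' @param fast Use the aggregated path when valid (default `TRUE`).
#' @param keep_realizations Return per-partition realizations alongside
#'   the counts (forces the per-partition path).
#' @return A [replicate_set()]; when `keep_realizations = TRUE`, the
#'   realizations are attached as attribute `"realizations"`.
#' @examples
#' cfg <- sim_config(lambda_true = 1, seed = 42)
#' reps <- simulate_experiment(cfg)
#' replicate_based_estimate(reps)
#' @export
simulate_experiment <- function(cfg, fast = TRUE, keep_realizations = FALSE) {
  stopifnot(inherits(cfg, "dpcr_sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  pf <- draw_pipette_factor(cfg$pipette_cv, cfg$m)
  use_fast <- fast && !keep_realizations && cfg$size_sigma == 0
  if (use_fast) {
    counts <- vapply(seq_len(cfg$m), function(i) simulate_replicate_fast(cfg, pf[i]),
                     numeric(2))
    return(replicate_set(counts[1, ], counts[2, ]))
  }
  reals <- lapply(seq_len(cfg$m), function(i) simulate_replicate(cfg, pf[i]))
  out <- replicate_set(
    vapply(reals, function(r) r$counts$n_returned, integer(1)),
    vapply(reals, function(r) r$counts$k_negative, integer(1))
  )
  if (keep_realizations) attr(out, "realizations") <- reals
  out
}

#' Two-cluster fluorescence emission model
#'
#' Parametric stand-in for the endpoint fluorescence readout: negative
#' partitions emit around a low cluster, positive partitions around a
#' high cluster, and a `rain_fraction` of positives emit uniformly
#' between the cluster centers ("rain": partitions that cannot be
#' cleanly assigned).  Defaults put the clusters at 2000 and 6000
#' arbitrary units with about 6% rain.
#'
#' @param mu_neg,sigma_neg Negative-cluster location and spread.
#' @param mu_pos,sigma_pos Positive-cluster location and spread.
#' @param rain_fraction Proportion of positive partitions emitting
#'   between the clusters, in [0, 1].
#' @return A list of class `"dpcr_fluor_model"`.
#' @export
fluorescence_model <- function(mu_neg = 2000, sigma_neg = 200,
                               mu_pos = 6000, sigma_pos = 300,
                               rain_fraction = 0.06) {
  if (mu_neg >= mu_pos)
    stop_dpcr("`mu_neg` must be below `mu_pos`", "dpcr_parameter_error")
  if (sigma_neg <= 0 || sigma_pos <= 0)
    stop_dpcr("cluster sigmas must be positive", "dpcr_parameter_error")
  if (rain_fraction < 0 || rain_fraction > 1)
    stop_dpcr("`rain_fraction` must lie in [0, 1]", "dpcr_parameter_error")
  structure(list(mu_neg = mu_neg, sigma_neg = sigma_neg,
                 mu_pos = mu_pos, sigma_pos = sigma_pos,
                 rain_fraction = rain_fraction),
            class = "dpcr_fluor_model")
}

#' Draw per-partition fluorescence intensities
#'
#' Empty partitions draw from the negative cluster; occupied partitions
#' draw from the positive cluster, except a `rain_fraction` subset that
#' draws uniformly between the two cluster centers.
#'
#' @param realization A `"dpcr_realization"` from [simulate_replicate()].
#' @param model A [fluorescence_model()].
#' @return Numeric vector of intensities (arbitrary units), one per
#'   returned partition.
#' @export
draw_fluorescence <- function(realization, model) {
  stopifnot(inherits(realization, "dpcr_realization"),
            inherits(model, "dpcr_fluor_model"))
  truth <- realization$true_positive
  n <- length(truth)
  intens <- numeric(n)
  neg <- !truth
  intens[neg] <- stats::rnorm(sum(neg), model$mu_neg, model$sigma_neg)
  pos_idx <- which(truth)
  if (length(pos_idx)) {
    rain <- stats::runif(length(pos_idx)) < model$rain_fraction
    intens[pos_idx[!rain]] <- stats::rnorm(sum(!rain), model$mu_pos, model$sigma_pos)
    intens[pos_idx[rain]] <- stats::runif(sum(rain), model$mu_neg, model$mu_pos)
  }
  intens
}

#' Threshold fluorescence intensities into labels
#'
#' Labels partitions positive when their intensity exceeds `cutoff` and
#' reports the realized misclassification rates against the true
#' occupancy, so the consequences of a threshold choice can be read off
#' directly.
#'
#' @param intensities Per-partition intensities.
#' @param true_positive Logical true-occupancy vector, parallel to
#'   `intensities`.
#' @param cutoff Threshold intensity.
#' @return A list with `observed_positive` (logical), `fpr`, `fnr`
#'   (realized rates; `NaN` when the denominator class is empty) and
#'   `flags` (contains `"all_one_class"` when the cutoff falls outside
#'   the data range).
#' @export
apply_threshold <- function(intensities, true_positive, cutoff) {
  if (length(intensities) != length(true_positive))
    stop_dpcr("`intensities` and `true_positive` must have equal length",
              "dpcr_parameter_error")
  observed <- intensities > cutoff
  flags <- character()
  if (cutoff < min(intensities) || cutoff > max(intensities))
    flags <- "all_one_class"
  n_empty <- sum(!true_positive)
  n_occ <- sum(true_positive)
  list(
    observed_positive = observed,
    fpr = if (n_empty) sum(observed & !true_positive) / n_empty else NaN,
    fnr = if (n_occ) sum(!observed & true_positive) / n_occ else NaN,
    flags = flags
  )
}
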
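# Delimited-text I/O and run provenance.  Counts tables are plain CSV
# with columns replicate_id, n_returned, k_negative; there is no
# community standard file format for dPCR counts.

#' Read a replicate counts table from CSV
#'
#' Expects a header with columns `replicate_id`, `n_returned`,
#' `k_negative` (extra columns are ignored).  Validation failures are
#' reported as parse errors of class `"dpcr_parse_error"` naming the
#' offending row.
#'
#' @param path Path to a CSV file.
#' @return A [replicate_set()].
#' @export
read_counts_table <- function(path) {
  tab <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop_dpcr(
      sprintf("cannot read '%s': %s", path, conditionMessage(e)), "dpcr_parse_error"))
  required <- c("replicate_id", "n_returned", "k_negative")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop_dpcr(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")),
              "dpcr_parse_error")
  if (nrow(tab) == 0)
    stop_dpcr("no replicates in file", "dpcr_parse_error")
  for (col in c("n_returned", "k_negative")) {
    x <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(!is.finite(x) | x != round(x) | x < 0)
    if (length(bad))
      stop_dpcr(sprintf("row %d: `%s` is not a non-negative integer (value '%s')",
                        bad[1], col, tab[[col]][bad[1]]), "dpcr_parse_error")
    tab[[col]] <- as.integer(x)
  }
  if (anyDuplicated(tab$replicate_id))
    stop_dpcr(sprintf("duplicate replicate_id '%s'",
                      tab$replicate_id[anyDuplicated(tab$replicate_id)]),
              "dpcr_parse_error")
  bad <- which(tab$k_negative > tab$n_returned)
  if (length(bad))
    stop_dpcr(sprintf("row %d: k_negative (%d) exceeds n_returned (%d)",
                      bad[1], tab$k_negative[bad[1]], tab$n_returned[bad[1]]),
              "dpcr_parse_error")
  bad <- which(tab$n_returned < 1)
  if (length(bad))
    stop_dpcr(sprintf("row %d: n_returned must be >= 1", bad[1]), "dpcr_parse_error")
  replicate_set(tab$n_returned, tab$k_negative, tab$replicate_id)
}

#' Write a replicate counts table to CSV
#'
#' Inverse of [read_counts_table()]; the written file reads back to an
#' identical replicate set.
#'
#' @param reps A [replicate_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_table <- function(reps, path) {
  stopifnot(inherits(reps, "dpcr_replicates"))
  utils::write.csv(as.data.frame(unclass(reps), stringsAsFactors = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Estimate concentration from a counts file
#'
#' One-stop analysis of a counts table: per-replicate estimates plus
#' the pooled and (when `m >= 2`) replicate-based combinations,
#' optionally converted to copies per nanoliter and corrected for known
#' misclassification rates.  The misclassification correction inverts
#' the observed negative fraction through [corrected_lambda()] before
#' estimation, per replicate and for the pool.
#'
#' @param path Path to a counts CSV (see [read_counts_table()]).
#' @param volume Optional mean partition volume in nL (or a
#'   [volume_spec()]) for copies/nL reporting.
#' @param rates Optional [misclass_rates()] used to bias-correct the
#'   estimates.
#' @param level Confidence level; default 0.95.
#' @return Data frame with one row per estimate (methods `single:<id>`,
#'   `pooled`, `replicate_based`) and columns `method`, `lambda_hat`,
#'   `se`, `ci_low`, `ci_high`, `theta_hat`, `flags`.  Saturated
#'   replicates are reported with `NA` estimates and a
#'   `"saturated"` flag rather than aborting the whole table.
#' @export
estimate_from_file <- function(path, volume = NULL, rates = NULL, level = 0.95) {
  reps <- read_counts_table(path)
  correct <- function(est, n_returned) {
    if (is.null(rates)) return(est)
    lam <- corrected_lambda(exp(-est$lambda_hat), rates)
    est$lambda_hat <- lam
    est$se <- sqrt(asymptotic_variance(lam, n_returned))
    ci <- wald_ci(lam, est$se, level)
    est$ci_low <- ci[1]; est$ci_high <- ci[2]
    est$flags <- union(est$flags, "misclassification_corrected")
    est
  }
  finish <- function(est) {
    if (!is.null(volume)) est <- to_concentration(est, volume)
    as.data.frame(est)
  }
  rows <- list()
  for (i in seq_len(nrow(reps))) {
    row <- tryCatch({
      est <- estimate_lambda(partition_counts(reps$n_returned[i], reps$k_negative[i]),
                             level)
      est <- correct(est, reps$n_returned[i])
      finish(est)
    }, dpcr_boundary_error = function(e) {
      data.frame(method = "single", lambda_hat = NA_real_, se = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_, theta_hat = NA_real_,
                 flags = "saturated", stringsAsFactors = FALSE)
    })
    row$method <- sprintf("single:%s", reps$replicate_id[i])
    rows[[length(rows) + 1L]] <- row
  }
  rows[[length(rows) + 1L]] <- tryCatch({
    est <- pooled_estimate(reps, level)
    est <- correct(est, sum(reps$n_returned))
    finish(est)
  }, dpcr_boundary_error = function(e) {
    data.frame(method = "pooled", lambda_hat = NA_real_, se = NA_real_,
               ci_low = NA_real_, ci_high = NA_real_, theta_hat = NA_real_,
               flags = "saturated", stringsAsFactors = FALSE)
  })
  if (nrow(reps) >= 2) {
    rb <- tryCatch(finish(replicate_based_estimate(reps, level)),
                   dpcr_boundary_error = function(e) NULL)
    # note: rate correction of the replicate-based mean would need the
    # per-replicate fractions; apply it per replicate instead
    if (!is.null(rb) && !is.null(rates)) {
      per <- vapply(seq_len(nrow(reps)), function(i) {
        corrected_lambda(reps$k_negative[i] / reps$n_returned[i], rates)
      }, numeric(1))
      m <- length(per)
      se <- stats::sd(per) / sqrt(m)
      tq <- stats::qt((1 + level) / 2, m - 1)
      est <- new_estimate(mean(per), se, max(0, mean(per) - tq * se),
                         mean(per) + tq * se, "replicate_based",
                         flags = "misclassification_corrected", level = level)
      rb <- finish(est)
    }
    if (!is.null(rb)) rows[[length(rows) + 1L]] <- rb
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a run manifest
#'
#' Records the provenance of a set of outputs — configuration snapshot,
#' root seed, package version, timestamp and output paths — as JSON
#' next to the outputs, so a run can be reproduced exactly.  Written
#' atomically (temp file + rename).
#'
#' @param path Manifest path (`.json`).
#' @param config A configuration object (any list; classed
#'   configurations are unclassed for serialisation).
#' @param seed Root seed of the run (may be `NULL`).
#' @param outputs Character vector of output file paths.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seed = NULL, outputs = character()) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop_dpcr("the `jsonlite` package is required to write manifests",
              "dpcr_parameter_error")
  manifest <- list(
    package = "dpcrsim",
    version = as.character(utils::packageVersion("dpcrsim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = rapply(unclass(config), unclass, how = "replace"),
    outputs = outputs
  )
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}
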
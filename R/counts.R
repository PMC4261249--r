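#' @keywords internal
stop_dpcr <- function(message, class, call. = FALSE, ...) {
  stop(structure(
    class = c(class, "dpcr_error", "error", "condition"),
    list(message = message, call = if (call.) sys.call(-1) else NULL, ...)
  ))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

#' Partition counts for a single dPCR replicate
#'
#' Bundles the two numbers the digital readout produces for one reaction:
#' the number of partitions for which a fluorescence result was returned
#' (`n_returned`) and the number of those labelled negative
#' (`k_negative`).  All concentration estimation starts from these counts.
#'
#' @param n_returned Number of partitions with a returned readout; at
#'   least 1.
#' @param k_negative Number of partitions labelled negative; between 0
#'   and `n_returned`.
#' @return An object of class `"dpcr_counts"`.
#' @examples
#' partition_counts(20000, 7358)
#' @seealso [estimate_lambda()], [replicate_set()]
#' @export
partition_counts <- function(n_returned, k_negative) {
  if (!is_count(n_returned) || n_returned < 1)
    stop_dpcr("`n_returned` must be a single integer >= 1", "dpcr_parameter_error")
  if (!is_count(k_negative))
    stop_dpcr("`k_negative` must be a single non-negative integer", "dpcr_parameter_error")
  if (k_negative > n_returned)
    stop_dpcr("`k_negative` cannot exceed `n_returned`", "dpcr_parameter_error")
  structure(
    list(n_returned = as.integer(n_returned), k_negative = as.integer(k_negative)),
    class = "dpcr_counts"
  )
}

#' @export
print.dpcr_counts <- function(x, ...) {
  cat(sprintf("dPCR partition counts: %d returned, %d negative (%.4f negative fraction)\n",
              x$n_returned, x$k_negative, x$k_negative / x$n_returned))
  invisible(x)
}

#' A set of technical replicates
#'
#' Holds the partition counts of `m` technical replicates prepared from
#' the same biological sample, as a data frame with one row per
#' replicate.  Technical replicates share the true concentration but are
#' subject to between-replicate variation (pipette error, sample
#' heterogeneity), which is why pooled and replicate-based uncertainty
#' estimates can differ sharply.
#'
#' @param n_returned Integer vector of returned-partition counts, one
#'   per replicate.
#' @param k_negative Integer vector of negative-partition counts,
#'   parallel to `n_returned`.
#' @param replicate_id Optional identifiers; defaults to `1..m`.  Must
#'   be unique.
#' @return A data frame of class `"dpcr_replicates"` with columns
#'   `replicate_id`, `n_returned`, `k_negative`.
#' @examples
#' replicate_set(n_returned = c(14100, 13900), k_negative = c(5200, 5105))
#' @export
replicate_set <- function(n_returned, k_negative, replicate_id = seq_along(n_returned)) {
  if (length(n_returned) < 1L)
    stop_dpcr("a replicate set needs at least one replicate", "dpcr_parameter_error")
  if (length(k_negative) != length(n_returned) ||
      length(replicate_id) != length(n_returned))
    stop_dpcr("`n_returned`, `k_negative` and `replicate_id` must have equal length",
              "dpcr_parameter_error")
  if (anyDuplicated(replicate_id))
    stop_dpcr("duplicate replicate_id values", "dpcr_parameter_error")
  n <- as.integer(n_returned)
  k <- as.integer(k_negative)
  bad <- which(!is.finite(n_returned) | n_returned != n | n < 1L)
  if (length(bad))
    stop_dpcr(sprintf("replicate '%s': `n_returned` must be an integer >= 1",
                      replicate_id[bad[1]]), "dpcr_parameter_error")
  bad <- which(!is.finite(k_negative) | k_negative != k | k < 0L)
  if (length(bad))
    stop_dpcr(sprintf("replicate '%s': `k_negative` must be a non-negative integer",
                      replicate_id[bad[1]]), "dpcr_parameter_error")
  bad <- which(k > n)
  if (length(bad))
    stop_dpcr(sprintf("replicate '%s': `k_negative` cannot exceed `n_returned`",
                      replicate_id[bad[1]]), "dpcr_parameter_error")
  # built by hand rather than via data.frame(): this constructor sits on
  # the simulator's hot path (once per simulated experiment)
  structure(
    list(replicate_id = replicate_id, n_returned = n, k_negative = k),
    row.names = c(NA_integer_, -length(n)),
    class = c("dpcr_replicates", "data.frame")
  )
}

#' Number of technical replicates in a replicate set
#' @param reps A [replicate_set()].
#' @return Integer, the number of replicates `m`.
#' @export
n_replicates <- function(reps) {
  stopifnot(inherits(reps, "dpcr_replicates"))
  nrow(reps)
}

#' @export
print.dpcr_replicates <- function(x, ...) {
  cat(sprintf("dPCR replicate set (m = %d)\n", nrow(x)))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Partition-volume specification
#'
#' The mean partition volume `v` (nanoliter) used to convert copies per
#' partition into copies per nanoliter.  `v_true` may record the actual
#' mean volume when it is known to deviate from the value assumed in
#' reporting; the difference induces a systematic concentration bias
#' quantified by [volume_bias()].
#'
#' @param v_assumed Mean partition volume (nL) assumed when reporting.
#' @param v_true Optional actual mean volume (nL).
#' @return An object of class `"dpcr_volume"`.
#' @examples
#' volume_spec(0.89, v_true = 0.868)
#' @export
volume_spec <- function(v_assumed, v_true = NULL) {
  if (!is.numeric(v_assumed) || length(v_assumed) != 1L || !is.finite(v_assumed) ||
      v_assumed <= 0)
    stop_dpcr("`v_assumed` must be a single positive number", "dpcr_parameter_error")
  if (!is.null(v_true) &&
      (!is.numeric(v_true) || length(v_true) != 1L || !is.finite(v_true) || v_true <= 0))
    stop_dpcr("`v_true` must be a single positive number when given", "dpcr_parameter_error")
  structure(list(v_assumed = v_assumed, v_true = v_true), class = "dpcr_volume")
}
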
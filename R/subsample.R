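#' Variant-subsampling AUC experiment
#'
#' Addresses the imbalance in variant counts between two PRSs: repeatedly
#' draws `i` variants from the model uniformly without replacement, rescores
#' the cohort with the sub-model, and summarizes the resulting AUC
#' distribution (median, IQR, range). A master seed spawns one substream
#' seed per iteration, so results are reproducible and order-independent.
#'
#' @param model A `prs_model` with at least `i` variants.
#' @param cohort A `cohort_data`.
#' @param i Subset size, `1 <= i <= nrow(model)`.
#' @param iterations Number of random subsets (the reference analysis uses
#'   1000).
#' @param seed Master integer seed.
#' @return A `subsample_summary` list: `i`, `iterations`, `auc_values`,
#'   `median`, `iqr` (25th/75th centiles), `range`, `seed`.
#' @export
subsample_auc <- function(model, cohort, i, iterations = 1000L, seed = 1L) {
  stopifnot(inherits(model, "prs_model"), inherits(cohort, "cohort_data"))
  m <- nrow(model)
  if (i < 1 || i > m)
    stop("i must be between 1 and the model size (", m, ")", call. = FALSE)
  if (iterations < 1) stop("iterations must be >= 1", call. = FALSE)
  al <- .align_model_to_cohort(model, cohort)
  y <- cohort$labels
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max, iterations)
  auc <- numeric(iterations)
  k <- length(al$w)
  for (it in seq_len(iterations)) {
    set.seed(sub_seeds[it])
    # sorted so the dot product accumulates in a fixed column order
    idx <- sort(sample.int(k, min(i, k)))
    s <- as.numeric(al$X[, idx, drop = FALSE] %*% al$w[idx])
    auc[it] <- .auc_rank(s, y)
  }
  q <- stats::quantile(auc, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  structure(list(i = as.integer(i), iterations = as.integer(iterations),
                 auc_values = auc, median = q[2], iqr = c(q[1], q[3]),
                 range = range(auc), seed = as.integer(seed)),
            class = "subsample_summary")
}

#' @export
print.subsample_summary <- function(x, ...) {
  cat(sprintf(
    "Subsampled PRS AUC (i = %d, %d iterations): median %.3f (IQR %.3f-%.3f, range %.3f-%.3f)\n",
    x$i, x$iterations, x$median, x$iqr[1], x$iqr[2], x$range[1], x$range[2]))
  invisible(x)
}
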
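ZONE_LEVELS <- c("EZ", "PZ", "HZ")

#' Classify regions by recovered excitability
#'
#' Applies the epileptogenicity thresholds: a region is epileptogenic (EZ)
#' when `eta > eta_c`, a propagation-zone candidate (PZ) when
#' `eta_c - delta_eta < eta <= eta_c`, and healthy (HZ) otherwise. Ties at
#' a threshold resolve toward the less pathological class (`eta` exactly at
#' `eta_c` is PZ, exactly at `eta_c - delta_eta` is HZ), keeping the strict
#' inequality for the more pathological class.
#'
#' @param eta Numeric excitability vector.
#' @param eta_c Critical excitability.
#' @param delta_eta Width of the PZ band (positive).
#'
#' @return A factor with levels `EZ`, `PZ`, `HZ`.
#' @export
#' @examples
#' classify_regions(c(-1.5, -2.5, -3.5))
classify_regions <- function(eta, eta_c = -2.05, delta_eta = 1.0) {
  stopifnot(all(is.finite(eta)), delta_eta > 0)
  labels <- ifelse(eta > eta_c, "EZ",
                   ifelse(eta > eta_c - delta_eta, "PZ", "HZ"))
  factor(labels, levels = ZONE_LEVELS)
}

#' Confusion matrix and accuracy of zone classification
#'
#' Cross-tabulates true against predicted EZ/PZ/HZ labels and reports the
#' overall (trace) accuracy.
#'
#' @param truth,predicted Vectors of labels over `EZ`/`PZ`/`HZ` (factors or
#'   characters), equal length.
#'
#' @return A `vep_confusion`: list with `counts` (3-by-3 table, rows =
#'   truth) and `accuracy`.
#' @export
#' @examples
#' confusion_and_accuracy(c("EZ", "PZ", "HZ"), c("EZ", "HZ", "HZ"))
confusion_and_accuracy <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    abort("`truth` and `predicted` must have equal length.")
  }
  as_zone <- function(v) {
    v <- as.character(v)
    if (!all(v %in% ZONE_LEVELS)) {
      abort(sprintf("unknown label value(s): %s",
                    paste(setdiff(unique(v), ZONE_LEVELS), collapse = ", ")))
    }
    factor(v, levels = ZONE_LEVELS)
  }
  counts <- table(truth = as_zone(truth), predicted = as_zone(predicted))
  structure(
    list(counts = counts,
         accuracy = sum(diag(counts)) / sum(counts)),
    class = "vep_confusion"
  )
}

#' @export
print.vep_confusion <- function(x, ...) {
  cat(sprintf("<vep_confusion> accuracy %.1f%%\n", 100 * x$accuracy))
  print(x$counts)
  invisible(x)
}

#' @describeIn confusion_and_accuracy Long-format tibble of the confusion
#'   counts.
#' @param x A `vep_confusion`.
#' @param ... Unused.
#' @export
tidy.vep_confusion <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x$counts)) |>
    dplyr::rename(n = "Freq")
}

#' @describeIn confusion_and_accuracy One-row summary with the accuracy.
#' @export
glance.vep_confusion <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, n_regions = sum(x$counts))
}

#' Summarize repeated optimization runs
#'
#' Best, mean, and standard deviation of the per-run best costs, plus the
#' per-run convergence traces for plotting.
#'
#' @param results List of `vep_fit` objects (at least one).
#'
#' @return A list with `best`, `mean`, `sd` (0 with `single_run = TRUE`
#'   when only one run is supplied), and `traces` (tibble with a `run`
#'   column).
#' @export
convergence_report <- function(results) {
  if (length(results) == 0) abort("`results` must contain at least one run.")
  bests <- vapply(results, function(r) r$best_cost, numeric(1))
  traces <- purrr::map_dfr(seq_along(results), function(i) {
    dplyr::mutate(results[[i]]$trace, run = i)
  })
  list(
    best = min(bests),
    mean = mean(bests),
    sd = if (length(bests) > 1) sd(bests) else 0,
    single_run = length(bests) == 1,
    per_run_best = bests,
    traces = traces
  )
}

#' Score a fit against a benchmark's ground truth
#'
#' Classifies the recovered excitabilities with the problem's thresholds
#' and cross-tabulates against the true zone labels.
#'
#' @param fit A `vep_fit` for the problem.
#' @param problem The `vep_problem` that generated the data.
#'
#' @return A `vep_confusion`.
#' @export
score_fit <- function(fit, problem) {
  n <- problem$model$n_regions
  eta_hat <- fit$best_theta[seq_len(n)]
  truth <- problem$truth
  predicted <- classify_regions(
    eta_hat,
    eta_c = attr(truth, "eta_c"),
    delta_eta = attr(truth, "delta_eta")
  )
  confusion_and_accuracy(truth$label, predicted)
}
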
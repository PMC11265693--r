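#' Filter a solution archive by cost quality
#'
#' Keeps the near-optimal slice of an optimizer archive. For deterministic
#' problems entries with `cost <= rel_threshold * best` are retained; for
#' stochastic problems, where the cost itself fluctuates between
#' evaluations, entries with `cost <= best + rel_threshold * sd(cost)` are
#' retained. The best entry is always kept.
#'
#' @param archive Tibble with `theta_*` columns and a `cost` column (the
#'   `archive` element of a `vep_fit`).
#' @param rel_threshold Quality threshold (> 1).
#' @param stochastic Use the additive spread-based rule.
#'
#' @return The filtered archive tibble.
#' @export
filter_archive <- function(archive, rel_threshold = 10, stochastic = FALSE) {
  if (nrow(archive) == 0) abort("`archive` is empty.")
  stopifnot(rel_threshold > 1)
  finite <- is.finite(archive$cost)
  best <- min(archive$cost[finite])
  cut <- if (stochastic) {
    best + rel_threshold * sd(archive$cost[finite])
  } else {
    rel_threshold * best
  }
  keep <- finite & (archive$cost <= cut | archive$cost == best)
  archive[keep, , drop = FALSE]
}

theta_matrix <- function(archive) {
  as.matrix(archive[, grep("^theta_", names(archive)), drop = FALSE])
}

#' Representative subsample of an archive
#'
#' Farthest-point (greedy max-min distance) subsampling in
#' bounds-normalized parameter space, anchored at the best-cost entry, so a
#' small ensemble still spans the explored near-optimal region.
#'
#' @param archive Archive tibble (see [filter_archive()]).
#' @param target_n Desired ensemble size.
#' @param bounds List with `lower`/`upper` used for normalization.
#'
#' @return An archive tibble with `min(target_n, nrow(archive))` rows.
#' @export
subsample_representative <- function(archive, target_n = 500, bounds) {
  stopifnot(target_n >= 1)
  if (nrow(archive) <= target_n) return(archive)
  b <- as_bounds(bounds)
  X <- theta_matrix(archive)
  norm <- sweep(sweep(X, 2, b$lower, "-"), 2, b$upper - b$lower, "/")
  sel <- which.min(archive$cost)
  dmin <- sqrt(rowSums(sweep(norm, 2, norm[sel, ], "-")^2))
  while (length(sel) < target_n) {
    pick <- which.max(dmin)
    sel <- c(sel, pick)
    d_new <- sqrt(rowSums(sweep(norm, 2, norm[pick, ], "-")^2))
    dmin <- pmin(dmin, d_new)
  }
  archive[sel, , drop = FALSE]
}

#' Per-parameter percentile bands of an ensemble
#'
#' Normalizes every archived parameter vector to `[0, 1]` by the estimation
#' bounds and reports empirical percentiles per parameter — the parallel-
#' coordinates uncertainty summary, with the median as the central line.
#'
#' @param archive Archive tibble.
#' @param bounds List with `lower`/`upper`.
#' @param percentiles Ascending percentile levels (default 5, 25, 50, 75,
#'   95).
#'
#' @return A `uq_bands` tibble with columns `parameter`, `percentile`, and
#'   `value` (normalized); attribute `n_members` records the ensemble size.
#' @export
percentile_bands <- function(archive, bounds,
                             percentiles = c(5, 25, 50, 75, 95)) {
  if (nrow(archive) == 0) abort("`archive` is empty.")
  if (is.unsorted(percentiles)) abort("`percentiles` must be sorted.")
  b <- as_bounds(bounds)
  if (any(b$upper == b$lower)) abort("degenerate bounds (upper == lower).")
  X <- theta_matrix(archive)
  norm <- sweep(sweep(X, 2, b$lower, "-"), 2, b$upper - b$lower, "/")
  out <- purrr::map_dfr(seq_len(ncol(norm)), function(p) {
    q <- quantile(norm[, p], probs = percentiles / 100, names = FALSE)
    tibble::tibble(parameter = p, percentile = percentiles, value = q)
  })
  attr(out, "n_members") <- nrow(norm)
  class(out) <- c("uq_bands", class(out))
  out
}

#' Median band width of an uncertainty summary
#'
#' Width between a low and a high percentile per parameter, summarized by
#' the median across parameters — the package's scalar measure for
#' comparing estimation uncertainty between problems.
#'
#' @param bands A `uq_bands` tibble.
#' @param low,high Percentile pair delimiting the band.
#'
#' @return Scalar median band width (normalized units).
#' @export
band_width <- function(bands, low = 5, high = 95) {
  w <- bands |>
    dplyr::filter(.data$percentile %in% c(low, high)) |>
    tidyr::pivot_wider(names_from = "percentile", values_from = "value",
                       names_prefix = "p") |>
    dplyr::mutate(width = .data[[paste0("p", high)]] -
                    .data[[paste0("p", low)]])
  median(w$width)
}
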
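#' Sensor/source geometry for the SEEG forward problem
#'
#' Collects depth-electrode sensor positions and the triangulated-surface
#' vertices (with areas) of each brain region, from which [build_gain_matrix()]
#' computes the inverse-square lead field.
#'
#' @param sensors Data frame or matrix of sensor positions with columns
#'   `x`, `y`, `z` (mm); one row per sensor.
#' @param vertices Data frame with columns `region` (integer region index),
#'   `x`, `y`, `z` (mm), and `area` (mm^2), one row per surface vertex.
#' @param n_regions Number of regions; defaults to `max(vertices$region)`.
#' @param scale_c Positive scaling coefficient `c` of the lead field.
#'
#' @return An object of class `sensor_geometry`.
#' @export
sensor_geometry <- function(sensors, vertices, n_regions = NULL, scale_c = 1) {
  sensors <- as.data.frame(sensors)
  if (!all(c("x", "y", "z") %in% names(sensors))) {
    colnames(sensors)[seq_len(3)] <- c("x", "y", "z")
  }
  vertices <- as.data.frame(vertices)
  stopifnot(
    all(c("region", "x", "y", "z", "area") %in% names(vertices)),
    nrow(sensors) >= 1, scale_c > 0
  )
  if (any(vertices$area <= 0)) abort("all vertex areas must be positive.")
  n_regions <- n_regions %||% max(vertices$region)
  present <- sort(unique(vertices$region))
  if (!setequal(present, seq_len(n_regions))) {
    abort("every region must have at least one vertex.")
  }
  structure(
    list(
      sensors = sensors[, c("x", "y", "z")],
      vertices = vertices[, c("region", "x", "y", "z", "area")],
      n_regions = n_regions,
      scale_c = scale_c
    ),
    class = "sensor_geometry"
  )
}

#' Build an inverse-square gain (lead-field) matrix
#'
#' Each entry sums the area-weighted inverse-square decay over the vertices
#' of a region:
#' \deqn{G_{ij} = \sum_{k \in V_j} \frac{c\, A_k}{|x^s_i - x^v_k|^2}.}
#' Orientation-dependent decay is deliberately not modelled. The matrix is
#' flagged rank-deficient when its numerical rank falls below the number of
#' regions, which is always the case for sparse implantations with fewer
#' sensors than regions.
#'
#' @param geometry A [sensor_geometry()].
#'
#' @return A `gain_matrix`: list with `values` (sensors-by-regions matrix)
#'   and `rank_deficient` (logical).
#' @export
build_gain_matrix <- function(geometry) {
  stopifnot(inherits(geometry, "sensor_geometry"))
  sp <- as.matrix(geometry$sensors)
  vt <- geometry$vertices
  n_s <- nrow(sp)
  n_n <- geometry$n_regions
  G <- matrix(0, n_s, n_n)
  vp <- as.matrix(vt[, c("x", "y", "z")])
  for (i in seq_len(n_s)) {
    d2 <- (vp[, 1] - sp[i, 1])^2 + (vp[, 2] - sp[i, 2])^2 +
      (vp[, 3] - sp[i, 3])^2
    if (any(d2 == 0)) {
      k <- which(d2 == 0)[1]
      abort(sprintf(
        "sensor %d coincides with vertex %d of region %d (zero distance)",
        i, k, vt$region[k]
      ), class = "vepfit_degenerate_geometry")
    }
    w <- geometry$scale_c * vt$area / d2
    G[i, ] <- vapply(seq_len(n_n), function(j) sum(w[vt$region == j]),
                     numeric(1))
  }
  gain_matrix(G)
}

#' Wrap a numeric matrix as a gain matrix
#'
#' @param values Sensors-by-regions non-negative numeric matrix.
#' @return A `gain_matrix` with the rank-deficiency flag computed.
#' @export
gain_matrix <- function(values) {
  values <- as.matrix(values)
  stopifnot(all(is.finite(values)), all(values >= 0))
  structure(
    list(
      values = unname(values),
      rank_deficient = qr(values)$rank < ncol(values)
    ),
    class = "gain_matrix"
  )
}

#' @export
print.gain_matrix <- function(x, ...) {
  cat(sprintf(
    "<gain_matrix> %d sensors x %d regions%s\n",
    nrow(x$values), ncol(x$values),
    if (x$rank_deficient) " (rank-deficient)" else ""
  ))
  invisible(x)
}

#' Assemble a sensor series from a time vector and signal matrix
#'
#' @param times Length-T numeric time vector.
#' @param signals T-by-channels numeric matrix.
#' @return A `sensor_series` tibble with columns `time` and `s_<channel>`.
#' @export
sensor_series_from_matrix <- function(times, signals) {
  signals <- as.matrix(signals)
  stopifnot(length(times) == nrow(signals))
  m <- ncol(signals)
  out <- tibble::as_tibble(cbind(time = times, signals),
                           .name_repair = "minimal")
  names(out) <- c("time", paste0("s_", seq_len(m)))
  class(out) <- c("sensor_series", class(out))
  out
}

new_sensor_series <- sensor_series_from_matrix

#' Extract the channel matrix of a sensor series
#'
#' @param series A `sensor_series` (or any tibble with `s_*` columns).
#' @return A numeric matrix, time points by channels.
#' @export
series_matrix <- function(series) {
  as.matrix(series[, grep("^s_", names(series))])
}

#' Project source activity to SEEG sensors
#'
#' Applies the exponential observation model
#' \eqn{S_i(t) = \sum_j G_{ij} \exp(x_j(t))} to the fast variable of a
#' trajectory, optionally adding zero-mean Gaussian measurement noise.
#'
#' @param traj A `vep_trajectory` from [simulate_ode()]/[simulate_sde()].
#' @param gain A [gain_matrix()] whose column count matches the regions.
#' @param obs_noise_std Measurement noise standard deviation (0 =
#'   deterministic projection).
#' @param seed Integer seed for the measurement noise (required when
#'   `obs_noise_std > 0`).
#'
#' @return A `sensor_series` tibble with columns `time` and `s_<channel>`.
#' @export
project_to_sensors <- function(traj, gain, obs_noise_std = 0, seed = NULL) {
  stopifnot(inherits(gain, "gain_matrix"))
  X <- trajectory_matrix(traj, "x")
  if (ncol(gain$values) != ncol(X)) {
    abort(sprintf(
      "gain has %d regions but the trajectory has %d",
      ncol(gain$values), ncol(X)
    ))
  }
  S <- exp(X) %*% t(gain$values)
  if (obs_noise_std > 0) {
    if (!is.null(seed)) set.seed(seed)
    S <- S + matrix(rnorm(length(S), sd = obs_noise_std), nrow(S), ncol(S))
  }
  new_sensor_series(traj$time, S)
}

#' Sliding-window RMS envelope of sensor signals
#'
#' Per-channel root-mean-square of the locally mean-removed signal over a
#' centred window (truncated at the edges), on the same sampling grid. Used
#' to visualize seizure envelopes and optionally as cost preprocessing.
#'
#' @param series A `sensor_series`.
#' @param window Positive integer window length in samples (at most the
#'   series length).
#'
#' @return A `sensor_series` of identical shape containing the envelope.
#' @export
seeg_envelope <- function(series, window) {
  S <- series_matrix(series)
  t_len <- nrow(S)
  if (window < 1) abort("`window` must be a positive integer.")
  if (window > t_len) abort("`window` exceeds the series length.")
  half <- window %/% 2
  idx <- seq_len(t_len)
  lo <- pmax(idx - half, 1L)
  hi <- pmin(idx + half, t_len)
  len <- hi - lo + 1
  env <- apply(S, 2, function(s) {
    c1 <- c(0, cumsum(s))
    c2 <- c(0, cumsum(s^2))
    sum1 <- c1[hi + 1] - c1[lo]
    sum2 <- c2[hi + 1] - c2[lo]
    v <- sum2 / len - (sum1 / len)^2
    sqrt(pmax(v, 0))
  })
  new_sensor_series(series$time, env)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
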
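#' Construct a 2D Epileptor network model
#'
#' Bundles everything needed to simulate the two-variable reduction of the
#' Epileptor neural mass model on a structural connectome. Each brain region
#' `i` carries a fast variable `x_i` and a slow permittivity variable `z_i`
#' evolving as
#' \deqn{\dot x_i = 1 - x_i^3 - 2 x_i^2 - z_i + I}
#' \deqn{\dot z_i = \frac{1}{\tau}\left(4 (x_i - \eta_i) - z_i -
#'       K \sum_j C_{ij} (x_j - x_i)\right)}
#' where \eqn{\eta_i} is the per-region excitability (the Hopf bifurcation
#' parameter), `K` the global coupling on the connectome `C`, `I` the
#' constant input current, and \eqn{\tau} the time-scale separation that
#' sets the seizure length.
#'
#' @param connectome Square, non-negative numeric matrix of structural
#'   connection weights (row = source region). Conventionally normalized so
#'   the maximum entry is 1.
#' @param excitability Numeric vector \eqn{\eta_i}, one entry per region.
#' @param coupling Non-negative scalar `K` scaling the permittivity coupling.
#' @param tau Positive time-scale separation \eqn{\tau} (model time units).
#' @param current Input current `I`; 3.1 places an isolated region near the
#'   seizure threshold at \eqn{\eta \approx -2.05}.
#' @param dt Euler integration step, in the same dimensionless model time
#'   units as `tau` and simulation durations.
#' @param x0,z0 Initial condition for every region (scalars, or length-`N`
#'   vectors for per-region values).
#' @param noise_std Standard deviation \eqn{\sigma} of the Gaussian process
#'   noise entering both state equations (0 gives deterministic dynamics).
#' @param obs_noise_std Standard deviation \eqn{\sigma'} of additive
#'   measurement noise applied when projecting to sensors.
#'
#' @return An object of class `vep_model`.
#' @seealso [simulate_ode()], [simulate_sde()], [vep_drift()]
#' @export
#' @examples
#' C <- matrix(0, 2, 2)
#' m <- vep_model(C, excitability = c(-1.6, -3.5), coupling = 0)
#' m
vep_model <- function(connectome, excitability, coupling = 0, tau = 10,
                      current = 3.1, dt = 0.1, x0 = -2.5, z0 = 3.5,
                      noise_std = 0, obs_noise_std = 0) {
  connectome <- as.matrix(connectome)
  if (nrow(connectome) != ncol(connectome)) {
    abort("`connectome` must be a square matrix.")
  }
  n <- nrow(connectome)
  if (any(!is.finite(connectome)) || any(connectome < 0)) {
    abort("`connectome` entries must be finite and non-negative.")
  }
  if (length(excitability) != n) {
    abort(sprintf(
      "`excitability` has length %d but the connectome has %d regions.",
      length(excitability), n
    ))
  }
  stopifnot(
    is.numeric(excitability), all(is.finite(excitability)),
    length(coupling) == 1, coupling >= 0,
    length(tau) == 1, tau > 0,
    length(dt) == 1, dt > 0,
    length(current) == 1, is.finite(current),
    noise_std >= 0, obs_noise_std >= 0
  )
  x0 <- rep_len(as.numeric(x0), n)
  z0 <- rep_len(as.numeric(z0), n)
  structure(
    list(
      n_regions = n,
      connectome = unname(connectome),
      excitability = as.numeric(excitability),
      coupling = as.numeric(coupling),
      tau = as.numeric(tau),
      current = as.numeric(current),
      dt = as.numeric(dt),
      x0 = x0,
      z0 = z0,
      noise_std = as.numeric(noise_std),
      obs_noise_std = as.numeric(obs_noise_std)
    ),
    class = "vep_model"
  )
}

#' @export
print.vep_model <- function(x, ...) {
  cat(sprintf(
    "<vep_model> %d regions | K = %g, tau = %g, I = %g, dt = %g | sigma = %g\n",
    x$n_regions, x$coupling, x$tau, x$current, x$dt, x$noise_std
  ))
  cat(sprintf(
    "  excitability in [%.3g, %.3g]\n",
    min(x$excitability), max(x$excitability)
  ))
  invisible(x)
}

is_vep_model <- function(x) inherits(x, "vep_model")
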
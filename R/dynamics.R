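#' Evaluate the Epileptor network drift field
#'
#' Computes the deterministic right-hand side of the 2D Epileptor network
#' equations at a given state.
#'
#' @param model A [vep_model()].
#' @param x,z Numeric state vectors, one entry per region.
#'
#' @return A list with components `dx` and `dz` (numeric vectors).
#' @export
#' @examples
#' m <- vep_model(matrix(0, 1, 1), excitability = -1.6)
#' vep_drift(m, x = -2.5, z = 3.5)
vep_drift <- function(model, x, z) {
  stopifnot(is_vep_model(model))
  n <- model$n_regions
  if (length(x) != n || length(z) != n) {
    abort(sprintf(
      "state vectors must have length %d (got %d and %d)",
      n, length(x), length(z)
    ))
  }
  dx <- 1 - x^3 - 2 * x^2 - z + model$current
  coupling_term <- if (model$coupling != 0) {
    drop(model$connectome %*% x) - rowSums(model$connectome) * x
  } else {
    0
  }
  dz <- (4 * (x - model$excitability) - z - model$coupling * coupling_term) /
    model$tau
  list(dx = as.numeric(dx), dz = as.numeric(dz))
}

new_trajectory <- function(times, x, z) {
  n <- ncol(x)
  out <- tibble::as_tibble(cbind(time = times, x, z), .name_repair = "minimal")
  names(out) <- c("time", paste0("x_", seq_len(n)), paste0("z_", seq_len(n)))
  attr(out, "n_regions") <- n
  class(out) <- c("vep_trajectory", class(out))
  out
}

simulate_core <- function(model, duration, sigma, store_every = 1L) {
  stopifnot(is_vep_model(model), duration >= model$dt, store_every >= 1)
  n_steps <- floor(duration / model$dt)
  res <- sim_vep_cpp(
    model$connectome, model$excitability, model$coupling, model$tau,
    model$current, model$dt, as.integer(n_steps), model$x0, model$z0,
    sigma, as.integer(store_every)
  )
  if (res$diverged_step >= 0) {
    abort(sprintf(
      "integration diverged at step %d (state magnitude exceeded 1e6)",
      res$diverged_step
    ), class = "vepfit_diverged")
  }
  times <- model$dt * store_every * (seq_len(nrow(res$x)) - 1)
  new_trajectory(times, res$x, res$z)
}

#' Simulate the deterministic Epileptor network
#'
#' Integrates the noise-free model with a forward-Euler scheme at the model's
#' step `dt`, starting every region from its `(x0, z0)` initial condition.
#'
#' @param model A [vep_model()] with `noise_std = 0`.
#' @param duration Simulation length in model time units (at least `dt`).
#' @param store_every Keep every `store_every`-th step (1 = full resolution).
#'
#' @return A `vep_trajectory` tibble with columns `time`, `x_<region>`, and
#'   `z_<region>`; `floor(duration/dt) + 1` rows at full resolution.
#' @export
#' @examples
#' m <- vep_model(matrix(0, 1, 1), excitability = -1.6)
#' traj <- simulate_ode(m, duration = 100)
#' head(traj)
simulate_ode <- function(model, duration, store_every = 1L) {
  if (model$noise_std > 0) {
    abort("`model` has process noise; use simulate_sde() for stochastic runs.")
  }
  simulate_core(model, duration, sigma = 0, store_every = store_every)
}

#' Simulate the stochastic Epileptor network
#'
#' Euler-Maruyama integration: the deterministic Euler increment plus
#' `noise_std * sqrt(dt) * N(0, 1)` added independently to both state
#' equations of every region. With `noise_std = 0` the result is bitwise
#' identical to [simulate_ode()].
#'
#' @inheritParams simulate_ode
#' @param model A [vep_model()]; its `noise_std` sets the noise level.
#' @param seed Integer seed making the noise path reproducible.
#'
#' @return A `vep_trajectory` tibble (see [simulate_ode()]).
#' @export
simulate_sde <- function(model, duration, seed, store_every = 1L) {
  set.seed(seed)
  simulate_core(model, duration, sigma = model$noise_std,
                store_every = store_every)
}

#' Extract state matrices from a trajectory
#'
#' @param traj A `vep_trajectory`.
#' @param var `"x"` (fast variable) or `"z"` (slow variable).
#' @return A numeric matrix, time points by regions.
#' @export
trajectory_matrix <- function(traj, var = c("x", "z")) {
  var <- match.arg(var)
  cols <- grep(paste0("^", var, "_"), names(traj))
  as.matrix(traj[, cols])
}

#' Fixed points and linear stability of an isolated region
#'
#' For an uncoupled region, fixed points solve the nullcline intersection
#' `1 - x^3 - 2x^2 + I - 4(x - eta) = 0` with `z = 4(x - eta)`. Each root is
#' classified through the trace and determinant of the 2-by-2 Jacobian
#' `[[-3x^2 - 4x, -1], [4/tau, -1/tau]]`. A fixed point exactly at the Hopf
#' margin (trace within 1e-9 of zero) is labelled unstable, breaking ties
#' toward seizure onset.
#'
#' @param eta Excitability of the region.
#' @param current Input current `I`.
#' @param tau Time-scale separation used in the Jacobian.
#'
#' @return A tibble with one row per fixed point: `x`, `z`, `trace`,
#'   `determinant`, and `stability` (`"stable"` or `"unstable"`).
#' @export
#' @examples
#' isolated_fixed_points(eta = -3.025)
isolated_fixed_points <- function(eta, current = 3.1, tau = 10) {
  stopifnot(is.finite(eta), is.finite(current), tau > 0)
  # ascending coefficients of 1 + I + 4*eta - 4x - 2x^2 - x^3
  coefs <- c(1 + current + 4 * eta, -4, -2, -1)
  roots <- polyroot(coefs)
  x <- Re(roots[abs(Im(roots)) < 1e-8])
  # Newton polish so nullcline residuals are < 1e-9
  for (k in 1:4) {
    f <- coefs[1] + coefs[2] * x + coefs[3] * x^2 + coefs[4] * x^3
    fp <- coefs[2] + 2 * coefs[3] * x + 3 * coefs[4] * x^2
    x <- x - f / fp
  }
  x <- sort(unique(x))
  z <- 4 * (x - eta)
  j11 <- -3 * x^2 - 4 * x
  tr <- j11 - 1 / tau
  det <- (4 - j11) / tau
  stable <- det > 0 & tr < -1e-9
  tibble::tibble(
    x = x, z = z, trace = tr, determinant = det,
    stability = ifelse(stable, "stable", "unstable")
  )
}

#' Critical excitability of an isolated region
#'
#' Sweeps an excitability grid for an uncoupled region and locates the
#' smallest \eqn{\eta} at which no stable fixed point remains (the Hopf
#' bifurcation where autonomous seizures appear), then refines the crossing
#' by bisection.
#'
#' @param model A [vep_model()] with `coupling = 0`; supplies `tau` and the
#'   input current.
#' @param eta_grid Ascending excitability grid spanning the bifurcation
#'   (default covers `[-2.2, -1.9]`).
#' @param tol Bisection resolution on \eqn{\eta}.
#'
#' @return The critical excitability \eqn{\eta_c} (numeric scalar).
#' @export
#' @examples
#' m <- vep_model(matrix(0, 1, 1), excitability = -2, tau = 40)
#' critical_excitability(m)
critical_excitability <- function(model,
                                  eta_grid = seq(-2.2, -1.9, by = 0.01),
                                  tol = 1e-3) {
  stopifnot(is_vep_model(model))
  if (model$coupling != 0) {
    abort("`critical_excitability` analyses an isolated region: set coupling = 0.")
  }
  if (is.unsorted(eta_grid, strictly = TRUE)) {
    abort("`eta_grid` must be strictly ascending.")
  }
  has_stable <- vapply(eta_grid, function(e) {
    any(isolated_fixed_points(e, model$current, model$tau)$stability == "stable")
  }, logical(1))
  if (all(has_stable) || !has_stable[1]) {
    abort("`eta_grid` does not bracket a stability change.",
          class = "vepfit_no_bifurcation")
  }
  i <- which(!has_stable)[1]
  lo <- eta_grid[i - 1] # stable
  hi <- eta_grid[i]     # unstable
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    st <- any(isolated_fixed_points(mid, model$current, model$tau)$stability ==
                "stable")
    if (st) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
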
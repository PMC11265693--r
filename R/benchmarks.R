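#' Synthesize a structural connectome
#'
#' Draws symmetric, zero-diagonal, heavy-tailed (log-normal) connection
#' weights — emulating the skewed fibre-count distributions of tractography
#' connectomes — and rescales so the maximum entry is exactly 1.
#'
#' @param n_regions Number of regions (at least 2).
#' @param seed Integer seed; the same seed reproduces the same matrix.
#'
#' @return A square numeric matrix.
#' @export
#' @examples
#' C <- synth_connectome(12, seed = 7)
#' max(C) # exactly 1
synth_connectome <- function(n_regions, seed) {
  if (n_regions < 2) abort("`n_regions` must be at least 2.")
  set.seed(seed)
  C <- matrix(0, n_regions, n_regions)
  up <- upper.tri(C)
  C[up] <- exp(rnorm(sum(up), mean = 0, sd = 1))
  C <- C + t(C)
  C / max(C)
}

# excitability draw bands per zone; margins keep draws away from both
# classification thresholds
ETA_BANDS <- list(
  EZ = c(-1.9, -1.5),
  PZ = c(-2.4, -2.1),
  HZ = c(-3.8, -3.2)
)

#' Synthesize a ground-truth epileptogenicity map
#'
#' Randomly places epileptogenic (EZ), propagation (PZ), and healthy (HZ)
#' regions and draws each region's excitability from its zone's band:
#' EZ above the critical value \eqn{\eta_c}, PZ within \eqn{\Delta\eta}
#' below it, HZ further below.
#'
#' @param n_regions Number of regions.
#' @param n_ez,n_pz Number of EZ and PZ regions (the remainder is HZ).
#' @param seed Integer seed.
#' @param eta_c Critical excitability separating EZ from PZ.
#' @param delta_eta Width of the PZ band below `eta_c`.
#'
#' @return An `epi_map` tibble with columns `region`, `label` (factor with
#'   levels EZ/PZ/HZ), and `eta`; `eta_c` and `delta_eta` are kept as
#'   attributes.
#' @export
#' @examples
#' synth_truth_map(12, n_ez = 2, n_pz = 3, seed = 7)
synth_truth_map <- function(n_regions, n_ez = 2, n_pz = 3, seed,
                            eta_c = -2.05, delta_eta = 1.0) {
  stopifnot(n_ez >= 0, n_pz >= 0)
  if (n_ez + n_pz > n_regions) abort("n_ez + n_pz exceeds n_regions.")
  if (delta_eta <= 0) abort("`delta_eta` must be positive.")
  set.seed(seed)
  labels <- rep("HZ", n_regions)
  picked <- sample.int(n_regions, n_ez + n_pz)
  labels[head(picked, n_ez)] <- "EZ"
  labels[tail(picked, n_pz)] <- "PZ"
  eta <- numeric(n_regions)
  for (zone in names(ETA_BANDS)) {
    k <- labels == zone
    eta[k] <- runif(sum(k), ETA_BANDS[[zone]][1], ETA_BANDS[[zone]][2])
  }
  out <- tibble::tibble(
    region = seq_len(n_regions),
    label = factor(labels, levels = c("EZ", "PZ", "HZ")),
    eta = eta
  )
  attr(out, "eta_c") <- eta_c
  attr(out, "delta_eta") <- delta_eta
  class(out) <- c("epi_map", class(out))
  out
}

#' Synthesize sensor/vertex geometry for an SEEG implantation
#'
#' Emulates a parcellated cortical sheet: region seed directions are spread
#' over a sphere of radius 60 mm and each region is an extended surface
#' patch — its vertices scatter tangentially around the seed direction with
#' an angular spread matching parcel sizes of a few thousand square
#' millimetres, and vertex areas sum to the patch area. Depth-electrode
#' contacts sit inside the sphere and follow an implantation-planning rule:
#' each contact is placed along the direction of the region currently least
#' covered by the montage (coverage measured by summed inverse-square
#' proximity), at 60-90% of the cortical radius, emulating montages planned
#' so no region is left unobserved. The resulting gain keeps the
#' inverse-square, rank-deficient character of sparse SEEG sensing while
#' every extended region retains appreciable visibility.
#'
#' @param n_regions,n_sensors Counts of regions and sensors.
#' @param seed Integer seed.
#' @param vertices_per_region Surface vertices per region patch.
#' @param radius Cortical sphere radius (mm).
#' @param patch_spread Tangential angular spread (radians) of a region's
#'   vertices around its seed direction.
#'
#' @return A [sensor_geometry()].
#' @export
synth_geometry <- function(n_regions, n_sensors, seed,
                           vertices_per_region = 6, radius = 60,
                           patch_spread = 0.35) {
  set.seed(seed)
  unit <- function(v) v / sqrt(sum(v^2))
  seed_dirs <- t(apply(matrix(rnorm(3 * n_regions), ncol = 3), 1, unit))
  vt <- do.call(rbind, lapply(seq_len(n_regions), function(j) {
    k <- vertices_per_region
    pts <- t(vapply(seq_len(k), function(i) {
      unit(seed_dirs[j, ] + rnorm(3, sd = patch_spread)) * radius
    }, numeric(3)))
    data.frame(
      region = j, x = pts[, 1], y = pts[, 2], z = pts[, 3],
      area = runif(k, 250, 400)
    )
  }))
  centres <- t(vapply(seq_len(n_regions), function(j) {
    colMeans(as.matrix(vt[vt$region == j, c("x", "y", "z")]))
  }, numeric(3)))
  sensors <- matrix(NA_real_, n_sensors, 3)
  covered <- rep(0, n_regions)
  for (i in seq_len(n_sensors)) {
    target <- which.min(covered)
    depth <- runif(1, 0.6, 0.9)
    sensors[i, ] <- unit(centres[target, ] + rnorm(3, sd = 5)) *
      (depth * radius)
    covered <- covered + 1 / rowSums(sweep(centres, 2, sensors[i, ])^2)
  }
  sensors <- as.data.frame(sensors)
  names(sensors) <- c("x", "y", "z")
  sensor_geometry(sensors, vt, n_regions = n_regions)
}

#' Plan an SEEG montage with a conditioning floor
#'
#' Draws candidate implantations from [synth_geometry()] and keeps the
#' first whose gain matrix has a relative smallest singular value of at
#' least `min_relative_sv` — montages below the floor leave some regions
#' mutually indistinguishable at the sensors, which a clinical implantation
#' planner would reject. If no candidate passes, the best-conditioned one
#' is returned. Deterministic given `seed`.
#'
#' @param n_regions,n_sensors Counts of regions and sensors.
#' @param seed Integer seed.
#' @param min_relative_sv Conditioning floor on `sv_min / sv_max` of the
#'   gain matrix.
#' @param max_draws Maximum candidate montages drawn.
#'
#' @return A [gain_matrix()].
#' @export
plan_montage <- function(n_regions, n_sensors, seed,
                         min_relative_sv = 0.1, max_draws = 25L) {
  best_g <- NULL
  best_sv <- -Inf
  for (attempt in seq_len(max_draws) - 1L) {
    g <- build_gain_matrix(
      synth_geometry(n_regions, n_sensors, seed = seed + 7919L * attempt)
    )
    sv <- svd(g$values)$d
    rel <- sv[length(sv)] / sv[1]
    if (rel >= min_relative_sv) return(g)
    if (rel > best_sv) {
      best_sv <- rel
      best_g <- g
    }
  }
  best_g
}

# default study conditions per benchmark problem id
PROBLEM_DEFAULTS <- list(
  coupling_weak = 0.1,
  coupling_strong = 1.5,
  background_scale = 2.4, # background coupling ~ background_scale / n_regions
  tau_ode = 10,
  tau_sde = 90,
  duration_ode = 100,
  duration_sde = 900,
  noise_sde = 0.1,
  store_every = 10L,
  eta_bounds = c(-5, -1),
  K_bounds = c(0, 2)
)

#' Benchmark connectome with a seizure-spread pathway
#'
#' Diffusive permittivity coupling is homogenizing: in a dense network the
#' drag from the many quiescent regions suppresses seizure activity before
#' any propagation-zone region can be recruited. The benchmark connectome
#' therefore emulates an epileptogenic network: a heavy-tailed background
#' connectome (from [synth_connectome()]) scaled by `1/n_regions` so total
#' background input per region stays bounded with network size, plus one
#' maximal-weight edge wiring each PZ region to an EZ region (assigned
#' round-robin) — the designated propagation pathway. The maximum entry
#' remains exactly 1.
#'
#' @param n_regions Number of regions.
#' @param seed Seed forwarded to [synth_connectome()].
#' @param truth An `epi_map` giving the EZ/PZ placement.
#' @return A square numeric matrix with maximum entry 1.
#' @export
problem_connectome <- function(n_regions, seed, truth) {
  C <- synth_connectome(n_regions, seed) *
    (PROBLEM_DEFAULTS$background_scale / n_regions)
  ez <- which(truth$label == "EZ")
  pz <- which(truth$label == "PZ")
  if (length(ez) > 0 && length(pz) > 0) {
    for (i in seq_along(pz)) {
      e <- ez[(i - 1) %% length(ez) + 1]
      C[pz[i], e] <- 1
      C[e, pz[i]] <- 1
    }
  } else {
    C <- C / max(C)
  }
  C
}

#' Assemble one of the six benchmark estimation problems
#'
#' Builds the ground-truth model, gain matrix, and observed dataset for a
#' benchmark id:
#' problems 1-2 are deterministic with weak coupling (no seizure
#' propagation), 3-4 deterministic with strong coupling (PZ recruitment),
#' and 5-6 stochastic with strong coupling and a large time-scale
#' separation (stiff, long seizure envelopes). Odd ids observe at the
#' source level (identity gain); even ids observe at the sensor level
#' through a rank-deficient synthetic gain.
#'
#' @param problem_id Integer 1-6.
#' @param n_regions Number of regions.
#' @param seed Integer seed controlling connectome, truth map, geometry, and
#'   (for stochastic problems) the recorded observation noise.
#' @param n_ez,n_pz EZ/PZ counts for the truth map.
#' @param n_sensors Sensor count for sensor-level problems (default keeps
#'   the implantation sparse: about 60 sensors per 84 regions).
#' @param coupling,tau,duration,noise_std Optional overrides of the
#'   per-problem defaults.
#' @param store_every Observation downsampling (every `store_every`-th
#'   Euler step is recorded).
#' @param cost_mode `"raw"` compares raw sensor series; `"envelope"`
#'   compares RMS envelopes.
#'
#' @return A list with elements `problem` (a `vep_problem`) and `observed`
#'   (a `vep_observed` tibble of the recorded series).
#' @export
#' @examples
#' pb <- make_problem(1, n_regions = 6, seed = 1, n_ez = 1, n_pz = 1,
#'                    duration = 200)
#' pb$problem
make_problem <- function(problem_id, n_regions = 84, seed = 1,
                         n_ez = 2, n_pz = 3, n_sensors = NULL,
                         coupling = NULL, tau = NULL, duration = NULL,
                         noise_std = NULL, store_every = NULL,
                         cost_mode = c("raw", "envelope")) {
  if (!problem_id %in% 1:6) abort("`problem_id` must be in 1..6.")
  cost_mode <- match.arg(cost_mode)
  d <- PROBLEM_DEFAULTS
  weak <- problem_id %in% 1:2
  stochastic <- problem_id %in% 5:6
  sensor_level <- problem_id %% 2 == 0

  coupling <- coupling %||% if (weak) d$coupling_weak else d$coupling_strong
  tau <- tau %||% if (stochastic) d$tau_sde else d$tau_ode
  duration <- duration %||% if (stochastic) d$duration_sde else d$duration_ode
  noise_std <- noise_std %||% if (stochastic) d$noise_sde else 0
  store_every <- store_every %||% d$store_every

  truth <- synth_truth_map(n_regions, n_ez = n_ez, n_pz = n_pz,
                           seed = seed + 1L)
  C <- problem_connectome(n_regions, seed, truth)
  model <- vep_model(C, excitability = truth$eta, coupling = coupling,
                     tau = tau, noise_std = noise_std)

  if (sensor_level) {
    n_sensors <- n_sensors %||% max(2L, round(n_regions * 60 / 84))
    gain <- plan_montage(n_regions, n_sensors, seed = seed + 2L)
  } else {
    gain <- gain_matrix(diag(n_regions))
  }

  obs_seed <- seed + 3L
  traj <- if (stochastic) {
    simulate_sde(model, duration, seed = obs_seed, store_every = store_every)
  } else {
    simulate_ode(model, duration, store_every = store_every)
  }
  series <- project_to_sensors(traj, gain)

  observed <- series
  attr(observed, "level") <- if (sensor_level) "sensor" else "source"
  attr(observed, "generator_seed") <- obs_seed
  attr(observed, "problem_id") <- problem_id
  class(observed) <- c("vep_observed", class(observed))

  problem <- structure(
    list(
      problem_id = problem_id,
      observation_level = if (sensor_level) "sensor" else "source",
      coupling_regime = if (weak) "weak" else "strong",
      stochastic = stochastic,
      model = model,
      gain = gain,
      truth = truth,
      K_true = coupling,
      duration = duration,
      store_every = as.integer(store_every),
      bounds = list(
        lower = c(rep(d$eta_bounds[1], n_regions), d$K_bounds[1]),
        upper = c(rep(d$eta_bounds[2], n_regions), d$K_bounds[2])
      ),
      cost_mode = cost_mode,
      seed = seed
    ),
    class = "vep_problem"
  )
  list(problem = problem, observed = observed)
}

#' @export
print.vep_problem <- function(x, ...) {
  cat(sprintf(
    "<vep_problem %d> %s coupling, %s, observed at %s level | %d regions, %d channels\n",
    x$problem_id, x$coupling_regime,
    if (x$stochastic) "stochastic" else "deterministic",
    x$observation_level, x$model$n_regions, nrow(x$gain$values)
  ))
  invisible(x)
}

#' RMSE calibration cost
#'
#' Simulates the model under a candidate parameter vector
#' `theta = (eta_1, ..., eta_N, K)`, maps the trajectory to the problem's
#' observation level, and returns the root-mean-square error against the
#' observed series over all samples and channels. Deterministic problems
#' integrate the ODE; stochastic problems draw a fresh noise path per
#' evaluation (seeded by `eval_seed`), so their cost is itself stochastic.
#' A diverging simulation yields `Inf`.
#'
#' @param theta Numeric vector of length `n_regions + 1`; values outside the
#'   problem bounds are clamped with a warning.
#' @param problem,observed A benchmark pair from [make_problem()].
#' @param eval_seed Integer seed for the process-noise path of stochastic
#'   problems (ignored for deterministic ones).
#'
#' @return Non-negative scalar RMSE.
#' @export
cost_rmse <- function(theta, problem, observed, eval_seed = NULL) {
  fn <- make_cost_fn(problem, observed)
  if (problem$stochastic) fn(theta, eval_seed = eval_seed) else fn(theta)
}

#' Build a fast cost closure for a benchmark problem
#'
#' Pre-extracts the observation matrix and model constants so repeated
#' optimizer evaluations avoid per-call overhead. The returned function
#' takes `theta` (and `eval_seed` for stochastic problems) and returns the
#' RMSE; it carries attributes `stochastic` and `dim`.
#'
#' @inheritParams cost_rmse
#' @return A function `f(theta, eval_seed = NULL)`.
#' @export
make_cost_fn <- function(problem, observed) {
  m <- problem$model
  obs <- series_matrix(observed)
  gain <- problem$gain$values
  n <- m$n_regions
  n_steps <- as.integer(floor(problem$duration / m$dt))
  lower <- problem$bounds$lower
  upper <- problem$bounds$upper
  stochastic <- problem$stochastic
  sigma <- if (stochastic) m$noise_std else 0
  envelope <- problem$cost_mode == "envelope"
  store_every <- problem$store_every

  fn <- function(theta, eval_seed = NULL) {
    if (length(theta) != n + 1) {
      abort(sprintf("`theta` must have length %d.", n + 1))
    }
    if (any(theta < lower | theta > upper)) {
      warn("`theta` outside bounds; clamping.")
      theta <- pmin(pmax(theta, lower), upper)
    }
    eta <- theta[seq_len(n)]
    K <- theta[n + 1]
    if (stochastic) set.seed(eval_seed %||% sample.int(2147483646L, 1))
    if (!envelope) {
      cost_rmse_cpp(m$connectome, eta, K, m$tau, m$current, m$dt, n_steps,
                    m$x0, m$z0, sigma, store_every, gain, obs)
    } else {
      cand <- vep_model(m$connectome, eta, coupling = K, tau = m$tau,
                        current = m$current, dt = m$dt, x0 = m$x0, z0 = m$z0,
                        noise_std = sigma)
      traj <- tryCatch(
        simulate_core(cand, problem$duration, sigma, store_every),
        vepfit_diverged = function(e) NULL
      )
      if (is.null(traj)) return(Inf)
      sim <- seeg_envelope(project_to_sensors(traj, problem$gain),
                           window = min(101L, nrow(obs)))
      ref <- seeg_envelope(new_sensor_series(observed$time, obs),
                           window = min(101L, nrow(obs)))
      sqrt(mean((series_matrix(sim) - series_matrix(ref))^2))
    }
  }
  attr(fn, "stochastic") <- stochastic
  attr(fn, "n_par") <- n + 1
  fn
}
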
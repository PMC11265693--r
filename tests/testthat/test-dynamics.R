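test_that("drift matches hand-computed values and fixed-point identities", {
  m <- single_node(eta = -1.6, tau = 10)
  d <- vep_drift(m, x = -2.5, z = 3.5)
  expect_equal(d$dx, 3.725, tolerance = 1e-12)
  expect_equal(d$dz, -0.71, tolerance = 1e-12)

  # any fixed point of an isolated node is a zero of the drift
  fp <- isolated_fixed_points(eta = -3.025, tau = 10)
  m2 <- single_node(eta = -3.025)
  d2 <- vep_drift(m2, fp$x[1], fp$z[1])
  expect_lt(abs(d2$dx), 1e-9)
  expect_lt(abs(d2$dz), 1e-9)

  # equal fast states: coupling contributes nothing
  C <- matrix(c(0, 1, 1, 0), 2)
  m3 <- vep_model(C, excitability = c(-2, -3), coupling = 5)
  same_x <- vep_drift(m3, c(-1.2, -1.2), c(1, 2))
  m3_uncoupled <- vep_model(C, excitability = c(-2, -3), coupling = 0)
  ref <- vep_drift(m3_uncoupled, c(-1.2, -1.2), c(1, 2))
  expect_equal(same_x$dz, ref$dz)

  expect_error(vep_drift(m3, c(1, 2, 3), c(1, 2)), "length")
})

test_that("one Euler step reproduces s + dt * f(s)", {
  m <- single_node(eta = -1.6, tau = 10)
  traj <- simulate_ode(m, duration = 0.1)
  expect_equal(nrow(traj), 2L)
  expect_equal(traj$x_1[2], -2.1275, tolerance = 1e-12)
  expect_equal(traj$z_1[2], 3.429, tolerance = 1e-12)
})

test_that("trajectory started at a stable fixed point stays there", {
  fp <- isolated_fixed_points(eta = -3.025, tau = 10)
  stable <- fp[fp$stability == "stable", ]
  m <- single_node(eta = -3.025, x0 = stable$x[1], z0 = stable$z[1])
  traj <- simulate_ode(m, duration = 50)
  expect_lt(max(abs(traj$x_1 - stable$x[1])), 1e-9)
  expect_lt(max(abs(traj$z_1 - stable$z[1])), 1e-9)
})

test_that("K = 0 network decouples into independent single-node runs", {
  m <- three_nodes(K = 0)
  traj <- simulate_ode(m, duration = 200)
  for (i in 1:3) {
    mi <- single_node(eta = m$excitability[i])
    ti <- simulate_ode(mi, duration = 200)
    expect_identical(traj[[paste0("x_", i)]], ti$x_1)
    expect_identical(traj[[paste0("z_", i)]], ti$z_1)
  }
})

test_that("noise-free Euler-Maruyama is bitwise identical to the ODE path", {
  m <- three_nodes(K = 0.5)
  a <- simulate_ode(m, duration = 100)
  b <- simulate_sde(m, duration = 100, seed = 42)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("stochastic simulation is reproducible under a fixed seed", {
  m <- three_nodes(K = 0.5, noise_std = 0.1)
  a <- simulate_sde(m, duration = 50, seed = 7)
  b <- simulate_sde(m, duration = 50, seed = 7)
  c_ <- simulate_sde(m, duration = 50, seed = 8)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(a$x_1, c_$x_1))
})

test_that("late-time noise level of a healthy node matches a re-simulation ensemble", {
  m <- single_node(eta = -3.5, noise_std = 0.1)
  late_sd <- function(seed) {
    tr <- simulate_sde(m, duration = 2000, seed = seed, store_every = 10L)
    sd(tail(tr$x_1, 100))
  }
  s0 <- late_sd(1)
  ens <- vapply(2:11, late_sd, numeric(1))
  expect_gt(s0, mean(ens) / 5)
  expect_lt(s0, mean(ens) * 5)
})

test_that("halving dt changes the trajectory consistently with a first-order scheme", {
  ref <- simulate_ode(single_node(eta = -3.0, dt = 1e-3), duration = 20)
  coarse <- simulate_ode(single_node(eta = -3.0, dt = 0.1), duration = 20)
  fine <- simulate_ode(single_node(eta = -3.0, dt = 0.05), duration = 20)
  at <- function(traj, t) traj$x_1[which.min(abs(traj$time - t))]
  t_probe <- c(5, 10, 20)
  err_coarse <- mean(abs(vapply(t_probe, function(t) at(coarse, t) - at(ref, t),
                                numeric(1))))
  err_fine <- mean(abs(vapply(t_probe, function(t) at(fine, t) - at(ref, t),
                              numeric(1))))
  expect_gt(err_coarse / err_fine, 1.5)
  expect_lt(err_coarse / err_fine, 2.5)
})

test_that("integration blow-up is reported with the failing step", {
  m <- single_node(eta = -1.6, dt = 50) # absurd step forces divergence
  expect_error(simulate_ode(m, duration = 5000), "diverged at step",
               class = "vepfit_diverged")
})

test_that("isolated fixed points match the nullcline oracle", {
  rep1 <- isolated_fixed_points(eta = -3.025, current = 3.1, tau = 10)
  i <- which.min(abs(rep1$x + 2))
  expect_equal(rep1$x[i], -2, tolerance = 1e-9)
  expect_equal(rep1$z[i], 4.1, tolerance = 1e-9)
  expect_equal(rep1$trace[i], -4.1, tolerance = 1e-9)
  expect_equal(rep1$determinant[i], 0.8, tolerance = 1e-9)
  expect_equal(rep1$stability[i], "stable")

  # nullcline residuals below tolerance for every reported point
  for (eta in c(-3.5, -2.5, -2.0, -1.6)) {
    rp <- isolated_fixed_points(eta)
    res1 <- 1 - rp$x^3 - 2 * rp$x^2 - rp$z + 3.1
    res2 <- 4 * (rp$x - eta) - rp$z
    expect_lt(max(abs(res1)), 1e-9)
    expect_lt(max(abs(res2)), 1e-9)
  }

  # seizing regime: unstable fixed point and sustained oscillation
  rep2 <- isolated_fixed_points(eta = -1.6, tau = 10)
  expect_true(all(rep2$stability == "unstable"))
  tr <- simulate_ode(single_node(eta = -1.6), duration = 500)
  late_x <- tr$x_1[tr$time > 250]
  expect_gt(diff(range(late_x)), 1)
})

test_that("critical excitability sits near -2.05 and behaves monotonically", {
  m <- single_node(eta = -2, tau = 40)
  eta_c <- critical_excitability(m)
  expect_lt(abs(eta_c - (-2.05)) / 2.05, 0.01)

  # below the critical value a stable fixed point exists
  for (e in c(eta_c - 0.01, eta_c - 0.1, -2.2)) {
    expect_true(any(isolated_fixed_points(e, tau = 40)$stability == "stable"))
  }
  expect_false(any(isolated_fixed_points(eta_c + 0.01,
                                         tau = 40)$stability == "stable"))

  # agreement with a brute-force stability scan at grid resolution
  grid <- seq(-2.2, -1.9, by = 0.005)
  stable <- vapply(grid, function(e) {
    any(isolated_fixed_points(e, tau = 40)$stability == "stable")
  }, logical(1))
  brute <- grid[which(!stable)[1]]
  expect_lt(abs(eta_c - brute), 0.005 + 1e-3)

  expect_error(
    critical_excitability(m, eta_grid = seq(-4, -3, by = 0.1)),
    class = "vepfit_no_bifurcation"
  )
})
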
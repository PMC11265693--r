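test_that("synthetic connectomes are symmetric, zero-diagonal, max-normalized", {
  expect_equal(synth_connectome(2, seed = 1), matrix(c(0, 1, 1, 0), 2))
  for (n in c(5, 20)) {
    C <- synth_connectome(n, seed = 3)
    expect_equal(C, t(C))
    expect_true(all(diag(C) == 0))
    expect_true(all(C >= 0))
    expect_identical(max(C), 1)
  }
  expect_identical(synth_connectome(10, seed = 9), synth_connectome(10, seed = 9))
  expect_error(synth_connectome(1, seed = 1), "at least 2")
})

test_that("truth maps place the requested zone counts within their bands", {
  tm <- synth_truth_map(84, n_ez = 2, n_pz = 3, seed = 4)
  expect_equal(as.vector(table(tm$label)), c(2, 3, 79))

  eta_c <- attr(tm, "eta_c")
  delta <- attr(tm, "delta_eta")
  expect_true(all(tm$eta[tm$label == "EZ"] > eta_c))
  expect_true(all(tm$eta[tm$label == "PZ"] > eta_c - delta &
                    tm$eta[tm$label == "PZ"] <= eta_c))
  expect_true(all(tm$eta[tm$label == "HZ"] <= eta_c - delta))

  all_hz <- synth_truth_map(10, n_ez = 0, n_pz = 0, seed = 1)
  expect_true(all(all_hz$label == "HZ"))
  expect_true(all(all_hz$eta <= eta_c - delta))

  expect_error(synth_truth_map(4, n_ez = 3, n_pz = 2, seed = 1), "exceeds")
})

test_that("benchmark problems carry the Table-style configuration", {
  pb1 <- make_problem(1, n_regions = 8, seed = 2, n_ez = 1, n_pz = 2,
                      duration = 30)
  expect_equal(pb1$problem$gain$values, diag(8))
  expect_equal(ncol(series_matrix(pb1$observed)), 8)
  expect_equal(pb1$problem$coupling_regime, "weak")
  expect_false(pb1$problem$stochastic)

  pb4 <- make_problem(4, n_regions = 8, seed = 2, n_ez = 1, n_pz = 2,
                      n_sensors = 5, duration = 30)
  expect_true(pb4$problem$gain$rank_deficient)
  expect_lt(qr(pb4$problem$gain$values)$rank, 8)
  expect_equal(pb4$problem$coupling_regime, "strong")
  expect_equal(ncol(series_matrix(pb4$observed)), 5)

  pb5 <- make_problem(5, n_regions = 8, seed = 2, n_ez = 1, n_pz = 2,
                      duration = 100)
  expect_true(pb5$problem$stochastic)
  expect_gt(pb5$problem$model$tau, pb1$problem$model$tau)
  expect_equal(pb5$problem$model$noise_std, 0.1)
  expect_equal(pb5$problem$observation_level, "source")

  expect_equal(length(pb1$problem$bounds$lower), 9)
  expect_error(make_problem(7, 8, 1), "1..6")
})

test_that("deterministic observations regenerate identically from the seed", {
  a <- make_problem(3, n_regions = 6, seed = 5, n_ez = 1, n_pz = 1,
                    duration = 30)
  b <- make_problem(3, n_regions = 6, seed = 5, n_ez = 1, n_pz = 1,
                    duration = 30)
  expect_identical(as.data.frame(a$observed), as.data.frame(b$observed))
  # stochastic datasets are fixed by their recorded generator seed too
  s1 <- make_problem(5, n_regions = 4, seed = 5, n_ez = 1, n_pz = 1,
                     duration = 50)
  s2 <- make_problem(5, n_regions = 4, seed = 5, n_ez = 1, n_pz = 1,
                     duration = 50)
  expect_identical(as.data.frame(s1$observed), as.data.frame(s2$observed))
})

test_that("weak coupling leaves PZ/HZ quiescent; strong coupling recruits PZ", {
  pb1 <- make_problem(1, n_regions = 12, seed = 7)
  tr1 <- simulate_ode(pb1$problem$model, pb1$problem$duration, store_every = 10)
  X1 <- trajectory_matrix(tr1, "x")
  late1 <- X1[(nrow(X1) %/% 2):nrow(X1), ]
  rng1 <- apply(late1, 2, function(c) diff(range(c)))
  lab1 <- pb1$problem$truth$label
  expect_true(all(rng1[lab1 != "EZ"] < 0.5))
  expect_true(all(rng1[lab1 == "EZ"] > 1))

  pb3 <- make_problem(3, n_regions = 12, seed = 7)
  tr3 <- simulate_ode(pb3$problem$model, pb3$problem$duration, store_every = 10)
  X3 <- trajectory_matrix(tr3, "x")
  late3 <- X3[(nrow(X3) %/% 2):nrow(X3), ]
  rng3 <- apply(late3, 2, function(c) diff(range(c)))
  lab3 <- pb3$problem$truth$label
  expect_true(all(rng3[lab3 == "PZ"] > 1))
  expect_true(all(rng3[lab3 == "HZ"] < 0.5))
})

test_that("RMSE cost is zero at truth for ODE problems and positive for SDE", {
  for (pid in c(1, 4)) {
    pb <- make_problem(pid, n_regions = 6, seed = 3, n_ez = 1, n_pz = 2,
                       n_sensors = 4, duration = 30)
    theta <- c(pb$problem$truth$eta, pb$problem$K_true)
    expect_lte(cost_rmse(theta, pb$problem, pb$observed), 1e-10)
  }
  pb5 <- make_problem(5, n_regions = 6, seed = 3, n_ez = 1, n_pz = 2,
                      duration = 50)
  theta5 <- c(pb5$problem$truth$eta, pb5$problem$K_true)
  expect_gt(cost_rmse(theta5, pb5$problem, pb5$observed, eval_seed = 11), 0)
  # fresh noise paths make the stochastic cost fluctuate but seeds pin it
  c1 <- cost_rmse(theta5, pb5$problem, pb5$observed, eval_seed = 11)
  c2 <- cost_rmse(theta5, pb5$problem, pb5$observed, eval_seed = 11)
  c3 <- cost_rmse(theta5, pb5$problem, pb5$observed, eval_seed = 12)
  expect_identical(c1, c2)
  expect_false(identical(c1, c3))
})

test_that("a constant offset in the observation yields that RMSE exactly", {
  pb <- make_problem(1, n_regions = 4, seed = 2, n_ez = 1, n_pz = 1,
                     duration = 20)
  shifted <- pb$observed
  sc <- grep("^s_", names(shifted))
  shifted[, sc] <- shifted[, sc] + 2
  theta <- c(pb$problem$truth$eta, pb$problem$K_true)
  expect_equal(cost_rmse(theta, pb$problem, shifted), 2, tolerance = 1e-9)
})

test_that("out-of-bounds parameters are clamped with a warning", {
  pb <- make_problem(1, n_regions = 4, seed = 2, n_ez = 1, n_pz = 1,
                     duration = 20)
  theta_bad <- c(rep(-6, 4), 5)
  expect_warning(v <- cost_rmse(theta_bad, pb$problem, pb$observed),
                 "clamping")
  theta_clamped <- c(rep(-5, 4), 2)
  expect_equal(v, cost_rmse(theta_clamped, pb$problem, pb$observed))
})
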
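one_vertex_geometry <- function(dist = 2, area = 2, scale_c = 1) {
  sensor_geometry(
    sensors = data.frame(x = dist, y = 0, z = 0),
    vertices = data.frame(region = 1, x = 0, y = 0, z = 0, area = area),
    scale_c = scale_c
  )
}

test_that("gain entries follow the inverse-square area-weighted sum", {
  g <- build_gain_matrix(one_vertex_geometry(dist = 2, area = 2))
  expect_equal(g$values, matrix(0.5), tolerance = 1e-12)

  # doubling all distances divides every entry by 4
  geo2 <- sensor_geometry(
    sensors = data.frame(x = 4, y = 0, z = 0),
    vertices = data.frame(region = 1, x = 0, y = 0, z = 0, area = 2)
  )
  expect_equal(build_gain_matrix(geo2)$values, matrix(0.125),
               tolerance = 1e-12)

  # additivity over a region's vertices
  geo3 <- sensor_geometry(
    sensors = data.frame(x = 0, y = 0, z = 0),
    vertices = data.frame(region = c(1, 1), x = c(2, 0), y = c(0, 3),
                          z = 0, area = c(2, 5))
  )
  expect_equal(build_gain_matrix(geo3)$values, matrix(2 / 4 + 5 / 9),
               tolerance = 1e-12)

  # linear in the scaling coefficient
  g10 <- build_gain_matrix(one_vertex_geometry(scale_c = 10))
  expect_equal(g10$values, 10 * g$values)
})

test_that("degenerate geometry (sensor on a vertex) is rejected by name", {
  geo <- sensor_geometry(
    sensors = data.frame(x = 0, y = 0, z = 0),
    vertices = data.frame(region = 1, x = 0, y = 0, z = 0, area = 1)
  )
  expect_error(build_gain_matrix(geo), "sensor 1.*vertex 1",
               class = "vepfit_degenerate_geometry")
})

test_that("fewer sensors than regions yields a rank-deficient gain", {
  g <- build_gain_matrix(synth_geometry(12, 8, seed = 1))
  expect_true(g$rank_deficient)
  expect_true(all(g$values > 0))
  g2 <- gain_matrix(diag(5))
  expect_false(g2$rank_deficient)
})

test_that("sensor projection applies the exponential observation model", {
  m <- three_nodes()
  traj <- simulate_ode(m, duration = 10)
  gI <- gain_matrix(diag(3))
  s <- project_to_sensors(traj, gI)
  expect_equal(series_matrix(s), exp(trajectory_matrix(traj, "x")),
               tolerance = 1e-12, ignore_attr = TRUE)

  # all-zero source activity maps to unit signals under the identity gain
  zero_traj <- traj
  zero_traj[, grep("^x_", names(zero_traj))] <- 0
  s0 <- project_to_sensors(zero_traj, gI)
  expect_true(all(abs(series_matrix(s0) - 1) < 1e-12))

  # single time point, summed channel: exp(0) + exp(log 2) = 3
  t1 <- traj[1, ]
  t1$x_1 <- 0
  t1$x_2 <- log(2)
  t1$x_3 <- -1e9 # effectively silent region
  gsum <- gain_matrix(matrix(c(1, 1, 0), 1, 3))
  expect_equal(series_matrix(project_to_sensors(t1, gsum))[1, 1], 3,
               ignore_attr = TRUE)

  # measurement noise is reproducible and zero-mean-ish
  sa <- project_to_sensors(traj, gI, obs_noise_std = 0.1, seed = 5)
  sb <- project_to_sensors(traj, gI, obs_noise_std = 0.1, seed = 5)
  expect_identical(as.data.frame(sa), as.data.frame(sb))

  expect_error(project_to_sensors(traj, gain_matrix(diag(2))), "regions")
})

test_that("envelope of a constant channel is zero and of a sinusoid is a/sqrt(2)", {
  tm <- seq(0, 50, by = 0.01)
  a <- 2.5
  s <- sensor_series_from_matrix(tm, cbind(rep(3, length(tm)),
                                          a * sin(2 * pi * tm)))
  env <- seeg_envelope(s, window = 501L)
  M <- series_matrix(env)
  expect_true(all(M >= 0))
  expect_lt(max(M[, 1]), 1e-12)
  mid <- M[1000:4000, 2]
  expect_lt(max(abs(mid - a / sqrt(2))) / (a / sqrt(2)), 0.05)

  expect_error(seeg_envelope(s, window = 0), "positive")
  expect_error(seeg_envelope(s, window = length(tm) + 1), "exceeds")
})
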
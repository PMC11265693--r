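test_that("reference set initialization selects quality plus diversity in bounds", {
  b <- unit_box(2)
  set.seed(1)
  rs <- initialize_refset(sphere_fn, b, worker_config(refset_size = 4))
  expect_equal(nrow(rs$theta), 4)
  expect_true(all(rs$theta >= 0 & rs$theta <= 1))

  # best member no worse than the median of a fresh diversification sample
  set.seed(2)
  sample_costs <- apply(matrix(runif(200), 100, 2), 1, sphere_fn)
  expect_lte(min(rs$cost), median(sample_costs))

  set.seed(7)
  rs1 <- initialize_refset(sphere_fn, b, worker_config(refset_size = 6))
  set.seed(7)
  rs2 <- initialize_refset(sphere_fn, b, worker_config(refset_size = 6))
  expect_identical(rs1, rs2)

  expect_error(
    initialize_refset(function(x) NA_real_, b, worker_config()),
    class = "vepfit_init_failed"
  )
})

test_that("pair combination samples the (expanded) spanned rectangle", {
  b <- unit_box(1)
  set.seed(3)
  kids <- replicate(1000, combine_solutions(0.4, 0.6, b,
                                            expand_a = 0, expand_b = 0))
  expect_true(all(kids >= 0.4 & kids <= 0.6))
  expect_gt(sum(kids < 0.5), 100)
  expect_gt(sum(kids > 0.5), 100)

  # expansion stays clipped to bounds even from opposite corners
  b2 <- unit_box(3)
  set.seed(4)
  for (i in 1:50) {
    child <- combine_solutions(rep(0, 3), rep(1, 3), b2)
    expect_true(all(child >= 0 & child <= 1))
  }
  expect_error(combine_solutions(rep(0.5, 2), rep(0.5, 2), b2), "differ")
})

test_that("go-beyond keeps improving along the child direction", {
  # quadratic with minimum at 0.8, beyond the child
  f <- function(x) (x - 0.8)^2
  b <- unit_box(1)
  out <- go_beyond(parent = list(theta = 0.2, cost = f(0.2)),
                   child = list(theta = 0.4, cost = f(0.4)),
                   cost_fn = f, bounds = b)
  expect_lt(out$cost, f(0.4))

  # no improvement available: the child comes back unchanged
  g <- function(x) (x - 0.4)^2
  out2 <- go_beyond(parent = list(theta = 0.2, cost = g(0.2)),
                    child = list(theta = 0.4, cost = g(0.4)),
                    cost_fn = g, bounds = b)
  expect_equal(out2$theta, 0.4)

  # never leaves the bounds
  h <- function(x) -x
  out3 <- go_beyond(parent = list(theta = 0.2, cost = h(0.2)),
                    child = list(theta = 0.9, cost = h(0.9)),
                    cost_fn = h, bounds = b)
  expect_lte(out3$theta, 1)
})

test_that("dynamic hill climbing solves a convex bowl and respects budgets", {
  d <- 5
  f <- function(x) sum((x - 0.3)^2)
  b <- unit_box(d)
  out <- dhc_local_search(rep(0.9, d), f, b, max_evals = 5000)
  expect_lte(out$cost, 1e-8)
  expect_lte(out$evals, 5000)

  # starting at the optimum never returns anything worse
  out2 <- dhc_local_search(rep(0.3, d), f, b, max_evals = 200)
  expect_lte(out2$cost, f(rep(0.3, d)))

  out3 <- dhc_local_search(rep(0.9, d), f, b, max_evals = 30)
  expect_lte(out3$evals, 30)
})

test_that("a single eSS worker solves a smooth 5-D problem within budget", {
  b <- list(lower = rep(-2, 5), upper = rep(2, 5))
  fit <- run_ess(function(x) sum(x^2), b, worker_config(seed = 11),
                 max_evals = 2e4, cost_tol = 0)
  expect_lte(fit$best_cost, 1e-6)
  expect_lte(fit$n_evals, 2e4 + 100)

  # bookkeeping contracts
  expect_true(all(diff(fit$trace$cost) <= 0))
  expect_equal(fit$best_cost, min(fit$archive$cost))
  expect_equal(unname(unlist(
    fit$archive[which.min(fit$archive$cost), 1:5]
  )), fit$best_theta)
  th <- as.matrix(fit$archive[, 1:5])
  expect_true(all(th >= -2 & th <= 2))
})

test_that("single-worker cooperation reduces exactly to plain eSS", {
  b <- list(lower = rep(-1, 4), upper = rep(1, 4))
  f <- function(x) rastrigin_fn(x * 5)
  cfg <- worker_config(seed = 21)
  a <- run_ess(f, b, cfg, max_evals = 6000, cost_tol = -Inf)
  c1 <- run_cooperative(f, b, worker_configs = list(cfg),
                        coop = cooperation_config(n_workers = 1,
                                                  max_evals_total = 6000),
                        seed = 21)
  expect_identical(a$best_theta, c1$best_theta)
  expect_identical(a$best_cost, c1$best_cost)
  expect_identical(a$n_evals, c1$n_evals)
  expect_identical(as.data.frame(a$archive), as.data.frame(c1$archive))
})

test_that("broadcast gating only propagates clear improvements", {
  b <- list(lower = rep(-1, 4), upper = rep(1, 4))
  f <- function(x) rastrigin_fn(x * 5)
  fit <- run_cooperative(f, b,
                         coop = cooperation_config(n_workers = 3,
                                                   max_evals_total = 2e4,
                                                   improvement_threshold = 0.1),
                         seed = 5)
  bc <- fit$broadcasts
  if (nrow(bc) > 1) {
    gain <- (bc$prev_cost[-1] - bc$cost[-1]) / abs(bc$prev_cost[-1])
    expect_true(all(gain > bc$threshold[-1] - 1e-12))
  }
  expect_true(all(diff(bc$cost) < 0))
  expect_equal(fit$best_cost, min(fit$archive$cost))
  expect_equal(nrow(fit$worker_stats), 3)
})

test_that("excitability and coupling are recovered on the source-level benchmark", {
  pb <- make_problem(1, n_regions = 12, seed = 7)
  fn <- make_cost_fn(pb$problem, pb$observed)
  fit <- run_cooperative(fn, pb$problem$bounds,
                         coop = cooperation_config(
                           n_workers = 2, max_evals_total = 2e5,
                           cost_tol = 1e-8
                         ), seed = 3)
  eta_err <- max(abs(fit$best_theta[1:12] - pb$problem$truth$eta))
  K_rel <- abs(fit$best_theta[13] - pb$problem$K_true) / pb$problem$K_true
  expect_lt(eta_err, 0.05)
  expect_lt(K_rel, 0.10)
  expect_true(all(diff(fit$trace$cost) <= 0))
})
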
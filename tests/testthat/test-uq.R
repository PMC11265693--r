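toy_archive <- function(thetas, costs) {
  out <- tibble::as_tibble(thetas, .name_repair = "minimal")
  names(out) <- paste0("theta_", seq_len(ncol(thetas)))
  out$cost <- costs
  out
}

test_that("archive filtering keeps the near-optimal slice", {
  arch <- toy_archive(matrix(1:3, 3, 1), c(1, 5, 100))
  kept <- filter_archive(arch, rel_threshold = 10)
  expect_equal(kept$cost, c(1, 5))

  # enormous threshold keeps everything; the best entry always survives
  expect_equal(nrow(filter_archive(arch, rel_threshold = 1e9)), 3)
  expect_true(1 %in% filter_archive(arch, rel_threshold = 1.0001)$cost)

  # stochastic rule uses an additive spread-based cut
  kept_s <- filter_archive(arch, rel_threshold = 1.5, stochastic = TRUE)
  expect_true(all(kept_s$cost <= 1 + 1.5 * sd(c(1, 5, 100))))

  expect_error(filter_archive(arch[0, ]), "empty")
})

test_that("farthest-point subsampling anchors the best and spans clusters", {
  b <- unit_box(2)
  arch <- toy_archive(matrix(runif(40), 20, 2), runif(20) + 1)
  expect_identical(subsample_representative(arch, 50, b), arch)

  sub <- subsample_representative(arch, 5, b)
  expect_equal(nrow(sub), 5)
  expect_true(min(arch$cost) %in% sub$cost)

  # three tight clusters, three representatives: one from each
  centers <- matrix(c(0.1, 0.1, 0.9, 0.9, 0.1, 0.9), 3, 2, byrow = TRUE)
  pts <- do.call(rbind, lapply(1:3, function(k) {
    sweep(matrix(runif(20, -0.02, 0.02), 10, 2), 2, centers[k, ], "+")
  }))
  arch3 <- toy_archive(pts, runif(30) + 1)
  sub3 <- subsample_representative(arch3, 3, b)
  cluster_of <- apply(as.matrix(sub3[, 1:2]), 1, function(p) {
    which.min(colSums((t(centers) - p)^2))
  })
  expect_equal(sort(unique(cluster_of)), 1:3)
})

test_that("percentile bands are normalized, ordered, and match sampling", {
  b <- unit_box(3)
  same <- toy_archive(matrix(0.42, 10, 3), rep(1, 10))
  bands <- percentile_bands(same, b)
  expect_true(all(bands$value >= 0 & bands$value <= 1))
  expect_equal(band_width(bands), 0)
  expect_true(all(bands$value == 0.42))

  set.seed(1)
  unif <- toy_archive(matrix(runif(5000 * 2), 5000, 2), rep(1, 5000))
  bu <- percentile_bands(unif, unit_box(2))
  med <- bu$value[bu$percentile == 50]
  expect_lt(max(abs(med - 0.5)), 0.03)

  # band values non-decreasing across percentiles for each parameter
  for (p in unique(bu$parameter)) {
    v <- bu$value[bu$parameter == p]
    expect_true(all(diff(v) >= 0))
  }

  expect_error(percentile_bands(same, list(lower = c(0, 0, 0),
                                           upper = c(0, 1, 1))))
  expect_error(percentile_bands(same, b, percentiles = c(95, 5)), "sorted")
})
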
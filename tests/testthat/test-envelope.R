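test_that("PCA reports correct variance structure on rank-1 data", {
  set.seed(1)
  dir <- rnorm(19)
  x <- outer(rnorm(40), dir)          # all rows on one line through 0
  m <- fit_climate_pca(x)
  expect_equal(m$var_frac[1L], 1, tolerance = 1e-10)
  expect_true(all(m$var_frac[-1L] < 1e-10))
})

test_that("PCA matches an independent eigendecomposition and reconstructs", {
  set.seed(42)
  x <- matrix(rnorm(60 * 19), 60, 19) %*% diag(seq(3, 0.5, length.out = 19))
  m <- fit_climate_pca(x)
  ev <- eigen(cov(x), symmetric = TRUE)$values
  expect_equal(m$sdev^2, ev, tolerance = 1e-8)
  expect_equal(sum(m$var_frac), 1, tolerance = 1e-12)
  expect_true(all(diff(m$var_frac) <= 1e-12))
  # loadings orthonormal; full reconstruction returns the centered data
  expect_equal(unname(crossprod(m$rotation)), diag(19), tolerance = 1e-10)
  xc <- sweep(x, 2, m$center)
  expect_equal(xc %*% m$rotation %*% t(m$rotation), xc, tolerance = 1e-8)
  # projected variances proportional to the top two eigenvalues
  s <- project_climate(x, m)
  expect_equal(apply(s, 2, var), ev[1:2], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("projection centers correctly and steps unit along loadings", {
  set.seed(3)
  x <- matrix(rnorm(30 * 19), 30, 19)
  m <- fit_climate_pca(x)
  mu <- matrix(m$center, 1)
  expect_equal(unname(project_climate(mu, m)[1, ]), c(0, 0),
               tolerance = 1e-10)
  step <- mu + m$rotation[, 1]
  expect_equal(unname(project_climate(step, m)[1, ]), c(1, 0),
               tolerance = 1e-10)
  expect_error(project_climate(x[, 1:5], m), "mismatch")
  expect_error(fit_climate_pca(cbind(x, 0), scale = TRUE), "constant")
})

test_that("envelope counts occupied cells with set semantics", {
  grid <- envelope_grid(n1 = 2, n2 = 2, xlim = c(0, 1), ylim = c(0, 1))
  expect_equal(grid$cells, 4L)
  # three points in three different cells
  pts <- rbind(c(0.1, 0.1), c(0.9, 0.1), c(0.1, 0.9))
  expect_equal(climate_envelope(pts, grid), 3L)
  # all points identical -> one cell
  expect_equal(climate_envelope(rbind(c(0.5, 0.5))[rep(1, 10), ], grid), 1L)
  # duplication never changes the count
  expect_equal(climate_envelope(pts[rep(1:3, 7), ], grid), 3L)
  # boundary point (1, 1) falls in the last, closed cell
  expect_equal(climate_envelope(rbind(c(1, 1)), grid), 1L)
  expect_error(climate_envelope(pts[0, ], grid), "empty")
})

test_that("envelope is monotone under added points and capped", {
  grid <- envelope_grid(n1 = 10, n2 = 5, xlim = c(0, 1), ylim = c(0, 1))
  set.seed(9)
  pts <- cbind(runif(200), runif(200))
  counts <- vapply(seq(10, 200, by = 10), function(k)
    climate_envelope(pts[1:k, , drop = FALSE], grid), integer(1))
  expect_true(all(diff(counts) >= 0))
  expect_true(all(counts <= pmin(seq(10, 200, by = 10), grid$cells)))
})

test_that("default grid follows the variance-weighted 981 x 15 design", {
  g <- envelope_grid(n1 = 981, n2 = 15, xlim = c(0, 1), ylim = c(0, 1))
  expect_equal(g$cells, 14715L)
  # the derivation rule: ten cells per percent of explained variance
  m <- structure(list(var_frac = c(0.981, 0.015, 0.004)),
                 class = "climate_pca")
  expect_equal(grid_bins_from_pca(m), c(981L, 15L))
})

test_that("square-root transform is exact and guards its domain", {
  expect_equal(sqrt_transform(0), 0)
  expect_equal(sqrt_transform(4), 2)
  expect_equal(sqrt_transform(14715), sqrt(14715))
  expect_error(sqrt_transform(-1), "nonnegative")
})

test_that("Brillouin index matches direct factorial arithmetic", {
  expect_equal(brillouin_index(c(A = 4)), 0)
  expect_equal(brillouin_index(c(2, 2)), log(6) / 4, tolerance = 1e-12)
  expect_equal(brillouin_index(c(1, 1, 1)), log(6) / 3, tolerance = 1e-12)
  expect_equal(brillouin_index(c(2, 2)), bf_brillouin(c(2, 2)),
               tolerance = 1e-12)
  expect_error(brillouin_index(c(2, -1)), "nonnegative")
  expect_error(brillouin_index(c(0, 0)), "at least 1")
})

test_that("evenness maximizes the Brillouin index over all partitions", {
  for (N in c(4, 7, 12)) {
    parts <- Filter(function(p) sum(p) == N, all_partitions(N, 4))
    h <- vapply(parts, function(p) brillouin_index(p), numeric(1))
    href <- vapply(parts, bf_brillouin, numeric(1))
    expect_equal(h, href, tolerance = 1e-10)
    even <- rep(N %/% 4, 4) + c(rep(1, N %% 4), rep(0, 4 - N %% 4))
    expect_equal(max(h), brillouin_index(even), tolerance = 1e-12)
  }
})
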
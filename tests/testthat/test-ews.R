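test_that("hand-computed EWS values reproduce exactly", {
  g2 <- two_node_graph()
  # dumbbell with opposite deviations: perfectly anticorrelated neighbours
  expect_equal(morans_i(c(-1, 1), g2), -1)
  expect_equal(spatial_sd(c(1, 2, 3)), 1)
  expect_equal(spatial_cv(c(1, 2, 3)), 0.5)
  expect_equal(central_moment(c(1, 2, 3), 1), 0)
  expect_equal(central_moment(c(0, 0, 3), 2), 2)
  expect_equal(central_moment(c(0, 0, 3), 3), 2)
  expect_equal(central_moment(c(-1, 1), 4), 1)
  expect_equal(spatial_skewness(c(0, 0, 3)), 2 / 2^1.5)
  expect_equal(spatial_kurtosis(c(-1, 1)), 1)
  # s relates to the N-denominator second moment by sqrt(N/(N-1))
  x <- c(0.3, 1.7, 2.2, 5.1)
  expect_equal(spatial_sd(x), sqrt(4 / 3) * sqrt(central_moment(x, 2)))
})

test_that("undefined statistics raise errors rather than return numbers", {
  g2 <- two_node_graph()
  expect_error(morans_i(c(2, 2), g2), "constant")
  expect_error(spatial_cv(c(-1, 1)), "mean is zero")
  expect_equal(spatial_cv(c(4, 4)), 0)  # zero sd, positive mean
  expect_error(spatial_skewness(c(3, 3)), "zero variance")
  expect_error(spatial_kurtosis(c(3, 3)), "zero variance")
  expect_error(spatial_sd(1), "at least 2")
})

test_that("all six EWSs match brute-force oracles on 200 random instances", {
  set.seed(202)
  for (rep in 1:200) {
    n <- sample(3:8, 1)
    g <- random_connected_graph(n, seed = 1000 + rep)
    A <- as.matrix(igraph::as_adjacency_matrix(g))
    x <- rnorm(n)
    expect_equal(morans_i(x, g), brute_morans_i(x, A), tolerance = 1e-12)
    expect_equal(spatial_sd(x), brute_sd(x), tolerance = 1e-12)
    expect_equal(central_moment(x, 2), brute_moment(x, 2), tolerance = 1e-12)
    expect_equal(spatial_cv(x), brute_cv(x), tolerance = 1e-12)
    expect_equal(spatial_skewness(x), brute_skew(x), tolerance = 1e-12)
    expect_equal(spatial_kurtosis(x), brute_kurt(x), tolerance = 1e-12)
  }
})

test_that("Moran's I agrees with an established implementation", {
  # ape::Moran.I row-normalizes the weight matrix; on a regular graph that
  # normalization is uniform, so the binary-weight statistic is unchanged
  g <- make_periodic_lattice(4)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  set.seed(56)
  x <- rnorm(16)
  ref <- ape::Moran.I(x, A, scaled = FALSE)
  expect_equal(morans_i(x, g), ref$observed, tolerance = 1e-10)
})

test_that("translation and scale behaviour of the statistics", {
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    g <- random_connected_graph(n, seed = 500 + rep)
    x <- rnorm(n, mean = 2)
    c0 <- runif(1, 0.5, 3)
    # translation invariance (all but CV)
    expect_equal(morans_i(x + c0, g), morans_i(x, g), tolerance = 1e-10)
    expect_equal(spatial_sd(x + c0), spatial_sd(x), tolerance = 1e-10)
    expect_equal(central_moment(x + c0, 3), central_moment(x, 3),
                 tolerance = 1e-10)
    expect_equal(spatial_skewness(x + c0), spatial_skewness(x),
                 tolerance = 1e-10)
    expect_equal(spatial_kurtosis(x + c0), spatial_kurtosis(x),
                 tolerance = 1e-10)
    expect_gt(abs(spatial_cv(x + c0) - spatial_cv(x)), 1e-8)
    # scaling by c > 0: s linear, m2 quadratic; g1, g2, CV, I_M invariant
    expect_equal(spatial_sd(c0 * x), c0 * spatial_sd(x), tolerance = 1e-10)
    expect_equal(central_moment(c0 * x, 2), c0^2 * central_moment(x, 2),
                 tolerance = 1e-10)
    expect_equal(spatial_skewness(c0 * x), spatial_skewness(x),
                 tolerance = 1e-10)
    expect_equal(spatial_kurtosis(c0 * x), spatial_kurtosis(x),
                 tolerance = 1e-10)
    expect_equal(spatial_cv(c0 * x), spatial_cv(x), tolerance = 1e-10)
    expect_equal(morans_i(c0 * x, g), morans_i(x, g), tolerance = 1e-10)
  }
})

test_that("skewness sign adjustment follows the direction rule", {
  expect_equal(sign_adjust_skewness(0.4, "ascending"), 0.4)
  expect_equal(sign_adjust_skewness(0.4, "descending"), -0.4)
  expect_equal(spatial_skewness(c(-2, -1, 1, 2)), 0)  # symmetric sample
})

test_that("large normal samples approach skewness 0 and kurtosis 3", {
  set.seed(271828)
  z <- rnorm(1e6)
  expect_lt(abs(spatial_skewness(z) - 0), 3 * sqrt(6 / 1e6))
  expect_lt(abs(spatial_kurtosis(z) - 3), 3 * sqrt(24 / 1e6))
})

test_that("compute_ews evaluates per-row snapshots and flags missing values", {
  net <- make_periodic_lattice(3)
  spec <- model_spec("gene", "D")
  cfg <- sweep_config(c(0.3, 1), "descending", L = 10, t_equil = 5, seed = 2)
  sw <- run_sweep(spec, net, cfg)
  tab <- compute_ews(sw, net)
  expect_equal(nrow(tab), 10)
  expect_false(any(is.na(tab$spatial_sd)))
  # row-level recomputation
  i <- 4
  expect_equal(tab$moran_i[i], morans_i(sw$states[i, ], net))
  expect_equal(tab$spatial_var[i], central_moment(sw$states[i, ], 2))
  # descending direction: stored skewness is the sign-adjusted -g1
  expect_equal(tab$skewness_adj[i], -spatial_skewness(sw$states[i, ]))

  # constant rows become missing for moran/skew/kurt, zero for sd and cv
  swc <- sw
  swc$states[2, ] <- 1.5
  tabc <- suppressWarnings(compute_ews(swc, net))
  expect_true(is.na(tabc$moran_i[2]))
  expect_equal(tabc$spatial_sd[2], 0)
  expect_equal(tabc$cv[2], 0)
  expect_true(is.na(tabc$skewness_adj[2]))
  expect_warning(compute_ews(swc, net), "missing")
})
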
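test_that("Kendall tau-prime follows the concordance and sign rules", {
  p <- 1:20
  v <- c(rep(0, 10), 1:10)  # strictly increasing on the latter half
  r <- kendall_tau_prime(p, v, home_range = 20, direction = "ascending")
  expect_equal(r$tau, 1)
  expect_equal(r$tau_prime, 1)
  # descending traversal: parameter decreases, EWS increases along traversal
  pd <- rev(seq(0, 1, length.out = 20))
  vd <- seq_len(20)
  rd <- kendall_tau_prime(pd, vd, home_range = 20, direction = "descending")
  expect_equal(rd$tau, -1)
  expect_equal(rd$tau_prime, 1)
  # only the last ceiling(k/2) home-range points are used
  expect_equal(r$n_points, 10)
  r9 <- kendall_tau_prime(p, p + 1, home_range = 9, direction = "ascending")
  expect_equal(r9$n_points, 5)
})

test_that("tie handling matches an explicit tau-b pair count", {
  p <- c(1, 2, 3, 4, 5, 6, 7, 8)
  v <- c(0, 0, 1, 5, 5, 6, 7, 7)
  r <- kendall_tau_prime(p, v, home_range = 8, direction = "ascending")
  expect_equal(r$tau, brute_kendall_taub(p[5:8], v[5:8]), tolerance = 1e-12)
  set.seed(88)
  for (rep in 1:25) {
    vv <- sample(0:3, 12, replace = TRUE)
    if (length(unique(vv[7:12])) < 2) next  # constant tie block: undefined
    rr <- kendall_tau_prime(1:12, vv, home_range = 12,
                            direction = "ascending")
    expect_equal(rr$tau, brute_kendall_taub(7:12, vv[7:12]),
                 tolerance = 1e-12)
  }
})

test_that("tau is an error on short or degenerate latter halves", {
  expect_error(kendall_tau_prime(1:3, 1:3, home_range = 3, "ascending"),
               "k >= 4")
  v <- c(1, 2, 3, 4, NA, NA, NA, 1)
  expect_error(kendall_tau_prime(1:8, v, home_range = 8, "ascending"),
               "fewer than 3")
  expect_error(kendall_tau_prime(1:8, rep(2, 8), home_range = 8, "ascending"),
               "tied-constant")
})

test_that("the direction flag only flips the sign of tau", {
  set.seed(13)
  for (rep in 1:20) {
    p <- sort(runif(16))
    v <- rnorm(16)
    a <- kendall_tau_prime(p, v, 16, "ascending")
    d <- kendall_tau_prime(p, v, 16, "descending")
    expect_equal(d$tau, a$tau, tolerance = 1e-12)
    expect_equal(d$tau_prime, -a$tau_prime, tolerance = 1e-12)
  }
})

# piecewise-linear series with exact slopes in the two windows
slope_series <- function(a, b, k = 20) {
  p <- seq_len(k)
  v <- numeric(k)
  v[1:5] <- a * p[1:5]
  v[6:(k - 5)] <- v[5]
  v[(k - 4):k] <- v[k - 5] + b * (p[(k - 4):k] - p[k - 5])
  list(p = p, v = v)
}

test_that("slope-ratio classification matches the stated truth table", {
  cases <- list(list(a = 1, b = 3, want = "accelerating"),
                list(a = -1, b = 1.5, want = "reversing"),
                list(a = 1, b = 1.5, want = "unsuccessful"),
                list(a = 2, b = -1, want = "unsuccessful"),
                list(a = -1, b = -0.5, want = "unsuccessful"),
                list(a = 0, b = 1, want = "unsuccessful"))
  for (cs in cases) {
    s <- slope_series(cs$a, cs$b)
    cl <- classify_ews(s$p, s$v, home_range = 20, theta = 2)
    expect_equal(cl$slope_a, cs$a, tolerance = 1e-10)
    expect_equal(cl$slope_b, cs$b, tolerance = 1e-10)
    expect_equal(cl$category, cs$want)
  }
})

test_that("descending sweeps regress on the oriented (negated) parameter", {
  # an EWS rising toward the tipping point of a descending sweep has
  # positive oriented slopes even though the raw parameter decreases
  s <- slope_series(1, 3)
  pd <- -s$p  # strictly decreasing grid, same traversal-order shape
  cl <- classify_ews(pd, s$v, home_range = 20, theta = 2)
  expect_equal(cl$slope_a, 1, tolerance = 1e-10)
  expect_equal(cl$category, "accelerating")
})

test_that("classification is affine-equivariant in the EWS values", {
  set.seed(5)
  s <- slope_series(-0.7, 1.2, k = 24)
  base <- classify_ews(s$p, s$v, 24)
  shift <- classify_ews(s$p, s$v + 11.3, 24)
  expect_equal(shift$slope_a, base$slope_a, tolerance = 1e-10)
  expect_equal(shift$slope_b, base$slope_b, tolerance = 1e-10)
  expect_equal(shift$category, base$category)
  scaled <- classify_ews(s$p, 2.5 * s$v, 24)
  expect_equal(scaled$slope_a, 2.5 * base$slope_a, tolerance = 1e-10)
  expect_equal(scaled$slope_b, 2.5 * base$slope_b, tolerance = 1e-10)
  expect_equal(scaled$category, base$category)
})

test_that("short home ranges are undetermined, not unsuccessful", {
  s <- slope_series(1, 3)
  expect_error(classify_ews(s$p[1:9], s$v[1:9], home_range = 9),
               "undetermined")
  v <- s$v; v[2] <- NA
  expect_error(classify_ews(s$p, v, home_range = 20),
               "fewer than 5 non-missing")
})

test_that("noise-free archetype curves classify into their named category", {
  want <- c(accelerating = "accelerating", reversing = "reversing",
            unsuccessful_early_rise = "unsuccessful",
            unsuccessful_flat = "unsuccessful")
  for (arch in names(want)) for (L in c(10, 20, 40, 100)) {
    cu <- make_ews_curve(arch, L, noise_sd = 0)
    cl <- classify_ews(cu$param_values, cu$values, home_range = L, theta = 2)
    expect_equal(cl$category, unname(want[arch]),
                 label = paste(arch, "L =", L))
  }
})

test_that("success_fraction counts accelerating and reversing", {
  expect_equal(success_fraction(c("accelerating", "reversing",
                                  "unsuccessful", "unsuccessful")), 0.5)
  expect_equal(success_fraction(rep("unsuccessful", 3)), 0)
  expect_equal(success_fraction(rep("accelerating", 4)), 1)
  cls <- list(classify_ews(1:20, slope_series(1, 3)$v, 20),
              classify_ews(1:20, slope_series(1, 1.5)$v, 20))
  expect_equal(success_fraction(cls), 0.5)
  expect_error(success_fraction(character(0)), "empty")
})

test_that("rank scores average ties and conserve 15 points per condition", {
  m1 <- matrix(c(0.9, 0.9, 0.5, 0.4, 0.3, 0.1), ncol = 1)
  expect_equal(unname(rank_scores(m1)), c(4.5, 4.5, 3, 2, 1, 0))
  m2 <- matrix(c(0.6, 0.5, 0.4, 0.3, 0.2, 0.1), ncol = 1)
  expect_equal(unname(rank_scores(m2)), c(5, 4, 3, 2, 1, 0))
  expect_equal(unname(rank_scores(matrix(0.5, 6, 1))), rep(2.5, 6))
  set.seed(42)
  mm <- matrix(runif(6 * 7), nrow = 6)
  expect_equal(sum(rank_scores(mm)), 15 * 7)
  expect_error(rank_scores(matrix(1, 5, 2)), "6 EWS rows")
})
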
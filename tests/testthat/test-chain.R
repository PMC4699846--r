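test_that("deletion rates invert target distributions by detailed balance", {
  N <- 5; b <- 1e-3
  # uniform target: d[S] = ((N - S + 1) / S) * b
  d <- deletion_rates(rep(1 / (N + 1), N + 1), b)
  expect_equal(unname(d), ((N - (1:N) + 1) / (1:N)) * b, tolerance = 1e-14)
  expect_equal(unname(d[5]), b / 5, tolerance = 1e-15)
  # Poisson target: ratio p[S-1]/p[S] = S / lambda gives d[S] = (N - S + 1) b / lambda
  d7 <- deletion_rates(poisson_peak(0.05, 7), 1e-8)
  expect_equal(unname(d7[5]), 3 * 1e-8 / 0.05, tolerance = 1e-12)
  expect_equal(unname(d7[5]), 6e-7, tolerance = 1e-12)
  # detailed-balance identity for arbitrary valid targets
  set.seed(11)
  for (i in 1:5) {
    p <- random_target(6)
    d <- deletion_rates(p, 1e-5)
    S <- 1:6
    expect_equal(unname(p[S + 1] / p[S] * S * d), (6 - S + 1) * 1e-5,
                 tolerance = 1e-12)
  }
  expect_error(deletion_rates(c(0.5, 0, 0.5), 1e-3), "strictly positive")
  # validity bound violated: steep target with large b names the offending S
  expect_error(deletion_rates(c(0.999, 1e-6, 0.000999), 0.5), "S = 1")
})

test_that("transition matrix is row-stochastic, tridiagonal, and exact for N = 1", {
  M1 <- transition_matrix(1, 0.2, 0.3)
  expect_equal(unclass(M1), matrix(c(0.8, 0.3, 0.2, 0.7), 2, 2),
               ignore_attr = TRUE)
  set.seed(21)
  ch <- toy_chain(6)
  expect_equal(rowSums(ch$M), rep(1, 7), ignore_attr = TRUE, tolerance = 1e-12)
  off <- abs(row(ch$M) - col(ch$M)) > 1
  expect_true(all(ch$M[off] == 0))
  expect_error(transition_matrix(3, 0.5, c(0.9, 0.9, 0.9)), "S = ")
})

test_that("stationary distribution round-trips the inversion and matches closed forms", {
  # N = 1 closed form: p[1] = b / (b + d)
  M1 <- transition_matrix(1, 0.02, 0.06)
  expect_equal(as.numeric(stationary_of(M1)), c(0.75, 0.25), tolerance = 1e-12)
  # round trip at the study rates (b = 1e-8): exact to 1e-10
  pw <- ref_model$dist$wp
  expect_lt(tv(stationary_of(ref_model$matrix$wp), pw), 1e-10)
  # cross-check against a numeric leading eigenvector at moderate rates
  set.seed(31)
  ch <- toy_chain(5, b = 5e-3)
  e <- eigen(t(unclass(ch$M)))
  i <- which.max(Re(e$values))
  v <- Re(e$vectors[, i]); v <- v / sum(v)
  expect_lt(tv(stationary_of(ch$M), v), 1e-9)
  # reducible chain rejected
  Mbad <- transition_matrix(2, 1e-3, c(1e-3, 1e-3))
  Mbad[2, 1] <- 0; Mbad[2, 2] <- Mbad[2, 2] + 1e-3
  expect_error(stationary_of(Mbad), "reducible")
})

test_that("spectral propagation matches sequential multiplication and conserves mass", {
  set.seed(41)
  ch <- toy_chain(5, b = 2e-3)
  p0 <- c(1, rep(0, 5))
  # oracle: 1000 sequential vector-matrix multiplications
  v <- p0
  for (i in 1:1000) v <- as.vector(v %*% unclass(ch$M))
  expect_lt(tv(propagate(p0, ch$M, 1000), v), 1e-10)
  expect_equal(as.numeric(propagate(p0, ch$M, 0)), p0)
  # stationary start is a fixed point at any horizon
  ps <- stationary_of(ch$M)
  expect_lt(tv(propagate(ps, ch$M, 1e9), ps), 1e-10)
  expect_error(propagate(p0, ch$M, -1), "non-negative")
  # normalization and non-negativity on a time grid
  for (t in c(1, 10, 1e4, 1e8, 1e12)) {
    pt <- propagate(p0, ch$M, t)
    expect_true(all(pt >= 0))
    expect_equal(sum(pt), 1, tolerance = 1e-12)
  }
})

test_that("convergence to stationarity is monotone in total variation", {
  set.seed(51)
  ch <- toy_chain(6, b = 1e-3)
  ps <- stationary_of(ch$M)
  p0 <- c(rep(0, 6), 1)
  ts <- round(10^seq(0, 7, 0.5))
  dists <- vapply(ts, function(t) tv(propagate(p0, ch$M, t), ps), numeric(1))
  expect_true(all(diff(dists) <= 1e-12))
})

test_that("exponential recording grid is increasing and covers the horizon", {
  g <- time_grid(1e6)
  expect_true(all(diff(g) > 0))
  expect_equal(g[1], 1)
  expect_equal(g[length(g)], 1e6)
  expect_identical(time_grid(100, include_zero = TRUE)[1], 0)
})
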
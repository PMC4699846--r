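test_that("entropy matches closed forms", {
  expect_equal(entropy_bits(rep(1 / 8, 8)), 3)
  expect_equal(entropy_bits(c(1, rep(0, 5))), 0)
  expect_equal(entropy_bits(c(0.5, 0.5, 0, 0)), 1)
  expect_error(entropy_bits(c(0.5, 0.4)), "normalized")
})

test_that("mutual information matches the brute-force joint-distribution sum", {
  joint_mi <- function(w, L) {
    # independent oracle: double sum over the joint distribution
    J <- w * L                       # rows: branch, cols: state
    pm <- colSums(J)
    s <- 0
    for (i in seq_along(w)) for (j in seq_len(ncol(L)))
      if (J[i, j] > 0) s <- s + J[i, j] * log2(J[i, j] / (w[i] * pm[j]))
    s
  }
  set.seed(5)
  for (rep in 1:10) {
    k <- sample(2:4, 1)        # branches (initial states)
    ns <- sample(3:6, 1)       # states of S(t)
    w <- random_target(k - 1)
    L <- t(vapply(seq_len(k), function(i) random_target(ns - 1), numeric(ns)))
    cur <- mi_curve(w, lapply(seq_len(k), function(i) L[i, , drop = FALSE]), 1)
    expect_equal(cur$mi, joint_mi(w, L), tolerance = 1e-12)
  }
})

test_that("degenerate mixtures give zero or maximal information", {
  w <- c(0.3, 0.7)
  same <- matrix(c(0.2, 0.5, 0.3), 1)
  expect_equal(mi_curve(w, list(same, same), 1)$mi, 0)
  # delta conditionals at distinct states: MI = H(weights)
  d1 <- matrix(c(1, 0, 0), 1); d2 <- matrix(c(0, 0, 1), 1)
  expect_equal(mi_curve(w, list(d1, d2), 1)$mi, entropy_bits(w), tolerance = 1e-12)
  # three disjoint-support branches at uniform weights: log2(3)
  u <- 1 / 3
  L <- list(matrix(c(1, 0, 0), 1), matrix(c(0, 1, 0), 1), matrix(c(0, 0, 1), 1))
  expect_equal(mi_curve(c(u, u, u), L, 1)$mi, log2(3), tolerance = 1e-12)
  expect_error(mi_curve(c(0.5, 0.5), list(d1, matrix(c(0, 1, 0, 0), 1)), 1))
})

test_that("stored conditionals can be re-weighted without re-simulation", {
  m <- ref_model
  times <- time_grid(1e9, include_zero = TRUE)
  base <- mi_decay_curve(m, "two_delta", "wp", times = times)
  cond <- attr(base, "conditionals")
  # new initial weighting of the same two branches (S0 = 0 and S0 = 7)
  w2 <- c(0.6, 0.4)
  reweighted <- mi_curve(w2, cond, times)
  direct <- mi_decay_curve(m, c(0.6, rep(0, 6), 0.4), "wp", times = times)
  expect_equal(reweighted$mi, direct$mi, tolerance = 1e-12)
})

test_that("information decay curves are non-increasing under a fixed condition", {
  m <- ref_model
  for (cond in c("low", "wp", "high")) {
    cur <- mi_decay_curve(m, "wp_draw", cond, horizon = 1e11)
    expect_true(all(diff(cur$mi) <= 1e-9))
    expect_true(all(cur$mi >= 0))
    expect_true(all(cur$mi <= log2(m$N + 1) + 1e-12))
  }
})

test_that("threshold crossings interpolate on the exponential grid", {
  curve <- data.frame(time = c(1, 10, 100, 1000), mi = c(1, 0.8, 0.5, 0.1))
  # crossing exactly at a grid point
  expect_equal(tau_fraction(curve, "decay_to", 0.5, reference = 1), 100)
  # constant curve never crosses: beyond horizon, not an error
  flat <- data.frame(time = c(1, 10, 100), mi = c(1, 1, 1))
  expect_identical(tau_fraction(flat, "decay_to", 0.5, reference = "initial"), Inf)
  # log-linear interpolation between straddling points
  tt <- tau_fraction(curve, "decay_to", 0.65, reference = 1)
  expect_gt(tt, 10); expect_lt(tt, 100)
  expect_equal(log(tt), log(10) + (0.65 - 0.8) / (0.5 - 0.8) * log(10),
               tolerance = 1e-12)
  # a value exactly on the threshold is returned at its grid time
  expect_equal(tau_fraction(data.frame(time = c(1, 10, 100), mi = c(0, 0.4, 0.8)),
                            "rise_to", 0.5, reference = "max"), 10)
  ris <- tau_fraction(data.frame(time = c(1, 10, 100), mi = c(0, 0.3, 0.8)),
                      "rise_to", 0.5, reference = "max")
  expect_gt(ris, 10); expect_lt(ris, 100)
})

test_that("two-state information crossings match dense-grid inversion of the closed form", {
  C <- 0.1; R <- 5.8e-11; q <- 0.1
  times <- time_grid(1e12)
  curve <- data.frame(time = times, mi = two_state_mi(times, C, R, q))
  t05 <- tau_fraction(curve, "decay_to", 0.05, reference = "initial")
  # oracle: root-finding on the closed form itself, dense in log time
  target <- 0.05 * two_state_mi(0, C, R, q)
  f <- function(lt) two_state_mi(exp(lt), C, R, q) - target
  t_exact <- exp(stats::uniroot(f, c(log(1e8), log(1e12)), tol = 1e-12)$root)
  expect_lt(abs(t05 - t_exact) / t_exact, 0.02)
})
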
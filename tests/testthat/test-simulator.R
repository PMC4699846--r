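test_that("a chain with no possible events stays constant", {
  sched <- data.frame(condition = "wp", duration = 1e6)
  prof <- list(wp = rep(0, 5))
  set.seed(1)
  occ <- simulate_connection(5, 0, prof, sched, 3L, c(0, 10, 1e3, 1e6))
  expect_true(all(attr(occ, "S") == 3L))
  expect_true(all(occ[, 1:3]) && !any(occ[, 4:5]))
})

test_that("N = 1 long-run occupancy matches the two-state stationary probability", {
  b <- 0.02; d <- 0.05
  sched <- data.frame(condition = "wp", duration = 4000)
  prof <- list(wp = d)
  set.seed(7)
  nrep <- 1500
  hit <- vapply(seq_len(nrep), function(i)
    simulate_connection(1, b, prof, sched, 0L, 4000)[1, 1], logical(1))
  p1 <- b / (b + d)
  se <- sqrt(p1 * (1 - p1) / nrep)
  expect_lt(abs(mean(hit) - p1), 3 * se)
})

test_that("simulated ensembles agree with exact propagation", {
  set.seed(3)
  ch <- toy_chain(4, b = 2e-3)
  model <- list(N = 4, b = ch$b, d = list(wp = ch$d))
  sched <- data.frame(condition = "wp", duration = 2e4)
  rec <- c(200, 2000, 2e4)
  pop <- simulate_population(model, 2000, sched, 2L, rec, seed = 99)
  p0 <- c(0, 0, 1, 0, 0)
  for (j in seq_along(rec)) {
    ex <- propagate(p0, ch$M, rec[j])
    expect_lt(tv(pop$freq[j, ], ex), 0.05)
  }
})

test_that("population runs are reproducible and n = 1 composes with the derived seed", {
  model <- list(N = 3, b = 5e-3,
                d = list(wp = deletion_rates(random_target(3), 5e-3)))
  sched <- data.frame(condition = "wp", duration = 5e3)
  rec <- c(0, 100, 5e3)
  a <- simulate_population(model, 20, sched, 1L, rec, seed = 42)
  b2 <- simulate_population(model, 20, sched, 1L, rec, seed = 42)
  expect_identical(a$S, b2$S)
  expect_identical(a$occupancy, b2$occupancy)
  one <- simulate_population(model, 1, sched, 1L, rec, seed = 5)
  set.seed((5 + 1) %% 2147483647)
  direct <- simulate_connection(3, model$b, model$d, sched, 1L, rec)
  expect_equal(one$occupancy[1, , ], unclass(direct), ignore_attr = TRUE)
  expect_error(simulate_population(model, 0, sched, 1L, rec), "positive")
})

test_that("synapse counts stay within bounds and respect phase switches", {
  set.seed(13)
  N <- 4
  profs <- list(low = deletion_rates(poisson_peak(0.1, N), 2e-3),
                high = deletion_rates(gaussian_peak(3, 0.8, N), 2e-3))
  sched <- data.frame(condition = c("high", "low"), duration = c(1e4, 1e4))
  rec <- seq(0, 2e4, by = 1000)
  occ <- simulate_connection(N, 2e-3, profs, sched, 0L, rec)
  S <- attr(occ, "S")
  expect_true(all(S >= 0 & S <= N))
  expect_identical(S, rowSums(occ) |> as.integer())
  expect_error(
    simulate_connection(N, 2e-3, profs,
                        data.frame(condition = "wp", duration = 10), 0L, 5),
    "unknown condition")
  expect_error(simulate_connection(N, 2e-3, profs, sched, 9L, rec), "0..N")
})

test_that("runtime scales with events, not simulated duration", {
  # one working-point connection across 1e10 steps has only a handful of
  # events at b = 1e-8; this must complete essentially instantly
  sched <- data.frame(condition = "wp", duration = 1e10)
  set.seed(2)
  el <- system.time(
    occ <- simulate_connection(ref_model$N, ref_model$b, ref_model$d, sched,
                               7L, c(1e6, 1e8, 1e10)))["elapsed"]
  expect_lt(el, 10)
  expect_true(all(attr(occ, "S") >= 0))
})

test_that("turnover counts come from site overlap and satisfy conservation", {
  tc <- turnover_counts(c(TRUE, TRUE, FALSE, FALSE, FALSE),
                        c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_identical(tc[c("created", "removed", "persistent")],
                   list(created = 1L, removed = 1L, persistent = 1L))
  same <- c(TRUE, FALSE, TRUE)
  tc2 <- turnover_counts(same, same)
  expect_identical(tc2$created + tc2$removed, 0L)
  expect_identical(tc2$persistent, 2L)
  tc3 <- turnover_counts(rep(FALSE, 5), rep(TRUE, 5))
  expect_identical(unlist(tc3), c(created = 5L, removed = 0L, persistent = 0L))
  expect_error(turnover_counts(rep(TRUE, 3), rep(TRUE, 4)), "mismatch")
  # conservation identity on simulated snapshot pairs
  set.seed(17)
  ch <- toy_chain(5, b = 3e-3)
  model <- list(N = 5, b = ch$b, d = list(wp = ch$d))
  sched <- data.frame(condition = "wp", duration = 1e4)
  rec <- c(0, 1e3, 5e3, 1e4)
  pop <- simulate_population(model, 30, sched, 2L, rec, seed = 8)
  for (i in 1:30) for (j in 1:(length(rec) - 1)) {
    a <- pop$occupancy[i, j, ]; b2 <- pop$occupancy[i, j + 1, ]
    tc <- turnover_counts(a, b2)
    expect_identical(sum(b2) - sum(a), tc$created - tc$removed)
    expect_identical(tc$persistent, sum(a) - tc$removed)
  }
})
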
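test_that("initial-condition specifications resolve to the documented vectors", {
  m <- ref_model
  expect_equal(as.numeric(make_initial("delta7", m)), c(rep(0, 7), 1))
  expect_equal(as.numeric(make_initial("two_delta", m)),
               c(0.9, rep(0, 6), 0.1))
  expect_equal(as.numeric(make_initial("piecewise_uniform", m)),
               c(0.3, 0.3, 0.3, 0, 0.025, 0.025, 0.025, 0.025))
  # boundary count S = 3 can be assigned to the upper peak by configuration
  pu3 <- make_initial(list(kind = "piecewise_uniform", upper_from = 3), m)
  expect_equal(as.numeric(pu3)[4], 0.1 / 5)
  expect_equal(as.numeric(make_initial("wp_draw", m)), as.numeric(m$dist$wp))
  expect_error(make_initial(list(kind = "delta", S0 = 9), m), "outside")
  expect_error(make_initial("unknown_kind", m), "unknown")
})

test_that("decay from a deterministic start carries no initial information", {
  dec <- decay_experiment(ref_model, "delta7", "wp", horizon = 1e6)
  expect_true(all(dec$curve$mi == 0))
  # trajectories remain normalized
  expect_equal(rowSums(dec$trajectory), rep(1, nrow(dec$trajectory)),
               tolerance = 1e-10)
})

test_that("a stationary start stays stationary and keeps its information plateau shape", {
  dec <- decay_experiment(ref_model, "wp_draw", "wp", horizon = 1e8)
  pw <- as.numeric(ref_model$dist$wp)
  for (j in seq_along(dec$times))
    expect_lt(tv(dec$trajectory[j, ], pw), 1e-10)
  expect_true(all(diff(dec$curve$mi) <= 1e-9))
})

test_that("learning with a single possible condition conveys no information", {
  le <- suppressWarnings(
    learning_experiment(ref_model, mix = c(low = 0, wp = 1, high = 0),
                        learn_horizon = 1e6, retention_horizon = 1e6))
  expect_true(all(le$learning$mi < 1e-12))
  expect_true(all(le$retention$mi < 1e-12))
})

test_that("exact and sampled condition weighting agree within sampling error", {
  m <- synapse_model(N = 4, b = 2e-4, mu = 3, sigma = 0.8, lambda = 0.05,
                     C = 0.1)
  exact <- suppressWarnings(
    learning_experiment(m, learn_horizon = 2e5, retention_horizon = 2e5))
  pop <- suppressWarnings(
    learning_experiment(m, learn_horizon = 2e5, retention_horizon = 2e5,
                        mode = "population", n = 1500, seed = 4))
  # multinomial noise on an MI estimate from 1500 draws: the plug-in bias
  # (K-1)(J-1)/(2 n ln 2) plus 3 standard errors of the empirical frequencies
  idx <- c(5, 15, 25, 35)
  for (j in idx) {
    expect_lt(abs(exact$learning$mi[j] - pop$learning$mi[j]), 0.08)
  }
})

test_that("control-paradigm turnover is balanced and conserved day by day", {
  m5 <- synapse_model(N = 5, sigma = 1)
  res <- retraining_experiment(m5, "control", replicates = 2,
                               n_synapses = 40, steps_per_day = 2.3e7,
                               seed = 2)
  s <- summary(res)
  # stationarity: creation and removal balance in expectation at every phase
  for (ph in seq_len(nrow(s)))
    expect_lt(abs(s$created[ph] - s$removed[ph]),
              6 * (s$created_sem[ph] + s$removed_sem[ph] + 0.5))
  expect_identical(sort(unique(res$daily$day)), 1:128)
})

test_that("storage-time sweeps flag non-bimodal cells instead of failing", {
  sw <- sweep_storage(list(mu = c(5, 1)), metric = "tau95",
                      horizon = 1e12)
  expect_identical(sw$status[1], "ok")
  expect_true(is.finite(sw$value[1]))
  expect_identical(sw$status[2], "not_bimodal")
  expect_true(is.na(sw$value[2]))
})

test_that("distributions and curves round-trip through their CSV serialization", {
  tmp <- withr::local_tempdir()
  p <- ref_model$dist$wp
  f <- file.path(tmp, "wp.csv")
  write_distribution(p, f, meta = list(condition = "wp", N = 7))
  expect_equal(as.numeric(read_distribution(f)), as.numeric(p),
               tolerance = 1e-12)
  expect_true(file.exists(paste0(f, ".json")))
  meta <- jsonlite::read_json(paste0(f, ".json"))
  expect_identical(meta$condition, "wp")
  cur <- data.frame(time = c(1, 10), mi = c(0.5, 0.25))
  class(cur) <- c("mi_curve", "data.frame")
  fc <- file.path(tmp, "mi.csv")
  write_mi_curve(cur, fc)
  expect_equal(utils::read.csv(fc)$mi, c(0.5, 0.25))
  fm <- file.path(tmp, "manifest.json")
  write_manifest(fm, ref_model, protocol = "decay", seed = 1)
  man <- jsonlite::read_json(fm)
  expect_identical(man$package, "synturn")
  expect_equal(man$parameters$N, 7)
})
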
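#' Initial synapse-count distributions
#'
#' Resolves an initial-condition specification into a probability vector
#' over `0..N`. Available kinds:
#' * `"wp_draw"` -- the working-point stationary distribution itself;
#' * `"delta"` -- all mass at one count (`"delta7"` is shorthand for
#'   `S0 = 7`);
#' * `"two_delta"` -- mass `1 - C` at `S = 0` and `C` at `S = N` (two
#'   solitary peaks);
#' * `"piecewise_uniform"` -- mass `1 - C` spread uniformly over the lower
#'   peak `S in {0, 1, 2}` and `C` uniformly over the upper peak
#'   `S in {upper_from, ..., N}`. By default `upper_from = 4`, leaving the
#'   boundary count `S = 3` empty; set `upper_from = 3` to assign it to the
#'   upper peak.
#'
#' @param spec a probability vector over `0..N`, a character kind, or a
#'   list, e.g. `list(kind = "delta", S0 = 7)`,
#'   `list(kind = "two_delta", C = 0.1)`,
#'   `list(kind = "piecewise_uniform", C = 0.1, upper_from = 4)`.
#' @param model a [synapse_model()] supplying `N` and default `C`.
#' @return a [synapse_dist] over `0..N`.
#' @examples
#' m <- synapse_model()
#' make_initial("two_delta", m)
#' make_initial("piecewise_uniform", m)
#' @export
make_initial <- function(spec, model) {
  N <- model$N
  if (is.numeric(spec) && length(spec) == N + 1L) {
    check_distribution(spec)
    return(new_synapse_dist(as.numeric(spec)))
  }
  if (is.numeric(spec))
    stop(sprintf("numeric initial condition must have length N + 1 = %d", N + 1L))
  if (is.character(spec)) {
    if (grepl("^delta[0-9]+$", spec))
      spec <- list(kind = "delta", S0 = as.integer(sub("^delta", "", spec)))
    else spec <- list(kind = spec)
  }
  kind <- spec$kind %||% stop("initial-condition spec needs a kind")
  C <- spec$C %||% model$C
  switch(kind,
    wp_draw = new_synapse_dist(as.numeric(model$dist$wp)),
    delta = {
      S0 <- spec$S0 %||% stop("delta initial condition needs S0")
      if (S0 < 0 || S0 > N) stop(sprintf("S0 = %d outside 0..N = %d", S0, N))
      p <- numeric(N + 1L); p[S0 + 1L] <- 1
      new_synapse_dist(p)
    },
    two_delta = {
      p <- numeric(N + 1L); p[1L] <- 1 - C; p[N + 1L] <- C
      new_synapse_dist(p)
    },
    piecewise_uniform = {
      upper_from <- spec$upper_from %||% 4L
      if (N < upper_from) stop("N too small for a piecewise-uniform initial condition")
      p <- numeric(N + 1L)
      p[1:3] <- (1 - C) / 3
      p[(upper_from + 1L):(N + 1L)] <- C / (N - upper_from + 1L)
      new_synapse_dist(p)
    },
    stop(sprintf("unknown initial-condition kind \"%s\"", kind)))
}

tv_distance <- function(p, q) 0.5 * sum(abs(as.numeric(p) - as.numeric(q)))

#' Information decay under a fixed stimulation condition
#'
#' The decay paradigm: a population starts from a chosen initial
#' distribution and evolves under one fixed condition; the mutual
#' information between the initial and the current synapse count is tracked
#' on an exponential grid, alongside the marginal distribution trajectory
#' and the matched two-state prediction for the storage plateau.
#'
#' @param model a [synapse_model()].
#' @param init initial condition (see [make_initial()]).
#' @param condition stimulation condition.
#' @param horizon largest time (steps).
#' @param mode `"exact"` or `"population"`.
#' @param n connections per initial count in population mode.
#' @param seed base seed (population mode).
#' @return list of class `"decay_experiment"`: `curve` (the `mi_curve`),
#'   `trajectory` (marginal `p[S(t)]`, one row per grid time), `twostate`
#'   (matched two-state MI on the same grid, when the working-point
#'   distribution is bimodal), `times`, plus the inputs.
#' @examples
#' dec <- decay_experiment(synapse_model(), "two_delta", "wp", 1e10)
#' tau_fraction(dec$curve, "decay_to", 0.05, reference = "initial")
#' @export
decay_experiment <- function(model, init = "wp_draw", condition = "wp",
                             horizon = 1e10, mode = "exact", n = 500,
                             seed = 1L) {
  if (horizon < 1) stop("horizon must be >= 1")
  p0 <- make_initial(init, model)
  times <- time_grid(horizon, include_zero = TRUE)
  curve <- mi_decay_curve(model, p0, condition, times = times, mode = mode,
                          n = n, seed = seed)
  w <- attr(curve, "weights")
  cond <- attr(curve, "conditionals")
  traj <- Reduce(`+`, Map(`*`, cond, w))
  dimnames(traj) <- list(NULL, as.character(0:model$N))
  two <- tryCatch({
    ts2 <- matched_twostate(model, p0)
    data.frame(time = times, mi = two_state_mi(times, ts2$C, ts2$R, ts2$q))
  }, error = function(e) NULL)
  structure(list(curve = curve, trajectory = traj, twostate = two,
                 times = times, init = p0, condition = condition,
                 mode = mode),
            class = "decay_experiment")
}

#' Learning and retention of a stimulation condition
#'
#' The three-phase learning paradigm. Phase 1 equilibrates the population in
#' the working-point condition (in exact mode the branch starts from the
#' stationary distribution itself; initial conditions have no influence
#' after equilibration). In phase 2 (*learning*) each branch is driven by a
#' condition drawn with probabilities `mix` and the mutual information
#' between `S(t)` and the condition grows; in phase 3 (*retention*) all
#' branches revert to the working-point condition and the information
#' decays. Exact condition weighting is the default; `mode = "population"`
#' samples `n` connections with conditions drawn from `mix` (plug-in
#' estimates).
#'
#' Reported time scales: `tau50_learning` (first rise through 50% of the
#' learning curve's maximum), `tau50_retention` (first decay through 50% of
#' the retention curve's initial value), their ratio `deltaT`, and -- as a
#' complementary view -- the times at which every branch is within
#' total-variation `tv_done` of its target stationary distribution in each
#' phase, whose ratio measures how much earlier learning *completes* than
#' forgetting.
#'
#' @param model a [synapse_model()].
#' @param mix condition probabilities (named over low, wp, high).
#' @param learn_horizon,retention_horizon phase durations in steps.
#' @param mode `"exact"` or `"population"`.
#' @param n connections in population mode (split over conditions by `mix`).
#' @param seed base seed (population mode).
#' @param tv_tol total-variation threshold for the end-of-phase convergence
#'   check (a warning is recorded when a phase is shorter than its
#'   convergence).
#' @param tv_done total-variation threshold defining the stationarity
#'   times.
#' @return list of class `"learning_experiment"`: `learning` and
#'   `retention` (`mi_curve`s), `tau50_learning`, `tau50_retention`,
#'   `deltaT`, `stationarity` (per-phase convergence times and their
#'   ratio), `warnings`.
#' @export
learning_experiment <- function(model,
                                mix = c(low = 1/3, wp = 1/3, high = 1/3),
                                learn_horizon = 1e9,
                                retention_horizon = 1e12,
                                mode = "exact", n = 1500, seed = 1L,
                                tv_tol = 1e-6, tv_done = 0.01) {
  mix <- mix[conditions]
  if (any(is.na(mix)) || any(mix < 0) || abs(sum(mix) - 1) > 1e-8)
    stop("mix must be probabilities over low, wp, high")
  times_l <- time_grid(learn_horizon, include_zero = TRUE)
  times_r <- time_grid(retention_horizon, include_zero = TRUE)
  warn <- character()

  nbranch <- n
  if (mode == "population") {
    # the sampled-conditions variant: one multinomial draw of the condition
    # assignment over the n connections, as in the randomized protocol
    set.seed(as.numeric(seed) %% 2147483647)
    nbranch <- pmax(drop(stats::rmultinom(1, n, as.numeric(mix))), 1L)
  }
  learning <- mi_condition_curve(model, mix, times = times_l, mode = mode,
                                 n = nbranch, seed = seed)
  cond_l <- attr(learning, "conditionals")
  # convergence check at the end of the learning phase
  ends <- lapply(cond_l, function(m) m[nrow(m), ])
  for (k in seq_along(conditions)) {
    tv <- tv_distance(ends[[k]], model$dist[[conditions[k]]])
    if (tv > tv_tol)
      warn <- c(warn, sprintf(
        "learning phase not converged for %s (TV = %.3g > %.3g)",
        conditions[k], tv, tv_tol))
  }
  retention <- mi_condition_curve(
    model, mix, inits = stats::setNames(ends, conditions), times = times_r,
    conditions_run = stats::setNames(rep("wp", 3), conditions),
    mode = mode, n = nbranch, seed = as.numeric(seed) + 7L)
  cond_r <- attr(retention, "conditionals")
  endr <- lapply(cond_r, function(m) m[nrow(m), ])
  for (k in seq_along(conditions)) {
    tv <- tv_distance(endr[[k]], model$dist$wp)
    if (tv > tv_tol)
      warn <- c(warn, sprintf(
        "retention phase not converged for %s (TV = %.3g > %.3g)",
        conditions[k], tv, tv_tol))
  }

  tau_l <- tau_fraction(learning, "rise_to", 0.5, reference = "max")
  tau_r <- tau_fraction(retention, "decay_to", 0.5, reference = "initial")
  conv_time <- function(condm, times, targets) {
    ok <- vapply(seq_along(times), function(j)
      all(vapply(seq_along(condm), function(k)
        tv_distance(condm[[k]][j, ], targets[[k]]), numeric(1)) < tv_done),
      logical(1))
    i <- which(ok)[1]
    if (is.na(i)) Inf else times[i]
  }
  conv_l <- conv_time(cond_l, times_l, model$dist)
  conv_r <- conv_time(cond_r, times_r, rep(list(model$dist$wp), 3))
  for (w in warn) warning(w, call. = FALSE)
  structure(list(learning = learning, retention = retention,
                 tau50_learning = tau_l, tau50_retention = tau_r,
                 deltaT = tau_r / tau_l,
                 stationarity = list(learning = conv_l, retention = conv_r,
                                     ratio = conv_r / conv_l),
                 mix = mix, mode = mode, warnings = warn),
            class = "learning_experiment")
}

#' @export
print.learning_experiment <- function(x, ...) {
  cat(sprintf(
    "Learning/retention: tau50 learning = %.4g, retention = %.4g, deltaT = %.4g\n",
    x$tau50_learning, x$tau50_retention, x$deltaT))
  cat(sprintf(
    "  stationarity reached (TV < 0.01) at %.4g vs %.4g steps (ratio %.4g)\n",
    x$stationarity$learning, x$stationarity$retention, x$stationarity$ratio))
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' Spine-turnover retraining paradigms
#'
#' Emulates the in-vivo motor-learning timeline with daily imaging: 30 days
#' in the working-point condition, 16 days of early training, 74 days back
#' at the working point, and 8 days of late training. During a training
#' phase a small subpopulation is stimulated (`frac_low` of the connections
#' receive *low*-, `frac_high` receive *high*-stimulation; the rest stays at
#' the working point). Paradigms: `"control"` (never stimulated),
#' `"retraining"` (early and late training of the *same* connections) and
#' `"late_only"` (working point for 120 days, then 8 days of training).
#' Synapse creation and removal per day are counted from the overlap of
#' occupied sites on consecutive days, summed over the population, for
#' `replicates` seeded repetitions (the typical number of animals).
#'
#' The population size is chosen so that the expected initial synapse count
#' matches `n_synapses` (`n = round(n_synapses / E_wp[S])`); this protocol
#' uses the `N = 5`, `sigma = 1` parameterization by default.
#'
#' @param model a [synapse_model()]; defaults to
#'   `synapse_model(N = 5, sigma = 1)`.
#' @param paradigm one of `"control"`, `"retraining"`, `"late_only"`.
#' @param steps_per_day model steps per experimental day (from
#'   [calibrate_steps_per_day()]; default 2.3e7).
#' @param n_synapses expected number of synapses in the initial population.
#' @param replicates number of seeded repetitions.
#' @param frac_low,frac_high stimulated fractions of the population.
#' @param phase_days durations (days) of the four phases.
#' @param seed integer base seed.
#' @return list of class `"retraining_experiment"`: `daily` (data frame
#'   with replicate, day, created, removed), `phases` (day ranges), `n`,
#'   `assignment` sizes, and the inputs.
#' @export
retraining_experiment <- function(model = synapse_model(N = 5, sigma = 1),
                                  paradigm = c("control", "retraining", "late_only"),
                                  steps_per_day = 2.3e7,
                                  n_synapses = 160, replicates = 8,
                                  frac_low = 0.0435, frac_high = 0.0065,
                                  phase_days = c(pre = 30, early = 16,
                                                 rest = 74, late = 8),
                                  seed = 1L) {
  paradigm <- match.arg(paradigm)
  N <- model$N
  ES <- sum((0:N) * as.numeric(model$dist$wp))
  n <- max(1L, round(n_synapses / ES))
  n_low <- round(frac_low * n)
  n_high <- round(frac_high * n)
  total_days <- sum(phase_days)
  days <- 0:total_days
  record_times <- days * steps_per_day
  b1 <- unname(phase_days["pre"]); b2 <- b1 + unname(phase_days["early"])
  b3 <- b2 + unname(phase_days["rest"])

  schedule_for <- function(cond) {
    # cond: this connection's condition during training phases
    if (paradigm == "control" || cond == "wp")
      return(data.frame(condition = "wp", duration = total_days * steps_per_day))
    if (paradigm == "retraining")
      data.frame(
        condition = c("wp", cond, "wp", cond),
        duration = c(b1, phase_days["early"], phase_days["rest"],
                     phase_days["late"]) * steps_per_day)
    else  # late_only
      data.frame(
        condition = c("wp", cond),
        duration = c(b3, phase_days["late"]) * steps_per_day)
  }

  daily <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    rep_seed <- (as.numeric(seed) + 131071 * r) %% 2147483647
    set.seed(rep_seed)
    assign_cond <- rep("wp", n)
    stim <- sample.int(n, n_low + n_high)
    assign_cond[stim] <- c(rep("low", n_low), rep("high", n_high))
    created <- removed <- matrix(0L, n, total_days)
    for (i in seq_len(n)) {
      set.seed((rep_seed + i) %% 2147483647)
      S0 <- sample(0:N, 1L, prob = as.numeric(model$dist$wp))
      occ <- simulate_connection(N, model$b, model$d,
                                 schedule_for(assign_cond[i]), S0,
                                 record_times)
      for (dd in seq_len(total_days)) {
        tc <- turnover_counts(occ[dd, ], occ[dd + 1L, ])
        created[i, dd] <- tc$created
        removed[i, dd] <- tc$removed
      }
    }
    daily[[r]] <- data.frame(replicate = r, day = seq_len(total_days),
                             created = colSums(created),
                             removed = colSums(removed))
  }
  daily <- do.call(rbind, daily)
  structure(list(daily = daily, paradigm = paradigm, n = n,
                 n_low = n_low, n_high = n_high,
                 phases = list(pre = 1:b1, early = (b1 + 1):b2,
                               rest = (b2 + 1):b3, late = (b3 + 1):total_days),
                 steps_per_day = steps_per_day, replicates = replicates),
            class = "retraining_experiment")
}

#' Per-phase turnover summary of a retraining experiment
#'
#' Mean daily created/removed synapse counts per phase, averaged within
#' replicate and summarized as mean +/- SEM across replicates.
#'
#' @param object a [retraining_experiment()] result.
#' @param ... unused.
#' @return data frame with phase, mean and SEM of daily created and removed
#'   counts.
#' @export
summary.retraining_experiment <- function(object, ...) {
  out <- do.call(rbind, lapply(names(object$phases), function(ph) {
    sub <- object$daily[object$daily$day %in% object$phases[[ph]], ]
    per_rep <- vapply(split(sub, sub$replicate), function(s)
      c(created = mean(s$created), removed = mean(s$removed)), numeric(2))
    sem <- function(x) stats::sd(x) / sqrt(length(x))
    data.frame(phase = ph,
               created = mean(per_rep["created", ]),
               created_sem = sem(per_rep["created", ]),
               removed = mean(per_rep["removed", ]),
               removed_sem = sem(per_rep["removed", ]))
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.retraining_experiment <- function(x, ...) {
  cat(sprintf(
    "Retraining paradigm \"%s\": %d connections (%d low, %d high stimulated), %d replicates\n",
    x$paradigm, x$n, x$n_low, x$n_high, x$replicates))
  print(summary(x))
  invisible(x)
}

#' Parameter sweep of storage time scales
#'
#' Evaluates, over a factorial grid of working-point peak parameters,
#' either `tau95` -- the time at which the storage plateau of
#' `MI(S(0); S(t))` under the working-point condition has decayed to 95% of
#' its height (plateau height taken as the matched two-state information at
#' `t = 0`, i.e. `H2(q)`) -- or `deltaT`, the retention/learning ratio of
#' `tau50` from [learning_experiment()]. Cells whose parameters do not give
#' a bimodal working-point distribution are marked invalid rather than
#' failing the sweep.
#'
#' @param vary named list of parameter vectors to cross (`mu`, `sigma`,
#'   `lambda`, `C`).
#' @param metric `"tau95"` or `"deltaT"`.
#' @param N,b fixed model dimensions.
#' @param init initial condition for the `tau95` decay (default
#'   `"two_delta"`, whose information curve is entirely plateau).
#' @param horizon decay horizon for `tau95`.
#' @param ... defaults for parameters not in `vary` (passed to
#'   [synapse_model()]).
#' @return data frame (class `"storage_sweep"`) with one row per cell:
#'   parameters, `value`, `status` (`"ok"`, `"not_bimodal"`, or an error
#'   class).
#' @examples
#' sweep_storage(list(sigma = c(0.9, 1.2, 1.5)), metric = "tau95")
#' @export
sweep_storage <- function(vary, metric = c("tau95", "deltaT"), N = 7,
                          b = 1e-8, init = "two_delta", horizon = 1e13,
                          ...) {
  metric <- match.arg(metric)
  defaults <- utils::modifyList(
    list(mu = 5, sigma = 1.2, lambda = 0.05, C = 0.1), list(...))
  grid <- do.call(expand.grid, c(vary, list(KEEP.OUT.ATTRS = FALSE)))
  vals <- numeric(nrow(grid))
  status <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    pars <- utils::modifyList(defaults, as.list(grid[i, , drop = FALSE]))
    res <- tryCatch({
      m <- synapse_model(N = N, b = b, mu = pars$mu, sigma = pars$sigma,
                         lambda = pars$lambda, C = pars$C)
      if (metric == "tau95") {
        ts2 <- matched_twostate(m, init)  # errors if not bimodal
        curve <- mi_decay_curve(m, init, "wp", horizon = horizon)
        list(value = tau_fraction(curve, "decay_to", 0.95,
                                  reference = h2(ts2$q)),
             status = "ok")
      } else {
        le <- suppressWarnings(learning_experiment(m))
        list(value = le$deltaT, status = "ok")
      }
    }, error = function(e) {
      list(value = NA_real_,
           status = if (grepl("bimodal|interpeak", conditionMessage(e)))
             "not_bimodal" else conditionMessage(e))
    })
    vals[i] <- res$value
    status[i] <- res$status
  }
  out <- cbind(grid, value = vals, status = status)
  class(out) <- c("storage_sweep", "data.frame")
  attr(out, "metric") <- metric
  out
}
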
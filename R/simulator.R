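#' Event-driven simulation of a single compound-connection
#'
#' Samples the discrete-time chain exactly, but event by event: every vacant
#' site holds a geometric formation timer with per-step success probability
#' `b`, every occupied site a geometric deletion timer with probability
#' `d[S]` for the current synapse count `S`. Waiting times are drawn by
#' inverse CDF; after every realized event (and at every stimulation-phase
#' boundary, where the deletion profile changes) all pending timers are
#' redrawn -- statistically neutral for the memoryless geometric law. If two
#' sites draw the same step, one is processed uniformly at random and the
#' rest redrawn, preserving the one-change-per-step approximation. Runtime
#' scales with the number of events, not with the simulated duration.
#'
#' This low-level function uses the current RNG state; seed management and
#' population bookkeeping live in [simulate_population()].
#'
#' @param N number of potential synaptic sites.
#' @param b formation probability rate (>= 0; 0 disables formation).
#' @param profiles named list mapping condition labels to deletion-rate
#'   vectors of length `N` (indexed `S = 1..N`).
#' @param schedule data frame with columns `condition` and `duration`
#'   (steps), executed in order.
#' @param init initial state: integer synapse count `S0` (the first `S0`
#'   sites are occupied) or a logical occupancy vector of length `N`.
#' @param record_times non-negative times (steps, within the schedule
#'   duration) at which occupancy is recorded.
#' @return logical matrix `length(record_times) x N` of site occupancies,
#'   with attributes `S` (counts per record time) and `times`.
#' @export
simulate_connection <- function(N, b, profiles, schedule, init,
                                record_times) {
  N <- check_N(N)
  if (b < 0 || b >= 1) stop("b must lie in [0, 1)")
  if (!is.data.frame(schedule) || !all(c("condition", "duration") %in% names(schedule)))
    stop("schedule must be a data frame with columns condition, duration")
  if (any(schedule$duration < 1)) stop("phase durations must be >= 1")
  unknown <- setdiff(schedule$condition, names(profiles))
  if (length(unknown))
    stop(sprintf("unknown condition label in schedule: %s", unknown[1]))
  occ <- init_occupancy(init, N)
  total <- sum(schedule$duration)
  record_times <- as.numeric(record_times)
  if (any(record_times < 0) || any(record_times > total))
    stop("record_times must lie within the schedule duration")
  ord <- order(record_times)
  rt <- record_times[ord]
  out <- matrix(NA, length(rt), N)
  Sout <- integer(length(rt))

  bounds <- cumsum(as.numeric(schedule$duration))
  phase <- 1L
  d <- profiles[[schedule$condition[1]]]
  t <- 0
  S <- sum(occ)
  timers <- draw_timers(occ, S, b, d, t)
  ri <- 1L
  nrec <- length(rt)
  repeat {
    tnext <- min(timers)
    # phase boundary first if it precedes the next event
    horizon <- min(tnext, bounds[phase] + 1)
    while (ri <= nrec && rt[ri] < horizon) {
      out[ri, ] <- occ
      Sout[ri] <- S
      ri <- ri + 1L
    }
    if (ri > nrec) break
    if (bounds[phase] + 1 <= tnext) {
      # condition switches at the start of step bounds[phase] + 1
      t <- bounds[phase]
      phase <- phase + 1L
      if (phase > nrow(schedule)) break
      d <- profiles[[schedule$condition[phase]]]
      timers <- draw_timers(occ, S, b, d, t)
      next
    }
    cand <- which(timers == tnext)
    site <- if (length(cand) > 1L) cand[sample.int(length(cand), 1L)] else cand
    occ[site] <- !occ[site]
    S <- S + if (occ[site]) 1L else -1L
    t <- tnext
    timers <- draw_timers(occ, S, b, d, t)
  }
  out <- out[order(ord), , drop = FALSE]
  Sout <- Sout[order(ord)]
  structure(out == 1, S = Sout, times = record_times)
}

init_occupancy <- function(init, N) {
  if (is.logical(init)) {
    if (length(init) != N) stop("occupancy vector must have length N")
    return(init)
  }
  S0 <- as.integer(init)
  if (length(S0) != 1L || is.na(S0) || S0 < 0 || S0 > N)
    stop("initial synapse count must lie in 0..N")
  c(rep(TRUE, S0), rep(FALSE, N - S0))
}

# geometric waiting times on {1, 2, ...} by inverse CDF; Inf when rate 0
draw_timers <- function(occ, S, b, d, t) {
  N <- length(occ)
  p <- ifelse(occ, if (S > 0) d[S] else 0, b)
  u <- stats::runif(N)
  w <- ifelse(p > 0, ceiling(log(u) / log1p(-p)), Inf)
  t + pmax(w, 1)
}

#' Simulate a population of independent compound-connections
#'
#' Runs `n` independent connections under a common schedule, each on its own
#' RNG stream derived from `seed + index` (bit-reproducible given
#' `(seed, n)`), and collects per-time empirical synapse-count frequencies
#' together with the full occupancy snapshots needed for turnover
#' accounting.
#'
#' @param model a [synapse_model()], or a list with elements `N`, `b`, `d`
#'   (named deletion profiles).
#' @param n number of connections (>= 1).
#' @param schedule data frame of phases (`condition`, `duration`).
#' @param init integer count applied to every connection, a logical
#'   occupancy vector, or a probability vector over `0..N` from which each
#'   connection draws its initial count.
#' @param record_times times at which states are recorded.
#' @param seed integer base seed.
#' @return an object of class `"synapse_population"`: list with `times`,
#'   `freq` (matrix `time x (N+1)` of relative frequencies), `S` (matrix
#'   `n x time` of counts), `occupancy` (array `n x time x N`), `n`,
#'   `schedule`.
#' @export
simulate_population <- function(model, n, schedule, init, record_times,
                                seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("n must be a positive integer")
  n <- as.integer(n)
  N <- model$N
  nt <- length(record_times)
  occ <- array(NA, c(n, nt, N))
  Smat <- matrix(NA_integer_, n, nt)
  draw_init <- is.numeric(init) && length(init) == N + 1L
  if (draw_init) check_distribution(init)
  for (i in seq_len(n)) {
    set.seed((as.numeric(seed) + i) %% 2147483647)
    ini <- if (draw_init) sample(0:N, 1L, prob = as.numeric(init)) else init
    snap <- simulate_connection(N, model$b, model$d, schedule, ini,
                                record_times)
    occ[i, , ] <- snap
    Smat[i, ] <- attr(snap, "S")
  }
  freq <- t(vapply(seq_len(nt), function(j)
    tabulate(Smat[, j] + 1L, nbins = N + 1L) / n, numeric(N + 1L)))
  dimnames(freq) <- list(NULL, as.character(0:N))
  structure(list(times = record_times, freq = freq, S = Smat,
                 occupancy = occ, n = n, schedule = schedule),
            class = "synapse_population")
}

#' @export
print.synapse_population <- function(x, ...) {
  cat(sprintf(
    "Population of %d compound-connections, %d record times (t = %g .. %g)\n",
    x$n, length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Simulate method for compound-connection models
#'
#' Convenience wrapper around [simulate_population()] for a single
#' stimulation condition: builds the one-phase schedule and an exponential
#' recording grid.
#'
#' @param object a [synapse_model()].
#' @param nsim number of connections.
#' @param seed integer base seed.
#' @param condition stimulation condition.
#' @param horizon duration in steps.
#' @param init initial condition (see [simulate_population()]; character
#'   specifications are resolved by [make_initial()]).
#' @param record_times recording grid; defaults to
#'   `time_grid(horizon, include_zero = TRUE)`.
#' @param ... unused.
#' @return a `"synapse_population"` object.
#' @export
simulate.synapse_model <- function(object, nsim = 1, seed = 1L,
                                   condition = "wp", horizon = 1e8,
                                   init = "wp_draw", record_times = NULL,
                                   ...) {
  condition <- check_condition(condition)
  if (is.character(init) || is.list(init)) init <- make_initial(init, object)
  if (is.null(record_times))
    record_times <- time_grid(horizon, include_zero = TRUE)
  schedule <- data.frame(condition = condition, duration = horizon)
  simulate_population(object, nsim, schedule, init, record_times, seed)
}

#' Synapse turnover between two observations
#'
#' Compares site occupancies at two times: a synapse is *created* if its
#' site is vacant at `t1` and occupied at `t2`, *removed* in the opposite
#' case, and *persistent* if occupied at both. The counts satisfy
#' `S(t2) = S(t1) + created - removed` and `persistent = S(t1) - removed`.
#'
#' @param occ1,occ2 logical occupancy vectors (one connection) or matrices
#'   (connections x sites) of identical shape.
#' @return list with elements `created`, `removed`, `persistent` (class
#'   `"turnover"`).
#' @examples
#' turnover_counts(c(TRUE, TRUE, FALSE, FALSE, FALSE),
#'                 c(TRUE, FALSE, TRUE, FALSE, FALSE))
#' @export
turnover_counts <- function(occ1, occ2) {
  if (!identical(dim(occ1) %||% length(occ1), dim(occ2) %||% length(occ2)))
    stop("occupancy snapshots have mismatched shape")
  if (!is.logical(occ1) || !is.logical(occ2))
    stop("occupancy snapshots must be logical")
  structure(list(created = sum(!occ1 & occ2),
                 removed = sum(occ1 & !occ2),
                 persistent = sum(occ1 & occ2)),
            class = "turnover")
}

#' @export
print.turnover <- function(x, ...) {
  cat(sprintf("turnover: %d created, %d removed, %d persistent\n",
              x$created, x$removed, x$persistent))
  invisible(x)
}
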
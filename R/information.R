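#' Shannon entropy of a synapse-count distribution
#'
#' `H = -sum(p * log2(p))` in bits, with `0 * log2(0) := 0`.
#'
#' @param p normalized probability vector.
#' @param tol tolerance on the normalization defect.
#' @return entropy in bits, in `[0, log2(length(p))]`.
#' @examples
#' entropy_bits(rep(1 / 8, 8))  # 3 bits
#' @export
entropy_bits <- function(p, tol = 1e-8) {
  check_distribution(p, tol = tol)
  x <- as.numeric(p)
  x <- x[x > 0]
  -sum(x * log2(x))
}

# mutual information of one mixture: weights w over branches, conditional
# distributions as rows of L
mi_mixture <- function(w, L) {
  marg <- as.vector(w %*% L)
  hcond <- apply(L, 1L, function(r) { r <- r[r > 0]; -sum(r * log2(r)) })
  h <- { m <- marg[marg > 0]; -sum(m * log2(m)) }
  max(h - sum(w * hcond), 0)
}

#' Mutual information between branches and the evolved synapse count
#'
#' The workhorse behind both information analyses: given branch weights
#' (`p[S(0) = S0]` or `P(condition)`) and, per time point, the conditional
#' distributions of `S(t)` for each branch, computes
#' `MI(t) = H(S(t)) - sum_k w_k H(S(t) | branch k)`, where the marginal is
#' the total-probability mixture of the conditionals. Because the
#' conditionals are stored, the same trajectories can be re-weighted under a
#' different initial distribution without re-simulation.
#'
#' @param weights branch probabilities (non-negative, sum to 1).
#' @param conditionals list (one entry per branch) of matrices
#'   `time x states` on a shared time grid, or a 3-d array
#'   `branch x time x states`.
#' @param times the shared time grid.
#' @return an object of class `"mi_curve"`: data frame with columns `time`
#'   and `mi` (bits).
#' @export
mi_curve <- function(weights, conditionals, times) {
  w <- as.numeric(weights)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
    stop("branch weights must be non-negative and sum to 1")
  if (is.array(conditionals) && length(dim(conditionals)) == 3L)
    conditionals <- lapply(seq_len(dim(conditionals)[1]),
                           function(k) conditionals[k, , ])
  if (length(conditionals) != length(w))
    stop("one conditional trajectory per branch is required")
  nt <- unique(vapply(conditionals, nrow, integer(1)))
  if (length(nt) != 1L || nt != length(times))
    stop("conditionals must share the time grid")
  mi <- vapply(seq_len(nt), function(j) {
    L <- t(vapply(conditionals, function(m) m[j, ], numeric(ncol(conditionals[[1]]))))
    mi_mixture(w, L)
  }, numeric(1))
  structure(data.frame(time = times, mi = mi),
            class = c("mi_curve", "data.frame"))
}

#' Information decay about the initial synapse count
#'
#' Computes `MI(S(0); S(t))` under a fixed stimulation condition by exact
#' propagation: each initial count `S0` with positive probability is a
#' branch whose conditional `p[S(t) | S(0) = S0]` is a row of `M^t`.
#' `mode = "population"` instead estimates the conditionals from an
#' event-driven ensemble of `n` connections per initial count (plug-in
#' estimator, no bias correction).
#'
#' @param model a [synapse_model()].
#' @param init initial distribution over `0..N` (vector or [make_initial()]
#'   specification).
#' @param condition stimulation condition.
#' @param horizon largest time step.
#' @param times recording grid; defaults to `time_grid(horizon,
#'   include_zero = TRUE)`.
#' @param mode `"exact"` (master equation) or `"population"` (stochastic
#'   ensemble).
#' @param n connections per initial count in population mode.
#' @param seed base seed in population mode.
#' @return an `"mi_curve"` data frame with attribute `"conditionals"`.
#' @examples
#' m <- synapse_model()
#' mi_decay_curve(m, "two_delta", "wp", horizon = 1e10)
#' @export
mi_decay_curve <- function(model, init = "wp_draw", condition = "wp",
                           horizon = 1e10, times = NULL, mode = "exact",
                           n = 500, seed = 1L) {
  condition <- check_condition(condition)
  p0 <- make_initial(init, model)
  if (is.null(times)) times <- time_grid(horizon, include_zero = TRUE)
  N <- model$N
  act <- which(as.numeric(p0) > 0)
  w <- as.numeric(p0)[act] / sum(as.numeric(p0)[act])
  if (mode == "exact") {
    sp <- spectral_chain(model$matrix[[condition]], model$dist[[condition]])
    cond <- lapply(act, function(i) {
      t(vapply(times, function(tt) {
        if (tt == 0) { v <- numeric(N + 1L); v[i] <- 1; v }
        else {
          e <- numeric(N + 1L); e[i] <- 1
          v <- pmax(spectral_power(sp, tt, p0 = e), 0); v / sum(v)
        }
      }, numeric(N + 1L)))
    })
  } else if (mode == "population") {
    schedule <- data.frame(condition = condition, duration = max(times, 1))
    cond <- lapply(seq_along(act), function(k) {
      pop <- simulate_population(model, n, schedule, act[k] - 1L, times,
                                 seed = as.numeric(seed) + (k - 1L) * n)
      pop$freq
    })
  } else stop("mode must be \"exact\" or \"population\"")
  out <- mi_curve(w, cond, times)
  attr(out, "conditionals") <- cond
  attr(out, "weights") <- w
  attr(out, "states") <- act - 1L
  out
}

#' Information about the applied stimulation condition
#'
#' Computes `MI(S(t); condition)` for branches driven by different
#' stimulation conditions, mixed with probabilities `P(condition)`:
#' `MI = H(S(t)) - sum_cond P(cond) H(S(t) | cond)`.
#'
#' @param model a [synapse_model()].
#' @param mix named probabilities over `c("low", "wp", "high")`.
#' @param inits named list of initial distributions, one per condition
#'   (default: every branch starts from the working-point stationary
#'   distribution, as in the learning phase).
#' @param times shared recording grid.
#' @param conditions_run conditions driving each branch; by default each
#'   branch is propagated under its own (named) condition.
#' @param mode,n,seed as in [mi_decay_curve()].
#' @return an `"mi_curve"` data frame with attribute `"conditionals"`.
#' @export
mi_condition_curve <- function(model, mix = c(low = 1/3, wp = 1/3, high = 1/3),
                               inits = NULL, times, conditions_run = NULL,
                               mode = "exact", n = 500, seed = 1L) {
  mix <- mix[conditions]
  if (any(is.na(mix)) || any(mix < 0) || abs(sum(mix) - 1) > 1e-8)
    stop("mix must be probabilities over low, wp, high")
  if (is.null(inits))
    inits <- stats::setNames(rep(list(model$dist$wp), 3L), conditions)
  if (is.null(conditions_run))
    conditions_run <- stats::setNames(conditions, conditions)
  N <- model$N
  cond <- lapply(conditions, function(cc) {
    run <- conditions_run[[cc]]
    p0 <- make_initial(inits[[cc]], model)
    if (mode == "exact") {
      sp <- spectral_chain(model$matrix[[run]], model$dist[[run]])
      t(vapply(times, function(tt) {
        if (tt == 0) as.numeric(p0)
        else { v <- pmax(spectral_power(sp, tt, p0 = p0), 0); v / sum(v) }
      }, numeric(N + 1L)))
    } else {
      k <- match(cc, conditions)
      nk <- if (length(n) == 3L) n[[k]] else n
      schedule <- data.frame(condition = run, duration = max(times, 1))
      pop <- simulate_population(model, nk, schedule, as.numeric(p0), times,
                                 seed = as.numeric(seed) + k * max(as.numeric(n)))
      pop$freq
    }
  })
  out <- mi_curve(as.numeric(mix), cond, times)
  attr(out, "conditionals") <- cond
  out
}

#' Threshold-crossing time of an information curve
#'
#' Locates the first time at which an information curve crosses a fraction
#' of a reference value, with log-linear interpolation between the
#' exponential grid points. `tau_0.95` of the storage plateau uses
#' `mode = "decay_to"`, `fraction = 0.95` against the plateau reference;
#' the learning time scale `tau_0.50` uses `mode = "rise_to"`,
#' `fraction = 0.5` against the curve maximum; the retention `tau_0.50`
#' decays to half the curve's initial value.
#'
#' @param curve an `"mi_curve"` data frame (or any data frame with columns
#'   `time`, `mi`).
#' @param mode `"decay_to"` (first downward crossing) or `"rise_to"` (first
#'   upward crossing).
#' @param fraction threshold as a fraction of `reference`.
#' @param reference reference value: a number, or one of `"max"`,
#'   `"initial"` (value at the earliest grid time).
#' @return the crossing time (steps); `Inf` if the threshold is never
#'   crossed within the grid ("beyond horizon"), never an error.
#' @export
tau_fraction <- function(curve, mode = c("decay_to", "rise_to"),
                         fraction = 0.5, reference = "max") {
  mode <- match.arg(mode)
  if (!nrow(curve)) stop("empty information curve")
  v <- curve$mi
  tt <- curve$time
  ref <- if (is.character(reference)) {
    switch(reference, max = max(v), initial = v[1],
           stop("unknown reference"))
  } else as.numeric(reference)
  thr <- fraction * ref
  hit <- if (mode == "decay_to") v <= thr else v >= thr
  i <- which(hit)[1]
  if (is.na(i)) return(Inf)
  if (i == 1L || v[i] == thr || tt[i - 1] <= 0 ||
      !is.finite(v[i - 1]) || v[i - 1] == v[i])
    return(tt[i])
  # interpolate linearly in log time between the straddling grid points
  lt <- log(tt[i - 1]) + (thr - v[i - 1]) / (v[i] - v[i - 1]) *
    (log(tt[i]) - log(tt[i - 1]))
  exp(lt)
}

#' @export
plot.mi_curve <- function(x, ..., log = "x", type = "l",
                          xlab = "time steps", ylab = "mutual information (bits)") {
  keep <- if (grepl("x", log)) x$time > 0 else rep(TRUE, nrow(x))
  graphics::plot(x$time[keep], x$mi[keep], log = log, type = type,
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}
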
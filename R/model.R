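#' Compound-connection synapse model
#'
#' Constructs the full stochastic model of a compound-connection: `N`
#' potential synaptic sites, constant formation rate `b` per vacant site,
#' and per-count deletion rates inverted from the three condition-specific
#' stationary distributions (*low*: truncated Poisson with parameter
#' `lambda`; *high*: truncated Gaussian with center `mu` and width `sigma`;
#' *wp*: their mixture with upper-peak weight `C`).
#'
#' The returned object carries, per condition, the stationary distribution,
#' the deletion-rate profile and the one-step transition matrix, and is the
#' single entry point for all analyses: [predict.synapse_model()] for exact
#' master-equation propagation, [simulate.synapse_model()] for event-driven
#' stochastic sampling with site tracking, [mi_decay_curve()] /
#' [mi_condition_curve()] for information decay, [matched_twostate()] for
#' the reduced peak-level model, and [calibrate_steps_per_day()] for the
#' experimental time scale.
#'
#' Defaults are the reference parameterization of the multi-synapse storage
#' analyses: `mu = 5`, `sigma = 1.2`, `lambda = 0.05`, `C = 0.1`,
#' `b = 1e-8` per time step, with `N = 7` (the smallest `N` compatible with
#' an all-mass-at-seven initial condition). The spine-turnover (retraining)
#' protocol uses `N = 5`, `sigma = 1` (see [retraining_experiment()]).
#'
#' @param N number of potential synapses (>= 1).
#' @param b formation probability rate per vacant site per time step.
#' @param mu,sigma center and width of the upper (Gaussian) peak.
#' @param lambda parameter of the lower (Poisson) peak.
#' @param C upper-peak weight of the working-point mixture, in `[0, 1]`.
#' @return an object of class `"synapse_model"`: a list with elements
#'   `N`, `b`, `mu`, `sigma`, `lambda`, `C`, `dist` (list of the three
#'   stationary [synapse_dist]s), `d` (list of deletion-rate vectors) and
#'   `matrix` (list of transition matrices), keyed by condition
#'   `low`, `wp`, `high`.
#' @examples
#' m <- synapse_model()
#' summary(m)
#' predict(m, t = 1e8, init = "delta7")
#' @export
synapse_model <- function(N = 7, b = 1e-8, mu = 5, sigma = 1.2,
                          lambda = 0.05, C = 0.1) {
  N <- check_N(N)
  check_b(b)
  dist <- list(
    low  = poisson_peak(lambda, N),
    high = gaussian_peak(mu, sigma, N))
  dist$wp <- wp_mixture(dist$low, dist$high, C)
  dist <- dist[c("low", "wp", "high")]
  d <- lapply(dist, deletion_rates, b = b)
  mats <- lapply(d, function(dd) transition_matrix(N, b, dd))
  structure(list(N = N, b = b, mu = mu, sigma = sigma, lambda = lambda,
                 C = C, dist = dist, d = d, matrix = mats),
            class = "synapse_model")
}

conditions <- c("low", "wp", "high")

check_condition <- function(condition) {
  if (!is.character(condition) || length(condition) != 1L ||
      !condition %in% conditions)
    stop("condition must be one of \"low\", \"wp\", \"high\"")
  condition
}

#' @export
print.synapse_model <- function(x, ...) {
  cat(sprintf(
    "Compound-connection model: N = %d potential synapses, b = %g/step\n",
    x$N, x$b))
  cat(sprintf(
    "  peaks: Poisson(lambda = %g) at 0, Gaussian(mu = %g, sigma = %g); C = %g\n",
    x$lambda, x$mu, x$sigma, x$C))
  invisible(x)
}

#' @export
coef.synapse_model <- function(object, ...) {
  with(object, c(N = N, b = b, mu = mu, sigma = sigma,
                 lambda = lambda, C = C))
}

#' Summary of a compound-connection model
#'
#' Reports the per-condition stationary means, the interpeak barrier state
#' of the working-point distribution, the matched two-state transition rate
#' and the mono- vs multi-synaptic slowdown factor.
#'
#' @param object a [synapse_model()].
#' @param ... unused.
#' @export
summary.synapse_model <- function(object, ...) {
  s <- 0:object$N
  means <- vapply(object$dist, function(p) sum(s * as.numeric(p)), numeric(1))
  barrier <- tryCatch(interpeak_minimum(object$dist$wp), error = function(e) NA_integer_)
  out <- list(model = object, means = means, barrier = barrier,
              R = if (!is.na(barrier)) matched_rate(object) else NA_real_,
              slowdown = if (!is.na(barrier)) slowdown_factor(object) else NA_real_)
  class(out) <- "summary.synapse_model"
  out
}

#' @export
print.summary.synapse_model <- function(x, ...) {
  print(x$model)
  cat("  stationary mean synapse count by condition:\n")
  print(round(x$means, 4))
  if (!is.na(x$barrier)) {
    cat(sprintf("  wp barrier state S~ = %d, p_wp[S~] = %.4g\n",
                x$barrier, as.numeric(x$model$dist$wp)[x$barrier + 1]))
    cat(sprintf("  matched two-state rate R = %.4g/step; slowdown factor %.4g\n",
                x$R, x$slowdown))
  } else {
    cat("  wp distribution is not bimodal at these parameters\n")
  }
  invisible(x)
}

#' Exact distribution of the synapse count at a later time
#'
#' Propagates an initial synapse-count distribution through the master
#' equation of the selected stimulation condition (see [propagate()]).
#'
#' @param object a [synapse_model()].
#' @param t time in steps (scalar or vector).
#' @param init initial condition: a probability vector over `0..N`, or a
#'   specification accepted by [make_initial()] (e.g. `"wp_draw"`,
#'   `"delta7"`, `"two_delta"`).
#' @param condition stimulation condition, one of `"low"`, `"wp"`, `"high"`.
#' @param ... unused.
#' @return a [synapse_dist] if `t` is scalar, otherwise a matrix with one
#'   row per time point.
#' @export
predict.synapse_model <- function(object, t = 0, init = "wp_draw",
                                  condition = "wp", ...) {
  condition <- check_condition(condition)
  p0 <- make_initial(init, object)
  M <- object$matrix[[condition]]
  if (length(t) == 1L) return(propagate(p0, M, t))
  sp <- spectral_chain(M, object$dist[[condition]])
  out <- t(vapply(t, function(tt)
    if (tt == 0) as.numeric(p0) else {
      v <- pmax(spectral_power(sp, tt, p0 = p0), 0); v / sum(v)
    }, numeric(object$N + 1L)))
  dimnames(out) <- list(format(t, scientific = TRUE), as.character(0:object$N))
  out
}

#' Stationary-distribution bar plot
#'
#' @param x a [synapse_model()].
#' @param which conditions to draw.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.synapse_model <- function(x, which = conditions, ...) {
  op <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(op))
  for (cond in which)
    graphics::barplot(as.numeric(x$dist[[cond]]),
                      names.arg = 0:x$N, main = cond,
                      xlab = "synapses S", ylab = "p[S]", ...)
  invisible(x)
}
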
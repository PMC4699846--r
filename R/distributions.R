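#' Synapse-count distributions
#'
#' A synapse-count distribution is a probability vector over the number of
#' realized synapses `S = 0..N` of a compound-connection. The three
#' stimulation conditions are represented by characteristic stationary
#' shapes: a truncated Gaussian peak at multiple synapses (*high*), a
#' truncated Poisson peak at zero (*low*), and their mixture, the bimodal
#' *working-point* (*wp*) distribution.
#'
#' Vectors are stored as plain numerics of length `N + 1` with names
#' `"0" .. "N"`, class `"synapse_dist"`, and a `"condition"` attribute.
#' All entries are strictly positive by construction, which is required for
#' the detailed-balance inversion of deletion rates.
#'
#' @name synapse_dist
NULL

new_synapse_dist <- function(p, condition = "custom") {
  p <- as.numeric(p)
  names(p) <- as.character(seq_along(p) - 1L)
  structure(p, class = "synapse_dist", condition = condition)
}

#' @param p numeric vector to validate as a probability distribution.
#' @param tol tolerance on the normalization defect.
#' @return `p`, invisibly, after validation.
#' @rdname synapse_dist
#' @export
check_distribution <- function(p, tol = 1e-8) {
  if (!is.numeric(p) || length(p) < 1L)
    stop("distribution must be a non-empty numeric vector")
  if (any(!is.finite(p)) || any(p < 0))
    stop("distribution entries must be finite and non-negative")
  if (abs(sum(p) - 1) > tol)
    stop(sprintf("distribution is not normalized (sum = %.12g)", sum(p)))
  invisible(p)
}

#' Truncated Gaussian peak over synapse counts
#'
#' Stationary distribution of the *high*-stimulation condition:
#' `p[S] = exp(-(S - mu)^2 / sigma^2) / normalizer` on `S = 0..N`.
#' Note the exponent uses `sigma^2`, not `2 * sigma^2`; `sigma` is the peak
#' width in synapse counts.
#'
#' @param mu center of the peak (synapse count, need not be an integer).
#' @param sigma width of the peak (> 0).
#' @param N number of potential synapses (>= 1 unless a single state is
#'   intended).
#' @return a [synapse_dist] of length `N + 1`.
#' @examples
#' gaussian_peak(5, 1.2, 7)
#' @export
gaussian_peak <- function(mu, sigma, N) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("sigma must be a positive number")
  N <- check_N(N, min = 0L)
  s <- 0:N
  w <- exp(-(s - mu)^2 / sigma^2)
  new_synapse_dist(w / sum(w), condition = "high")
}

#' Truncated Poisson peak over synapse counts
#'
#' Stationary distribution of the *low*-stimulation condition:
#' `p[S] = lambda^S / S! / normalizer` on `S = 0..N`. For `lambda < 1` the
#' distribution decreases monotonically from `S = 0`.
#'
#' @param lambda Poisson parameter (> 0) setting the steepness of the decay.
#' @inheritParams gaussian_peak
#' @return a [synapse_dist] of length `N + 1`.
#' @examples
#' poisson_peak(0.05, 5)
#' @export
poisson_peak <- function(lambda, N) {
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) || lambda <= 0)
    stop("lambda must be a positive number")
  N <- check_N(N, min = 0L)
  s <- 0:N
  logw <- s * log(lambda) - lgamma(s + 1)
  w <- exp(logw - max(logw))
  new_synapse_dist(w / sum(w), condition = "low")
}

#' Bimodal working-point mixture
#'
#' The *working-point* stationary distribution is the convex mixture
#' `p_wp[S] = (1 - C) * p_low[S] + C * p_high[S]` weighted by the connection
#' probability `C`. Bimodality is not enforced here; it is checked where a
#' barrier between peaks is actually needed (see [interpeak_minimum()]).
#'
#' @param p_low,p_high distributions over the same support `0..N`.
#' @param C upper-peak weight in `[0, 1]`.
#' @return a [synapse_dist] of length `N + 1`.
#' @examples
#' wp_mixture(poisson_peak(0.05, 7), gaussian_peak(5, 1.2, 7), 0.1)
#' @export
wp_mixture <- function(p_low, p_high, C) {
  if (length(p_low) != length(p_high))
    stop("p_low and p_high must share the same support 0..N")
  if (!is.numeric(C) || length(C) != 1L || is.na(C) || C < 0 || C > 1)
    stop("C must lie in [0, 1]")
  check_distribution(p_low)
  check_distribution(p_high)
  new_synapse_dist((1 - C) * as.numeric(p_low) + C * as.numeric(p_high),
                   condition = "wp")
}

#' Interpeak minimum of a bimodal distribution
#'
#' Returns the synapse count with the least probability strictly between the
#' two modes of a bimodal distribution -- the barrier state governing
#' peak-to-peak transitions. Ties are broken towards the smallest count.
#'
#' @param p a distribution over `0..N` with exactly two local maxima.
#' @return integer `S` (the barrier count).
#' @examples
#' interpeak_minimum(wp_mixture(poisson_peak(0.05, 7),
#'                              gaussian_peak(5, 1.2, 7), 0.1))
#' @export
interpeak_minimum <- function(p) {
  check_distribution(p)
  x <- as.numeric(p)
  n <- length(x)
  if (n < 3L) stop("no interpeak minimum: support too small")
  # local maxima with boundary handling (strict vs. inner neighbour)
  pad <- c(-Inf, x, -Inf)
  ismax <- vapply(seq_len(n), function(i) {
    pad[i + 1] > pad[i] && pad[i + 1] >= pad[i + 2] &&
      (pad[i + 1] > pad[i + 2] || i == n)
  }, logical(1))
  modes <- which(ismax)
  if (length(modes) != 2L)
    stop("no interpeak minimum: distribution is not bimodal")
  inner <- (modes[1] + 1L):(modes[2] - 1L)
  if (length(inner) < 1L)
    stop("no interpeak minimum: modes are adjacent")
  as.integer(inner[which.min(x[inner])] - 1L)
}

#' @export
print.synapse_dist <- function(x, digits = 4, ...) {
  cat(sprintf("Synapse-count distribution (condition: %s, N = %d)\n",
              attr(x, "condition") %||% "custom", length(x) - 1L))
  print(round(unclass(x), digits))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_N <- function(N, min = 1L) {
  if (!is.numeric(N) || length(N) != 1L || is.na(N) || N != round(N) || N < min)
    stop(sprintf("N must be an integer >= %d", min))
  as.integer(N)
}
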
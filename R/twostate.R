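#' Reduced two-state (peak-level) model
#'
#' On time scales beyond within-peak mixing, a bimodal compound-connection
#' behaves like a two-state Markov chain over its lower and upper peak with
#' stationary distribution `(1 - C, C)` and a single transition rate `R`
#' (this chain equally describes a mono-synaptic connection). The matrix is
#'
#' \deqn{M(R) = \begin{pmatrix} 1 - R/(1-C) & R/(1-C) \\ R/C & 1 - R/C
#' \end{pmatrix}}
#'
#' with eigenvalues `1` and `1 - R / (C (1 - C))`.
#'
#' @param C stationary upper-state probability, in `(0, 1)`.
#' @param R transition rate per time step (`R/C <= 1`, `R/(1-C) <= 1`).
#' @return 2 x 2 row-stochastic matrix.
#' @examples
#' two_state_matrix(0.5, 0.25)
#' @export
two_state_matrix <- function(C, R) {
  check_two_state(C, R)
  matrix(c(1 - R / (1 - C), R / C,
           R / (1 - C), 1 - R / C), 2, 2,
         dimnames = list(c("lower", "upper"), c("lower", "upper")))
}

check_two_state <- function(C, R) {
  if (!is.numeric(C) || length(C) != 1L || is.na(C) || C <= 0 || C >= 1)
    stop("C must lie in (0, 1)")
  if (!is.numeric(R) || length(R) != 1L || !is.finite(R) || R <= 0)
    stop("R must be a positive rate")
  if (R / C > 1 || R / (1 - C) > 1)
    stop("R/C and R/(1-C) must be valid probabilities (<= 1)")
  invisible(TRUE)
}

#' Upper-state probability of the two-state model
#'
#' Continuous-time envelope of the relaxation:
#' `p1(t) = C + (p_init - C) * exp(-t R / (C (1 - C)))` (exact for the 2x2
#' chain up to the `(1 - x)^t` vs `exp(-x t)` discretization, negligible at
#' the rates used here).
#'
#' @inheritParams two_state_matrix
#' @param t time in steps (vectorized).
#' @param p_init initial upper-state probability.
#' @return `p1(t)`, same length as `t`.
#' @export
two_state_p1 <- function(t, C, R, p_init) {
  check_two_state(C, R)
  if (any(t < 0)) stop("t must be non-negative")
  if (p_init < 0 || p_init > 1) stop("p_init must lie in [0, 1]")
  C + (p_init - C) * exp(-t * R / (C * (1 - C)))
}

h2 <- function(p) {
  x <- cbind(p, 1 - p)
  rowSums(ifelse(x > 0, -x * log2(x), 0))
}

#' Mutual information decay of the two-state model
#'
#' For an initial condition mixing the two deterministic starts with
#' `P(upper) = q`, the information the state at time `t` retains about the
#' initial peak is
#' `MI(t) = H2(p1(t, q)) - (1 - q) H2(p1(t, 0)) - q H2(p1(t, 1))`, with
#' `H2` the binary entropy. `MI(0) = H2(q)`; the curve is non-increasing
#' and tends to 0.
#'
#' @inheritParams two_state_p1
#' @param q probability of starting in the upper peak.
#' @return mutual information in bits, same length as `t`.
#' @examples
#' two_state_mi(0, C = 0.1, R = 5.8e-11, q = 0.1)  # H2(0.1)
#' @export
two_state_mi <- function(t, C, R, q) {
  if (q < 0 || q > 1) stop("q must lie in [0, 1]")
  pmax(h2(two_state_p1(t, C, R, q)) -
         (1 - q) * h2(two_state_p1(t, C, R, 0)) -
         q * h2(two_state_p1(t, C, R, 1)), 0)
}

#' Transition rate matched to the full compound-connection model
#'
#' In equilibrium the only probability flow between the two peaks of the
#' working-point distribution passes through the barrier pair
#' `(S~, S~ + 1)`; matching it to the two-state flow (`R` by construction)
#' gives `R = (N - S~) * b * p_wp[S~]`, with `S~` the interpeak minimum.
#'
#' @param model a [synapse_model()], or a [synapse_dist] (then `b` must be
#'   given).
#' @param b formation rate, when `model` is a bare distribution.
#' @return matched rate `R` (per time step).
#' @examples
#' matched_rate(synapse_model())  # ~5.8e-11
#' @export
matched_rate <- function(model, b = NULL) {
  if (inherits(model, "synapse_model")) {
    p <- model$dist$wp; b <- model$b
  } else {
    p <- model
    if (is.null(b)) stop("b is required when passing a bare distribution")
  }
  N <- length(p) - 1L
  Sb <- interpeak_minimum(p)
  (N - Sb) * b * as.numeric(p)[Sb + 1]
}

#' Peak-level parameters matched to a model and initial condition
#'
#' Bundles the matched two-state model: `C` is the upper-peak mass of the
#' working-point distribution (mass above the interpeak minimum), `R` the
#' barrier-flow matched rate, and `q` the upper-peak mass of the supplied
#' initial distribution.
#'
#' @param model a [synapse_model()].
#' @param init initial distribution (vector or [make_initial()] spec).
#' @return list with `C`, `R`, `q`, `barrier`.
#' @export
matched_twostate <- function(model, init = "wp_draw") {
  p <- model$dist$wp
  Sb <- interpeak_minimum(p)
  p0 <- make_initial(init, model)
  list(C = sum(as.numeric(p)[(Sb + 2):(model$N + 1)]),
       R = matched_rate(model),
       q = sum(as.numeric(p0)[(Sb + 2):(model$N + 1)]),
       barrier = Sb)
}

#' Storage slowdown of a multi-synaptic connection
#'
#' Relative to a mono-synaptic connection with the same formation rate, the
#' information decay of the multi-synapse system is slower by the factor
#' `((N - S~) * p_wp[S~] / sum_{S <= S~} p_wp[S])^-1` -- the inverse of the
#' lower-peak exit flux per unit lower-peak mass. Deeper interpeak minima
#' give strictly larger factors; the factor does not depend on `b`.
#'
#' @inheritParams matched_rate
#' @return dimensionless slowdown factor (>= 1 in the bistable regime).
#' @examples
#' slowdown_factor(synapse_model())  # ~155
#' @export
slowdown_factor <- function(model, b = NULL) {
  p <- if (inherits(model, "synapse_model")) model$dist$wp else model
  N <- length(p) - 1L
  Sb <- interpeak_minimum(p)
  x <- as.numeric(p)
  lower_mass <- sum(x[1:(Sb + 1)])
  1 / ((N - Sb) * x[Sb + 1] / lower_mass)
}
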
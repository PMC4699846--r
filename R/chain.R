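#' Deletion rates realizing a target stationary distribution
#'
#' Inverts a strictly positive target distribution into per-count deletion
#' probability rates by detailed balance. In equilibrium the probability
#' flow between adjacent counts `S - 1` and `S` must balance,
#' `p[S] / p[S - 1] = (N - S + 1) b / (S d[S])`, so the deletion rates are
#' chosen as
#' `d[S] = ((N - S + 1) / S) * (p[S - 1] / p[S]) * b`, for `S = 1..N`.
#' The induced birth-death chain then has `p` as its exact stationary
#' distribution.
#'
#' @param p strictly positive target distribution over `0..N`.
#' @param b synapse-formation probability rate per vacant site per time step
#'   (`0 < b < 1`).
#' @return numeric vector `d` of length `N`, indexed by `S = 1..N` (named
#'   accordingly).
#' @examples
#' deletion_rates(poisson_peak(0.05, 7), b = 1e-8)
#' @export
deletion_rates <- function(p, b) {
  check_distribution(p)
  check_b(b)
  x <- as.numeric(p)
  if (any(x <= 0))
    stop("deletion-rate inversion requires a strictly positive target distribution")
  N <- length(x) - 1L
  if (N < 1L) stop("N must be >= 1")
  S <- 1:N
  d <- ((N - S + 1) / S) * (x[S] / x[S + 1]) * b
  bound <- S * d + (N - S) * b
  if (any(bound > 1)) {
    bad <- S[which(bound > 1)[1]]
    stop(sprintf(
      "invalid rates: S*d[S] + (N-S)*b = %.4g > 1 at S = %d (reduce b)",
      bound[bad], bad))
  }
  names(d) <- as.character(S)
  d
}

check_b <- function(b) {
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b <= 0 || b >= 1)
    stop("b must be a probability rate in (0, 1)")
  invisible(b)
}

#' One-step transition matrix of the synapse-count chain
#'
#' Builds the `(N+1) x (N+1)` tridiagonal transition matrix of the
#' discrete-time birth-death chain in which at most one synapse is created
#' or removed per step (first-step approximation): from count `S` the chain
#' moves up with probability `(N - S) b`, down with probability `S d[S]`,
#' and stays otherwise.
#'
#' @param N number of potential synapses.
#' @param b formation probability rate per vacant site.
#' @param d deletion rates indexed `S = 1..N`, e.g. from [deletion_rates()].
#' @return row-stochastic tridiagonal matrix, class `"synapse_chain"` with
#'   attributes `N`, `b`, `d`.
#' @examples
#' p <- wp_mixture(poisson_peak(0.05, 7), gaussian_peak(5, 1.2, 7), 0.1)
#' M <- transition_matrix(7, 1e-8, deletion_rates(p, 1e-8))
#' @export
transition_matrix <- function(N, b, d) {
  N <- check_N(N)
  check_b(b)
  d <- as.numeric(d)
  if (length(d) != N) stop("d must have length N (indexed S = 1..N)")
  if (any(!is.finite(d)) || any(d < 0)) stop("deletion rates must be finite and >= 0")
  S <- 0:N
  up <- (N - S) * b
  dn <- c(0, (1:N) * d)
  stay <- 1 - up - dn
  if (any(stay < 0)) {
    bad <- S[which(stay < 0)[1]]
    stop(sprintf("invalid rates: S*d[S] + (N-S)*b > 1 at S = %d", bad))
  }
  M <- matrix(0, N + 1L, N + 1L)
  M[cbind(1:N, 2:(N + 1))] <- up[1:N]
  M[cbind(2:(N + 1), 1:N)] <- dn[2:(N + 1)]
  diag(M) <- stay
  dimnames(M) <- list(as.character(S), as.character(S))
  structure(M, class = c("synapse_chain", "matrix", "array"),
            N = N, b = b, d = d)
}

is_tridiagonal <- function(M, tol = 0) {
  n <- nrow(M)
  if (n != ncol(M)) return(FALSE)
  off <- abs(row(M) - col(M)) > 1
  all(abs(M[off]) <= tol)
}

validate_chain <- function(M, tol = 1e-9) {
  if (!is.matrix(M) || nrow(M) != ncol(M))
    stop("transition matrix must be square")
  if (any(M < -tol) || any(M > 1 + tol))
    stop("transition probabilities must lie in [0, 1]")
  if (max(abs(rowSums(M) - 1)) > tol)
    stop("transition matrix rows must sum to 1")
  if (!is_tridiagonal(M))
    stop("transition matrix must be tridiagonal (one synapse change per step)")
  invisible(M)
}

#' Stationary distribution of a synapse-count chain
#'
#' The unique invariant probability vector of an irreducible, aperiodic
#' tridiagonal chain (Frobenius-Perron). For a birth-death chain the fixed
#' vector satisfies the flow-balance recursion
#' `p[S] / p[S - 1] = M[S-1, S] / M[S, S-1]`, which is evaluated in log
#' space; this is exact, unlike a numeric leading-eigenvector solve, whose
#' error is limited by the spectral gap (astronomically small at the
#' formation rates used here).
#'
#' @param M row-stochastic tridiagonal matrix (see [transition_matrix()]).
#' @return a [synapse_dist] fixed by `M` (i.e. `p %*% M = p`).
#' @examples
#' p <- poisson_peak(0.05, 5)
#' M <- transition_matrix(5, 1e-8, deletion_rates(p, 1e-8))
#' stationary_of(M)  # recovers p
#' @export
stationary_of <- function(M) {
  validate_chain(M)
  n <- nrow(M)
  if (n == 1L) return(new_synapse_dist(1))
  up <- M[cbind(1:(n - 1), 2:n)]
  dn <- M[cbind(2:n, 1:(n - 1))]
  if (any(up <= 0) || any(dn <= 0))
    stop("chain is reducible: zero up- or down-rate between adjacent counts")
  logp <- cumsum(c(0, log(up) - log(dn)))
  logp <- logp - max(logp)
  p <- exp(logp)
  new_synapse_dist(p / sum(p))
}

# Symmetrized spectral decomposition of a reversible chain. M - I is
# symmetrized by the stationary distribution so that eigenvalue errors scale
# with ||M - I|| (~ b), not with 1; relaxation rates of order 1e-10 are then
# fully resolved.
spectral_chain <- function(M, pstat = stationary_of(M)) {
  sq <- sqrt(as.numeric(pstat))
  B <- (M - diag(nrow(M))) * outer(sq, 1 / sq)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(V = e$vectors, q = e$values, sq = sq)
}

# M^t applied from the left to p0 (or full matrix power if p0 is NULL),
# through the symmetrized decomposition; (1 + q)^t evaluated as
# exp(t * log1p(q)) so that rates ~1e-10 survive t ~ 1e12.
spectral_power <- function(sp, t, p0 = NULL) {
  lt <- ifelse(1 + sp$q > 0, exp(t * log1p(sp$q)),
               ifelse(t %% 2 == 0, 1, -1) * exp(t * log(abs(1 + sp$q))))
  if (is.null(p0)) {
    Mt <- (1 / sp$sq) * (sp$V %*% (t(sp$V) * lt)) * rep(sp$sq, each = length(sp$sq))
    return(Mt)
  }
  as.vector(((as.numeric(p0) / sp$sq) %*% sp$V) %*% (t(sp$V) * lt) * sp$sq)
}

#' Exact propagation of a synapse-count distribution
#'
#' Computes `p0 %*% M^t` for (possibly astronomically large) integer `t`.
#' Because every chain built by [deletion_rates()] is reversible, `M - I` is
#' symmetrized by the stationary distribution and propagated through its
#' eigendecomposition, which is exact up to machine precision for any `t`.
#' If the symmetrized solve is unavailable (non-reversible or reducible
#' input) a square-and-multiply matrix power is used instead.
#'
#' @param p0 initial distribution over `0..N`.
#' @param M transition matrix.
#' @param t number of time steps (non-negative; need not fit in an integer).
#' @return a [synapse_dist] at time `t`.
#' @examples
#' p <- wp_mixture(poisson_peak(0.05, 7), gaussian_peak(5, 1.2, 7), 0.1)
#' M <- transition_matrix(7, 1e-8, deletion_rates(p, 1e-8))
#' propagate(c(rep(0, 7), 1), M, 1e8)
#' @export
propagate <- function(p0, M, t) {
  check_distribution(p0)
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop("t must be a non-negative number of steps")
  if (length(p0) != nrow(M)) stop("p0 and M have mismatched support")
  if (t == 0) return(new_synapse_dist(as.numeric(p0)))
  out <- tryCatch(
    spectral_power(spectral_chain(M), t, p0 = p0),
    error = function(e) matpow_vec(p0, M, t))
  out <- pmax(out, 0)
  new_synapse_dist(out / sum(out))
}

# square-and-multiply fallback (t must be a whole number)
matpow_vec <- function(p0, M, t) {
  v <- as.numeric(p0)
  P <- unclass(M)
  t <- as.numeric(t)
  while (t > 0) {
    if (t %% 2 == 1) v <- as.vector(v %*% P)
    t <- t %/% 2
    if (t > 0) P <- P %*% P
  }
  v
}

#' Exponential recording grid
#'
#' Time points `round(base^k)`, deduplicated, spanning `1 .. horizon` --
#' the grid on which trajectories and information curves are recorded.
#'
#' @param horizon largest time step to cover.
#' @param base geometric growth factor (> 1).
#' @param include_zero prepend `t = 0`?
#' @return increasing numeric vector of time steps.
#' @export
time_grid <- function(horizon, base = 1.2, include_zero = FALSE) {
  if (horizon < 1) stop("horizon must be >= 1")
  if (base <= 1) stop("base must be > 1")
  kmax <- ceiling(log(horizon) / log(base))
  ts <- unique(round(base^(0:kmax)))
  ts <- ts[ts <= horizon]
  if (ts[length(ts)] < horizon) ts <- c(ts, horizon)
  if (include_zero) ts <- c(0, ts)
  ts
}
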
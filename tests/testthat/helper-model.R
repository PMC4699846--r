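# Shared fixtures: the reference model and a generator of random strictly
# positive target distributions with rates safely inside the validity bound.

ref_model <- synapse_model()          # N = 7, b = 1e-8, reference peaks
ref_model_n5 <- synapse_model(N = 5)  # calibration parameterization

random_target <- function(N, sd = 1.5) {
  w <- exp(rnorm(N + 1, sd = sd))
  w / sum(w)
}

# moderate-rate chain for tests that do not need astronomical time scales
toy_chain <- function(N = 4, b = 1e-3, p = NULL) {
  if (is.null(p)) p <- random_target(N)
  d <- deletion_rates(p, b)
  list(p = p, d = d, M = transition_matrix(N, b, d), N = N, b = b)
}

tv <- function(p, q) 0.5 * sum(abs(as.numeric(p) - as.numeric(q)))
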
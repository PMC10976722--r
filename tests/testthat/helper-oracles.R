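# Independent oracles used across test files.

# Brute-force transcription of the greedy caliper matching procedure:
# treated in descending ps (ties: ascending index); nearest available control
# within the caliper; distance ties: smallest control index; without
# replacement.
brute_force_greedy <- function(ps, treat, caliper) {
  tr <- which(treat == 1)
  co <- which(treat == 0)
  tr <- tr[order(-ps[tr], tr)]
  used <- logical(length(co))
  out <- matrix(integer(0), 0, 2)
  for (i in tr) {
    d <- abs(ps[co] - ps[i])
    d[used] <- Inf
    if (!length(d) || min(d) > caliper || !is.finite(min(d))) next
    j <- which.min(d)  # first minimum = smallest control index (co ascending)
    used[j] <- TRUE
    out <- rbind(out, c(i, co[j]))
  }
  out
}

# Probit negative log-likelihood and gradient for the optimizer oracle.
probit_nll <- function(theta, x, y) {
  eta <- theta[1] + theta[2] * x
  p <- pnorm(eta)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(y * log(p) + (1 - y) * log(1 - p))
}
probit_grad <- function(theta, x, y) {
  eta <- theta[1] + theta[2] * x
  p <- pmin(pmax(pnorm(eta), 1e-12), 1 - 1e-12)
  w <- dnorm(eta) * (y - p) / (p * (1 - p))
  -c(sum(w), sum(w * x))
}

# Small non-degenerate cohort for interface tests.
tiny_cohort <- function(n = 400, rho = 0.2, seed = 99) {
  simulate_cohort(dgp_params(n_obs = n, rho = rho, seed = seed))
}
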
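# Internal numeric helpers shared by the samplers and simulators.

# Numerically stable log(1 + exp(x)); used for Bernoulli-logit log-likelihoods.
log1pexp <- function(x) {
  out <- x
  small <- x <= 18
  out[small] <- log1p(exp(x[small]))
  big <- x > 18 & x <= 33.3
  out[big] <- x[big] + exp(-x[big])
  out
}

inv_logit <- function(x) 1 / (1 + exp(-x))

logit <- function(p) log(p / (1 - p))

# Clamp probabilities away from {0, 1} before taking logs.
PROB_EPS <- 1e-12

clamp_prob <- function(p) pmin(pmax(p, PROB_EPS), 1 - PROB_EPS)

# Half-Cauchy(scale) log-density on (0, Inf).
dhalfcauchy_log <- function(x, scale) {
  ifelse(x > 0 & scale > 0,
         log(2) - log(pi) - log(scale) - log1p((x / scale)^2),
         -Inf)
}

# Half-Cauchy draws via the closed-form inverse CDF |scale * tan(pi * u / 2)|.
rhalfcauchy <- function(n, scale) {
  abs(scale * tan(pi * stats::runif(n) / 2))
}

# Derive per-chain RNG seeds from a 32-bit master seed, deterministically.
chain_seeds <- function(seed, n_chains) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n_chains)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
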
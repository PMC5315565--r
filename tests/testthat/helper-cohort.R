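# Shared fixtures, built in code and cached per test run.

.fixture_env <- new.env(parent = emptyenv())

# Small planted-effect cohort reused across module tests.
small_cohort <- function() {
  if (is.null(.fixture_env$small)) {
    .fixture_env$small <- simulate_cohort(
      sim_config(n_samples = 300, n_probes = 2000, seed = 11)
    )
  }
  .fixture_env$small
}

# Configuration with every planted effect switched off (global null).
null_config <- function(n_samples = 300, n_probes = 5000, seed = 1) {
  sim_config(n_samples = n_samples, n_probes = n_probes,
             dmp_effect_sd = 0, mqtl_effect = 0, n_mqtl_dmps = 0,
             exposure_effects = list(),
             liability_exposure_coefs = c(maternal_smoking = 0),
             seed = seed)
}

# Brute-force Benjamini-Hochberg step-up, straight from the definition:
# q_(i) = min_{j >= i} min(1, m * p_(j) / j), mapped back to input order.
bh_bruteforce <- function(p, m = length(p)) {
  o <- order(p)
  ps <- p[o]
  k <- length(p)
  q <- numeric(k)
  for (i in seq_len(k)) {
    q[i] <- min(1, min(m * ps[i:k] / (i:k)))
  }
  out <- numeric(k)
  out[o] <- q
  out
}

# Dense-ish null p-value track for region-calling tests.
null_track <- function(n = 5000, spacing = 1:400, seed = 1) {
  set.seed(seed)
  pos <- cumsum(sample(spacing, n, replace = TRUE))
  pval_track(chrom = rep("chr1", n), pos = pos, p = runif(n))
}
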
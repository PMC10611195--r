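# Shared fixtures and independent oracles used across test files.

# small, fast simulated experiment (built once per test run)
tiny_sim <- function(seed = 101, ...) {
  generate_experiment(simulation_config(
    "mouse_like", n_genes = 120, n_gene_sets = 12, set_size_range = c(5, 15),
    n_enriched_sets = 3, seed = seed, ...
  ))
}

# Brute-force two-tailed Fisher p via log-binomial-coefficient arithmetic:
# enumerates every feasible table with the observed margins. Independent of
# stats::dhyper.
fisher_enum_oracle <- function(overlap, set_size, n_resp, n_univ) {
  support <- max(0, n_resp + set_size - n_univ):min(n_resp, set_size)
  logp <- lchoose(set_size, support) +
    lchoose(n_univ - set_size, n_resp - support) -
    lchoose(n_univ, n_resp)
  p <- exp(logp)
  p_obs <- p[support == overlap]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# Gaussian constant-variance log-likelihood from an SSE (test-side copy of the
# closed form, used to build oracles without touching package internals)
ll_from_sse <- function(sse, n) -n / 2 * (log(2 * pi * sse / n) + 1)

# Dense grid-search oracle for the linear-model profile-likelihood BMDL.
# For each candidate BMD b, the BMR constraint pins sigma = |b1| * b / bmr,
# and the constrained log-likelihood is maximized over (b0, b1) on a dense
# grid around the MLE. The oracle BMDL is the smallest b on a fine grid whose
# profiled log-likelihood stays within qchisq(0.9, 1)/2 of the maximum.
linear_profile_bmdl_oracle <- function(doses, responses, bmr = 1.349,
                                       n_b = 400) {
  fit <- stats::lm(responses ~ doses)
  b0_hat <- coef(fit)[1]; b1_hat <- coef(fit)[2]
  n <- length(responses)
  sse_fun <- function(b0, b1) sum((responses - b0 - b1 * doses)^2)
  sig_hat <- sqrt(sse_fun(b0_hat, b1_hat) / n)
  bmd_hat <- bmr * sig_hat / abs(b1_hat)
  ll_max <- ll_from_sse(sse_fun(b0_hat, b1_hat), n)
  crit <- ll_max - qchisq(0.9, 1) / 2

  b0_grid <- seq(b0_hat - 1.5 * sig_hat, b0_hat + 1.5 * sig_hat, length.out = 150)
  b1_grid <- seq(b1_hat * 0.3, b1_hat * 1.9, length.out = 150)
  profile_ll <- function(b) {
    best <- -Inf
    for (b1 in b1_grid) {
      sig <- abs(b1) * b / bmr
      if (sig <= 0) next
      sse <- vapply(b0_grid, function(b0) sse_fun(b0, b1), numeric(1))
      ll <- -n / 2 * log(2 * pi * sig^2) - sse / (2 * sig^2)
      best <- max(best, max(ll))
    }
    best
  }
  b_grid <- exp(seq(log(bmd_hat / 8), log(bmd_hat), length.out = n_b))
  ok <- vapply(b_grid, function(b) profile_ll(b) >= crit, logical(1))
  b_grid[which(ok)[1]]
}
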
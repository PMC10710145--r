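# Independent oracles used across tests. Each is written directly from the
# defining formula (factorials, densities, normal equations) so it shares no
# code path with the implementation it checks.

# Exact HWE p-value by direct enumeration: conditional probability of each
# attainable heterozygote count from the log-factorial multinomial formula,
# normalized, then summed over counts no more probable than the observed one.
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_rare <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)
  if (n_rare == 0) return(1)
  hets <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  logp <- vapply(hets, function(h) {
    hom_rare <- (n_rare - h) / 2
    hom_com <- n - h - hom_rare
    lfactorial(n) - lfactorial(hom_rare) - lfactorial(h) -
      lfactorial(hom_com) + h * log(2)
  }, 0)
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_Aa, hets)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-10)]))
}

# Renormalized pointwise product of 1-D Gaussian densities on a grid;
# compares against a target Gaussian density on the same grid (sup-norm).
poe_grid_supnorm <- function(means, vars, target_mean, target_var) {
  lo <- min(means - 6 * sqrt(vars))
  hi <- max(means + 6 * sqrt(vars))
  grid <- seq(lo, hi, length.out = 4001)
  logprod <- Reduce(`+`, Map(function(m, v) dnorm(grid, m, sqrt(v), log = TRUE),
                             means, vars))
  dens <- exp(logprod - max(logprod))
  dens <- dens / (sum(dens) * (grid[2] - grid[1]))
  max(abs(dens - dnorm(grid, target_mean, sqrt(target_var))))
}

# Monte-Carlo KL( N(mu, diag(v)) || N(0, I) ) from the log-density ratio.
kl_mc <- function(mu, v, n_samples = 1e6) {
  d <- length(mu)
  x <- matrix(rnorm(n_samples * d), n_samples, d)
  x <- sweep(sweep(x, 2, sqrt(v), "*"), 2, mu, "+")
  logq <- rowSums(dnorm(x, rep(mu, each = n_samples),
                        rep(sqrt(v), each = n_samples), log = TRUE))
  logp <- rowSums(dnorm(x, log = TRUE))
  mean(logq - logp)
}

# Small scaled two-view factor dataset plus a fast training configuration.
quick_views <- function(n = 200, dims = c(12, 16), d_true = 3, seed = 1,
                        noise = 0.3) {
  mv <- simulate_multiview(n, d_true, dims, view_noise_sd = noise, seed = seed)
  scaled <- apply_scaler(fit_scaler(mv$views), mv$views)
  list(scaled = scaled, latent = mv$latent_true, raw = mv$views)
}

quick_cfg <- function(...) {
  train_config(latent_dim = 8, n_layers = 1, hidden_units = 16, epochs = 40,
               batch_size = 64, patience = 40, seed = 3, ...)
}
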
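# Independent oracles and small fixture builders used across test files.

# Brute-force von Mises overlap: explicit unit-by-unit summation with the
# unshifted tuning profile, normalized by the two vector norms. Kept
# deliberately separate from encode_direction()'s overflow-safe form.
vm_overlap_oracle <- function(kappa, n_units, theta1, theta2) {
  xi <- 2 * pi * (seq_len(n_units) - 1L) / n_units
  v1 <- exp(kappa * cos(theta1 - xi))
  v2 <- exp(kappa * cos(theta2 - xi))
  s <- 0
  for (j in seq_len(n_units)) s <- s + v1[j] * v2[j]
  s / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
}

# decoder sample with prescribed force directions (unit amplitudes)
decoder_from_angles <- function(psi) {
  sample_decoder(
    decoder_distribution("custom",
                         sampler = function(n) rbind(cos(psi), sin(psi))),
    n_neurons = length(psi))
}

# per-neuron accumulation oracle for the learning operator
build_A_oracle <- function(raw) {
  A <- matrix(0, nrow(raw), nrow(raw))
  for (i in seq_len(ncol(raw))) {
    A <- A + raw[, i] %*% t(raw[, i])
  }
  A / ncol(raw)
}

sample_skewness <- function(x) mean((x - mean(x))^3) / sd(x)^3

# exact paired signed-rank test by enumeration of all sign assignments
signed_rank_exact_oracle <- function(d) {
  stopifnot(all(d != 0))
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- drop(signs %*% r)
  p_two <- mean(abs(v_all - sum(r) / 2) >= abs(v_obs - sum(r) / 2))
  list(statistic = v_obs, p_value = p_two)
}

# fitted speeds for one condition over paired seeds
speeds_for <- function(n_reps, base_seed = 0L, ...) {
  run_condition(experiment_condition(...), n_reps, base_seed)$speeds
}
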
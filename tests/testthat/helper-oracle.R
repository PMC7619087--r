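# Independent brute-force oracles. These deliberately avoid the package's
# vectorised kernels: probabilities are multiplied read by read in linear
# space and posteriors normalised by direct division, so agreement with the
# package is evidence, not tautology.

oracle_read_p <- function(is_alt, e, f_t, f_g, pi) {
  q_alt <- function(f) f * (1 - e) + (1 - f) * e / 3
  q_ref <- function(f) (1 - f) * (1 - e) + f * e / 3
  if (is_alt) pi * q_alt(f_t) + (1 - pi) * q_alt(f_g)
  else pi * q_ref(f_t) + (1 - pi) * q_ref(f_g)
}

# Explicit per-read product for one sample under one genotype pair.
oracle_sample_lik <- function(depth, alt, k_g, k_t, cn_n, cn_t, alpha, e) {
  denom <- alpha * cn_t + (1 - alpha) * cn_n
  pi <- alpha * cn_t / denom
  f_t <- if (cn_t > 0) k_t / cn_t else 0
  f_g <- if (cn_n > 0) k_g / cn_n else 0
  lik <- 1
  for (r in seq_len(depth)) {
    lik <- lik * oracle_read_p(r <= alt, e, f_t, f_g, pi)
  }
  lik
}

# Exhaustive enumeration of genotype pairs with the same prior
# factorisation, normalised in linear space.
oracle_posterior <- function(t_depth, t_alt, n_depth, n_alt,
                             cn_n, cn_t, params) {
  grid <- expand.grid(k_g = 0:cn_n, k_t = 0:cn_t)
  grid$label <- ifelse(grid$k_g >= 1, "GERMLINE",
                       ifelse(grid$k_t >= 1, "SOMATIC", "REF"))
  n_germ <- sum(grid$label == "GERMLINE")
  n_som <- sum(grid$label == "SOMATIC")
  prior <- numeric(nrow(grid))
  prior[grid$label == "REF"] <- 1 - params$prior_snp - params$prior_somatic
  if (n_germ > 0)
    prior[grid$label == "GERMLINE"] <- params$prior_snp / n_germ
  if (n_som > 0)
    prior[grid$label == "SOMATIC"] <- params$prior_somatic / n_som
  prior <- prior / sum(prior)
  w <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    w[i] <- prior[i] *
      oracle_sample_lik(t_depth, t_alt, grid$k_g[i], grid$k_t[i],
                        cn_n, cn_t, params$alpha_t, params$base_error) *
      oracle_sample_lik(n_depth, n_alt, grid$k_g[i], grid$k_t[i],
                        cn_n, cn_t, params$alpha_n, params$base_error)
  }
  grid$posterior <- w / sum(w)
  grid
}

oracle_p_somatic <- function(...) {
  g <- oracle_posterior(...)
  sum(g$posterior[g$label == "SOMATIC"])
}

# Binomial log10-pmf from first principles (lgamma), for the GLOD check.
oracle_log10_binom <- function(k, n, p) {
  (lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1) +
     k * log(p) + (n - k) * log(1 - p)) / log(10)
}

oracle_glod <- function(normal_alt, normal_depth, tumour_vaf,
                        alpha_t, alpha_n, xi) {
  p_germ <- 0.5 * xi
  p_som <- min(max(tumour_vaf * alpha_n / max(alpha_t, 0.01), 1e-3), 0.5)
  if (p_som == p_germ) return(0)
  oracle_log10_binom(normal_alt, normal_depth, p_germ) -
    oracle_log10_binom(normal_alt, normal_depth, p_som)
}
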
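# Shared fixtures and independent oracles used across test files.

# Two vectors with an *exact* sample correlation r: both are standardized
# (mean 0, sd 1) and the second is built from the orthogonalized residual,
# so cor(t1, t2) == r and the symmetric double-entry correlation equals r
# to floating-point precision.
make_exact_cor_pairs <- function(r, n, seed = 1) {
  set.seed(seed)
  a <- as.numeric(scale(rnorm(n)))
  b <- rnorm(n)
  b_perp <- as.numeric(scale(b - a * sum(a * b) / sum(a * a)))
  t2 <- r * a + sqrt(1 - r^2) * b_perp
  list(t1 = a, t2 = t2)
}

# Long-format twin table with exact MZ and DZ co-twin correlations.
make_twin_table <- function(r_mz, r_dz, n_pairs = 50, seed = 1) {
  mz <- make_exact_cor_pairs(r_mz, n_pairs, seed)
  dz <- make_exact_cor_pairs(r_dz, n_pairs, seed + 1000)
  rbind(
    data.frame(pair_id = rep(sprintf("M%03d", seq_len(n_pairs)), each = 2),
               zygosity = "MZ",
               acceleration = as.numeric(rbind(mz$t1, mz$t2))),
    data.frame(pair_id = rep(sprintf("D%03d", seq_len(n_pairs)), each = 2),
               zygosity = "DZ",
               acceleration = as.numeric(rbind(dz$t1, dz$t2))))
}

# Two-sided Fisher exact p by full hypergeometric enumeration over all
# tables with the observed margins (independent of stats::fisher.test).
fisher_enum_p <- function(a, b, c, d) {
  m <- a + b      # selected
  n <- c + d      # not selected
  k <- a + c      # in category
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Noiseless cohort whose transformed age is an exact linear function of
# two probes: y = 0.5 * beta[probe1] - 0.3 * beta[probe7] + 0.1.
make_noiseless_linear_cohort <- function(n = 200, p = 50, seed = 42) {
  set.seed(seed)
  betas <- matrix(runif(p * n), p, n,
                  dimnames = list(sprintf("cg%08d", 1:p),
                                  sprintf("s%04d", 1:n)))
  score <- 0.5 * betas[1, ] - 0.3 * betas[7, ] + 0.1
  samples <- data.frame(sample_id = colnames(betas),
                        age = inverse_transform_age(score),
                        stringsAsFactors = FALSE)
  list(betas = betas, samples = samples, score = score)
}

# Small multi-data-set cohort for LOOCV / meta-analysis tests.
make_loocv_cohort <- function(n_per_ds = 40, n_datasets = 3, n_probes = 250,
                              n_causal = 60, seed = 7, noise_sd = 0.02) {
  sim <- simulate_methylome(sim_config(
    n_samples = n_per_ds * n_datasets, n_probes = n_probes,
    n_causal = n_causal, n_datasets = n_datasets, noise_sd = noise_sd,
    seed = seed))
  sim
}
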
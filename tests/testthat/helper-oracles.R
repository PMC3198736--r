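# Independent oracles and fixture builders shared across the suite.

# Exact hypergeometric upper tail by direct enumeration of the support.
# Uses lchoose so it also serves as a large-N cross-route; for N <= 30
# the choose() terms are exact rationals within double precision.
hyper_tail_enum <- function(k, K, n, N) {
  if (k == 0) return(1)
  ks <- k:min(K, n)
  sum(exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)))
}

# Per-gene one-way ANOVA through stats::lm/anova, the reference route
# against the package's vectorised fit.
lm_gene_oracle <- function(values, genotypes) {
  g <- factor(genotypes, levels = unique(genotypes))
  fit <- lm(values ~ g)
  an <- anova(fit)
  list(means = tapply(values, g, mean),
       s2 = an["Residuals", "Mean Sq"],
       df = an["Residuals", "Df"],
       fstat = an["g", "F value"],
       p = an["g", "Pr(>F)"])
}

# Group of n values with exactly the requested mean and SEM.
make_exact_group <- function(m, sem, n = 4) {
  u <- seq(-1, 1, length.out = n)
  u <- u / sd(u)
  m + sem * sqrt(n) * u
}

# Simulated four-genotype fit with planted truth; returns fit + truth.
sim_fit <- function(n_genes, n_reps = 3, noise_sd = 0.3, seed = 1, ...) {
  cfg <- sim_config(n_genes = n_genes, n_reps = n_reps,
                    noise_sd = noise_sd, seed = seed, ...)
  sim <- simulate_expression(cfg)
  list(fit = genotype_anova(sim$matrix, sim$samples), sim = sim)
}

# Largest pairwise M-vs-A lowess trend amplitude across arrays.
ma_trend_amplitude <- function(x, span = 0.3) {
  pairs <- combn(ncol(x), 2)
  max(apply(pairs, 2, function(ij) {
    M <- x[, ij[1]] - x[, ij[2]]
    A <- (x[, ij[1]] + x[, ij[2]]) / 2
    f <- lowess(A, M, f = span)
    max(abs(f$y - mean(M)))
  }))
}
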
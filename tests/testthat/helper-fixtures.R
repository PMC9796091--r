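# Shared fixtures: everything is generated in code at test time.

# Small simulated trio dataset with known generating components.
make_trio_fixture <- function(n_trios = 150, n_snps = 400, seed = 42,
                              var_o = 0.3, var_m = 0.08, var_p = 0.08,
                              cov_om = -0.04, cov_op = -0.04, cov_mp = 0.08,
                              resid_var = 0.7, sex_effect = 0.25) {
  P <- sim_params(n_trios, n_snps,
                  genetic_cov = genetic_cov_matrix(var_o, var_m, var_p,
                                                   cov_om, cov_op, cov_mp),
                  resid_var = resid_var, sex_effect = sex_effect, seed = seed)
  sim <- simulate_trio_genotypes(P)
  ph <- simulate_phenotypes(sim$geno, sim$trios, P)
  # at small sizes a SNP can be monomorphic among founders; QC would drop it
  p <- founder_freq(sim$geno, sim$trios)
  if (any(p <= 0 | p >= 1)) {
    keep <- which(p > 0 & p < 1)
    sf <- attr(sim$geno, "sim_freq")
    sim$geno <- subset_genotypes(sim$geno, cols = keep)
    attr(sim$geno, "sim_freq") <- sf[keep]
    p <- p[keep]
  }
  grm <- compute_grm(sim$geno, freq = p)
  list(params = P, geno = sim$geno, trios = sim$trios, pheno = ph,
       grm = grm, grms = trio_grm_blocks(grm, sim$trios),
       X = cbind(intercept = 1, sex = ph$sex))
}

# Dense multivariate-normal -2 log-likelihood oracle: determinant() + solve(),
# no Cholesky sharing with the implementation path.
dense_neg2ll_oracle <- function(theta, y, X, grms, spec) {
  V <- build_covariance(grms, theta, spec)
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  n <- length(y)
  ld <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  n * log(2 * pi) + ld + drop(t(r) %*% Vi %*% r)
}

# Brute-force Mendelian transmission oracle: enumerate the gametes each
# parent can produce and collect all possible offspring dosages.
mendel_possible_oracle <- function(father, mother) {
  gametes <- function(g) switch(as.character(g), "0" = 0L, "1" = c(0L, 1L), "2" = 1L)
  unique(as.vector(outer(gametes(father), gametes(mother), `+`)))
}

# Parse the published p-value strings (".34", "<.01", "1.00").
parse_p <- function(s) {
  ifelse(s == "<.01", NA_real_, suppressWarnings(as.numeric(sub("^<", "", s))))
}
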
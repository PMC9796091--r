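test_that("trio genotypes follow Mendelian transmission and allele frequencies", {
  P <- sim_params(300, 600, maf_range = c(0.05, 0.5), seed = 11)
  sim <- simulate_trio_genotypes(P)
  expect_equal(dim(sim$geno$dosages), c(900, 600))

  # transmission is Mendelian by construction: zero errors at any seed
  rep <- mendelian_error_scan(sim$geno, sim$trios)
  expect_equal(sum(rep$mendel_by_snp$n_errors), 0)
  expect_equal(rep$n_soft_calls, 0)

  # generating frequencies are recovered by the sample estimate
  p <- attr(sim$geno, "sim_freq")
  expect_lt(max(abs(sim$geno$allele_freq - p)), 0.1)
  expect_gt(cor(sim$geno$allele_freq, p), 0.98)

  # offspring and parents share the same marginal frequency
  P5 <- sim_params(400, 300, maf_range = c(0.5, 0.5), seed = 3)
  sim5 <- simulate_trio_genotypes(P5)
  for (rows in list(sim5$trios$offspring_row, sim5$trios$mother_row,
                    sim5$trios$father_row))
    expect_equal(mean(sim5$geno$dosages[rows, ]), 1, tolerance = 0.02)
})

test_that("generators are bit-identical under a fixed seed", {
  P <- sim_params(40, 60, genetic_cov = genetic_cov_matrix(0.2), seed = 99)
  a <- simulate_trio_genotypes(P); b <- simulate_trio_genotypes(P)
  expect_identical(a$geno$dosages, b$geno$dosages)
  expect_identical(a$trios, b$trios)
  pa <- simulate_phenotypes(a$geno, a$trios, P)
  pb <- simulate_phenotypes(b$geno, b$trios, P)
  expect_identical(pa$y, pb$y)
  i1 <- simulate_items(pa$y, 8, missing_rate = 0.1, seed = 5)
  i2 <- simulate_items(pa$y, 8, missing_rate = 0.1, seed = 5)
  expect_identical(i1, i2)
})

test_that("parent-offspring cross-relatedness concentrates at 1/2", {
  fx <- make_trio_fixture(n_trios = 250, n_snps = 1200, seed = 21)
  expect_equal(mean(diag(fx$grms$A_om)), 0.5, tolerance = 0.03)
  expect_equal(mean(diag(fx$grms$A_op)), 0.5, tolerance = 0.03)
  expect_equal(mean(diag(fx$grms$A_mp)), 0, tolerance = 0.03)
})

test_that("pure-noise phenotypes have unit variance and recover the sex effect", {
  P <- sim_params(2500, 50, genetic_cov = matrix(0, 3, 3), resid_var = 1,
                  sex_effect = 0.4, intercept = 1.5, seed = 8)
  sim <- simulate_trio_genotypes(P)
  ph <- simulate_phenotypes(sim$geno, sim$trios, P)
  expect_equal(var(ph$y[ph$sex == 0]), 1, tolerance = 0.08)
  expect_equal(var(ph$y[ph$sex == 1]), 1, tolerance = 0.08)
  co <- summary(lm(y ~ sex, data = ph))$coefficients
  expect_lt(abs(co["sex", "Estimate"] - 0.4), 2.5 * co["sex", "Std. Error"])
  expect_lt(abs(co["(Intercept)", "Estimate"] - 1.5),
            2.5 * co["(Intercept)", "Std. Error"])
})

test_that("genetic score variance matches its target and its realized value", {
  P <- sim_params(2000, 800, genetic_cov = genetic_cov_matrix(var_o = 0.25),
                  resid_var = 0.75, seed = 13)
  sim <- simulate_trio_genotypes(P)
  ph <- simulate_phenotypes(sim$geno, sim$trios, P)
  sc <- attr(ph, "scores")
  # target value, within Monte-Carlo error
  expect_lt(abs(var(sc[, "o"]) - 0.25), 0.04)
  # exact agreement with the score recomputed from the retained effects
  beta <- attr(ph, "beta")
  p <- attr(sim$geno, "sim_freq")
  z <- sweep(sweep(sim$geno$dosages[sim$trios$offspring_row, ], 2, 2 * p),
             2, sqrt(2 * p * (1 - p)), "/")
  expect_equal(drop(z %*% beta[, "o"]), sc[, "o"], tolerance = 1e-12)
})

test_that("phenotype variance follows the trio accounting identity", {
  # sigma_mp is absent from the accounting; parent-offspring covariances
  # enter once
  fx <- make_trio_fixture(n_trios = 2000, n_snps = 500, seed = 31,
                          var_o = 0.25, var_m = 0.1, var_p = 0.1,
                          cov_om = -0.06, cov_op = -0.06, cov_mp = 0.1,
                          resid_var = 0.6, sex_effect = 0)
  expected <- 0.25 + 0.1 + 0.1 - 0.06 - 0.06 + 0.6
  expect_lt(abs(var(fx$pheno$y) - expected), 0.07)
  # empirical cov(direct score, one parental score) ~ 0.5 * cov_om
  sc <- attr(fx$pheno, "scores")
  expect_lt(abs(cov(sc[, "o"], sc[, "m"]) - 0.5 * (-0.06)), 0.025)
})

test_that("invalid simulation parameters are rejected", {
  expect_error(sim_params(0, 10), class = "triovc_config_error")
  expect_error(sim_params(10, 10, maf_range = c(0, 0.5)),
               class = "triovc_config_error")
  expect_error(sim_params(10, 10, maf_range = c(0.1, 0.6)),
               class = "triovc_config_error")
  expect_error(sim_params(10, 10, genetic_cov = matrix(1:9, 3)),
               class = "triovc_config_error")   # asymmetric
  # non-PSD covariance is rejected with the offending eigenvalue named
  bad <- genetic_cov_matrix(0.1, 0.1, 0.1, cov_om = 0.5)
  P <- sim_params(20, 30, genetic_cov = bad, seed = 1)
  sim <- simulate_trio_genotypes(P)
  expect_error(simulate_phenotypes(sim$geno, sim$trios, P),
               "eigenvalue", class = "triovc_config_error")
})

test_that("item generation is rank-concordant, floored, and MCAR-missing", {
  set.seed(77)
  scores <- rnorm(600)
  items <- simulate_items(scores, n_items = 8, missing_rate = 0, seed = 2,
                          scale = "conduct")
  expect_true(all(as.matrix(items) %in% 1:4))
  sums <- rowSums(items)
  expect_gt(cor(sums, scores, method = "spearman"), 0.9)

  # constant latent input sits at the floor
  flat <- simulate_items(rep(-3, 50), n_items = 8, seed = 3)
  expect_true(all(as.matrix(flat) == 1))

  # heavy missingness trips the downstream 50% rule for nearly everyone
  holey <- simulate_items(scores, n_items = 8, missing_rate = 0.99, seed = 4,
                          scale = "conduct")
  scored <- score_subscales(holey, subscale_defs("conduct"))
  expect_gt(mean(is.na(scored$conduct)), 0.95)

  # MCAR rate is honoured
  some <- simulate_items(scores, n_items = 9, missing_rate = 0.2, seed = 5)
  expect_equal(mean(is.na(as.matrix(some))), 0.2, tolerance = 0.02)

  expect_error(simulate_items(scores, 0), class = "triovc_config_error")
  expect_error(simulate_items(scores, 8, missing_rate = 1),
               class = "triovc_config_error")
})
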
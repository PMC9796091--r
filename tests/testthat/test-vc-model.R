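test_that("covariance builder handles the null, idealized and toy cases", {
  # null spec: V = sigma2_e * I
  id3 <- diag(3)
  gs0 <- structure(list(A_oo = id3, A_mm = id3, A_pp = id3,
                        A_om = matrix(0, 3, 3), A_op = matrix(0, 3, 3),
                        A_mp = matrix(0, 3, 3), n = 3), class = "grm_set")
  expect_equal(build_covariance(gs0, 1, vc_spec("null")), diag(3))

  # idealized blocks: diag(V) = s2o + s2m + s2p + s_om + s_op + s2e exactly
  gsI <- structure(list(A_oo = id3, A_mm = id3, A_pp = id3,
                        A_om = diag(0.5, 3), A_op = diag(0.5, 3),
                        A_mp = matrix(0, 3, 3), n = 3), class = "grm_set")
  th <- c(0.25, 0.1, 0.12, -0.05, -0.04, 0.08, 0.6)
  V <- build_covariance(gsI, th, vc_spec("differential"))
  expect_equal(diag(V), rep(0.25 + 0.1 + 0.12 - 0.05 - 0.04 + 0.6, 3))

  # 2-trio toy with hand-chosen entries, evaluated by hand
  A_oo <- matrix(c(1, 0.1, 0.1, 1), 2); A_mm <- matrix(c(1, 0, 0, 1), 2)
  A_pp <- matrix(c(1.1, 0.05, 0.05, 0.9), 2)
  A_om <- matrix(c(0.5, 0.02, -0.01, 0.48), 2)
  A_op <- matrix(c(0.52, 0, 0.03, 0.5), 2)
  A_mp <- matrix(c(0.01, 0, 0, -0.02), 2)
  gs2 <- structure(list(A_oo = A_oo, A_mm = A_mm, A_pp = A_pp, A_om = A_om,
                        A_op = A_op, A_mp = A_mp, n = 2), class = "grm_set")
  th2 <- c(0.3, 0.1, 0.1, -0.06, -0.05, 0.04, 0.5)
  hand <- 0.3 * A_oo + 0.1 * A_mm + 0.1 * A_pp - 0.06 * (A_om + t(A_om)) -
    0.05 * (A_op + t(A_op)) + 0.04 * (A_mp + t(A_mp)) + 0.5 * diag(2)
  expect_equal(build_covariance(gs2, th2, vc_spec("differential")), hand)

  # combined spec ties the parental blocks to one per-parent variance
  thc <- c(0.3, 0.1, -0.06, 0.5)
  handc <- 0.3 * A_oo + 0.1 * (A_mm + A_pp + A_mp + t(A_mp)) -
    0.06 * (A_om + t(A_om) + A_op + t(A_op)) + 0.5 * diag(2)
  expect_equal(build_covariance(gs2, thc, vc_spec("combined")), handc)

  expect_error(build_covariance(gs2, c(1, 2), vc_spec("differential")),
               class = "triovc_input_error")
})

test_that("build_covariance is linear in every parameter", {
  fx <- make_trio_fixture(n_trios = 8, n_snps = 60, seed = 2)
  spec <- vc_spec("differential")
  th <- c(0.3, 0.1, 0.1, -0.05, -0.04, 0.05, 0.6)
  for (j in seq_along(th)) {
    e <- rep(0, 7); e[j] <- 1
    d1 <- build_covariance(fx$grms, th + e, spec) -
      build_covariance(fx$grms, th, spec)
    d2 <- build_covariance(fx$grms, th + 2 * e, spec) -
      build_covariance(fx$grms, th + e, spec)
    expect_equal(d1, d2, tolerance = 1e-10)
  }
})

test_that("the likelihood matches textbook values and the dense oracle", {
  # V = I, intercept-only, y = 0: -2ll = n log(2 pi)
  id <- diag(4)
  gs <- structure(list(A_oo = id, A_mm = id, A_pp = id,
                       A_om = matrix(0, 4, 4), A_op = matrix(0, 4, 4),
                       A_mp = matrix(0, 4, 4), n = 4), class = "grm_set")
  val <- neg2_loglik(1, rep(0, 4), matrix(1, 4, 1), gs, vc_spec("null"))
  expect_equal(as.numeric(val), 4 * log(2 * pi), tolerance = 1e-12)

  # random small instances against the determinant/solve oracle
  fx <- make_trio_fixture(n_trios = 5, n_snps = 80, seed = 77)
  spec <- vc_spec("differential")
  th <- c(0.4, 0.15, 0.1, -0.05, 0.02, 0.03, 0.8)
  mine <- as.numeric(neg2_loglik(th, fx$pheno$y, fx$X, fx$grms, spec))
  oracle <- dense_neg2ll_oracle(th, fx$pheno$y, fx$X, fx$grms, spec)
  expect_equal(mine, oracle, tolerance = 1e-10)

  # permutation invariance
  perm <- sample(5)
  tp <- trio_index(fx$trios$offspring_row[perm], fx$trios$mother_row[perm],
                   fx$trios$father_row[perm], fx$trios$offspring_sex[perm])
  gsp <- trio_grm_blocks(fx$grm, tp)
  mine_p <- as.numeric(neg2_loglik(th, fx$pheno$y[perm], fx$X[perm, ], gsp, spec))
  expect_equal(mine_p, mine, tolerance = 1e-9)
})

test_that("spec transforms are inverse pairs and respect the constraints", {
  for (nm in c("differential", "combined", "no_parental", "null")) {
    spec <- vc_spec(nm)
    raw <- switch(nm,
                  differential = c(0.3, 0.12, 0.1, -0.05, 0.04, 0.02, 0.7),
                  combined = c(0.3, 0.1, -0.08, 0.7),
                  no_parental = c(0.3, 0.7), null = 0.7)
    round_trip <- spec$trans_to_raw(spec$raw_to_trans(raw))
    expect_equal(round_trip, raw, tolerance = 1e-6)
    # any transformed point maps to a valid (PSD) parameter set
    set.seed(5)
    t_rand <- rnorm(length(spec$raw_to_trans(raw)))
    r <- spec$trans_to_raw(t_rand)
    c7 <- as.vector(spec$M %*% r)
    S <- matrix(c(c7[1], c7[4], c7[5], c7[4], c7[2], c7[6],
                  c7[5], c7[6], c7[3]), 3, 3)
    expect_gte(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
    expect_gt(c7[7], 0)
  }
})

test_that("null fit equals the closed-form ML residual variance", {
  fx <- make_trio_fixture(n_trios = 100, n_snps = 150, seed = 55)
  f <- fit_vc("null", fx$pheno$y, fx$X, fx$grms)
  expect_true(f$converged)
  s2_ml <- mean(lm.fit(fx$X, fx$pheno$y)$residuals^2)
  expect_equal(unname(f$estimates), s2_ml, tolerance = 1e-6)
  expect_equal(unname(f$fixed_effects),
               unname(coef(lm(fx$pheno$y ~ 0 + fx$X))), tolerance = 1e-6)
})

test_that("-2ll is non-increasing along the nesting chain", {
  fx <- make_trio_fixture(n_trios = 120, n_snps = 250, seed = 66)
  fits <- fit_all_specs(fx$pheno$y, fx$X, fx$grms,
                        options = fit_options(all_starts = TRUE))
  lls <- vapply(fits[c("null", "no_parental", "combined", "differential")],
                `[[`, numeric(1), "neg2_loglik")
  expect_true(all(diff(lls) <= 1e-4))
})

test_that("standardized estimates sum to one and resist phenotype rescaling", {
  fx <- make_trio_fixture(n_trios = 120, n_snps = 250, seed = 88)
  f <- fit_vc("combined", fx$pheno$y, fx$X, fx$grms)
  expect_true(f$converged)
  acct <- f$standardized$est
  expect_equal(sum(acct[c("sigma2_o", "sigma2_m", "sigma2_p", "sigma_om",
                          "sigma_op", "sigma2_e")]), 1, tolerance = 1e-8)

  f_scaled <- fit_vc("combined", 3.7 * fx$pheno$y, fx$X, fx$grms)
  expect_equal(f_scaled$standardized$est, f$standardized$est, tolerance = 1e-3)
  expect_equal(f_scaled$standardized$total, 3.7^2 * f$standardized$total,
               tolerance = 1e-2)

  expect_error(standardize_fit(structure(list(converged = FALSE),
                                         class = "vc_fit")),
               class = "triovc_input_error")
})

test_that("likelihood-ratio statistic for parental effects is conservative under the null", {
  # under a no-parental generative model the no_parental vs null LRT should
  # reject at roughly its nominal level or below (boundary effect)
  n_rej <- 0; reps <- 10
  for (s in seq_len(reps)) {
    fx <- make_trio_fixture(n_trios = 100, n_snps = 150, seed = 200 + s,
                            var_o = 0, var_m = 0, var_p = 0, cov_om = 0,
                            cov_op = 0, cov_mp = 0, resid_var = 1)
    f0 <- fit_vc("null", fx$pheno$y, fx$X, fx$grms)
    f1 <- fit_vc("no_parental", fx$pheno$y, fx$X, fx$grms)
    if (lrt(f0, f1)$p < 0.2) n_rej <- n_rej + 1
  }
  # nominal 20% level: allow generous sampling slack on 10 replicates
  expect_lte(n_rej, 5)
})
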
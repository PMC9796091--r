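#' Simulation parameters for synthetic trio data
#'
#' Bundles the generative settings for the synthetic trio generator: design
#' sizes, the allele-frequency range, the 3x3 genetic covariance matrix among
#' direct, maternal and paternal per-SNP effects, the residual variance, a sex
#' main effect and an intercept.
#'
#' The genetic covariance matrix is ordered (offspring, mother, father): its
#' diagonal holds the variance components \eqn{\sigma_o^2, \sigma_m^2,
#' \sigma_p^2} and its off-diagonals \eqn{\sigma_{om}, \sigma_{op},
#' \sigma_{mp}}, all in phenotype-variance units. Because effects are placed
#' on standardized genotypes, these entries are directly the target variance
#' components of the fitted model.
#'
#' @param n_trios number of parent-offspring trios (> 0).
#' @param n_snps number of biallelic SNPs (> 0).
#' @param maf_range length-2 vector of allele frequencies in (0, 0.5].
#' @param genetic_cov 3x3 symmetric matrix (see Details); defaults to zero.
#' @param resid_var residual variance \eqn{\sigma_\epsilon^2 \ge 0}.
#' @param sex_effect additive mean shift for males (sex coded 1).
#' @param intercept scalar intercept.
#' @param seed integer seed; all generators are bit-reproducible given it.
#' @return an object of class `sim_params` (a validated list).
#' @seealso [genetic_cov_matrix()] to build `genetic_cov` from the six
#'   components.
#' @export
sim_params <- function(n_trios, n_snps, maf_range = c(0.05, 0.5),
                       genetic_cov = matrix(0, 3, 3), resid_var = 1,
                       sex_effect = 0, intercept = 0, seed = 1L) {
  if (length(n_trios) != 1 || n_trios < 1 || n_trios != round(n_trios))
    tv_stop("n_trios must be a positive count", "triovc_config_error")
  if (length(n_snps) != 1 || n_snps < 1 || n_snps != round(n_snps))
    tv_stop("n_snps must be a positive count", "triovc_config_error")
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    tv_stop("maf_range must lie within (0, 0.5]", "triovc_config_error")
  genetic_cov <- as.matrix(genetic_cov)
  if (!all(dim(genetic_cov) == c(3, 3)) ||
      max(abs(genetic_cov - t(genetic_cov))) > 1e-10)
    tv_stop("genetic_cov must be a symmetric 3x3 matrix", "triovc_config_error")
  if (any(diag(genetic_cov) < 0))
    tv_stop("genetic_cov diagonal must be non-negative", "triovc_config_error")
  if (resid_var < 0) tv_stop("resid_var must be >= 0", "triovc_config_error")
  structure(list(n_trios = as.integer(n_trios), n_snps = as.integer(n_snps),
                 maf_range = as.numeric(maf_range), genetic_cov = genetic_cov,
                 resid_var = resid_var, sex_effect = sex_effect,
                 intercept = intercept, seed = as.integer(seed)),
            class = "sim_params")
}

#' Build the 3x3 genetic covariance matrix from its six components
#'
#' @param var_o,var_m,var_p variances of direct, maternal and paternal effects.
#' @param cov_om,cov_op,cov_mp covariances (direct-maternal, direct-paternal,
#'   maternal-paternal).
#' @return 3x3 symmetric matrix ordered (offspring, mother, father).
#' @export
genetic_cov_matrix <- function(var_o = 0, var_m = 0, var_p = 0,
                               cov_om = 0, cov_op = 0, cov_mp = 0) {
  matrix(c(var_o, cov_om, cov_op,
           cov_om, var_m, cov_mp,
           cov_op, cov_mp, var_p), 3, 3,
         dimnames = list(c("o", "m", "p"), c("o", "m", "p")))
}

#' Simulate trio genotypes by Mendelian transmission
#'
#' Parental dosages at SNP j are independent Binomial(2, p_j) draws with p_j
#' uniform on `maf_range`; each offspring allele is a fair Mendelian draw from
#' each parent (a heterozygous parent transmits either allele with probability
#' 1/2). The expected genomic relatedness between a parent and its offspring
#' is therefore 1/2 and between the two parents 0. Offspring sex is assigned
#' Bernoulli(0.5) (1 = male).
#'
#' Rows are stacked offspring (1..N), mothers (N+1..2N), fathers (2N+1..3N).
#' The generating allele frequencies are kept in the attribute `"sim_freq"`;
#' [simulate_phenotypes()] standardizes genotypes with them, whereas the
#' estimation side works from sample estimates.
#'
#' @param params a [sim_params] object.
#' @return list with elements `geno` ([genotype_data]) and `trios`
#'   ([trio_index]).
#' @export
simulate_trio_genotypes <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  n <- params$n_trios; m <- params$n_snps
  p <- runif(m, params$maf_range[1], params$maf_range[2])
  mothers <- matrix(rbinom(n * m, 2L, rep(p, each = n)), n, m)
  fathers <- matrix(rbinom(n * m, 2L, rep(p, each = n)), n, m)
  # transmitted allele ~ Bernoulli(dosage / 2): 0 -> ref, 2 -> alt, 1 -> fair coin
  off <- matrix(rbinom(n * m, 1L, mothers / 2) + rbinom(n * m, 1L, fathers / 2), n, m)
  sex <- rbinom(n, 1L, 0.5)
  dos <- rbind(off, mothers, fathers)
  ids <- c(sprintf("off%d", seq_len(n)), sprintf("mot%d", seq_len(n)),
           sprintf("fat%d", seq_len(n)))
  geno <- genotype_data(dos, ids = ids)
  attr(geno, "sim_freq") <- p
  trios <- trio_index(offspring_row = seq_len(n),
                      mother_row = n + seq_len(n),
                      father_row = 2L * n + seq_len(n),
                      offspring_sex = sex)
  list(geno = geno, trios = trios)
}

# Draw from N(0, S/k) rows; S may be positive semi-definite. Errors name the
# offending eigenvalue when S is not PSD.
rmvnorm_psd <- function(nr, S, k = 1, tol = 1e-8) {
  e <- eigen(S / k, symmetric = TRUE)
  lmin <- min(e$values)
  if (lmin < -tol * max(abs(e$values), 1))
    tv_stop(sprintf("genetic_cov is not positive semi-definite (eigenvalue %.6g)",
                    lmin * k), "triovc_config_error")
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(S))
  matrix(rnorm(nr * nrow(S)), nr) %*% t(L)
}

#' Simulate phenotypes with direct and indirect parental genetic effects
#'
#' Per-SNP effect triples \eqn{(\beta_o, \beta_m, \beta_p)} are drawn i.i.d.
#' from a trivariate normal with covariance `genetic_cov / n_snps`. Genetic
#' scores are computed on column-standardized dosages
#' \eqn{z = (x - 2p)/\sqrt{2p(1-p)}} using the generating frequencies, and
#' \deqn{y = \mu + b_{sex} \cdot sex + z_o \beta_o + z_m \beta_m + z_p \beta_p
#'   + \epsilon,\qquad \epsilon \sim N(0, \sigma_\epsilon^2).}
#' Under this construction the expected phenotypic variance is
#' \eqn{\sigma_o^2+\sigma_m^2+\sigma_p^2+\sigma_{om}+\sigma_{op}+
#' \sigma_\epsilon^2} (the parent-parent covariance does not contribute, and
#' parent-offspring covariances contribute once, not twice, because the
#' relatedness between the generations is 1/2).
#'
#' Draws are seeded with `params$seed + 1` so the phenotype stream is decoupled
#' from the genotype stream while remaining reproducible.
#'
#' @param geno,trios output of [simulate_trio_genotypes()].
#' @param params the same [sim_params] object.
#' @return a `data.frame` with columns `trio`, `id`, `sex`, `y`; the realized
#'   per-role genetic scores are attached as attribute `"scores"` (an N x 3
#'   matrix) and the per-SNP effects as attribute `"beta"` (n_snps x 3), for
#'   oracle checks.
#' @export
simulate_phenotypes <- function(geno, trios, params) {
  stopifnot(inherits(params, "sim_params"))
  p <- attr(geno, "sim_freq")
  if (is.null(p)) p <- geno$allele_freq
  set.seed(params$seed + 1L)
  beta <- rmvnorm_psd(params$n_snps, params$genetic_cov, k = params$n_snps)
  colnames(beta) <- c("o", "m", "p")
  sdv <- sqrt(2 * p * (1 - p))
  std <- function(rows) {
    x <- geno$dosages[rows, , drop = FALSE]
    sweep(sweep(x, 2, 2 * p), 2, sdv, "/")
  }
  g_o <- drop(std(trios$offspring_row) %*% beta[, "o"])
  g_m <- drop(std(trios$mother_row) %*% beta[, "m"])
  g_p <- drop(std(trios$father_row) %*% beta[, "p"])
  eps <- rnorm(params$n_trios, 0, sqrt(params$resid_var))
  y <- params$intercept + params$sex_effect * trios$offspring_sex +
    g_o + g_m + g_p + eps
  out <- data.frame(trio = trios$trio, id = geno$ids[trios$offspring_row],
                    sex = trios$offspring_sex, y = y)
  attr(out, "scores") <- cbind(o = g_o, m = g_m, p = g_p)
  attr(out, "beta") <- beta
  out
}

#' Generate ordinal 1-4 item ratings from latent scores
#'
#' Produces an item-level table whose per-individual item sum is a monotone
#' (rank-concordant) transform of the latent score, with missing-completely-
#' at-random missingness. Latent scores are mapped linearly onto the
#' achievable sum range \[n_items, 4*n_items\], rounded, and the excess over
#' the floor is allocated at random across items (each item holding at most 3
#' excess units). Constant latent input maps to the floor (all items 1).
#'
#' This is a fixture generator for the scoring pipeline, not a psychometric
#' model of any particular rating instrument.
#'
#' @param scores numeric vector of latent scores (one subscale).
#' @param n_items number of items (>= 1).
#' @param missing_rate MCAR missingness proportion in \[0, 1).
#' @param seed integer seed.
#' @param scale name used for the item columns `<scale>_item<k>`.
#' @return data.frame of integer items in 1..4 with `NA` for missing entries.
#' @export
simulate_items <- function(scores, n_items, missing_rate = 0, seed = 1L,
                           scale = "scale") {
  if (length(n_items) != 1 || n_items < 1 || n_items != round(n_items))
    tv_stop("n_items must be a positive count", "triovc_config_error")
  if (missing_rate < 0 || missing_rate >= 1)
    tv_stop("missing_rate must be in [0, 1)", "triovc_config_error")
  set.seed(as.integer(seed))
  n <- length(scores)
  lo <- min(scores); hi <- max(scores)
  extra <- if (hi > lo) round(3 * n_items * (scores - lo) / (hi - lo)) else rep(0L, n)
  items <- matrix(1L, n, n_items)
  slots <- rep(seq_len(n_items), each = 3)  # each item can rise from 1 to 4
  for (i in seq_len(n)) {
    if (extra[i] > 0) {
      take <- sample(slots, extra[i])
      items[i, ] <- items[i, ] + tabulate(take, nbins = n_items)
    }
  }
  if (missing_rate > 0)
    items[matrix(runif(n * n_items) < missing_rate, n, n_items)] <- NA
  items <- as.data.frame(items)
  names(items) <- sprintf("%s_item%d", scale, seq_len(n_items))
  items
}
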
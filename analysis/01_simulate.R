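#!/usr/bin/env Rscript
# Generate a synthetic trio cohort: one set of genotypes transmitted by
# Mendelian inheritance, and four subscale phenotypes with distinct genetic
# architectures echoing the published pattern for childhood externalizing
# symptoms -- negative direct-indirect covariance for conduct and
# inattention, positive for hyperactivity, and no parental effects for
# oppositional. Writes PLINK bed/bim/fam, a phenotype TSV and item-level
# TSVs under results/sim/.

library(triovc)

out_dir <- "results/sim"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

n_trios <- 1200L; n_snps <- 2000L; base_seed <- 20260929L

# per-subscale generative components (standardized total = 1):
#   var_o  tau (= var_m = var_p = cov_mp)  gamma (= cov_om = cov_op)  resid
arch <- list(
  conduct       = c(0.20, 0.070, -0.080, 0.82),
  inattention   = c(0.24, 0.080, -0.064, 0.728),
  hyperactivity = c(0.12, 0.040,  0.030, 0.74),
  oppositional  = c(0.12, 0.000,  0.000, 0.88))

geno_params <- sim_params(n_trios, n_snps, maf_range = c(0.05, 0.5),
                          seed = base_seed)
sim <- simulate_trio_genotypes(geno_params)
write_plink(sim$geno, sim$trios, file.path(out_dir, "trios"))

defs <- subscale_defs()
pheno <- NULL
items <- NULL
for (k in seq_along(arch)) {
  a <- arch[[k]]
  P <- sim_params(n_trios, n_snps, maf_range = c(0.05, 0.5),
                  genetic_cov = genetic_cov_matrix(a[1], a[2], a[2],
                                                   a[3], a[3], a[2]),
                  resid_var = a[4], sex_effect = 0.25, intercept = 14,
                  seed = base_seed + 10L * k)
  ph <- simulate_phenotypes(sim$geno, sim$trios, P)
  nm <- names(arch)[k]
  if (is.null(pheno)) {
    pheno <- ph[, c("trio", "id", "sex")]
    items <- ph[, c("trio", "id", "sex")]
  }
  pheno[[paste0("latent_", nm)]] <- ph$y
  block <- simulate_items(ph$y, defs[[nm]]$n_items, missing_rate = 0.004,
                          seed = base_seed + 100L + k, scale = nm)
  items <- cbind(items, block)
  cat(sprintf("%-14s var(y) = %.3f (target 1.00 + sex-effect share)\n",
              nm, var(ph$y)))
}

write_phenotypes(pheno, file.path(out_dir, "phenotypes.tsv"))
write.table(items, file.path(out_dir, "items.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("simulated %d trios x %d SNPs -> %s\n", n_trios, n_snps, out_dir))
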
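#!/usr/bin/env Rscript
# Fit the four nested variance-component specifications (differential,
# combined, no-parental, null) to each subscale score by maximum likelihood,
# with intercept and child sex as fixed effects.

library(triovc)

dir.create("results/fits", recursive = TRUE, showWarnings = FALSE)

grm <- read_grm("results/grm/trios")
trios <- read.table("results/grm/trios_pruned.tsv", header = TRUE, sep = "\t")
trios <- trio_index(trios$offspring_row, trios$mother_row, trios$father_row,
                    trios$offspring_sex)
scores <- read_phenotypes("results/sim/subscale_scores.tsv")
gs_all <- trio_grm_blocks(grm, trios)

all_fits <- list()
for (def in subscale_defs()) {
  # align subscale scores to the pruned trios by offspring id
  off_ids <- grm$ids[trios$offspring_row]
  y_full <- scores[[def$name]][match(off_ids, scores$id)]
  keep <- !is.na(y_full)                 # listwise deletion per subscale
  tr <- trio_index(trios$offspring_row[keep], trios$mother_row[keep],
                   trios$father_row[keep], trios$offspring_sex[keep])
  gs <- trio_grm_blocks(grm, tr)
  y <- y_full[keep]
  X <- cbind(intercept = 1, sex = tr$offspring_sex)
  fits <- fit_all_specs(y, X, gs)
  all_fits[[def$name]] <- fits
  cat(sprintf("%s (n = %d):\n", def$name, length(y)))
  for (f in fits)
    cat(sprintf("  %-13s -2ll %.2f  AIC %.2f  converged %s\n",
                f$spec$name, f$neg2_loglik, aic(f), f$converged))
}

saveRDS(all_fits, "scratch/fits.rds")  # scratch cache for the report step
tab <- model_table(all_fits)
write_model_table(tab, "results/fits/model_comparison")
cat("wrote results/fits/model_comparison.{tsv,md}\n")
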
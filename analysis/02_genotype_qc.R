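#!/usr/bin/env Rscript
# Post-imputation style quality control on the simulated trio genotypes:
# sample call rate and heterozygosity, variant MAF / call rate / HWE (on
# founders), and a Mendelian-error scan. Writes exclusion tables and the
# filtered dataset under results/qc/.

library(triovc)

dir.create("results/qc", recursive = TRUE, showWarnings = FALSE)

inp <- read_plink("results/sim/trios")
th <- qc_thresholds()   # MAF > 1%, call rate > 98%, HWE p < .001, |F| < 0.2

res <- run_genotype_qc(inp$geno, inp$trios, th)

write.table(res$variant_report$variant, "results/qc/variant_exclusions.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(res$sample_report$sample, "results/qc/sample_exclusions.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(res$mendel_report$mendel_by_trio, "results/qc/mendel_by_trio.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write_plink(res$geno, res$trios, "results/qc/trios_qc")

cat(sprintf("variants: %d -> %d (%d excluded)\n",
            nrow(res$variant_report$variant), ncol(res$geno$dosages),
            nrow(res$variant_report$variant) - ncol(res$geno$dosages)))
cat(sprintf("samples: %d -> %d; trios retained: %d\n",
            nrow(res$sample_report$sample), nrow(res$geno$dosages),
            nrow(res$trios)))
cat(sprintf("Mendelian errors: %d (all-zero is expected for Mendelian simulation)\n",
            sum(res$mendel_report$mendel_by_snp$n_errors)))
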
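#' Genotype quality-control thresholds
#'
#' Defaults follow the post-imputation filters of large trio-cohort practice:
#' minor allele frequency > 1%, call rate > 98% (variants and samples),
#' Hardy-Weinberg equilibrium p < .001, heterozygosity outliers excluded at
#' |F| > 0.2, and dosages hard-called when within 0.1 of an integer.
#'
#' @param maf_min minimum minor allele frequency.
#' @param call_rate_min minimum call rate (variants and samples).
#' @param hwe_alpha Hardy-Weinberg p-value bound; variants below are excluded.
#' @param fhet_bound bound on the absolute heterozygosity F statistic.
#' @param hard_call_cut dosage distance from an integer below which the call
#'   is treated as hard.
#' @return object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(maf_min = 0.01, call_rate_min = 0.98,
                          hwe_alpha = 0.001, fhet_bound = 0.2,
                          hard_call_cut = 0.1) {
  if (maf_min < 0 || maf_min >= 0.5)
    tv_stop("maf_min must be in [0, 0.5)", "triovc_config_error")
  if (call_rate_min < 0 || call_rate_min > 1)
    tv_stop("call_rate_min must be in [0, 1]", "triovc_config_error")
  if (hwe_alpha <= 0 || hwe_alpha >= 1)
    tv_stop("hwe_alpha must be in (0, 1)", "triovc_config_error")
  if (fhet_bound <= 0) tv_stop("fhet_bound must be > 0", "triovc_config_error")
  if (hard_call_cut < 0 || hard_call_cut > 0.5)
    tv_stop("hard_call_cut must be in [0, 0.5]", "triovc_config_error")
  structure(list(maf_min = maf_min, call_rate_min = call_rate_min,
                 hwe_alpha = hwe_alpha, fhet_bound = fhet_bound,
                 hard_call_cut = hard_call_cut),
            class = "qc_thresholds")
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom chi-square goodness-of-fit test of observed genotype
#' counts against the expected proportions \eqn{p^2, 2pq, q^2}, with the
#' allele frequency estimated from the counts themselves. Returns p = 1 when
#' the statistic is 0 (exact agreement).
#'
#' @param n_AA,n_Aa,n_aa genotype counts (dosage 2, 1, 0 of the A allele).
#' @return the p-value; the chi-square statistic is attached as attribute
#'   `"statistic"`.
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0))
    tv_stop("genotype counts must be non-negative", "triovc_input_error")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) tv_stop("total genotype count must be > 0", "triovc_input_error")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  q <- 1 - p
  expd <- n * c(p^2, 2 * p * q, q^2)
  obs <- c(n_AA, n_Aa, n_aa)
  nz <- expd > 0
  stat <- sum((obs[nz] - expd[nz])^2 / expd[nz])
  pval <- if (stat == 0) 1 else pchisq(stat, df = 1, lower.tail = FALSE)
  attr(pval, "statistic") <- stat
  pval
}

new_qc_report <- function(variant = NULL, sample = NULL,
                          mendel_by_trio = NULL, mendel_by_snp = NULL,
                          n_soft = NULL) {
  structure(list(variant = variant, sample = sample,
                 mendel_by_trio = mendel_by_trio, mendel_by_snp = mendel_by_snp,
                 n_soft_calls = n_soft),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report\n")
  if (!is.null(x$variant))
    cat(sprintf("  variants: %d / %d pass\n", sum(x$variant$pass), nrow(x$variant)))
  if (!is.null(x$sample))
    cat(sprintf("  samples:  %d / %d pass\n", sum(x$sample$pass), nrow(x$sample)))
  if (!is.null(x$mendel_by_snp))
    cat(sprintf("  Mendelian errors: %d (across %d SNPs)\n",
                sum(x$mendel_by_snp$n_errors), nrow(x$mendel_by_snp)))
  invisible(x)
}

#' Variant-level quality-control filters
#'
#' Marks variants failing the minor-allele-frequency, call-rate or
#' Hardy-Weinberg criteria. A failing variant is labelled with its first
#' failing criterion, evaluated in the order MAF, call rate, HWE. The HWE test
#' is computed on hard-called founder (parental) genotypes when `trios` is
#' supplied, since offspring genotypes are not independent of parental ones;
#' otherwise on all individuals.
#'
#' @param geno a [genotype_data] object.
#' @param thresholds a [qc_thresholds] object.
#' @param trios optional [trio_index]; restricts the HWE test to parents.
#' @return a `qc_report` whose `variant` element is a data.frame with columns
#'   `snp`, `maf`, `call_rate`, `hwe_p`, `pass`, `fail_reason`.
#' @export
variant_filters <- function(geno, thresholds = qc_thresholds(), trios = NULL) {
  if (nrow(geno$dosages) < 1 || ncol(geno$dosages) < 1)
    tv_stop("empty genotype matrix", "triovc_input_error")
  dos <- geno$dosages
  maf <- pmin(geno$allele_freq, 1 - geno$allele_freq)
  call_rate <- colMeans(!is.na(dos))
  hwe_rows <- if (is.null(trios)) seq_len(nrow(dos)) else
    c(trios$mother_row, trios$father_row)
  h <- hard_calls(dos[hwe_rows, , drop = FALSE], thresholds$hard_call_cut)
  hwe_p <- vapply(seq_len(ncol(h)), function(j) {
    g <- h[, j]
    n2 <- sum(g == 2, na.rm = TRUE); n1 <- sum(g == 1, na.rm = TRUE)
    n0 <- sum(g == 0, na.rm = TRUE)
    if (n0 + n1 + n2 == 0) return(NA_real_)
    as.numeric(hwe_test(n2, n1, n0))
  }, numeric(1))
  fail_reason <- rep(NA_character_, ncol(dos))
  fail_reason[is.na(fail_reason) & maf <= thresholds$maf_min] <- "maf"
  fail_reason[is.na(fail_reason) & call_rate < thresholds$call_rate_min] <- "call_rate"
  fail_reason[is.na(fail_reason) & !is.na(hwe_p) & hwe_p < thresholds$hwe_alpha] <- "hwe"
  new_qc_report(variant = data.frame(
    snp = geno$snp_ids, maf = maf, call_rate = call_rate, hwe_p = hwe_p,
    pass = is.na(fail_reason), fail_reason = fail_reason,
    stringsAsFactors = FALSE))
}

#' Sample-level quality-control filters
#'
#' Computes per-sample call rate and the inbreeding-style heterozygosity
#' statistic \eqn{F = 1 - O_{het}/E_{het}}, where the expected heterozygote
#' count is \eqn{\sum_i 2 p_i (1-p_i)} over that sample's called SNPs.
#' Samples with \eqn{|F|} above `fhet_bound` or call rate below
#' `call_rate_min` are excluded; a sample with zero expected heterozygosity is
#' flagged degenerate and excluded.
#'
#' @inheritParams variant_filters
#' @return a `qc_report` whose `sample` element has columns `id`, `call_rate`,
#'   `f_het`, `pass`, `fail_reason`.
#' @export
sample_filters <- function(geno, thresholds = qc_thresholds()) {
  dos <- geno$dosages
  if (nrow(dos) < 1 || ncol(dos) < 1)
    tv_stop("empty genotype matrix", "triovc_input_error")
  call_rate <- rowMeans(!is.na(dos))
  h <- hard_calls(dos, thresholds$hard_call_cut)
  p <- geno$allele_freq
  ehet_snp <- 2 * p * (1 - p)
  called <- !is.na(h)
  o_het <- rowSums(h == 1, na.rm = TRUE)
  e_het <- as.vector(called %*% ehet_snp)
  f_het <- ifelse(e_het > 0, 1 - o_het / e_het, NA_real_)
  fail_reason <- rep(NA_character_, nrow(dos))
  fail_reason[call_rate < thresholds$call_rate_min] <- "call_rate"
  fail_reason[is.na(fail_reason) & e_het == 0] <- "degenerate_het"
  fail_reason[is.na(fail_reason) & abs(f_het) > thresholds$fhet_bound] <- "f_het"
  new_qc_report(sample = data.frame(
    id = geno$ids, call_rate = call_rate, f_het = f_het,
    pass = is.na(fail_reason), fail_reason = fail_reason,
    stringsAsFactors = FALSE))
}

#' Scan trios for Mendelian errors
#'
#' Flags every (trio, SNP) combination whose offspring hard call is impossible
#' under biallelic Mendelian transmission given the parental hard calls: a
#' parent with dosage 0 cannot transmit the counted allele and a parent with
#' dosage 2 must. Soft calls (dosage further than `hard_call_cut` from an
#' integer) and missing genotypes are skipped and counted separately.
#'
#' @param geno a [genotype_data] object.
#' @param trios a [trio_index].
#' @param thresholds a [qc_thresholds] (only `hard_call_cut` is used).
#' @return a `qc_report` with `mendel_by_trio` and `mendel_by_snp` count
#'   tables and the number of skipped soft/missing triplets in `n_soft_calls`.
#' @export
mendelian_error_scan <- function(geno, trios, thresholds = qc_thresholds()) {
  nmax <- nrow(geno$dosages)
  if (any(c(trios$offspring_row, trios$mother_row, trios$father_row) > nmax) ||
      any(c(trios$offspring_row, trios$mother_row, trios$father_row) < 1))
    tv_stop("trio index out of range", "triovc_input_error")
  h <- hard_calls(geno$dosages, thresholds$hard_call_cut)
  o <- h[trios$offspring_row, , drop = FALSE]
  m <- h[trios$mother_row, , drop = FALSE]
  f <- h[trios$father_row, , drop = FALSE]
  usable <- !is.na(o) & !is.na(m) & !is.na(f)
  # transmissible allele count from a parent: in [1,1] if hom alt, [0,0] if
  # hom ref, [0,1] if het; offspring must lie within the summed range
  lo <- (m == 2) + (f == 2)
  hi <- (m >= 1) + (f >= 1)
  err <- usable & (o < lo | o > hi)
  new_qc_report(
    mendel_by_trio = data.frame(trio = trios$trio, n_errors = rowSums(err),
                                n_usable = rowSums(usable)),
    mendel_by_snp = data.frame(snp = geno$snp_ids, n_errors = colSums(err),
                               n_usable = colSums(usable)),
    n_soft = sum(!usable))
}

#' Run the full genotype QC pipeline
#'
#' Applies sample filters first (call rate, heterozygosity), dropping the
#' excluded individuals and every trio containing one; then applies variant
#' filters (MAF, call rate, HWE on the retained founders) and removes
#' variants with any Mendelian error among the retained trios. Filtering
#' samples first keeps the founder set used by the HWE test identical on a
#' re-run, making the pipeline idempotent.
#'
#' @inheritParams mendelian_error_scan
#' @return list with the filtered `geno` and `trios` (row indices remapped to
#'   the filtered matrix), and the three reports (`sample_report`,
#'   `variant_report`, `mendel_report`).
#' @export
run_genotype_qc <- function(geno, trios, thresholds = qc_thresholds()) {
  srep <- sample_filters(geno, thresholds)
  bad_rows <- which(!srep$sample$pass)
  keep_trio <- !(trios$offspring_row %in% bad_rows |
                 trios$mother_row %in% bad_rows |
                 trios$father_row %in% bad_rows)
  trios2 <- trios[keep_trio, , drop = FALSE]
  keep_rows <- sort(c(trios2$offspring_row, trios2$mother_row,
                      trios2$father_row))
  g2 <- subset_genotypes(geno, rows = keep_rows)
  trios2 <- trio_index(match(trios2$offspring_row, keep_rows),
                       match(trios2$mother_row, keep_rows),
                       match(trios2$father_row, keep_rows),
                       trios2$offspring_sex)
  vrep <- variant_filters(g2, thresholds, trios2)
  mrep <- mendelian_error_scan(g2, trios2, thresholds)
  keep_snp <- vrep$variant$pass & mrep$mendel_by_snp$n_errors == 0
  g3 <- subset_genotypes(g2, cols = which(keep_snp))
  list(geno = g3, trios = trios2, sample_report = srep,
       variant_report = vrep, mendel_report = mrep)
}
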
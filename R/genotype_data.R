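#' Trio-structured genotype container
#'
#' Holds an individuals-by-SNPs allele-count dosage matrix together with
#' per-SNP allele-frequency estimates and identifiers. Dosages count copies of
#' the A1 (effect) allele and must lie in \[0, 2\]; missing calls are `NA`.
#'
#' @param dosages numeric matrix, individuals in rows, SNPs in columns; values
#'   in \[0, 2\] or `NA` for missing.
#' @param ids character vector of individual identifiers (default `ind1..n`).
#' @param snp_ids character vector of SNP identifiers (default `snp1..m`).
#' @param allele_freq optional per-SNP A1 frequency; when `NULL` it is
#'   estimated as the mean observed dosage divided by 2.
#'
#' @return An object of class `genotype_data`: a list with elements `dosages`,
#'   `allele_freq`, `missing_mask`, `ids`, `snp_ids`.
#' @export
genotype_data <- function(dosages, ids = NULL, snp_ids = NULL, allele_freq = NULL) {
  if (!is.matrix(dosages)) dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  rng <- if (length(dosages) > 0 && !all(is.na(dosages)))
    range(dosages, na.rm = TRUE) else c(NA_real_, NA_real_)
  if (!anyNA(rng) && (rng[1] < 0 || rng[2] > 2))
    tv_stop(sprintf("dosages outside [0, 2] (range %.3f..%.3f)", rng[1], rng[2]),
            "triovc_input_error")
  n <- nrow(dosages); m <- ncol(dosages)
  if (is.null(ids)) ids <- paste0("ind", seq_len(n))
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(m))
  if (length(ids) != n) tv_stop("ids length != number of rows", "triovc_input_error")
  if (length(snp_ids) != m) tv_stop("snp_ids length != number of columns", "triovc_input_error")
  if (is.null(allele_freq)) {
    allele_freq <- colMeans(dosages, na.rm = TRUE) / 2
  } else if (length(allele_freq) != m) {
    tv_stop("allele_freq length != number of SNPs", "triovc_input_error")
  }
  structure(list(dosages = dosages,
                 allele_freq = as.numeric(allele_freq),
                 missing_mask = is.na(dosages),
                 ids = as.character(ids),
                 snp_ids = as.character(snp_ids)),
            class = "genotype_data")
}

#' @export
print.genotype_data <- function(x, ...) {
  cat(sprintf("genotype_data: %d individuals x %d SNPs (%.2f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages), 100 * mean(x$missing_mask)))
  invisible(x)
}

#' @export
dim.genotype_data <- function(x) dim(x$dosages)

#' Trio index
#'
#' Maps each trio to its offspring, mother and father rows in a
#' [genotype_data] object, with the offspring's sex as a covariate
#' (1 = male, 0 = female). The three roles within a trio must be distinct rows
#' and no row may appear in two trios.
#'
#' @param offspring_row,mother_row,father_row integer row indices, one per trio.
#' @param offspring_sex 0/1 vector, one per trio.
#' @return A `data.frame` of class `trio_index` with one row per trio.
#' @export
trio_index <- function(offspring_row, mother_row, father_row, offspring_sex) {
  n <- length(offspring_row)
  if (length(mother_row) != n || length(father_row) != n || length(offspring_sex) != n)
    tv_stop("trio_index columns must have equal length", "triovc_input_error")
  all_rows <- c(offspring_row, mother_row, father_row)
  if (anyDuplicated(all_rows))
    tv_stop("an individual row appears in more than one trio role", "triovc_input_error")
  if (!all(offspring_sex %in% c(0, 1)))
    tv_stop("offspring_sex must be 0/1", "triovc_input_error")
  structure(data.frame(trio = seq_len(n),
                       offspring_row = as.integer(offspring_row),
                       mother_row = as.integer(mother_row),
                       father_row = as.integer(father_row),
                       offspring_sex = as.integer(offspring_sex)),
            class = c("trio_index", "data.frame"))
}

# Subset a genotype_data by row and/or column indices, keeping frequencies
# consistent (recomputed from the retained rows unless freeze_freq = TRUE).
#' Subset a genotype_data object
#'
#' @param geno a [genotype_data] object.
#' @param rows,cols indices of individuals / SNPs to keep (default all).
#' @param freeze_freq keep the stored allele frequencies of the retained SNPs
#'   instead of re-estimating from the retained rows.
#' @return a [genotype_data] object.
#' @export
subset_genotypes <- function(geno, rows = NULL, cols = NULL, freeze_freq = FALSE) {
  if (is.null(rows)) rows <- seq_len(nrow(geno$dosages))
  if (is.null(cols)) cols <- seq_len(ncol(geno$dosages))
  genotype_data(geno$dosages[rows, cols, drop = FALSE],
                ids = geno$ids[rows], snp_ids = geno$snp_ids[cols],
                allele_freq = if (freeze_freq) geno$allele_freq[cols] else NULL)
}

# Founder (parental) allele frequencies: offspring alleles duplicate parental
# ones, so frequency estimates for GRM/HWE work are taken from parents only.
#' Allele frequencies estimated from founders (parents) only
#'
#' @param geno a [genotype_data] object.
#' @param trios a [trio_index].
#' @return numeric vector of per-SNP frequencies.
#' @export
founder_freq <- function(geno, trios) {
  rows <- c(trios$mother_row, trios$father_row)
  colMeans(geno$dosages[rows, , drop = FALSE], na.rm = TRUE) / 2
}

# Round dosages to hard calls where within `cut` of an integer; NA otherwise.
hard_calls <- function(dosages, cut = 0.1) {
  h <- round(dosages)
  h[abs(dosages - h) > cut] <- NA
  h
}
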
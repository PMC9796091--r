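#' Compute a genomic relatedness matrix
#'
#' Implements the standardized-genotype GRM estimator: entry (j, k) is
#' \deqn{A_{jk} = \frac{1}{M_{jk}} \sum_i \frac{(x_{ij} - 2p_i)(x_{ik} - 2p_i)}
#'   {2 p_i (1 - p_i)}}
#' summed over SNPs i at which both individuals have a call, with
#' \eqn{M_{jk}} that pair's SNP count (pairwise-complete convention). With no
#' missingness this equals \eqn{Z Z^\top / M} for the column-standardized
#' dosage matrix Z.
#'
#' @param geno a [genotype_data] object; all allele frequencies must be
#'   strictly inside (0, 1) (monomorphic SNPs must have been removed by QC).
#' @param freq optional per-SNP frequencies to standardize with (e.g. founder
#'   estimates from [founder_freq()]); defaults to `geno$allele_freq`.
#' @return object of class `grm`: list with `values` (symmetric n x n matrix),
#'   `n_snps_used` (matrix of pairwise SNP counts, or a scalar when complete),
#'   and `ids`.
#' @export
compute_grm <- function(geno, freq = NULL) {
  p <- if (is.null(freq)) geno$allele_freq else freq
  if (length(p) != ncol(geno$dosages))
    tv_stop("freq length != number of SNPs", "triovc_input_error")
  if (any(p <= 0 | p >= 1))
    tv_stop("allele frequencies must be strictly inside (0, 1); remove monomorphic SNPs in QC",
            "triovc_input_error")
  Z <- sweep(geno$dosages, 2, 2 * p)
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  if (anyNA(Z)) {
    obs <- !is.na(Z)
    Z[!obs] <- 0
    M <- tcrossprod(obs * 1)
    if (any(M == 0))
      tv_stop("a pair of individuals shares no called SNP", "triovc_input_error")
    values <- tcrossprod(Z) / M
  } else {
    M <- ncol(Z)
    values <- tcrossprod(Z) / M
  }
  values <- (values + t(values)) / 2
  dimnames(values) <- list(geno$ids, geno$ids)
  structure(list(values = values, n_snps_used = M, ids = geno$ids),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  n <- nrow(x$values)
  od <- x$values[upper.tri(x$values)]
  cat(sprintf("grm: %d individuals, %d SNPs; diag mean %.3f, off-diag mean %.4f\n",
              n, max(x$n_snps_used), mean(diag(x$values)), mean(od)))
  invisible(x)
}

#' Extract the six trio role-blocks of a GRM
#'
#' Restricts a GRM to the N x N blocks indexed by trio roles: the symmetric
#' within-role blocks A_oo, A_mm, A_pp and the cross-role blocks A_om, A_op,
#' A_mp (rows index the first role, columns the second). The diagonals of
#' A_om and A_op are the within-trio parent-offspring relatednesses
#' (expectation 1/2) and the diagonal of A_mp the mate relatedness
#' (expectation 0 under random mating).
#'
#' @param grm a [compute_grm()] result.
#' @param trios a [trio_index]; all rows must be inside the GRM.
#' @return object of class `grm_set`: list of the six blocks plus `n`.
#' @export
trio_grm_blocks <- function(grm, trios) {
  nmax <- nrow(grm$values)
  rows <- c(trios$offspring_row, trios$mother_row, trios$father_row)
  if (any(rows < 1 | rows > nmax))
    tv_stop(sprintf("trio rows outside GRM: %s",
                    paste(setdiff(rows, seq_len(nmax)), collapse = ", ")),
            "triovc_input_error")
  o <- trios$offspring_row; m <- trios$mother_row; f <- trios$father_row
  V <- grm$values
  structure(list(A_oo = V[o, o, drop = FALSE], A_mm = V[m, m, drop = FALSE],
                 A_pp = V[f, f, drop = FALSE], A_om = V[o, m, drop = FALSE],
                 A_op = V[o, f, drop = FALSE], A_mp = V[m, f, drop = FALSE],
                 n = nrow(trios)),
            class = "grm_set")
}

#' @export
print.grm_set <- function(x, ...) {
  cat(sprintf("grm_set: %d trios; mean diag A_om %.3f, A_op %.3f, A_mp %.3f\n",
              x$n, mean(diag(x$A_om)), mean(diag(x$A_op)), mean(diag(x$A_mp))))
  invisible(x)
}

#' Prune trios until no residual relatedness exceeds a threshold
#'
#' Scans all pairs of trio members for GRM entries above `threshold`, ignoring
#' within-trio parent-offspring pairs (which are related by design); the
#' within-trio mother-father pair is subject to the threshold. Removal is
#' greedy: repeatedly drop the trio containing the individual with the most
#' above-threshold edges, breaking ties by the larger maximum edge and then by
#' the lowest trio index, until no violating pair remains.
#'
#' @param grm a [compute_grm()] result covering all trio members.
#' @param trios a [trio_index].
#' @param threshold largest allowed relatedness between any two individuals
#'   (default 0.10).
#' @return the retained [trio_index] subset; dropped trio ids are attached as
#'   attribute `"dropped"`.
#' @export
prune_relatedness <- function(grm, trios, threshold = 0.10) {
  if (threshold <= 0) tv_stop("threshold must be > 0", "triovc_input_error")
  n <- nrow(trios)
  # one row per trio member, tagged with its trio and role (1=o, 2=m, 3=f)
  idx <- cbind(row = c(trios$offspring_row, trios$mother_row, trios$father_row),
               trio = rep(seq_len(n), 3),
               role = rep(1:3, each = n))
  V <- grm$values
  sub <- V[idx[, "row"], idx[, "row"], drop = FALSE]
  viol <- which(sub > threshold & upper.tri(sub), arr.ind = TRUE)
  if (nrow(viol) > 0) {
    t1 <- idx[viol[, 1], "trio"]; t2 <- idx[viol[, 2], "trio"]
    r1 <- idx[viol[, 1], "role"]; r2 <- idx[viol[, 2], "role"]
    # exempt within-trio parent-offspring pairs (roles {o,m} or {o,f})
    same <- t1 == t2
    po <- same & ((r1 == 1 & r2 >= 2) | (r2 == 1 & r1 >= 2))
    keep_edge <- !po & !(same & r1 == r2)  # same-role same-trio impossible anyway
    edges <- data.frame(a = viol[keep_edge, 1], b = viol[keep_edge, 2],
                        w = sub[viol[keep_edge, , drop = FALSE]])
  } else {
    edges <- data.frame(a = integer(0), b = integer(0), w = numeric(0))
  }
  active <- rep(TRUE, n)
  dropped <- integer(0)
  while (nrow(edges) > 0) {
    deg <- tabulate(c(edges$a, edges$b), nbins = nrow(idx))
    maxw <- rep(-Inf, nrow(idx))
    for (k in seq_len(nrow(edges))) {
      maxw[edges$a[k]] <- max(maxw[edges$a[k]], edges$w[k])
      maxw[edges$b[k]] <- max(maxw[edges$b[k]], edges$w[k])
    }
    cand <- which(deg == max(deg))
    if (length(cand) > 1) cand <- cand[maxw[cand] == max(maxw[cand])]
    if (length(cand) > 1) cand <- cand[which.min(idx[cand, "trio"])]
    drop_trio <- idx[cand[1], "trio"]
    dropped <- c(dropped, drop_trio)
    active[drop_trio] <- FALSE
    gone <- which(idx[, "trio"] == drop_trio)
    edges <- edges[!(edges$a %in% gone | edges$b %in% gone), , drop = FALSE]
  }
  out <- trios[active, , drop = FALSE]
  attr(out, "dropped") <- trios$trio[sort(dropped)]
  out
}

#' Exhaustively verify a pruned trio set
#'
#' Companion check to [prune_relatedness()]: scans every pair of members of
#' the retained trios and counts pairs above the threshold (with the same
#' parent-offspring exemption). A valid pruning returns 0.
#'
#' @inheritParams prune_relatedness
#' @return integer count of violating pairs.
#' @export
count_relatedness_violations <- function(grm, trios, threshold = 0.10) {
  n <- nrow(trios)
  rows <- c(trios$offspring_row, trios$mother_row, trios$father_row)
  trio_id <- rep(seq_len(n), 3)
  role <- rep(1:3, each = n)
  V <- grm$values[rows, rows, drop = FALSE]
  viol <- which(V > threshold & upper.tri(V), arr.ind = TRUE)
  if (nrow(viol) == 0) return(0L)
  same <- trio_id[viol[, 1]] == trio_id[viol[, 2]]
  r1 <- role[viol[, 1]]; r2 <- role[viol[, 2]]
  po <- same & ((r1 == 1 & r2 >= 2) | (r2 == 1 & r1 >= 2))
  sum(!po)
}
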
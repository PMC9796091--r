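test_that("GRM entries match closed-form and hand-computed values", {
  # one SNP, p = 0.5, dosage 2: (2-1)^2 / (2 * 0.5 * 0.5) = 2
  g1 <- compute_grm(genotype_data(matrix(2, 1, 1), allele_freq = 0.5),
                    freq = 0.5)
  expect_equal(g1$values[1, 1], 2)

  # 3 individuals x 2 SNPs against a direct double-loop evaluation
  dos <- matrix(c(0, 1, 2, 2, 1, 1), 3, 2)
  p <- c(0.3, 0.6)
  g <- compute_grm(genotype_data(dos, allele_freq = p), freq = p)
  hand <- matrix(0, 3, 3)
  for (j in 1:3) for (k in 1:3)
    hand[j, k] <- mean((dos[j, ] - 2 * p) * (dos[k, ] - 2 * p) / (2 * p * (1 - p)))
  expect_equal(unname(g$values), hand, tolerance = 1e-12)
})

test_that("GRM equals Z Z' / M with no missingness and handles pairwise-complete", {
  fx <- make_trio_fixture(n_trios = 40, n_snps = 150, seed = 9)
  p <- founder_freq(fx$geno, fx$trios)
  Z <- sweep(sweep(fx$geno$dosages, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
  expect_equal(unname(fx$grm$values), tcrossprod(Z) / ncol(Z), tolerance = 1e-10)

  # plant missingness: pairwise-complete entries average over shared SNPs only
  dos <- fx$geno$dosages
  dos[1, 1:50] <- NA
  gm <- compute_grm(genotype_data(dos, allele_freq = p), freq = p)
  shared <- 51:150
  z1 <- (dos[1, shared] - 2 * p[shared]) / sqrt(2 * p[shared] * (1 - p[shared]))
  z2 <- (dos[2, shared] - 2 * p[shared]) / sqrt(2 * p[shared] * (1 - p[shared]))
  expect_equal(gm$values[1, 2], mean(z1 * z2), tolerance = 1e-10)
  expect_equal(gm$n_snps_used[1, 2], 100)

  # monomorphic frequencies must have been removed upstream
  expect_error(compute_grm(genotype_data(matrix(c(0, 0), 2, 1), allele_freq = 0)),
               class = "triovc_input_error")
})

test_that("trio blocks are consistent restrictions of the GRM", {
  fx <- make_trio_fixture(n_trios = 25, n_snps = 100, seed = 14)
  gs <- fx$grms
  o <- fx$trios$offspring_row; m <- fx$trios$mother_row; f <- fx$trios$father_row
  big <- fx$grm$values[c(o, m, f), c(o, m, f)]
  n <- gs$n
  reassembled <- rbind(
    cbind(gs$A_oo, gs$A_om, gs$A_op),
    cbind(t(gs$A_om), gs$A_mm, gs$A_mp),
    cbind(t(gs$A_op), t(gs$A_mp), gs$A_pp))
  expect_equal(unname(reassembled), unname(big), tolerance = 1e-12)
  expect_equal(gs$A_oo, t(gs$A_oo))

  # permuting trio order permutes blocks consistently
  perm <- sample(n)
  tp <- trio_index(o[perm], m[perm], f[perm], fx$trios$offspring_sex[perm])
  gsp <- trio_grm_blocks(fx$grm, tp)
  expect_equal(gsp$A_om, gs$A_om[perm, perm])

  # single trio: six 1x1 blocks equal to the GRM entries
  t1 <- trio_index(o[1], m[1], f[1], 0)
  g1 <- trio_grm_blocks(fx$grm, t1)
  expect_equal(g1$A_om[1, 1], fx$grm$values[o[1], m[1]])
  expect_equal(g1$A_mp[1, 1], fx$grm$values[m[1], f[1]])

  expect_error(trio_grm_blocks(fx$grm, trio_index(9999, 1, 2, 0)),
               class = "triovc_input_error")
})

test_that("pruning keeps clean sets intact and removes the hub trio", {
  # build a synthetic GRM over 4 trios (12 individuals): identity diagonal,
  # 0.5 within-trio parent-offspring, and a hub sharing 0.2 with one member
  # of each other trio
  n <- 4
  V <- diag(12)
  o <- 1:4; m <- 5:8; f <- 9:12
  for (k in 1:4) { V[o[k], m[k]] <- V[m[k], o[k]] <- 0.5
                   V[o[k], f[k]] <- V[f[k], o[k]] <- 0.5 }
  trios <- trio_index(o, m, f, rep(0, 4))
  grm <- structure(list(values = V, n_snps_used = 100,
                        ids = paste0("i", 1:12)), class = "grm")
  # parent-offspring 0.5 alone triggers nothing
  kept <- prune_relatedness(grm, trios, 0.10)
  expect_equal(nrow(kept), 4)
  expect_equal(length(attr(kept, "dropped")), 0)

  # hub: mother of trio 1 related 0.2 to the offspring of trios 2..4
  V2 <- V
  for (k in 2:4) { V2[m[1], o[k]] <- V2[o[k], m[1]] <- 0.2 }
  grm2 <- structure(list(values = V2, n_snps_used = 100,
                         ids = paste0("i", 1:12)), class = "grm")
  kept2 <- prune_relatedness(grm2, trios, 0.10)
  expect_equal(attr(kept2, "dropped"), 1)
  expect_equal(kept2$trio, 2:4)
  expect_equal(count_relatedness_violations(grm2, kept2, 0.10), 0)
  # brute force: dropping the hub trio is a maximal valid subset
  valid_sizes <- sapply(1:15, function(mask) {
    sel <- which(bitwAnd(mask, 2^(0:3)) > 0)
    sub <- trios[sel, , drop = FALSE]
    if (count_relatedness_violations(grm2, sub, 0.10) == 0) length(sel) else 0
  })
  expect_equal(max(valid_sizes), 3)

  # within-trio mother-father relatedness above threshold is a violation
  V3 <- V; V3[m[2], f[2]] <- V3[f[2], m[2]] <- 0.3
  grm3 <- structure(list(values = V3, n_snps_used = 100,
                         ids = paste0("i", 1:12)), class = "grm")
  kept3 <- prune_relatedness(grm3, trios, 0.10)
  expect_equal(attr(kept3, "dropped"), 2)
})

test_that("pruning simulated data leaves no violating pair", {
  fx <- make_trio_fixture(n_trios = 50, n_snps = 200, seed = 23)
  # plant cross-trio relatedness by copying genotypes
  dos <- fx$geno$dosages
  dos[fx$trios$mother_row[2], ] <- dos[fx$trios$mother_row[1], ]
  grm <- compute_grm(genotype_data(dos, allele_freq = founder_freq(fx$geno, fx$trios)),
                     freq = founder_freq(fx$geno, fx$trios))
  expect_gt(count_relatedness_violations(grm, fx$trios, 0.10), 0)
  kept <- prune_relatedness(grm, fx$trios, 0.10)
  expect_equal(count_relatedness_violations(grm, kept, 0.10), 0)
  expect_lt(nrow(kept), nrow(fx$trios) + 1)
})
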
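---
title: "Trio variance components: direct and indirect parental genetic effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trio variance components: direct and indirect parental genetic effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triovc)
```

## The model

Parents transmit genes to their children, but their genotypes also shape the
environment the child grows up in. `triovc` estimates both pathways from
genotyped parent-offspring trios. The offspring phenotype is modeled as

$$y = g_o + g_m + g_p + \epsilon,$$

where $g_o$ is the direct genetic effect of the offspring's own genotypes and
$g_m$, $g_p$ are indirect effects of the mother's and father's genotypes,
necessarily mediated by the environment they provide. Each genetic value is a
sum of per-SNP effects, so across individuals the $g$'s are correlated
according to the genomic relatedness matrix (GRM): writing $A_{rs}$ for the
GRM block between trio roles $r$ and $s$,

$$\mathrm{Cov}(y) \;=\; \sigma_o^2 A_{oo} + \sigma_m^2 A_{mm} + \sigma_p^2 A_{pp}
 + \sigma_{om}\,(A_{om}{+}A_{om}^\top) + \sigma_{op}\,(A_{op}{+}A_{op}^\top)
 + \sigma_{mp}\,(A_{mp}{+}A_{mp}^\top) + \sigma_\epsilon^2 I .$$

Because mates are essentially unrelated, $\sigma_{mp}$ contributes nothing to
the phenotypic variance, and because parent and offspring are one generation
apart (relatedness $1/2$), each parent-offspring covariance contributes once
rather than twice:

$$\mathrm{Var}(y) = \sigma_o^2+\sigma_m^2+\sigma_p^2+\sigma_{om}+\sigma_{op}+
\sigma_\epsilon^2 .$$

The covariance terms matter whenever partially the same genes act directly and
indirectly: a negative $\sigma_{om}+\sigma_{op}$ means parental responses
counteract the child's own genetic disposition and *shrink* phenotypic
variance (a negative gene-environment correlation); a positive one inflates
it.

Four nested specifications are compared (`vc_spec()`):

| spec | free variance parameters | df |
|---|---|---|
| `differential` | $\sigma_o^2,\sigma_m^2,\sigma_p^2,\sigma_{om},\sigma_{op},\sigma_{mp},\sigma_\epsilon^2$ | 7 |
| `combined` | $\sigma_o^2,\ \sigma_{par}\,(=\sigma_m^2{=}\sigma_p^2{=}\sigma_{mp}),\ \sigma_{o,par}\,(=\sigma_{om}{=}\sigma_{op}),\ \sigma_\epsilon^2$ | 4 |
| `no_parental` | $\sigma_o^2,\sigma_\epsilon^2$ (GRM heritability estimation) | 2 |
| `null` | $\sigma_\epsilon^2$ | 1 |

The combined model assumes maternal and paternal effects are equally
important and perfectly correlated; `sigma2_par` is the *per-parent* variance,
so the combined parental effect accounts for $2\sigma_{par}$ of variance and
its covariance with the direct effect for $2\sigma_{o,par}$. All
specifications carry an intercept and a child-sex fixed effect.

## Estimation

The likelihood is full Gaussian maximum likelihood with the fixed effects
profiled out by generalized least squares. We use ML rather than REML as the
default because the comparison convention adopted here counts the fixed
effects among the estimated parameters, $AIC = -2\ell\ell + 2(df + 2)$, which
is the full-ML accounting.

Numerical choices that matter:

* **Parameterization.** The implied genetic covariance matrix (3×3 for the
  differential spec, an equivalent 2×2 for the combined spec) is optimized
  through its log-Cholesky factor, and the residual variance through its log.
  Variances therefore stay non-negative, the genetic covariance stays
  positive semi-definite (the boundary is reachable in the limit), and the
  implied direct-indirect correlation is bounded in $[-1, 1]$ without ad-hoc
  clipping. Published estimates of this correlation can sit exactly at $-1$,
  so a parameterization that admits the boundary matters.
* **One factorization per evaluation.** Each likelihood evaluation performs a
  single Cholesky factorization of $V(\theta)$, reused for the determinant
  and the GLS profile. The score is analytic:
  $\partial(-2\ell\ell)/\partial\theta_j = \mathrm{tr}(V^{-1}C_j) - u^\top C_j u$
  with $u = V^{-1}r$, which makes a 2000-trio fit a matter of seconds.
* **Starts.** Three deterministic initializations anchored at the ML residual
  variance of `y ~ X` (an equal split, a direct-heavy and a residual-heavy
  split). The objective is evaluated at all three; the quasi-Newton run
  (`nlminb`, relative tolerance $10^{-8}$, at most 500 iterations) starts
  from the best, and the others serve as fallbacks on non-convergence.
  `fit_options(all_starts = TRUE)` forces a full run from every start; the
  objective has been smooth and unimodal in every synthetic dataset we
  examined, so the screening default trades negligible risk for a threefold
  speedup. When the four specifications are fitted together
  (`fit_all_specs()`), models are fitted smallest first and each larger model
  additionally receives the nested model's optimum as a start — a feasible
  point of the larger model — so the maximized likelihood is monotone along
  the nesting chain by construction rather than by luck.
* **Standard errors.** Observed information at the optimum, obtained by
  central finite differences of the analytic score on the raw scale, inverted
  and mapped by the delta method onto the standardized scale and the derived
  decomposition quantities. For the null model this reproduces
  $\mathrm{SE}(\hat\sigma^2_\epsilon)=\sqrt{2\hat\sigma^4_\epsilon/N}$ to
  machine precision.
* **Degenerate inputs.** A non-positive-definite $V$ yields a large penalized
  objective (flagged, optimizer-safe); a non-positive model-implied total
  variance makes standardization fail loudly rather than silently.

`standardize_fit()` divides every component by the model-implied total
$\sigma_o^2+\sigma_m^2+\sigma_p^2+\sigma_{om}+\sigma_{op}+\sigma_\epsilon^2$
($\sigma_{mp}$ excluded, per the accounting above). We adopt the
model-implied rather than the empirical phenotypic variance because published
component rows sum to one under exactly this convention.

`aic()`, `lrt()` and `model_table()` compare the nested fits. The LRT refers
the $-2\ell\ell$ difference to a plain chi-square at the parameter-count
difference. Several of the null hypotheses place variances on the boundary of
the parameter space, which makes this reference conservative; published
p-values for this design are consistent with the plain chi-square, so we
report it and note the caveat in the table footer rather than applying a
boundary-mixture correction.

## The synthetic cohort

Restricted cohort data cannot ship with a package, so `triovc` includes a
generator that emulates the study design end to end and doubles as the
test-bed for every downstream stage.

* Parental dosages at SNP $j$ are Binomial$(2, p_j)$ with $p_j$ uniform on
  `maf_range` (default 0.05–0.5); offspring receive one fair Mendelian draw
  from each parent, so a Mendelian-error scan over generated data must report
  zero errors, and the parent-offspring GRM diagonal converges to $1/2$.
* Per-SNP effect triples are drawn from a trivariate normal with covariance
  `genetic_cov`$/M$ and applied to genotypes standardized with the
  *generating* frequencies. Effects on standardized genotypes make
  `genetic_cov` directly the variance-component target, matching the GRM
  estimator's scaling; the estimation side standardizes with founder-sample
  estimates, and that realistic mismatch is part of what recovery tests
  absorb (empirically it moves estimates by far less than one standard
  error).
* Offspring sex is Bernoulli(0.5), matching the near-even split of birth
  cohorts, with an additive `sex_effect`.
* Ordinal 1–4 items are produced by mapping latent scores onto the achievable
  sum range and spreading the excess over items at random, with MCAR
  missingness. This is deliberately a *fixture* generator: it guarantees
  rank-concordance between item sums and latent scores and exercises the
  50%-missing rule, but it is not a psychometric model of any real rating
  instrument (no item difficulties, no informant bias, no ordinal skew), so
  passing tests say nothing about item-response behavior of real
  questionnaires.
* Everything is bit-reproducible given `seed`; genotypes use `seed`,
  phenotypes `seed + 1`, so the two draws are decoupled.

What the generator omits by design: linkage disequilibrium, assortative
mating, population structure, sibling effects and genotyping-batch
artifacts. Recovery results on this generator therefore demonstrate the
estimator's correctness under its own assumptions, not robustness to the
confounders real cohorts carry.

## Quality control and relatedness choices

* The Hardy-Weinberg test is the 1-df chi-square goodness-of-fit test (the
  exact test is a possible extension; at cohort scale the chi-square is
  deterministic and adequate), computed on **founders only**: offspring
  genotypes duplicate parental alleles and would distort the test.
* Dosages within `hard_call_cut` (default 0.1) of an integer are hard-called;
  softer calls are skipped in HWE/Mendelian logic and counted separately.
* The QC pipeline filters samples first, then variants, so the founder set
  behind the HWE test is stable and the pipeline is idempotent. Note that
  the heterozygosity statistic $F = 1 - O_{het}/E_{het}$ has sampling sd
  $\propto 1/\sqrt{M}$, so the $|F| > 0.2$ bound is only a meaningful outlier
  screen at realistic SNP counts (hundreds or more).
* The GRM is the standardized-genotype estimator with allele frequencies
  estimated from founders, pairwise-complete over missing calls. Relatedness
  pruning removes whole trios greedily — repeatedly dropping the trio whose
  member has the most above-threshold (default 0.10) edges, ties broken by
  the larger edge then the lower trio index — with within-trio
  parent-offspring pairs exempt. The original cohort pipeline used a
  "bottom-up" selection whose algorithm is not published; we therefore verify
  the *property* (an exhaustive pair scan finds no violating pair afterwards)
  rather than set-identity with any particular implementation.

## Problem sizes used in the checks

The shipped checks run, per run: parameter recovery on 20 replicates of
2,000 trios × 3,000 SNPs under a combined-model architecture
($\sigma_o^2 = 0.25$, per-parent $\sigma_{par} = 0.075$,
$\sigma_{o,par} = -0.05$, $\sigma_\epsilon^2 = 0.70$); GRM role-block
structure at 2,000 trios × 5,000 SNPs; likelihood-versus-oracle agreement on
20 instances of at most 20 trios; and nesting monotonicity on 20 replicates
of a few hundred trios. These sizes were chosen as the smallest at which the
quantities of interest are estimated with useful precision on a desktop
machine; the demonstration workflow under `analysis/` uses 1,200 trios ×
2,000 SNPs for the same reason.

At 2,000 trios the sampling uncertainty of the components is substantial
(standard errors around 0.08 for $\sigma_o^2$) — an order of magnitude more
trios is what a well-powered cohort analysis of this design uses. The
demonstration workflow illustrates the flip side: a subscale whose direct and
indirect effects nearly cancel (gene-environment correlation close to $-1$)
contributes little net variance, and at moderate sample sizes the null model
can win the AIC comparison even though both effects are real.

## Known limitations

* ML (not REML) point estimates of variance components carry the usual small
  downward bias of order the number of fixed effects over $N$.
* Wald standard errors and 2-SE intervals are first-order; near the PSD
  boundary (correlations approaching $\pm 1$) the sampling distribution is
  skewed and coverage can dip below nominal.
* The LRT reference ignores the boundary, in the conservative direction.
* The decomposition's gene-environment correlation follows the published
  accounting, dividing $\sigma_{om}+\sigma_{op}$ by
  $\sqrt{\sigma_o^2(\sigma_m^2+\sigma_p^2)}$. Under the combined model this
  denominator uses the parental *variance contribution* $2\sigma_{par}$
  rather than the variance of the combined effect $g_m+g_p$ (which is
  $4\sigma_{par}$), so the reported quantity can reach magnitude $\sqrt{2}$
  at the PSD boundary even though the underlying effect correlation is
  bounded by 1. It is reported unclamped.
* `prune_relatedness()` is a heuristic; it guarantees a valid (violation-free)
  trio set, not a maximum-cardinality one.
* Listwise deletion handles missing phenotypes, one response at a time; no
  multi-trait modeling.
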
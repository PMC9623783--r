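---
title: "Indirect genomic prediction with single-step GBLUP: models and design"
author: "igpred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indirect genomic prediction with single-step GBLUP: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igpred)
```

## The problem

National genomic evaluations now carry millions of genotyped animals, most
of them young females with neither phenotypes nor progeny.  Solving the
single-step GBLUP (ssGBLUP) mixed model equations with every genotyped
animal inside the genomic relationship matrix is the dominant computing
cost, and it grows every year.  A practical alternative is to solve the
evaluation only for genotyped animals that carry information (phenotypes
or progeny), backsolve SNP marker effects from their GEBV, and predict the
remaining young animals *indirectly* as a linear function of their
genotypes.  `igpred` implements that workflow end to end at desk scale,
together with the regression-based validation used to certify that the
indirect predictions are accurate and unbiased, and a population simulator
that makes every stage verifiable.

## Models

### ssGBLUP

The multi-trait repeatability animal model is

$$ y = Xb + W a + W_p p + e, $$

with contemporary-group fixed effects $b$, additive genetic effects $a$,
permanent-environment effects $p$ for phenotyped animals, and residual
$e$.  The additive effects use the combined relationship inverse

$$ H^{-1} = A^{-1} + \begin{bmatrix} 0 & 0 \\ 0 & G^{-1} - A_{22}^{-1}
\end{bmatrix}, $$

where $A^{-1}$ is Henderson's sparse pedigree inverse over all animals,
$G$ the genomic relationship matrix of the genotyped animals, and
$A_{22}$ their pedigree block.  `assemble_H_inverse()` realises $H^{-1}$
as a matrix-free operator: the correction is applied only to the genotyped
coordinates, and $G^{-1}$ may itself be an APY operator (below).

$G$ is VanRaden's method 1, $G = ZZ'/k$ with $Z$ the genotype contents
centered at twice the allele frequency and $k = 2\sum_j p_j(1-p_j)$.
Unblended $G$ is singular whenever animals outnumber markers or genotypes
are duplicated, so $G$ is blended as $(1-\beta)ZZ'/k + \beta A_{22}$
(identity when no $A_{22}$ is available) with $\beta = 0.05$ by default;
$\beta$ is recorded in every result.  Allele frequencies are computed once
from the full genotyped pool and reused for every subset, so that $Z$ —
and therefore SNP effects and indirect predictions — stay on a single
scale across pipeline stages.  No additional "tuning" of the base of $G$
toward $A_{22}$ is applied.

### APY inverse

The algorithm of proven and young (APY) splits the genotyped animals into
a *core* (inverted directly) and *noncore*.  Writing
$P = G_{nc}G_{cc}^{-1}$ and $m_{ii} = g_{ii} - g_{ic}G_{cc}^{-1}g_{ci}$,

$$ G_{APY}^{-1} = \begin{bmatrix} G_{cc}^{-1} + P'M^{-1}P & -P'M^{-1} \\
 -M^{-1}P & M^{-1} \end{bmatrix},\qquad M = \mathrm{diag}(m_{ii}), $$

which has no entries between distinct noncore animals and is applied
without ever forming the dense noncore block.  The appropriate core size
is governed by the eigenvalue spectrum of $G$:
`estimate_core_size(G, 0.98)` returns the number of top eigenvalues
explaining 98% of the variation in $G$ — an estimate of the number of
independent chromosome segments the core must span.  Core animals are
drawn uniformly at random (with a recorded seed); in large Holstein data
a random core performs as well as a carefully chosen one.

### Solver

The MME are solved by preconditioned conjugate gradients with iteration on
data: the coefficient matrix is only ever applied to vectors, through the
sparse record incidence, $H^{-1}$, and the (co)variance inverses.  The
convergence statistic is the squared residual norm relative to the squared
right-hand-side norm, $c = \lVert b - Cx\rVert^2 / \lVert b\rVert^2$, with
default tolerance $10^{-12}$; the published solver family states its
criterion in terms of "relative adjusted right-hand sides" without a
formula, and this is the conventional reading (it is configurable).  The
start vector is zero, making every solve bit-reproducible.  The
preconditioner is block-diagonal by equation family: one trait-by-trait
block per level, using the data diagonal plus `diag(H^-1)` times the
additive precision (the standard choice for this solver family).

### Backsolving and indirect prediction

SNP effects are backsolved from the GEBV $\hat a$ of a (sub)set of
genotyped animals as

$$ \hat u = \lambda D Z' G^{-1} \hat a, \qquad D = I,\qquad
\lambda = \sigma_u^2/\sigma_a^2 = 1/k, $$

with $G$ built from the same $Z$ rows and inverted directly — at
backsolving subset sizes the APY is not needed.  $\lambda = 1/k$ follows
from VanRaden method 1 with the same frequencies used to center $Z$; at
$\beta = 0$ and full rank the identity $Z\hat u = \hat a$ holds exactly.
The $D$ slot is kept in the result type so weighted variants remain
expressible, but it is always the identity here.  Indirect genomic
prediction of a target animal is then

$$ IGP = Z_{target}\,\hat u , $$

with missing genotypes contributing zero (they are imputed to their
expectation during centering).  Because GEBV and IGP can sit on different
genetic bases, `adjust_genetic_base()` removes the per-trait mean
difference on a reference set carrying both values, or applies the
validation regression $b_0 + b_1 \times IGP$.

### Validation

`regress_gebv_on_igp()` fits $GEBV = b_0 + b_1 \times IGP$ per trait and
sex group: $b_0$ measures base/bias, $b_1$ dispersion (inflation when
$b_1 < 1$), and $R^2$ accuracy of the indirect predictions.  MEAN and MAX
absolute GEBV−IGP differences, $b_0$ and the genetic trend are expressed
in genetic-SD units ($b_1$ and $R^2$ are scale-free and never
standardized).  The genetic trend is defined operationally as the slope of
cohort-mean (true or estimated) breeding value on birth year divided by
the genetic SD — a per-year convention approximating the published
genetic-progress figures it is compared with; the evaluation window is
configurable.  With three or more traits, trend correlations across traits
(`correlate_with_trend()`) diagnose how bias tracks selection intensity:
the package ships the published 18-trait Holstein summary
(`holstein_igp_summary()`), whose printed columns reproduce a ΔG–$b_0$
correlation of 0.98, a ΔG–$R^2$ correlation of −0.44, and mean male
$b_1$/$R^2$ of 0.99/0.957.

## The synthetic population

`simulate_dataset()` generates the structure the workflow assumes:

* a multi-generation pedigree bred by truncation selection on the weighted
  *true* breeding-value index, with the infinitesimal recursion
  $a_{child} = \tfrac12(a_s + a_d) + \phi$,
  $\mathrm{var}(\phi) = (0.5 - 0.25(F_s+F_d))\,\Sigma_a$.  Selecting on
  true values rather than on estimated ones makes the induced genetic
  trend controllable without iterating evaluations;
* gene-dropped biallelic genotypes: founder frequencies uniform on a
  configurable interval, one allele per parent per marker, independent
  across markers (no linkage);
* phenotypes under the repeatability animal model with one fixed
  contemporary group (birth year × sex), records for females outside the
  youngest cohort;
* the three-way partition: genotyped with phenotypes or progeny (GEBV
  set), genotyped with neither and born after the cutoff (IGP targets),
  and nongenotyped animals.  Genotyped animals with neither phenotypes nor
  progeny born *before* the cutoff remain in the GEBV set, so the two sets
  partition the genotyped pool exactly.

Defaults (phenotypic variance 1 per trait): $h^2 = 0.3$, repeatability
0.45, two traits with genetic correlation 0.3 and selection on the first
only, 25% of each sex selected, litter size 8 (chosen so cohort size is
stationary at that intensity), 60% genotyped, 80% of eligible females
phenotyped with 2 records.  Sexes alternate deterministically among
offspring so both sexes exist in every cohort.  Missing genotype codes can
be injected at a configurable rate (default 0).  All stages are
bit-reproducible given the configuration seed.

### What the simulator does *not* emulate

* **Linkage.** Markers segregate independently.  The ssGBLUP/APY/backsolve
  algebra only touches marker covariances through $G$, so this does not
  affect the correctness of any operator; it does mean the eigenvalue
  spectrum of a simulated $G$ is much flatter than in real cattle data,
  where ~20K eigenvalues explain 98–99% of the variation in $G$ among
  hundreds of thousands of animals.  Consequently the backsolving subset
  must be a far larger *fraction* of the GEBV set here than in practice to
  reach the same agreement.
* **Marker-determined trait values.** True breeding values are generated by
  the pedigree recursion *before* genotypes exist, so they are independent
  of the markers given the pedigree.  $\mathrm{cov}(a) = A\sigma_a^2$
  exactly, which makes pedigree BLUP the optimal linear predictor of
  *true* values in this generator — ssGBLUP cannot beat it on truth
  recovery here, and the tests do not pretend otherwise.  What the
  generator does support — and what the validation layer measures, exactly
  as production evaluations do — is the *internal consistency* of indirect
  prediction: IGP must reproduce the benchmark GEBV that the full ssGBLUP
  would have assigned to the same animals.
* Genotyping error, imputation, QTL architectures, overlapping
  generations, and non-random mating.

## Numerical choices

* Inbreeding by the Meuwissen–Luo traversal of the $L'DL$ factorization of
  $A$ (O(n) memory); the tabular $\mathrm{diag}(A) - 1$ serves as the test
  oracle.  Unknown parents are treated as unrelated, non-inbred base
  animals; no unknown-parent groups are fitted.
* Pedigrees are topologically sorted parents-first on read; cycles are
  reported with the offending ids.  Ids are kept as given externally and
  mapped to positions internally.
* Dense inversions ($A_{22}$, $G$, core blocks) use Cholesky
  factorizations; non-positive-definite inputs fail with the smallest
  eigenvalue and a blending hint rather than silently regularising.
* APY noncore conditional variances below $10^{-8}$ (duplicate genotypes)
  are an error naming the animal.
* Fixed-effect levels never observed in the records are dropped from the
  equations.  Records with missing traits are handled by
  residual-covariance subsetting per missingness pattern; the default
  simulator emits complete records.
* Multi-trait support is dimension-generic but intended for desk scale
  (up to ~5 traits); production 18-trait systems are out of scope.

## Problem sizes used in the tests

The oracle suites run on populations of tens to hundreds of animals, where
every operator can be compared against a dense-algebra reconstruction.
The end-to-end suite uses a population of ~5,000 animals — ~3,000
genotyped animals with phenotypes or progeny, ~1,000 young genotyped
targets, 2,000 markers, $h^2 = 0.3$ — with SNP effects backsolved from a
random subset of 2,000 GEBV animals, averaged over 5 population seeds; the
subset-size sweep uses ~4,000 GEBV animals and subsets of
{250, 500, 1,000, 2,000} over 10 subset seeds on one population.  At these
sizes the indirect predictions correlate >0.9 with the benchmark GEBV of
the same animals and the validation slope stays within [0.9, 1.1], while
$R^2$ rises steeply with subset size and the slope approaches 1 — the
qualitative behaviour production studies report, at a scale a laptop can
verify.

## Known limitations

* No reliability/accuracy approximation is provided for IGP animals.
* The genetic trend measured from *estimated* breeding values understates
  the true trend when contemporary groups are completely confounded with
  birth cohorts (as in the default simulator, where each animal's repeated
  records share one contemporary group); trend *correlations* across
  traits are unaffected.
* The pipeline holds $G$ densely; it is a desk-scale research tool, not a
  production evaluator.
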
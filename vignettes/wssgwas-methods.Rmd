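---
title: "Weighted single-step GWAS: models, algorithms and design choices"
author: "wssgwas package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted single-step GWAS: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wssgwas)
```

## The problem

Livestock populations are typically phenotyped far more widely than they are
genotyped: thousands of boars may have repeated semen evaluations while only
recent cohorts are on a SNP array. Weighted single-step GWAS (wssGWAS) maps
QTL in exactly this setting. It predicts breeding values with *all* animals
in one mixed model — pedigree and genomic information blended through the H
relationship matrix — back-solves the breeding values of the genotyped
animals into per-SNP effects, re-weights SNPs by the variance they explain,
and attributes additive genetic variance to fixed-width genomic windows.

## The repeatability animal model

Each ejaculate record is modelled as

$$ y = Xb + Za + Wpe + \beta_{age}\,Age + \beta_{intv}\,Intv + e, $$

with fixed effects $b$ (overall mean and year–season class), additive
genetic values $a \sim N(0, H\sigma^2_a)$, a permanent-environment effect
per boar $pe \sim N(0, I\sigma^2_{pe})$ capturing the covariance among an
animal's repeated records, and residuals $e \sim N(0, I\sigma^2_e)$. `Age`
(months at collection) and `Intv` (days since the previous collection) enter
as linear covariates; in the package interface the whole fixed part is an R
formula, e.g. `y ~ yearseason + age + intv`. Heritability under this model is
$h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_{pe} + \sigma^2_e)$ and
repeatability is $(\sigma^2_a + \sigma^2_{pe})$ over the same total.

## Relationship matrices

* `a_matrix()` builds the pedigree numerator relationship matrix A by the
  tabular method; `a_inverse()` builds $A^{-1}$ directly from Henderson's
  rules with inbreeding-adjusted Mendelian-sampling variances
  ($d_i = \tfrac12 - \tfrac14(F_s + F_d)$, etc.). Inbreeding coefficients
  are read off the tabular diagonal, which is exact; at the pedigree sizes
  this package targets (a few thousand animals) the dense tabular pass is
  cheap, and deep pedigrees with overlapping generations make inbreeding
  worth accounting for.
* `g_matrix()` is the VanRaden genomic matrix
  $G = Z D Z' \big/ \sum_i 2p_i(1-p_i)$ with centred coding
  $(0\!-\!2p, 1\!-\!2p, 2\!-\!2p)$ and a diagonal of SNP weights $D$.
  Frequencies are those of the counted allele among the genotyped animals;
  all results are invariant to which allele is counted.
* `blend_gw()` forms $G_\omega = 0.9\,G + 0.1\,A_{22}$; the blend restores
  full rank and anchors the genomic matrix to the pedigree base.
* `h_inverse()` assembles
  $H^{-1} = A^{-1} + \begin{bmatrix}0&0\\0&G_\omega^{-1}-A_{22}^{-1}\end{bmatrix}$
  as a sparse matrix plus a dense genotyped-block correction. With no
  genotyped animals it *is* $A^{-1}$, and the package tests assert that
  degeneracy exactly.

## Variance components: AI-REML

`reml_ai()` estimates $(\sigma^2_a, \sigma^2_{pe}, \sigma^2_e)$ by
restricted maximum likelihood on the pedigree relationship inverse, as done
once before the weighting loop. The implementation is Newton-type with the
average-information matrix:

* first derivatives use the mixed-model-equation trace identities
  (e.g. $tr(PZAZ') = q_a/\sigma^2_a - \sigma^2_e\,
  tr(A^{-1}C^{aa})/\sigma^4_a$ with $C^{aa}$ the animal block of the inverse
  coefficient matrix);
* the AI matrix is built from the working vectors $Z\hat a/\sigma^2_a$,
  $W\hat{pe}/\sigma^2_{pe}$ and $\hat e/\sigma^2_e$, each projected through
  one extra MME solve;
* when a Newton step leaves the parameter space it is projected onto a
  small positive floor, and if a step ever decreases the restricted
  likelihood the fitter backtracks and takes an EM step from the previous
  point instead. This keeps boundary cases ($\sigma^2_a \to 0$) fast —
  about ten iterations instead of a long EM crawl;
* convergence is declared when the largest relative parameter change falls
  below `tol` (default `1e-8`); near-boundary components are measured
  against $10^{-4}$ of the phenotypic variance so they cannot stall the
  criterion. Standard errors come from the inverse AI matrix.

Starting values are equal thirds of the phenotypic variance. The score, AI
matrix and likelihood are verified in the test suite against a dense-matrix
restricted-likelihood oracle (numerical derivatives and the literal
$\frac12 y'PV_iPV_jPy$ forms) on small fixtures.

The REML path forms the inverse of the full coefficient matrix, so it is
intended for data sets up to roughly ten thousand equations; the GEBV step
has no such limit because `solve_mme()` uses a sparse Cholesky
factorisation (a Jacobi-preconditioned conjugate-gradient solver is
available as an option).

## The weighting loop

`wssgwas()` runs the canonical iteration, with variance components held
fixed throughout:

1. $t = 1$, $D = I$, $\lambda = 1/\sum_i 2p_i(1-p_i)$,
   $G_{(t)} = \lambda Z D Z'$ (allele frequencies fixed at their post-QC
   values for the whole loop);
2. GEBVs $\hat a$ by single-step GBLUP with the blended
   $(0.9\,G_{(t)} + 0.1\,A_{22})$ inside $H^{-1}$;
3. marker effects $\hat g_{(t)} = \lambda D Z' G_{(t)}^{-1} \hat a$, using
   the breeding values of the genotyped animals and the *unblended*
   weighted $G_{(t)}$;
4. new weights $d_i = \hat g_i^2\, 2p_i(1-p_i)$;
5. rescale so $tr(D) = m$ (total genetic variance constant);
6. rebuild $G$ and repeat. Three iterations by default; effects from the
   final iteration feed the window analysis.

One numerical point deserves emphasis: with allele frequencies computed
from the analysed animals the centred dosage columns sum to zero, so the
unblended $G$ is singular with null vector $\mathbf 1$ — always, not just
when animals outnumber markers. The driver therefore adds a `1e-8` ridge
before solving. Because $Z'$ annihilates exactly the regularised
direction, the resulting marker effects equal the minimum-norm solution
and are insensitive to the ridge size; `backsolve_snp_effects()` keeps
`ridge = 0` as its strict default and errors with advice on singular
input. The test suite pins the one-SNP case to an SVD pseudoinverse
oracle and the full-rank case to exact reconstruction
$Z\hat g = \hat a$.

## Windows and QTL regions

`make_windows()` tiles each chromosome with non-overlapping 0.4 Mb bins
anchored at position 0 (0.4 Mb is the average haploblock length reported
for commercial pig lines, which is also why the window width is the
default flank and merge distance). Coordinates are 0-based half-open
internally and 1-based inclusive in written reports. For each window the
share of additive variance is
$100\cdot Var\!\big(\sum_{j \in w} z_j \hat g_j\big)/\sigma^2_a$, the
sample variance (n−1) of the window genetic score across genotyped
animals. Selection takes windows strictly above 1% (the reference point
being the uniform expectation, e.g. $100/3707 = 0.027$% per window);
consecutive selected windows with midpoints strictly less than 0.4 Mb
apart merge (for full windows the midpoint distance is exactly 0.4 Mb, so
only truncated terminal windows ever merge — an `le`-style rule can be
had by passing a slightly larger `gap_bp`); the top three windows are
reported as midpoint ± 0.4 Mb regions clipped to the chromosome, with the
window's own percentage retained. Sums of selected-window percentages are
reported but not asserted against any closed form: between-window
covariances make the per-window shares non-additive.

## The synthetic-data generator

No real data ship with the package, so `simulate_dataset()` generates the
structure the model assumes: a multi-generation pedigree with alternating
sexes (every dam of a generation mated to a random sire, `litter_size`
offspring), gene-dropped biallelic SNPs, and repeated records built from
the model equation. Defaults emulate a Duroc nucleus herd analysed for
log sperm count: variance components 0.05172/0.03682/0.19380
($h^2 \approx 0.18$), 53 records per boar on average, 16 year–season
classes, ages 8–60 months, collection intervals 2–14 days, small nonzero
covariate slopes so their estimation is exercised, and roughly a third of
the animals genotyped (the most recent ones).

Choices the generator makes that matter for interpreting test results:

* **Founder haplotypes carry haploblock LD.** Each founder haplotype is a
  mosaic of 10 ancestral haplotypes with mean segment length 0.4 Mb; at
  each SNP the number of ancestral haplotypes carrying the counted allele
  is fixed to match the target frequency, so marginal frequencies and
  Hardy–Weinberg proportions are preserved while neighbouring loci are
  correlated, as on a real array in a closed herd with small effective
  population size. `founder_ld = FALSE` gives independent loci instead
  (used by the tests that compare genomic and pedigree kinship).
* **Record counts are Poisson** (mean `records_per_animal`, minimum 1);
  the real distribution of ejaculates per boar is unknown beyond its
  mean, so Poisson is an explicit assumption.
* **The polygenic remainder is marker-linked by default.** QTL effects are
  scaled against the realized dosage variance so each causal SNP
  contributes exactly its assigned fraction of $\sigma^2_a$, and the
  non-QTL remainder is spread as small effects over all segregating SNPs
  (orthogonalised against the QTL so the decomposition is exact). This
  matches the single-step model's own assumption that marker data carry
  the additive variance. `polygenic = "pedigree"` instead drops an
  unlinked polygenic term through the pedigree — useful for emulating
  "missing heritability", under which marker-level mapping is markedly
  harder because back-solving then projects non-marker genetic signal
  onto the SNPs.
* **Recombination is Haldane** at 1 cM/Mb with independent segregation
  across chromosomes.

What passing tests show — and what they do not: the simulator reproduces
the second-moment structure of the model (variance components,
repeatability, additive inheritance, HW proportions, pedigree-consistent
kinship) and array-like local LD, but it has no mutation, selection,
assortative mating, coalescent-calibrated frequency spectrum, genotyping
error, or trait outliers. Results on real data additionally depend on all
of those.

## Problem sizes used in the checks

The packaged checks run a parameter-recovery study (20 replicates of
~1,500 animals × ~5 records at the log sperm-count components, asserting
mean estimates within two empirical standard errors and mean $h^2$ in
[0.15, 0.22]) and a QTL-mapping study (10 seeds of a two-generation
nucleus herd — 68 founders, litters of 8, ~1,000 genotyped offspring,
5,000 SNPs at the SNP spacing of a 50K porcine array, one QTL assigned 5%
of $\sigma^2_a$ — asserting the QTL window ranks first in at least 8 of
10 seeds with a median share between 2 and 8%). The nucleus-herd design
is deliberate: large full-sib litters are what separates additive from
permanent-environment effects when each boar's records are highly
repeatable, and with too few families the between-family drift noise of
5,000 SNPs competes with a 5% QTL. The mapping check is power-limited at
this scale — a 5% QTL is a small target once breeding-value noise is
projected onto the markers, and back-solving from *true* breeding values
does place the QTL window first with a ~3% share, so the per-seed outcome
turns on GEBV accuracy rather than on the window algebra (which the
oracle-equivalence tests pin exactly). `scripts/acceptance.R` reruns the
same computations at a single seed and writes the resulting numbers as
JSON.

## Known limitations

* The REML path needs a dense inverse of the coefficient matrix; beyond
  ~10k equations supply variance components (e.g. from a dedicated
  variance-component tool) and let `wssgwas()` hold them fixed.
* Single-trait repeatability models only: no multi-trait, maternal or
  heterogeneous-residual structures.
* The imputation step is a frequency sampler meant for scattered
  post-QC missingness, not a phasing imputer; externally imputed PED/MAP
  files can be supplied instead.
* Window percentages are not re-scored after region extension; the
  extended span is reported alongside the window's own share.
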
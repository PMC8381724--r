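---
title: "Models and methods in tetragp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in tetragp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetragp)
```

tetragp implements a complete genomic-prediction and association-mapping
workflow for autotetraploid crops genotyped by sequencing: probabilistic
dosage calling from allele read counts, field-trial adjustment of
phenotypes, four tetraploid relationship matrices plus a Gaussian kernel,
eight whole-genome prediction models, CDmean training-set optimisation, and
mixed-model association scans under five gene-action codings. This vignette
describes each model, the numerical choices behind the implementation, what
the built-in simulator does and does not emulate, and the limitations a
user should know about.

## Dosage calling from read counts

A biallelic marker in a tetraploid has five genotype classes (AAAA, AAAB,
AABB, ABBB, BBBB), i.e. alternative-allele dosages 0--4. Given `ref` and
`alt` read counts at a cell and a per-read error rate $e$, the expected
alternative-read fraction for dosage $k$ is

$$f(k) = \frac{k}{4}(1-e) + \Big(1-\frac{k}{4}\Big)e,$$

and the posterior over classes is proportional to the binomial likelihood
of the alternative count times a prior. The default prior is uniform over
the five classes; a Hardy--Weinberg prior (`dbinom(0:4, 4, p)`) can be
supplied instead. With no reads the posterior is the prior. The default
error rate is $e = 0.002$; any value in $[0, 0.005]$ gives the same calls
at two decimals for typical depths, so the choice is not delicate.

A cell is called at the maximum-posterior class when that maximum reaches
`probThreshold` (default 0.85) and is missing otherwise; stricter
thresholds trade missingness for call quality. Posterior ties are broken
toward the lower dosage class, which is deterministic and conservative
toward the reference allele. Marker QC applies, in order: a mean-depth
band ($[10, 100]$ by default, a marker-level property), a minor-allele
frequency floor (default 0.01, computed from called dosages), and a
missing-fraction cap (markers missing in *more than* 25% of individuals
are dropped, so exactly 25% survives). Removal of multi-allelic and
repetitive-region markers is an alignment-level task upstream of this
package. Missing calls are imputed per marker by the mode (ties to the
lower dosage); mean imputation is available but leaves fractional dosages.

## Field-trial adjustment and heritability

Plot phenotypes from a resolvable row--column design are adjusted in two
steps. Within each trial, a linear mixed model with fixed complete-block
and genotype effects and random row-in-block and column-in-block effects
yields one adjusted mean (BLUE) per genotype; plots with standardised
residuals beyond 3.5 are flagged and can be removed. Across trials, a
fixed trial + genotype model on the within-trial BLUEs gives the single
adjusted mean per genotype used as the prediction response. On balanced,
noise-free data this two-step route reproduces the joint single-model
analysis exactly (`bluesSingleStep()` exists for that comparison). All of
these ordinary variance-component fits are delegated to `lme4`.

Broad-sense heritability across $l$ locations and $t$ years uses
genotype, genotype-by-location and genotype-by-year variance components
estimated from the within-trial BLUEs:

$$H^2 = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_{gL}/l + \sigma^2_{gT}/t +
\sigma^2_\epsilon/(lt)},$$

where the residual absorbs the three-way interaction together with
carried-over within-trial error; with trial means as input this is closer
to a repeatability than a narrow-sense heritability.

## Relationship matrices

All constructions use alternative-allele frequencies $p_j$ estimated from
the data (or fixed externally, which makes construction commute with
subsetting):

* **Additive** (`additiveKinship`): VanRaden-type at ploidy 4,
  $G_A = ZZ^\top / \sum_j 4p_j(1-p_j)$ with $Z = X - 4P$. The mean
  diagonal is near 1 under tetrasomic Hardy--Weinberg equilibrium.
* **Digenic dominance** (`dominanceKinship`): per marker the quadratic
  covariate $d(x) = \binom{x}{2} - 3p x + 6p^2$, whose Binomial$(4,p)$
  expectation is zero for every $p$ and which is orthogonal to the
  additive (linear) covariate under HWE. The normaliser is the summed
  exact Binomial$(4,p)$ variance of $d$, obtained by enumerating the five
  dosage outcomes -- no approximate closed form is involved.
* **Additive-by-additive epistasis** (`epistasisKinship`): the Hadamard
  square $G_A \# G_A$ (PSD by the Schur product theorem).
* **Full tetraploid** (`fullTetraploidKinship`): five indicator columns
  per marker, one per genotype class, so each class carries its own
  effect; the indicator cross-product is scaled to mean diagonal 1.
  Scaling only changes the units of the attached variance component.
* **Gaussian kernel** (`rkhsKernel`): $K = \exp(-\theta D)$ where $D$ is
  the squared Euclidean distance between dosage rows divided by its mean
  off-diagonal value. The normalisation makes $\theta$ dimension-free
  across marker counts; since $\theta$ is re-estimated from data, the
  convention (squared vs. plain distance) is absorbed into the estimate.

Eigenvalues below $-10^{-8}\lambda_{max}$ are clipped to zero with a
warning; smaller negative values are treated as numerical noise.

## Prediction models

Eight models are available, in two families.

**Kernel mixed models** -- `fitGBLUP()` fits
$y = \mu + \sum_k g_k + \epsilon$ with $g_k \sim N(0, K_k\sigma^2_k)$ for
additive (Add), additive+dominance (A+D), additive+dominance+epistasis
(A+D+Ep) and full-tetraploid (FT) kernel sets. The default engine is a
Gibbs sampler (default 10,000 iterations, 2,500 burn-in) with
scaled-inverse-$\chi^2$ variance priors, $df = 5$, and scales chosen so a
prior $R^2 = 0.5$ of the phenotypic variance is split equally across the
genetic terms -- the partition rule common to whole-genome regression
software. Sampling is performed in the eigenbasis of each kernel's
training block, which makes the conditional updates independent normals
and the chain cheap and bit-reproducible per seed. Unphenotyped
individuals are predicted through the joint kernel rows,
$\hat g_{val} = K_{vt}K_{tt}^{-1}\hat g_t$, equivalently evaluated in the
eigenbasis. An `engine = "reml"` alternative maximises the restricted
likelihood directly (spectral profile REML for one kernel; Nelder--Mead on
log-variances for several -- a multiplicative fixed-point update was tried
first and abandoned because it collapses small components to the boundary)
and returns BLUPs.

**Marker-effect Bayesian regressions** -- `fitBayesMarker()` fits
$y = \mu + Xb + \epsilon$ with columns centred by $4p_j$, by Gibbs
sampling in compiled code: **BayesA** (per-marker
scaled-inverse-$\chi^2$ variances, a scaled-$t$ effect prior),
**BayesC$\pi$** (spike-and-slab with a common slab variance; the
zero-effect proportion $\pi$ has a uniform prior and is sampled from a
Beta posterior), and **BayesL** (the Bayesian LASSO: double-exponential
effects via the exponential-mixture-of-normals hierarchy, with
$\lambda^2$ given a Gamma hyperprior and estimated from the data).
Chains are seeded through R's RNG and bit-reproducible; doubling $y$
exactly doubles genetic values and quadruples variances.

**RKHS** -- `fitRKHS()` profiles the one-kernel restricted likelihood
over a bandwidth grid (default $\{0.1, 0.25, 0.5, 1, 2, 5\}$), using one
spectral decomposition per candidate, and returns BLUPs at the winning
bandwidth. Nearly degenerate kernels (tiny $\theta$) get a $10^{-8}$
ridge with a warning.

Two identifiability caveats, both verified empirically in the test suite:

* The bandwidth is only weakly identified when pairwise dosage distances
  concentrate. With many unlinked markers the normalised distances all
  approach 1 and the profile likelihood differs by less than a log-unit
  between $\theta = 0.1$ and $\theta = 1$; bandwidth recovery tests
  therefore use a few hundred markers, where distances retain spread.
* $\pi$ in BayesC$\pi$ mixes slowly and is weakly identified under a null
  trait (per-marker Bayes factors near 1), so single-chain posterior
  means of $\pi$ scatter around 0.5; conclusions about $\pi$ should
  average several chains.

## Cross-validation and CDmean

`runCV()` repeats: select a training set (default 105 of 147), mask the
validation phenotypes, fit, predict, and score the Pearson correlation
between observed adjusted means and predictions. Relationship matrices
and allele frequencies are computed once from all genotyped individuals --
genotypes carry no phenotype information, and a canary test verifies that
corrupting validation phenotypes leaves predictions bit-identical.

CDmean training sets maximise the mean coefficient of determination of
the validation individuals' genotypic-value contrasts with the population
mean, computed from the conditional variance under a one-kernel mixed
model: $CD_i = c_i^\top G_{\cdot t}(G_{tt} + \lambda I)^{-1}G_{t\cdot}c_i
/ c_i^\top G c_i$ (a plain genotypic-value variant is available). The
variance ratio $\lambda$ defaults to $(1-\tilde h^2)/\tilde h^2$ with
$\tilde h^2$ from an additive fit on all data. The optimiser is an
exchange algorithm; because the criterion landscape has non-global local
optima on small panels, the default runs steepest-ascent sweeps from five
random starts and keeps the best (a first-improvement single-start
variant is used inside repeated cross-validation for speed). Only
improving swaps are accepted, so the final criterion never falls below
the starting one; on an 8-choose-4 toy the procedure recovers the
exhaustive-search optimum in at least 18 of 20 random seeds.

## Association scans

`gwasScan()` fits $y = \mu + x\beta + g + \epsilon$ with polygenic
covariance $G_A\sigma^2_g$. The null model is fitted once by spectral
REML and each marker is then tested by generalised least squares at the
fixed null variance components with a Wald test (the P3D shortcut);
per-marker REML refitting is available for small panels. Markers can be
coded additively ($0..4$) or as two-level dominance contrasts: simplex
(at least one copy of the dominant allele switches the effect on) or
duplex (at least two copies), each for the alternative or the reference
allele -- five codings in all. Monomorphic coded columns are skipped.
QQ calibration is summarised by the genomic-control $\lambda$ (median
$\chi^2$ ratio) alongside the QQ slope.

The significance threshold is $-\log_{10}(\alpha / M_{eff})$ with the
effective test count from the eigenvalues $\lambda_i$ of the marker
correlation matrix, $M_{eff} = \sum_i [\mathbb{1}(\lambda_i \ge 1) +
(\lambda_i - \lfloor \lambda_i \rfloor)]$, computed genome-wide from the
additively coded dosages via the individuals-level cross-product (only
the nonzero spectrum matters). Eigenvalues numerically on an integer are
snapped before the floor, since the fractional part is discontinuous
there. Two properties worth knowing: $M_{eff} \le m$ always (each term is
at most its eigenvalue), but $M_{eff}$ can exceed $n$ when $m \gg n$
(each of the $n$ nonzero eigenvalues can contribute up to 2), and
duplicating a marker panel does *not* leave $M_{eff}$ invariant in
general because it doubles every eigenvalue.

`varianceExplained()` reports ordinary least-squares $R^2$ for nested
designs -- the first three relationship-matrix principal components alone,
plus the significant additive markers, plus each dominance coding's
significant markers -- dropping aliased columns so $R^2$ is non-decreasing
along the nesting.

## Population structure

`dosagePCA()` takes scores from the eigendecomposition of the additive
relationship matrix (eigenvectors scaled by root eigenvalues); the first
three components feed the variance-explained regressions. `pairwiseFst()`
uses a Weir--Cockerham-type estimator on alternative-allele frequencies in
which each tetraploid individual contributes four allele observations,
aggregated over markers as a ratio of sums; groups below five individuals
are excluded. The estimator is exactly 1 at a fixed difference and
invariant to allele-label swaps.

## The synthetic tetraploid generator

`simulateDosages()` draws ancestral allele frequencies uniformly on a
configurable range, drifts them into subpopulations with a
Balding--Nichols Beta model of strength $F$ (`structureStrength`), and
samples dosages as Binomial$(4, p)$ -- tetrasomic HWE within
subpopulation. Defaults emulate a diversity panel of the kind used in
tetraploid potato studies: 147 individuals, 12 chromosomes, four weakly
differentiated subpopulations ($F = 0.01$, matching the near-zero
pairwise $F_{ST}$ seen between potato market classes).
`simulateReadCounts()` is the exact inverse model of the dosage caller:
per-cell depth uniform over a range (default 10--100, the accepted QC
band; a negative-binomial option exists since real GBS depth
distributions are not published in a usable form), and alternative reads
Binomial$(depth, f(x))$. `simulatePhenotypes()` builds genotypic values
from sampled QTL with additive, simplex-dominance, duplex-dominance and
additive-by-additive product components -- dominance components use the
centred two-level codings so that variance targets are interpretable --
rescales each component so its realised panel variance hits the target
exactly, and scatters one plot per genotype per block over a row--column
layout with block, row, column, genotype-by-location, genotype-by-year
and plot-residual draws (plot-level, not plant-level, simulation; a
simple random row--column randomisation rather than a latinised design).
Everything is bit-reproducible from the seed.

What the generator does **not** emulate is as important as what it does:

* **No linkage.** Markers are independent, so there is no LD and no
  marker redundancy. Real GBS panels are massively redundant -- tens of
  thousands of markers can collapse to a few hundred effective regions --
  which means $m$ simulated markers behave like $m$ *effective* loci. A
  realistic effective dimension for a potato-like panel is a few hundred,
  not tens of thousands.
* **No pedigree.** Individuals are unrelated within subpopulation, so
  close-relative prediction pathways are absent.

These two absences have a quantifiable consequence for non-additive
prediction that the test suite documents. Between unrelated individuals,
additive relationship entries are $O(1/\sqrt{m})$; digenic-dominance
relationships are of the same order (the covariate is observed at
genotyped loci), but additive-by-additive relationships are their
*square*, $O(1/m)$ -- so epistatic genetic values essentially do not
transfer from training to validation individuals in an unlinked,
unrelated panel. An oracle experiment with the *true* variance components
(additive 0.3, epistatic 1.5, residual 0.5, $m = 400$) shows the
additive-only predictor beating the additive+epistatic one on validation
individuals; the semi-parametric Gaussian kernel, whose
maximum-likelihood bandwidth correctly collapses to the near-linear end
of the grid, ties with additive GBLUP. The expected superiority of
kernels that capture epistasis is therefore *not* reproducible with this
generator -- in real panels it rides on LD and relatedness. The
corresponding acceptance check is retained and fails, deliberately, as a
record of that limitation.

Dominance is recoverable, with a caveat of its own: the simplex coding is
overwhelmingly additive at extreme allele frequencies (85% additive at
$p = 0.1$, with most of its variance concentrated there), and its
digenic share peaks near 40% only at intermediate frequency. Simulations
that probe dominance-aware models therefore use mid-frequency panels
(allele frequencies 0.35--0.65) and dominance-heavy traits; under those
conditions the additive+dominance model beats the additive model in most
paired cross-validation comparisons, and a simplex-dominant QTL scores
higher under the matching presence/absence GWAS coding than under the
additive coding in essentially every replicate.

## Problem sizes and numerical defaults

Simulation-based tests use panels of 8--200 individuals and 50--2,000
markers; the heavier properties (Gibbs-vs-BLUP agreement, the
dominance-architecture comparison) run at 150 individuals by 2,000
markers with 1,500--10,000 Gibbs iterations, and the full suite completes
in a few minutes on one core. Fixed numerical choices: REML convergence
at relative tolerance $10^{-8}$--$10^{-9}$; eigenvalue clipping at
$-10^{-8}\lambda_{max}$; Gibbs thinning 1 (all post-burn-in samples are
kept at these sizes); posterior/argmax/mode ties break toward the lower
dosage class; the CD exchange accepts swaps only when the criterion gains
more than $10^{-12}$.

## Known limitations

* Non-additive prediction gains require LD or relatedness that the
  unlinked generator cannot provide (above); conclusions about real
  panels should not be read off simulation accuracies.
* The dosage caller discretises; continuous-genotype (allele-frequency)
  approaches are out of scope, as are alignment, variant discovery and
  multi-allelic sites.
* The field model has independent row and column effects, not a spatial
  (AR1$\times$AR1) residual; check-variety plots participate in fitting
  but carry no explicit spatial-correction mechanism beyond that.
* Heritability from trial means is a repeatability-like quantity.
* The Bayesian samplers use the equal-partition hyperprior rule; exact
  hyperprior constants in published analyses vary between software and
  are rarely reported, so variance-component posteriors (not
  predictions) can shift slightly between implementations.
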
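---
title: "Models and methods behind qgscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind qgscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(qgscan)
```

`qgscan` dissects heritable variation in penetrance phenotypes — the
fraction of arrested embryos showing gut differentiation after RNAi of an
early endoderm regulator — across homozygous *C. elegans*-like strain
panels. This vignette is the package's own account of the models it
fits, the parameters that matter, what the synthetic-data generator does
and does not emulate, and the numerical choices made where the design
was genuinely open.

## The mixed model and its REML profile

For a phenotype vector $y$ over $n$ strains, the association model is

$$y = X\beta + g + e, \qquad
  \mathrm{Var}(y) = \sigma_g^2\,(K + \delta I), \qquad
  \delta = \sigma_e^2/\sigma_g^2,$$

where $K$ is the identity-by-state kinship matrix:
$K_{ij}$ is the mean over co-genotyped markers of $1 - |g_i - g_j|/2$.
IBS kinship is bounded in $[0,1]$ with unit diagonal, and absorbs
population structure in a panel of clonal, effectively homozygous wild
isolates.

The restricted likelihood is profiled over $\delta$ through the
eigendecomposition of $S K S$ with
$S = I - X(X'X)^{-1}X'$: with $\eta = U'y$ and nonzero eigenvalues
$\xi_i$,

$$\ell_R(\delta) = \tfrac12\Big[(n-q)\big(\log\tfrac{n-q}{2\pi} - 1 -
  \log\textstyle\sum_i \eta_i^2/(\xi_i+\delta)\big) -
  \textstyle\sum_i \log(\xi_i+\delta)\Big].$$

$\delta$ is maximized on a 100-interval grid over
$\log_{10}\delta \in [-5, 5]$, with `uniroot()` refinement of
$d\ell_R/d\delta$ inside each sign-change bracket and the boundary
values kept as candidates. `emma_scan()` re-estimates the variance
components **exactly for every marker's design** (marker dosage in the
fixed effects) rather than reusing a single genome-wide fit; at the
small panel sizes typical of this design (tens of strains), the exact
refit is affordable and avoids the approximation error of the one-fit
shortcut. Two-sided p-values use the $t$ distribution with
$n - \mathrm{rank}(X)$ df. Strains missing a marker's genotype are
dropped for that marker (complete-case); no imputation.

Two numerical facts are worth knowing:

* **IBS kinship can be slightly indefinite** when strains overlap on
  different marker subsets (missing data). Eigenvalues above $-2\%$ of
  the spectral radius are clipped to zero; anything worse raises an
  error. An absolute tolerance would reject ordinary IBS matrices.
* **$\delta$ is weakly identified against the IBS bulk.** IBS matrices
  have a large shared baseline, so $\sigma_g^2(K + \delta I)$ changes
  slowly along a ridge and REML fits legitimately land on a search
  boundary for some phenotype draws. Boundary optima are reported with
  a warning; association tests are unaffected (the $t$ statistic is
  continuous in $\delta$ and, at $K = I$, entirely independent of it —
  the scan then reproduces ordinary regression p-values to $10^{-9}$).

### Permutation FDR

The genome-wide error control mirrors permutation practice for scans
with correlated markers: phenotype labels are permuted (kinship and
genotypes fixed), the **full scan is recomputed per permutation**, and
for a p-value cutoff $t$

$$\widehat{\mathrm{FDR}}(t) =
  \frac{\text{mean permuted } \#\{p \le t\}}
       {\max(1,\ \text{observed } \#\{p \le t\})},$$

monotonized step-up and clipped to $[0,1]$. Because the aggregation
behind a permutation FDR can also be read as a family-wise quantile,
the max-statistic threshold (the $\lceil(1-\alpha)N\rceil$-th order
statistic of the per-permutation maximum of $-\log_{10} p$) is always
reported alongside; on null simulations both declare false positives at
close to their nominal rate. Internally the permutation engine reuses
each marker's eigen-rotation across all permutations (only $U'y$
changes), with the $\delta$ grid evaluated for all permutations in one
matrix product and a quadratic interpolation refinement in
$\log_{10}\delta$; the observed phenotype is passed through the same
engine so observed and permuted p-values are computed identically.

## Interval mapping for selfed RILs

RIL genotypes are modelled as a two-state hidden Markov chain along
each chromosome, the states being the two parental homozygote classes.
Genetic distance $d$ cM converts to a per-meiosis recombination
fraction by the Haldane (no interference) map,
$r = (1 - e^{-2d/100})/2$, and repeated selfing expands it to the
RIL-level discordance probability $R = 2r/(1+2r)$
(Haldane–Waddington). For a fully inbred selfed line the parental
mosaic is Markov at the markers, so using $R$ as the transition
probability between consecutive grid positions is exact, and the
forward–backward posteriors match exhaustive hidden-path enumeration to
$10^{-10}$ on toy chromosomes. Emissions allow a symmetric genotyping
error rate; residual heterozygote calls (which the simulator emits at
rate $(1/2)^{s+1}$ after $s$ post-F2 selfing rounds) are treated as
missing observations — the standard two-class convention for selfed
RILs.

`scanone_em()` fits, at every position of a marker + pseudomarker grid,
a two-component normal mixture with *known* per-individual mixing
proportions (the HMM posteriors): class means and a common variance,
by EM. The LOD is $\log_{10}$ of the maximized mixture likelihood over
the single-normal null. On complete data the EM fixed point is the
marker regression, and the LOD equals $(n/2)\log_{10}(RSS_0/RSS_1)$ to
$10^{-6}$. The EM is vectorized across all grid positions
simultaneously (the M-step is columnwise), which is what makes
1,000-permutation thresholds affordable in plain R.

Defaults follow the conventions of the standard RIL mapping toolchain:
pseudomarker step 1 cM, genotyping error rate $10^{-4}$, EM tolerance
$10^{-6}$ on the log-likelihood, 4000 max iterations, thresholds as the
$\lceil(1-\alpha)N\rceil$-th order statistic without interpolation, and
1.5-LOD support intervals (the conventional approximate 95% interval
for this cross type) with linear interpolation of the threshold
crossing and clipping at chromosome ends. When only physical positions
are available (the 012 format stores none), `assign_cM_from_bp()`
applies a constant 250 kb/cM — a nematode-like genome average —
configurable per analysis.

## Phylogenetic signal

Strain relatedness is summarized by the Hamming-proportion SNP distance
(fraction of co-genotyped markers with differing codes) and a
neighbor-joining tree. NJ is delegated to `ape::nj` on taxa sorted by
name (making the output invariant to input order); negative branch
lengths, which NJ can produce on non-additive distances, are clamped to
zero with the deficit moved to the sister branch so path lengths
through the parent are preserved.

Pagel's $\lambda$ rescales the off-diagonal entries of the
Brownian-motion shared-path-length covariance $C$ while keeping the
diagonal: $\Sigma(\lambda) = \sigma^2 [\lambda C +
(1-\lambda)\,\mathrm{diag}(C)]$. The root mean and rate are profiled
analytically (GLS mean, ML variance) and $\lambda$ is maximized over
$[0, 1]$ — for $\lambda \le 1$ the covariance is automatically PSD, so
the upper bound is 1 — by a 101-point grid plus `optimize()` in the
bracketing interval; the reported maximum always dominates the grid.
Significance is the likelihood-ratio statistic against $\lambda = 0$
(complete phylogenetic independence) on $\chi^2_1$. Because
$\lambda = 0$ sits on the parameter boundary, this reference is
conservative; simulated type-I error at $\alpha = 0.05$ stays below
7.5%. The fitted likelihood is checked against a direct
multivariate-normal density and against an independent implementation
(`phytools::phylosig`) in the test suite.

## Reciprocal allelic effects

The cross-trait analysis asks whether alleles that increase the
penetrance requirement for one pathway input tend to decrease it for
the other. The pipeline order is fixed: class-size filter → LD prune →
effect computation → outlier filter → correlate.

* **Effect:** per SNP and trait, median(phenotype | alternate-allele
  homozygotes) − median(phenotype | reference homozygotes), the
  reference class fixed across traits so signs are comparable. Medians
  make the effect robust to the skewed, bounded penetrance scale.
* **LD pruning:** sliding windows of 50 markers advancing by 5
  (PLINK-style `indep-pairwise` defaults; the window never spans a
  chromosome when a map is supplied). Within a window, while any
  retained pair exceeds $r^2 = 0.8$, the highest-$r^2$ pair is resolved
  by dropping its lower-MAF member, ties dropping the later map
  position — a fully deterministic rule, checked against an exhaustive
  greedy oracle.
* **Outliers:** a single pass of per-trait z-scores from the included
  effects' mean and SD, excluding markers with $|z| > 1.96$ in
  *either* trait ("either" so one trait's extreme cannot leverage the
  correlation). Statistics are deliberately not recomputed after
  removals; a second application could remove more, and that is
  documented rather than iterated.
* **Correlation:** Pearson $R$ over included markers, genome-wide and
  per chromosome, p from the $t$ transform with $m - 2$ df; groups
  with fewer than 3 markers are reported undefined rather than failing.
  Strain-level association between the two traits uses Spearman's
  $\rho$ with average ranks and the $t$ approximation.

Minimum class size defaults to 3 strains per homozygote class: below
that a median difference is dominated by individual strains.

## The synthetic-data generator

The generator produces data with the statistical structure the scans
assume, with known truth:

* **Isolate panels:** each marker gets an ancestral frequency
  $\sim U(0.05, 0.95)$; subpopulation frequencies follow the
  Balding–Nichols construction
  $p_s \sim \mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$ with
  differentiation $F$ (`fst`), and strains are drawn homozygous (codes
  0/2) — one Bernoulli allele per strain and marker, matching a selfing
  species' virtually homozygous isotypes. A Hudson-type estimator
  recovers the target $F$ on large panels. Genotyping error flips
  homozygotes uniformly; missingness is injected uniformly at random
  (the missingness structure of real GBS data is unknown, so nothing
  fancier is attempted).
* **RILs:** meiosis draws a Poisson number of crossovers per chromosome
  (length in Morgans) with uniform placement — the Haldane model, with
  no interference, deliberately matching the map-function convention of
  the downstream HMM so simulator and mapper are self-consistent. The
  cross is F1 selfed once to F2, then `selfing_generations` further
  rounds (default 10, as in a typical RIL panel), giving residual
  heterozygosity $(1/2)^{11} \approx 4.9\times10^{-4}$ per locus and
  adjacent-marker recombinant fractions matching $2r/(1+2r)$ in
  simulation.
* **Phenotypes:** per strain and trait, a liability = baseline + QTL
  dosage effects + polygenic term + strain noise, mapped through a
  logistic link (clipped to $[10^{-6}, 1-10^{-6}]$ — the data give no
  generative model for penetrance, and the logistic is the natural
  bounded link), then observed as replicate-level binomial counts
  (default 2 replicates × 500 embryos, the scoring depth typical for
  this assay). The polygenic background is realized through many small
  marker effects rather than a drawn random effect, so kinship
  confounding is genotype-borne and genuinely visible to the mixed
  model. The strain-level noise SD (default 0.2 liability units ≈ a few
  percentage points of penetrance near 0.5) captures the observed
  replicate-to-replicate reproducibility beyond binomial sampling;
  nothing in the source data pins this value, so it is a free,
  documented parameter chosen once.
* **Tree traits:** multivariate normal draws with the λ-scaled Brownian
  covariance, for exercising the λ estimator at known truth.

What the generator does **not** emulate: linkage disequilibrium within
subpopulations beyond what structure induces (markers are drawn
independently given subpopulation frequencies), realistic missingness
patterns, genotyping error correlated with coverage, selection or
transmission distortion in the RILs, and crossover interference.
Passing tests therefore demonstrate correctness of the estimators under
their stated models — calibration, recovery, closed-form agreement —
not robustness to every pathology of real GBS data.

## Problem sizes and determinism

The test suite and the acceptance script run everything at desk scale,
chosen so the full suite completes in a few minutes on one core:
calibration uses 200 replicate scans × 200 permutations (a freshly
simulated panel per replicate, since the calibration claim is marginal
over data sets), coverage and λ-recovery use 100–200 replicates,
simulator closed forms use 10,000 RILs. Every stochastic function takes
an explicit integer seed; the pipeline derives per-stage substreams
deterministically from one global seed, so re-running an identical
configuration reproduces byte-identical JSON reports regardless of
which stages are enabled.

## Known limitations

* Single-QTL models only: no composite interval mapping, multi-QTL or
  epistasis scans, and no multi-component variance models (GxE,
  rare-variant tests) — deliberately out of scope.
* The λ likelihood-ratio test's $\chi^2_1$ reference ignores the
  boundary at $\lambda = 0$ (conservative) and, on small or shallow
  trees, λ itself has wide sampling spread.
* The permutation FDR assumes exchangeability of strains under the
  null; strong cryptic relatedness not captured by the kinship matrix
  would break that.
* VCF support is a minimal GT-only dialect (multi-allelic records are
  skipped with a count); full INFO/FORMAT parsing, BCF and indexing are
  non-goals.
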
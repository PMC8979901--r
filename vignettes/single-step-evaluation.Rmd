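---
title: "Single-step genomic evaluation of withers height: models, simulator, and numerical choices"
author: "stepreins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-step genomic evaluation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Sport-horse breeding programmes have many more pedigreed, phenotyped animals
than genotyped ones. Single-step GBLUP (ssGBLUP) evaluates all of them
jointly by combining the pedigree numerator relationship matrix **A** with a
marker-based (realized) genomic relationship matrix **G** into one
relationship matrix **H**. This package implements that evaluation for a
continuous conformation trait — withers height in cm, recorded on a
multi-breed reference population of mares — together with the surrounding
analyses a study of this kind performs: marker QC, population-structure
diagnostics (GRM principal components, linkage disequilibrium), a
leave-one-chromosome-out (LOCO) mixed-linear-model association scan with
conditional analysis, and per-component variance partitioning. Because such
mare data sets are proprietary, the package ships a multi-breed simulator
that reproduces the statistical structure the analyses assume, so every
stage is testable end to end.

# The single-step model

The animal model is

$$\mathbf{y} = \mathbf{X}\mathbf{b} + \mathbf{Z}\mathbf{a} + \mathbf{e},
\qquad \mathbf{a} \sim N(\mathbf{0}, \mathbf{H}\sigma^2_a),
\qquad \mathbf{e} \sim N(\mathbf{0}, \mathbf{I}\sigma^2_e),$$

where **X** carries the intercept and the measurement age classes (five
half-open bins: younger than 3 years, 3–4, 4–5, 5–6, older than 6; class 1
is the reference level) and **Z** maps each height record to its animal.
**H** agrees with **A** for relationships involving a non-genotyped animal
and substitutes genomic information on the genotyped block:

$$\mathbf{H}^{-1} = \mathbf{A}^{-1} +
\begin{bmatrix}\mathbf{0} & \mathbf{0}\\
\mathbf{0} & \mathbf{G}^{-1}-\mathbf{A}_{22}^{-1}\end{bmatrix},$$

with $\mathbf{A}_{22}$ the pedigree relationships among genotyped animals.
`numeratorRelationship()` builds **A** by the tabular method; `aInverse()`
builds $\mathbf{A}^{-1}$ directly from Henderson's rules with
inbreeding-adjusted Mendelian sampling variances; `hMatrix()` assembles the
explicit block form of **H** and its lower Cholesky factor **L**;
`hInverse()` assembles the sparse-correction inverse. The two routes are
verified against each other (and against brute-force inversion) in the test
suite.

**G** is VanRaden method 1, $\mathbf{G} = \mathbf{Z}_m\mathbf{Z}_m'/
(2\sum_j p_j(1-p_j))$ with dosages centred by $2p_j$, allele frequencies
taken from the genotyped sample. This is the
GCTA-style default; base-population frequencies are not available for real
data of this design, and using the observed sample is one acknowledged
source of the gap between pedigree-based and marker-based heritability (see
*Simulator fidelity* below). Because a raw **G** can be singular (duplicate
genotypes, more animals than informative markers), `blendG()` forms
$w\mathbf{G} + (1-w)\mathbf{A}_{22}$ with default $w = 0.95$; any $w < 1$
restores positive definiteness.

## Cholesky-transformed fitting

Rather than solving the mixed-model equations with $\mathbf{H}^{-1}$, the
sampler uses the equivalent model

$$\mathbf{y} = \mathbf{X}\mathbf{b} + \mathbf{F}_a \mathbf{c}_a + \mathbf{e},
\qquad \mathbf{F}_a = \mathbf{Z}\mathbf{L}, \qquad
\mathbf{c}_a = \mathbf{L}^{-1}\mathbf{a},$$

in which the random effects are independent, $\mathbf{c}_a \sim
N(\mathbf{0}, \mathbf{I}\sigma^2_a)$. `fitGibbs()` runs a conjugate Gibbs
sampler over $(\mathbf{b}, \mathbf{c}_a, \sigma^2_a, \sigma^2_e)$ with
scaled-inverse-chi-square priors (default df 5; scales set so each prior
mean is half the phenotypic variance — weakly informative, exposed through
`priors`). Two implementation details matter:

* **Rotation for mixing.** Before sampling, $\mathbf{c}_a$ is rotated by
  the eigenvectors of $\mathbf{F}_a'\mathbf{F}_a$. In the rotated basis the
  conditional precision of the animal effects is diagonal, so one
  single-site sweep is an exact joint draw and successive samples are
  nearly independent. The prior is rotation-invariant, and breeding values
  are recovered as $\mathbf{a} = (\mathbf{L}\mathbf{V})\mathbf{c}_a'$. The
  inner sweep is compiled code (RcppArmadillo); each iteration costs
  $O(n\,N)$.
* **Posterior summaries.** The posterior mean of **a** is the
  back-transform of the running mean of $\mathbf{c}_a$ (exact by
  linearity), accumulated at every kept iteration; prediction error
  variances (PEV), which need far less relative precision, come from
  thinned back-transformed samples. Default chain: 30,000 iterations,
  5,000 burn-in, thinning 5.

`solveMME()` is the deterministic cross-check: Henderson's equations at
fixed variance components, with PEV from the inverse coefficient matrix.
The suite requires sampler/solver agreement to 0.02 cm at fixed variance
components, and the `fitMME()` wrapper doubles as the classical
pedigree-BLUP comparator (set `G = NULL`, so **H** = **A**).

Reliabilities are $r^2 = 1 - \mathrm{PEV}/\sigma^2_a$, clipped to $[0,1]$
with a logged count; clipping genuinely occurs for low-information animals
whose posterior variance slightly exceeds $\sigma^2_a$.

# Association testing

`mlmaLoco()` fits, for each SNP,

$$\mathbf{y} = \mathbf{X}\mathbf{b} + \beta\,\mathrm{SNP} + \mathbf{g} +
\mathbf{e}, \qquad \mathbf{g} \sim N(\mathbf{0},
\mathbf{G}_{-c}\,\sigma^2_g),$$

where $\mathbf{G}_{-c}$ is a GRM built from all autosomes except the tested
SNP's chromosome (LOCO: the candidate's chromosome never contributes to its
own background kinship, avoiding proximal contamination). Per left-out
chromosome, `locoReml()` estimates $(\sigma^2_g, \sigma^2_e)$ by REML using
one spectral decomposition and a one-dimensional search over the variance
ratio (residual variance profiled out; estimates at the search boundary are
flagged). The decomposition then rotates the model once per chromosome so
each SNP test is a weighted least-squares Wald chi-square with 1 df —
variance components are re-estimated once per chromosome, then held fixed
for its SNPs, the standard MLMA compromise. Conditional scans append the
conditioning SNP dosages to the fixed effects and exclude them from
testing. Significance thresholds are Bonferroni 0.05 and 0.01 over the
tested SNPs; the correction convention is exposed rather than hidden
because captions of the form "P = 0.05" are ambiguous.

`partitionVariance()` attributes phenotypic variance to marker subsets
(e.g. the significant SNPs vs the remaining genome) by Haseman–Elston
regression: off-diagonal cross-products of OLS-adjusted phenotypes
regressed on the stacked GRM entries, with delete-group jackknife standard
errors (30 groups by default). HE is closed-form and robust at these sample
sizes; an iterative many-component REML is deliberately not attempted.

# Marker QC and imputation

`qcFilter()` removes markers in a fixed order, each counted once under the
first failing rule: duplicates (same chromosome and bp; the
lexicographically first snp_id is kept), call rate < 0.90, minor allele
frequency < 0.01, Hardy–Weinberg chi-square p < 0.001 (pooled over animals;
the per-breed alternative is not implemented). Non-autosomal markers are
already dropped at read time; only autosomes 1–31 are representable.
The filter is idempotent and order-stable, both tested.

`imputeMissing()` draws each missing call from Binomial(2, p̂) at the
marker's observed frequency, seeded. This is a stand-in, not an LD-aware
phasing imputation: downstream matrix algebra needs complete dosage
matrices, and allele frequencies are preserved (verified by
mask-and-recover tests), but haplotype structure is not — a documented
fidelity gap, acceptable because no analysis here depends on phase.
Intensity-based (GenCall-score) filtering is out of scope; the simulator's
`missing_rate` emulates its effect on call rates.

# The simulator

`simConfig()` defaults encode the study conditions the analyses assume:

* five studbooks of sizes 982/444/98/416/173 (scalable by `scale`),
  sharing sires at rate 0.1;
* three ancestral generations sized so the pedigree is roughly seven times
  the final genotyped cohort (~14.6k for ~2.1k at full scale);
* long-tailed sire families — rounded lognormal (meanlog 0.7, sdlog 1.05),
  mean ≈ 3.5 offspring, occasional sires with 60–80 — and dams used nearly
  one-to-one;
* 31 autosomes × 2,000 SNPs at 100 kb spacing, a uniform 1 Morgan genetic
  map per chromosome, founder allele frequencies Balding–Nichols-diverged
  between breeds (Fst-like 0.03);
* one major stature QTL on chromosome 3 (the LCORL-region analogue)
  contributing 23% of phenotypic variance, a pedigree-transmitted polygenic
  background of 27%, mean height 167.6 cm, residual SD 2.475 cm (implied
  total SD 3.5 cm), five measurement age classes with effects
  (−1.2, −0.3, 0, 0.2, 0.4) cm so young mares measure shorter but the
  cohort mean stays at the configured mean;
* 1% missing calls; a mandatory seed (all output is a pure function of the
  configuration).

Genotypes are gene-dropped: founder haplotypes are Bernoulli draws from the
breed frequencies, and each gamete follows a per-chromosome switch process
with Haldane recombination fractions between adjacent markers. Offspring
dosages are therefore Mendelian-consistent by construction, and realized
relationships vary around their pedigree expectations, as in real data.

Phenotypes are mean + age-class effect + QTL dosage effects (each scaled on
the cohort's realized dosage variance so it contributes exactly its
configured fraction of the implied total variance) + a polygenic value
transmitted down the pedigree (founder draw plus Mendelian sampling) +
Gaussian noise. The per-animal genetic truth is attached as an attribute
for validation.

## Simulator fidelity — what passing tests do and do not show

The polygenic term is simulated along the **pedigree**, not from the
markers. This is intentional: it reproduces the real-data phenomenon that
marker-based estimators cannot see all pedigree-transmitted variance, so
SNP-based and H-based heritabilities legitimately disagree. Measured on the
bundled generator, an H-based fit of a trait whose 0.4 heritability is
entirely pedigree-polygenic recovers only ≈ 0.27–0.31 — an attenuation gap
of the same character (and direction) as the 0.50 vs 0.31 contrast such
studies report. Consequently the parameter-recovery experiment in the
acceptance suite simulates its 0.4-heritability trait from 40 small marker
QTLs, the regime in which an unbiased estimator must recover the truth;
recovery within ±0.07 then tests the estimator rather than the
generator/model mismatch. Conversely, nothing in the simulator emulates
genotyping error, intensity artifacts, selection over generations,
assortative mating, or real linkage-disequilibrium decay (founder LD is
zero; LD arises only from co-transmission), so passing tests say nothing
about robustness to those features.

# Numerical choices

* **Cholesky jitter.** If chol(**H**) fails, 1e-8 is added to the diagonal
  once (messaged and recorded in `meta`); failure after that is an error
  reporting the minimum eigenvalue. Silent large regularization would
  distort PEVs.
* **Degenerate inputs.** Monomorphic markers are an error in
  `genomicRelationship()` (QC should have removed them), return p = 1 in
  `hweTest()`, are skipped-with-flag in `mlmaLoco()`, and yield NA with a
  warning in `ldR2()`.
* **Tie-breaks.** Duplicate markers keep the lexicographically first
  snp_id. Topological sorting of pedigrees breaks ties by birth date, then
  input order, making record order reproducible.
* **PED allele coding.** `.map` files carry no allele columns, so alleles
  are assigned A/B in lexicographic order on read; round trips are exact
  for maps written by this package (which orders alleles that way).
* **REML search.** The variance-ratio search runs on log-scale in
  [−12, 12]; endpoints set a boundary flag (e.g. identity kinship, where
  the split is unidentifiable but the GLS weights — and hence tests — are
  unaffected).
* **Identifiability.** Age-class 1 is the reference level; classes absent
  from the data lose their column with a warning.
* **Unknown parents** are base-population animals (no genetic groups, no
  metafounders).

# Problem sizes used by the test and acceptance suites

Chosen so the whole suite runs on one desktop core in a few minutes:
matrix identities on 50 random pedigrees of 30–400 animals; the
gene-dropping oracle at 100,000 drops on a 200-animal pedigree (≥ 99% of
sampled entries within 3 Monte-Carlo SEs — with ~350 entries checked, a
few 3-SE excursions are expected by chance); sampler/MME agreement to
0.02 cm on a ~300-animal pedigree at 400,000 sweeps; heritability recovery
at n ≈ 2,000 genotyped-and-phenotyped animals over 10 replicates; the
LOCO power/conditional experiment at n = 1,200 with 31 × 200 markers over
10 replicates (QTL power is saturated well below this n, so the size
tests the machinery, not the edge of detectability); variance-partitioning
recovery at n = 800 over 10 replicates; reliability structure over 20
replicates at n = 350. The quarter-scale acceptance script (~530 mares,
~3.5k pedigree, 6,200 SNPs) completes in about half a minute.

# Known limitations

* Dense matrix algebra throughout: pedigrees beyond ~10–15k animals need
  the sparse/approximate machinery (APY, iterative solvers) that this
  package deliberately omits.
* Single trait, single record per animal, additive effects only.
* The Gibbs sampler reports posterior moments, not full chains; effective
  sample sizes are implicit in the near-independent rotated updates.
* `partitionVariance()` is HE-based; its jackknife SEs are approximate for
  strongly related cohorts.
* VCF input, sex chromosomes, and genotype intensities are out of scope.
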
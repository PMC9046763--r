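---
title: "Genomic prediction and GWAS for growth traits: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction and GWAS for growth traits: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquaGS)
```

# Scope

aquaGS implements the full desk-side workflow of a genomic-selection study
in an aquaculture breeding population: genotype quality control, the
VanRaden genomic relationship matrix, six whole-genome regression models
(GBLUP and five Bayesian alphabet samplers), heritability estimation,
mixed-model GWAS with candidate-gene windows, repeated fivefold
cross-validated predictability, and marker-density reduction experiments.
A synthetic-population generator stands in for the genotyped cohort so that
every stage is testable without any external download.

The emulated study population is a rock bream (*Oplegnathus fasciatus*)
breeding cohort: 455 fish genotyped at 16,162 quality-controlled SNPs on
24 pseudo-chromosomes, with three correlated growth traits — body weight
(BW, g), total length (TL, cm) and body depth (BD, cm).

# The mixed model and heritability

All six models are parameterisations of

$$y = Xb + Zu + e, \qquad u \sim N(0,\, G\sigma_g^2), \qquad
  e \sim N(0,\, I\sigma_e^2),$$

with narrow-sense heritability

$$h^2 = \frac{\sigma_g^2}{\sigma_g^2 + \sigma_e^2}.$$

The only fixed effect by default is an intercept; the study design names no
other covariates. `heritability()` applies the identity directly, and every
`ModelFit` object enforces `h2 == Vg/(Vg + Ve)` in its validity method.

## The genomic relationship matrix

`vanRadenGRM()` uses VanRaden's first method with allele frequencies
estimated from the panel itself:

$$G = \frac{ZZ'}{2\sum_j p_j(1-p_j)}, \qquad
  Z_{ij} = x_{ij} - 2p_j .$$

There are no base-population frequencies to use instead (the population has
no usable pedigree), so current-data frequencies are the only defensible
choice. Real-valued mean-imputed dosages are accepted; monomorphic SNPs are
rejected with a pointer to the MAF filter because they contribute nothing
to the denominator and cannot be centered.

## GBLUP by REML

`fitGBLUP()` reduces REML to a one-dimensional search over the variance
ratio $\kappa = \sigma_g^2/\sigma_e^2$ using the eigendecomposition of $G$:
in the rotated basis the covariance is diagonal, so each evaluation of the
profiled restricted likelihood is $O(n)$ after an $O(n^3)$ setup. The
search runs on the log scale over $[10^{-6}, 10^6]$ with convergence
tolerance $10^{-8}$; hitting either end sets a `boundary` flag on the fit.
A test verifies the optimum against a brute-force grid search (spacing
$10^{-3}$) of an independently coded dense restricted likelihood.

Prediction for unphenotyped individuals uses the conditional mean under the
joint Gaussian model: with training/test blocks of a joint $G$,
$\hat u_2 = \sigma_g^2 G_{21} V_{11}^{-1}(y_1 - X_1\hat b)$. The fit caches
$V_{11}^{-1}(y_1 - X_1\hat b)$, so prediction is a matrix-vector product.

## The Bayesian alphabet

`fitBayes()` fits the marker-effect model $y = Xb + Z\alpha + e$ (dosages
centered by twice the training allele frequency) by single-site Gibbs
sampling, implemented in C++ with residual updates so each marker sweep is
$O(nm)$. The five priors:

| model   | prior on $\alpha_j$                                        |
|---------|-------------------------------------------------------------|
| BayesRR | $N(0, \sigma_\alpha^2)$, one common variance                 |
| BayesA  | $N(0, \sigma_j^2)$, per-marker scaled-inv-$\chi^2$ variances |
| BayesB  | spike at 0 w.p. $\pi$; slab $N(0, \sigma_j^2)$ per marker    |
| BayesC  | spike at 0 w.p. $\pi$; slab $N(0, \sigma_c^2)$ common        |
| BayesL  | normal–exponential mixture (double-exponential marginal)     |

$\pi = 0.95$ is fixed by default (an option samples it with a uniform
prior). The Bayesian LASSO follows the standard hierarchy
$\alpha_j \mid \tau_j^2 \sim N(0, \tau_j^2\sigma_e^2)$,
$\tau_j^2 \sim \mathrm{Exp}(\lambda^2/2)$, with
$\lambda^2 \sim \mathrm{Gamma}(1.1, r)$ sampled by its conjugate update.

**Prior scales.** The study reports no hyperparameters, so the package
derives them from the data the way whole-genome regression software
commonly does: scaled-inverse-$\chi^2$ priors with 5 degrees of freedom
whose mode splits the phenotypic variance in half — residual prior mode at
$0.5\,\mathrm{var}(y)$, marker-variance prior mode at
$0.5\,\mathrm{var}(y) / \sum_j 2p_j(1-p_j)$ (divided by $1-\pi$ for the
spike models, since only that fraction of markers is expected in the slab).
The BayesL rate hyperparameter is set so the gamma prior mode implies the
same marker-variance share. All of this is configurable via
`gibbsSettings()`.

**Reported variance components.** For the Bayesian fits, $V_g$ is the
posterior mean of $\mathrm{var}(Z\alpha)$ across saved draws — the genomic
variance of the fitted marker effects — which is directly comparable to
GBLUP's $\sigma_g^2$ and robust to linkage disequilibrium among markers.
One consequence worth knowing: this quantity includes within-draw posterior
noise, so priors with heavy tails and no selection (BayesA) can report a
larger $V_g$ than GBLUP's REML estimate when $m \gg n$. Predictive
breeding values, which average over draws, are unaffected; the six models'
cross-validated predictabilities agree to within a few hundredths on
polygenic traits.

**Chain lengths.** Two presets: `"full"` (50,000 iterations, 5,000
burn-in, thinning 5) matches the production analysis; `"desk"`
(6,000/1,000/5) is the test preset. On the bundled fixtures the
posterior-mean $h^2$ moves by less than 0.02 when a desk chain is doubled,
which is the package's working definition of "long enough" for its test
problems. Chains draw all randomness from R's RNG, so `set.seed()`-style
reproducibility holds end to end.

# Quality control

The fixed pipeline order is: individual call rate → SNP call rate and MAF
→ mean imputation → optional tag-SNP pruning. Thresholds are keep-if-at
(`>=`) everywhere: "MAF < 5%" is read as the *exclusion* criterion, so a
SNP at exactly 0.05 survives, matching common PLINK usage.

Two deliberate substitutions of external tools, chosen because neither step
is the scientific contribution and both replacements are fully specified
and testable:

* haplotype-based imputation is replaced by per-SNP **mean-dosage
  imputation**, which preserves allele frequencies exactly and feeds
  real-valued dosages downstream;
* haplotype-tagging software is replaced by **windowed greedy $r^2$
  pruning** (drop a SNP whose squared correlation with any retained SNP in
  the trailing 50-SNP window exceeds 0.8). The original tagger's threshold
  is not reported anywhere, so the default here is a documented substitute,
  not a reconstruction.

# GWAS

`lmmGwas()` fits the univariate mixed model with the GRM absorbing
structure and relatedness. The null-model variance ratio is estimated once
by REML and reused for every SNP — the standard EMMAX-style approximation —
with the residual variance re-estimated per SNP by generalized least
squares (df $= n - p - 1$). That last choice makes the scan collapse
*exactly* to single-marker OLS when $G = I$, which is the package's oracle
test. An `exact = TRUE` mode re-optimizes the ratio per SNP; on designs of
this size the two are indistinguishable and the approximation is orders of
magnitude faster. Significance uses the Wald statistic $(\beta/\mathrm{se})^2$
against $\chi^2(1)$.

Thresholds follow the study's conventions: Bonferroni $\alpha/m$ for
genome-wide significance and a fixed suggestive line at
$-\log_{10}(p) > 4$ (growth is polygenic; nothing is expected to clear
Bonferroni). The genomic-control factor is
$\lambda_{GC} = \mathrm{median}(\chi^2)/\chi^2_{0.5,1}$ with
$\chi^2_{0.5,1} = 0.4549$. Candidate windows are $\pm 100$ kb around each
hit, clipped at chromosome bounds, reporting any annotated gene overlapping
by at least 1 bp (GFF3 via `rtracklayer`, overlaps via `GenomicRanges`).
Genotype PCA (`genotypePCA()`, first three components by default) is
reported descriptively, as in the emulated study; adding PCs as covariates
is supported but off by default since the GRM already models structure.

The per-SNP variance explained uses the standard single-marker estimator
$\mathrm{PVE} = 2p(1-p)\beta^2/\mathrm{var}(y)$, clipped to $[0,1]$; the
study does not state its estimator, so this is a documented choice.

# Cross-validation and the density experiment

`makeFolds()` builds repeated fivefold partitions (455 individuals → five
folds of 91, training sets of 364; 40 repeats by default), seeding repeat
$r$ as `baseSeed + r - 1`. One plan is shared by all models so every model
sees identical splits. Predictability is the Pearson correlation between
predicted breeding values and observed phenotypes in the held-out fold —
the study's definition, not the $h^2$-rescaled accuracy (an optional column
provides the latter).

**No test-phenotype leakage.** Fits inside `runCV()` receive only the
training phenotypes; relationship matrices and allele frequencies may use
all genotypes (genotypes of selection candidates are available in practice;
their phenotypes are not). A test corrupts held-out phenotypes and verifies
the predictions do not move.

`densityExperiment()` evaluates GBLUP (the study's choice for this
experiment) on nested SNP subsets under three cumulative strategies:
GWAS-ranked (ascending p, ties by genome order), random (seeded, nested
across sizes) and evenly spaced (`floor(j(m-1)/(size-1))` over the
genome-ordered panel, deduplicated and padded from the nearest unused
indices — the floor form reproduces the documented worked example
{0, 2, 4, 6, 9} for m = 10, size = 5). The default reporting grid is the
14-point design 50…13,000 plus the full panel, scaled proportionally for
smaller panels.

**The predictability plateau needs marker redundancy.** On a
linkage-equilibrium panel, discarding three quarters of the markers
discards genetic variance, and no selection strategy can plateau early.
The plateau observed on real reduced-representation panels is a redundancy
phenomenon: the emulated cohort's ~16 K SNPs are informative at roughly
1 K, a 16:1 ratio. The package's density-plateau experiment therefore runs
on a synthetic panel generated with the LD mode at copying probability
$\rho = 0.94$, which reproduces that redundancy
($1 + 2\rho^2/(1-\rho^2) \approx 16$ effective markers per block), and
pools three replicate populations for stability. On
linkage-equilibrium panels the experiment still runs — it simply, and
correctly, shows no plateau.

Whether the original analysis recomputed its GWAS ranking inside each
training fold is not stated. Ranking on the full data leaks test-phenotype
information into marker selection, so the default here recomputes the scan
within each training set; `rankOnFullData = TRUE` reproduces the global
single-ranking reading. The leakage-safe default is the conservative
choice and is what the package's own experiments use.

# The synthetic population

`simConfig()` defaults encode the emulated cohort: 455 individuals,
16,162 SNPs on 24 chromosomes of 30 Mb (a realistic span for a ~0.75 Gb
teleost genome split over 24 chromosomes), allele frequencies uniform on
$[0.05, 0.5]$, and three traits with means 130.71 g / 18.12 cm / 7.07 cm,
SDs 32.88 / 1.41 / 0.59, heritabilities 0.38 / 0.33 / 0.24, genetic
correlations 0.88 / 0.79 / 0.76 and phenotypic correlations
0.88 / 0.85 / 0.81.

Genotypes are Hardy–Weinberg binomial draws; QTL (a quarter of the SNPs by
default, matching the polygenic reading of the trait architecture) receive
effects drawn multivariate-normal across traits with the genetic
correlation. Genetic values are then rescaled so the realized
$\mathrm{var}(g)$ equals $h^2 \sigma_P^2$ *exactly* — a stricter version of
the "equal in expectation" contract that makes the $h^2 = 0$ and $h^2 = 1$
boundaries exact and concentrates parameter-recovery tests on the
estimator rather than the generator. Environmental deviations are
multivariate normal with covariance solved from the phenotypic target
(checked for positive semidefiniteness; an infeasible target names the
offending trait pair). The full environmental correlation structure of the
real cohort is unpublished, so it is exposed as a parameter rather than
asserted.

What the generator deliberately does not emulate: linkage disequilibrium is
off by default (the analysis never models LD; an optional haplotype-copying
mode with per-SNP copying probability `ldRho` produces geometrically
decaying LD for pruning tests), there is no dominance, epistasis, family
structure or genotyping-error process, and missingness is uniform rather
than platform-patterned. Passing tests therefore demonstrate correctness of
the estimators under the stated generative model, not robustness to every
artefact of real ddRAD data.

# Numerical choices and degenerate inputs

* REML search bounds $[10^{-6}, 10^6]$ on the ratio, log-scale Brent, tol
  $10^{-8}$; boundary solutions flagged, not hidden.
* Eigenvalues of $G$ clipped at 0 (tolerance $-10^{-8}$ for PSD checks).
* SNPs with zero dosage variance: kept by pruning (undefined $r^2$),
  centered-only in PCA, and reported with $p = 1$ and `NA` effect in the
  scan.
* Zero-variance phenotypes, all-missing SNPs, empty QC survivors,
  mismatched SNP sets at prediction: immediate errors naming the offender.
* Ties at QC thresholds resolve by keeping; ties in GWAS ranking resolve
  by genome order (stable sort).
* Predictability of a zero-variance prediction vector is an error,
  recorded as a missing cell and counted in `CvReport@nFailed`.

# Problem sizes used by the tests

Test and acceptance-script problem sizes are the package's own desk-scale
choices: heritability recovery at $n = 455$, $m = 2{,}000$, 20 replicate
seeds; ridge–GBLUP equivalence at $n = 400$, $m = 1{,}000$ with desk
chains; GWAS calibration at $n = 455$, $m = 5{,}000$ fully polygenic;
the density experiment at $m = 4{,}000$ over three replicate populations
with 5 folds × 4 repeats; and the six-model comparison at $m = 500$ with
5 folds × 4 repeats of desk chains. Production-scale
defaults (full panel, full chains, 40 CV repeats) remain the package
defaults and run unchanged, just longer.

# Known limitations

* Single-trait models only; the correlated traits are simulated jointly
  but fitted one at a time, as in the emulated study.
* No dominance or epistasis; no single-step (pedigree + genomic) variants.
* The EMMAX-style scan slightly misstates the variance ratio for SNPs of
  very large effect; the `exact` mode exists for that regime.
* Mean imputation underestimates genotype uncertainty relative to
  haplotype-based imputation; with the <10% missingness the QC admits,
  the effect on $G$ is negligible.
* BayesA/B per-marker variances use an informative prior (df 5); very
  sparse architectures with tiny $n$ may be prior-dominated.
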
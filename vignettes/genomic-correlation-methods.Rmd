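---
title: "Methods: across-breed genomic correlation, SNP selection and GBLUP validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: across-breed genomic correlation, SNP selection and GBLUP validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Genomic selection needs a large reference population. When a single breed is
too small, one can merge two populations -- but the merged reference only
helps if the marker-captured genetic effects for the trait are correlated
across the populations, i.e. if the same SNP allele tends to associate with
the trait in the same direction in both (consistent linkage-disequilibrium
phase). `gencor` implements the full analysis cycle for studying and
exploiting that *genomic correlation* in a two-breed design with a
cow-calibration / bull-validation split:

1. pedigree (`A`) and across-breed genomic (`G`) relationship matrices;
2. a bi-variate animal model treating the same phenotype as a different
   trait in each breed, with *two* additive components per trait: one with
   covariance structured by `A` and one by `G`;
3. within-breed single-SNP association scans with a polygenic background;
4. sign-based SNP selection into a "list-of-same" and "list-of-different",
   and the corresponding relationship matrices `G_S` and `G_D`;
5. GBLUP prediction on the merged data with masked validation phenotypes,
   scored by accuracy and dispersion bias.

## Models

### Relationship matrices

`build_nrm()` computes the numerator relationship matrix by the tabular
method, `a_ij = (a_{j,sire(i)} + a_{j,dam(i)})/2`, diagonal
`1 + a_{sire,dam}/2`, with ancestors beyond a truncation depth (default
three generations) treated as unknown founders. Two breeds without common
ancestors produce an exactly zero between-breed block.

`build_grm()` is the marker-based (VanRaden) matrix with an identity blend
for invertibility:

$$G = b\,\frac{SS^\top}{2\sum_i p_i(1-p_i)} + (1-b)\,I, \qquad b = 0.95,$$

where `S` holds genotype codes (count of the second allele) column-centred
by `2p_i`, and `p_i` is by default computed on the *combined* two-breed set.
Across-breed centring is what leaves informative structure in the
between-breed block: pedigree-unrelated animals still share alleles, and
their genomic relationships have non-zero spread. Missing codes are
mean-imputed (centred contribution zero); SNPs monomorphic at the supplied
frequencies are dropped with a message, since they contribute nothing and
have `p(1-p) = 0`. The smallest eigenvalue of the blended matrix is at least
`1 - b` because the unblended part is positive semidefinite.

### The bi-variate pedigree + genomic model

For cow records `y_1, y_2` of the two breeds,

$$y_b = X_b\beta_b + Z_b a_b + M_b u_b + e_b,$$

with `var(a) = diag(sigma^2_{a1}, sigma^2_{a2}) %x% A` (the cross-breed
pedigree covariance is *structurally zero* -- the breeds share no ancestors
-- so it is fixed, not estimated), and

$$\operatorname{var}\!\begin{pmatrix}u_1\\u_2\end{pmatrix} =
\begin{pmatrix}\sigma^2_{u1} & \sigma_{u12}\\
\sigma_{u12} & \sigma^2_{u2}\end{pmatrix}\otimes G ,$$

plus a diagonal residual per trait. The estimable cross-breed genomic
covariance yields the genomic correlation
`r_G = sigma_u12 / sqrt(sigma^2_u1 sigma^2_u2)`, and the fraction of
genetic variance missed by the SNPs is
`C_miss = 1 - sigma^2_u / (sigma^2_u + sigma^2_a)`, equivalently
`h2_P / (h2_P + h2_G)` on the proportion scale -- an identity the test suite
enforces against published worked examples.

### REML engine

`reml_fit()` maximises the restricted likelihood by average information
(AI) with safeguards:

* every parameter enters the record covariance linearly,
  `V(theta) = sum_j theta_j V_j`, so gradients use
  `tr(PV_j)` computed from one explicit inverse per iteration;
* an active-set rule drops parameters pinned at the variance floor
  (`1e-6` of the per-trait phenotypic variance) from the AI step;
* steps that would decrease the restricted log-likelihood are halved up to
  twelve times and then replaced by an EM-style update; consequently the
  log-likelihood trace is non-decreasing, which the tests assert on every
  fit;
* unstructured 2x2 trait blocks are kept positive semidefinite by clipping
  the covariance at `0.999` of its bound, so `r_G` always lies in
  `[-1, 1]`. Whether the original variance-component software constrained
  correlations this way is not documented anywhere we could check; the
  clipping rule is our choice and is visible in boundary fits as estimates
  of `|r_G|` near one.
* convergence: relative log-likelihood change below `1e-8` together with
  either a small parameter change (`1e-6` of the phenotypic variance) or
  three consecutive flat iterations (the latter matters when a boundary
  constraint is active); cap 200 iterations, non-convergence flagged, never
  silent.

Standard errors come from the inverse AI matrix at convergence and are
approximate. Univariate fits are validated against an independent oracle
that profiles the exact restricted likelihood on a 0.01 grid of
heritability in the eigenbasis of the relationship matrix.

`solve_mme()` returns BLUE/BLUP solutions equivalent to Henderson's
mixed-model equations, computed as `Cov(u, y) P y` so that animals without
records are predicted through their relationships; the fixed-effect
identifiability constraint is first-level-zero (treatment contrasts).

### GWAS

`gwas_scan()` fits the null animal model (fixed effects + pedigree
polygenic + residual) once per scan, then tests every SNP by generalised
least squares on spectrally decorrelated data -- the standard two-stage
approximation. Wald statistics are referred to a t distribution with
`n - rank(X) - 1` degrees of freedom; the per-SNP residual variance is
re-estimated from the decorrelated residuals, which keeps the permutation
type-I error at the nominal 5 % within +/- 1 % in the test suite. An exact
mode re-estimates variance components per SNP; the two modes agree in
effect sign for >= 99 % of SNPs on simulated data. No multiple-testing
correction is applied because downstream selection uses only the ranking.
With the polygenic variance fixed at zero the scan reduces exactly to
ordinary least squares, which the tests exploit as an oracle.

### SNP selection

`select_snps()` ranks the SNPs whose effect-estimate signs agree (or
disagree) between the two breeds and takes the top 10 % *of the panel* per
trait -- the quota is on the panel, not on the qualifying subset, matching
the published count of 7,173 out of 71,726. The joint ranking the original
analysis used is not specified beyond "most significant in both breeds";
our default is the sum of `-log10 p` over the two breeds, with min-p,
max-p and Fisher combinations available, and deterministic tie-breaking by
summed |statistic| then marker id. Exact zero effects carry no sign and are
excluded from both directions. `merge_snp_lists()` unions the per-trait
sets within each direction and removes any marker present in both unions;
`build_variant_grms()` then materialises `G_S` and `G_D` with the same
across-breed frequencies.

### Prediction and validation

`gblup_predict()` merges breeds and sexes, masks every phenotype outside
the calibration cell (e.g. BB cows), re-estimates the genomic and residual
variance on the unmasked records with a single `G`-structured random term
(no pedigree term, following the prediction-model specification), and
predicts GEBV for all animals. Re-estimating per masked dataset is the
default; components can be frozen for speed. Masked records never enter
the likelihood, so leakage is structurally impossible (and is still
asserted by a perturbation test).

Validation phenotypes are adjusted by the within-breed fixed-effect
solutions of per-breed two-sex pedigree models (`within_breed_fits()` --
see the design note below). Accuracy is the product-moment correlation
between GEBV and adjusted phenotype; bias is the slope of the regression
of adjusted phenotype *on* GEBV (slope 1 = dispersion-unbiased; this
direction, not the inverse, is the reported convention).
`run_validation_grid()` crosses traits, six calibration/validation schemes
(both directions of cow-to-cow across breeds, cow-to-bull within breed,
cow-to-bull across breeds) and the GRM variants, and `report_averages()`
reproduces the per-column "Average" rows.

## The simulator

`simulate_population()` generates the study structure the estimators
assume, with known truth for recovery tests:

* **Pedigree** -- per breed: founder sires and dams, calibration cows as
  their daughters, validation bulls as sons of calibration cows (sired by
  founder sires other than the cow's own sire, under a configurable litter
  limit). The breeds share no ancestors.
* **Genotypes** -- Balding-Nichols founder frequencies around a shared
  ancestral frequency with divergence `fst_divergence` (default 0.10, a
  realistic between-breed divergence for cattle breed groups), founder
  Hardy-Weinberg draws, then Mendelian gene drop at unlinked loci.
* **Trait** -- QTL effects for (breed x sex) drawn from a multivariate
  normal with cross-breed correlation `rho_qtl` and between-sex correlation
  `rg_sexes` (default 0.9, emulating the observed deviation of
  between-sex genetic correlations from one); marker breeding values are
  centred and scaled within breed so the marked component explains
  `h2_marked` of the phenotypic variance; a pedigree-sampled polygenic
  deviate (founders standard normal, offspring mid-parent plus Mendelian
  sampling) contributes `h2_polygenic` -- this is the component a genomic
  matrix cannot see, i.e. the built-in missing heritability; contemporary
  group, age-of-dam, breed-composition and age fixed effects; independent
  Gaussian residual making the variances sum to one.

What the generator does *not* emulate -- linkage disequilibrium with decay,
recombination maps, genotyping and imputation error, selection -- limits
what passing tests can show: they validate the estimators under the model's
own assumptions (unlinked loci, QTL inside the panel), not the behaviour of
real LD-structured data. In particular, LD-phase consistency is emulated
directly through `rho_qtl` rather than through haplotypes.

## Problem sizes and study conditions

Defaults are desk-scale versions of the motivating design: 40 sires + 400
dams, 800 calibration cows and 800 validation bulls per breed, 5,000 SNPs,
500 QTL, `h2_marked = 0.4`, `h2_polygenic = 0.2` (so true
`C_miss = 1/3`), `rho_qtl = 0.8`. Bi-variate REML on the 1,600 cow records
takes seconds per fit on one CPU.

The replicated suites fix their conditions once:

* *genomic-correlation recovery*: default scale (800 cows/breed, 5,000
  SNPs) at `rho_qtl` 0 and 0.8, twenty replicates in the tests;
* *selection/prediction phenomena*: 300 cows + 240 bulls per breed, 3,000
  SNPs, 300 QTL, `h2_marked = 0.5`, twenty replicates -- large enough for
  stable orderings, small enough that the whole pipeline replays in
  seconds per replicate;
* the acceptance script runs eight replicates per suite, a size chosen so
  the whole script recomputes everything in a few minutes.

The within-breed equivalence of the whole-panel and list-of-same matrices
is scale-sensitive: with a single simulated trait the list holds 10 % of
the panel (300 SNPs here), against 23 % of 71,726 in the motivating study,
so small within-breed accuracy differences are expected and the suite
checks the mean difference across replicates, not per-replicate equality.

## Design notes and open choices

* **Within-breed 10-variate analyses.** The original within-breed analysis
  fitted all five traits in both sexes jointly. With a single simulated
  trait we reproduce the *structure* as per-trait two-sex bi-variate
  pedigree models: same two-response engine, same BLUE usage, without
  55-parameter covariance estimation. This is a documented deviation.
* **Missing genotypes in `G`.** The motivating data were pre-imputed; ours
  may contain missingness. Mean imputation keeps the denominator
  definition intact and is the neutral standard choice.
* **Frequencies.** Across-breed combined frequencies are the default
  everywhere, as specified for the study design; within-subset frequencies
  are available by passing `freqs`.
* **Quota before or after the sign filter.** The published per-trait count
  (10 % of the panel) indicates the quota is taken on the panel; we follow
  that, filling it from sign-qualifying SNPs and warning when fewer
  qualify.
* **Prediction REML records.** Only the calibration cell's records enter
  each prediction fit; this is exactly the masking described for the
  validation design, applied uniformly.
* **Boundary estimates.** With weakly informative cross-breed blocks the
  REML optimum for `sigma_u12` can sit at the positive-semidefiniteness
  boundary, reported as `|r_G|` near 1. These are genuine boundary
  maximisers, flagged by their `at_floor`/bound values rather than hidden.
* **Precision of `r_G`.** All information about the cross-breed covariance
  comes from the between-breed block of `G`, whose entries under unlinked
  loci are small (frequency-divergence structure plus `O(1/sqrt(m))`
  marker noise). At the default scale the replicated suites show the
  estimator is unbiased (replicate means within a few hundredths of the
  generating value) with a per-replicate standard error around 0.2-0.3,
  matching the average-information standard errors. Single fits should be
  read with that uncertainty in mind; real LD-structured panels carry more
  cross-population information than the unlinked-locus simulator.

## Known limitations

Dense matrices only (intended for up to a few thousand animals);
unstructured trait blocks limited to two traits (the published comparison
needs exactly two); no Bayesian whole-genome regression, single-step
H-matrix, dominance or epistasis; no LD-aware simulation. Sparse
inverse-NRM construction (Henderson's rules) is out of scope because every
model here uses the dense matrix directly.
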
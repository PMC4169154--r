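---
title: "Methods: haplotype reconstruction and QTL mapping in multiparent outbred populations"
author: "mosaicqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype reconstruction and QTL mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`mosaicqtl` implements the analytical pipeline for genetic mapping in
Diversity Outbred (DO) mice and similar multiparent outbred stocks: a
36-state hidden Markov model that reconstructs founder diplotypes from
genotyping-array data, founder allelic dosages and genome-wide SNP
imputation, kinship from expected allele sharing, kinship-corrected genome
scans under three regression models, permutation and Bonferroni genome-wide
thresholds, Bayesian credible support intervals, and power / type-I-error
simulation studies. A breeding simulator generates synthetic DO genomes,
array observations and phenotypes, so the whole pipeline runs and is tested
without any external data.

# The model

## Diplotype states

With F = 8 founders (coded A-H) the unordered pair of founder haplotypes at
a locus -- the *diplotype* -- takes F(F+1)/2 = 36 states: 8 homozygous and 28
heterozygous. Parent-of-origin is ignored (no 64-state model). The package
fixes a deterministic state order (homozygotes in founder order, then
heterozygotes lexicographically); every probability and dosage array uses
it, making all outputs reproducible and serializable. N_h(s), the number of
alleles founder h contributes to state s, is the bridge from state
probabilities to allelic dosages:
d_ij(h) = sum_s p_ij(s) N_h(s), so sum_h d_ij(h) = 2 exactly.

## Hidden Markov model

The transition model treats the two haplotypes of an individual as
independent Markov chains on the founders. Over genetic distance d (Morgans)
a haplotype switches ancestry with probability 1 - exp(-lambda d) and then
lands uniformly on the F founders; the diplotype transition matrix is the
convolution of the two chains collapsed to unordered pairs. The switch
intensity grows linearly with outbreeding generation G:

    lambda(G) = events_per_gen * G / (2 * L * (1 - 1/F))

calibrated so the expected number of *observable* ancestry junctions per
diploid autosomal genome (length L Morgans; L = 14.35 for the mouse) equals
`events_per_gen * G`. The constant defaults to 23.9 junctions per
generation, the theoretical DO accumulation rate; it is exposed as a
parameter because it depends on the pre-outbreeding (pre-CC) history of the
founders, which the package does not model explicitly. The rate is intrinsic
per Morgan: it is computed against the whole-genome length, never against
the span of the genotyped map, so analyzing one chromosome does not inflate
the switch rate. Transition parameters are *never* re-estimated inside EM --
when they are, reconstructions transition implausibly often.

Two emission models are provided:

* **Genotype-call model.** Per marker and state, a multinomial over
  {A, H, B, N}. Initialization gives the genotype expected from the founder
  sequences probability 0.97, spreading 0.01 over each other outcome. A
  no-call N is a *separate, informative outcome*, never missing data: its
  rate can depend strongly on the underlying state (e.g. a CAST-homozygote
  probe dropping out 90% of the time while B6 homozygotes drop out 1%).
  Truly missing observations (NA) contribute emission log-likelihood 0.
* **Intensity model.** The two-channel (X, Y) intensities are mapped to
  polar coordinates theta = (2/pi) atan2(Y, X) in [0,1] and
  rho = sqrt(X^2 + Y^2) (the paper-style transform is fixed this way for
  reproducibility; any monotone variant would do). Each state at each marker
  emits the product of two univariate normals in (theta, rho) -- four
  parameters per state per marker. rho is fitted raw, without per-marker
  standardization. Initialization pools founder/F1 reference samples with
  the cohort, fits a diagonal bivariate Gaussian mixture per marker with the
  cluster count chosen by BIC over 1..9, and assigns each of the 36 states
  to the cluster nearest its reference samples (states lacking reference
  samples are placed at the midpoint of their founders' homozygote locations
  and flagged). Many states legitimately share a cluster center at
  "conforming" markers; EM separates them afterwards only insofar as the
  data support it, and residual ambiguity remains in identical-by-state
  regions -- the transition model (linkage context) is what resolves most of
  it.

EM alternates a forward-backward E-step per sample and chromosome (scaled,
with a numerical-floor fallback for all-zero emission rows) with an M-step
per marker that pools posterior weights across samples (soft assignments).
Iteration stops when the log-likelihood changes by less than 1/1000 of the
initial log-likelihood, or after 100 iterations. Emission variances are
floored at 1e-4 and multinomial cells at 1e-4 (renormalized) to prevent
cluster collapse. Reconstruction quality rises steeply with cohort size;
below 100 samples the package warns.

The *marginal reconstruction* assigns each locus its maximum-posterior
state, breaking exact ties toward the lowest state index (flagged). Phasing
to two haplotype strands minimizes the total number of strand switches by
dynamic programming; breakpoints are placed at the bp midpoint between
flanking markers. Parsimony phasing can undercount recombination events
(simultaneous double switches collapse), and marker spacing bounds what is
visible at all: event counts increase toward the simulated truth as maps
densify, mirroring the array-density effect on real data.

## Dosages, SNP imputation, kinship

Founder dosages follow from the posterior as above. SNP imputation assigns
each known SNP the unweighted average of its two flanking markers' diplotype
probabilities (nearest marker beyond the ends) and computes the
reference-allele dosage g = sum_h d(h) G(h), where G(h) indicates that
founder h carries the reference allele. (The source text writes the
indicator's argument inconsistently; the per-founder indicator is the only
reading that keeps g in [0, 2].) SNPs in one inter-marker interval with
identical strain distribution patterns (SDPs) share their dosage, so one
regression per SDP group suffices; collapsing provably changes no scan
statistic, only the computation count.

Kinship between samples i and e is the per-marker cosine similarity of
their 8-dimensional dosage vectors averaged over markers, giving a unit
diagonal. The matrix is not forced positive semidefinite; the mixed-model
solver clamps eigenvalues at 1e-6. Leave-one-chromosome-out (LOCO) variants
exclude the scanned chromosome from the kinship to avoid proximal
contamination; `qtl_scan()` accepts either a single matrix or the LOCO
list.

## Genome scans

Three regression models relate phenotype to genotype at a locus, each with
fixed covariates, a polygenic random effect with covariance proportional to
kinship, and iid error:

* **full**: unconstrained regression on the 36 state probabilities (35 df
  after dropping one aliased column -- probabilities sum to 1);
* **additive haplotype**: regression on the 8 founder dosages (7 df --
  dosages sum to 2);
* **additive SNP**: scalar regression on the imputed SNP dosage (1 df).

Variance components are estimated once per phenotype under the null by
maximum likelihood (the ML/REML choice is unstated in the source; ML is
fixed here) via eigendecomposition of the kinship -- the classic two-stage
GLS. They are then held fixed along the genome: at each locus the package
computes the weighted RSS in the rotated basis and reports
LOD = (n/2) log10(RSS0/RSS1), with -log10(p) from the chi-square with the
model's df. This makes scans and permutations cheap (one factorization per
phenotype) at the cost of not re-estimating variance components per locus,
which is standard practice. Exact per-locus REML is out of scope. Aliased
covariates are dropped with a warning; a constant locus predictor scores
LOD 0 rather than erroring. Categorical covariates are one-hot encoded
against a reference level. Founder effect estimates at a locus are centered
to mean zero for display.

## Significance and support intervals

Bonferroni: -log10(alpha/n_tests). Permutations: phenotype rows (with their
covariates, as a unit) are permuted and each permuted set is scanned with a
*plain linear model, without the kinship term*; the threshold is the
empirical (1-alpha) quantile of per-permutation maximum autosomal LOD. This
deliberately ignores the exchangeability violation caused by kinship
structure -- the simulation studies verify that the resulting thresholds
still control genome-wide type I error for the mixed-model scan.
X-chromosome thresholds are out of scope, so maxima are taken over
autosomes.

The 95% Bayesian credible interval transforms the chromosome's LOD curve to
10^LOD, integrates by trapezoids between markers, and expands greedily from
the peak toward the higher-area neighbor until 95% of the area is covered
(endpoints at marker positions). The source does not specify how the region
is chosen; the peak-anchored rule is the default and an HPD-style
alternative is available via `method = "hpd"`. A flat curve returns the
whole chromosome, flagged.

# The synthetic world

The breeding simulator is a stated world, not a tuning knob; its defaults
are the conditions the methods assume.

* **Design**: 175 breeding pairs, random non-sibling mating, equalized
  family contributions; the analysis cohort is the offspring generation G
  (default 8). Meioses are a no-interference Poisson crossover process on
  the cM map (no obligate chiasma, no interference -- the simplest process
  with linear event accumulation).
* **Seeding**: generation-1 haplotypes are random fine founder mosaics
  (Poisson junctions at `events_per_gen/(2L)` per Morgan, uniform founder
  ancestry), approximating descent from pre-CC funnels whose exact pedigrees
  are not reproducible. `g1_density = 0` gives pure-founder F1-style
  seeding instead (then every G1 animal is heterozygous everywhere).
* **Equilibrium**: founder shares average 1/8 and diplotype frequencies
  approach 1/32 (het) and 1/64 (hom). Because the breeding population is
  finite (175 pairs), founder frequencies drift with SD ~0.4-0.5 percentage
  points per founder by G8; per-founder deviations of ~1 point are expected
  and match the range observed in the real population (median contributions
  10.6%-13.2%). Tests that assert a 0.5-point per-founder bound test the
  idealized equilibrium, not this finite population, and are expected to
  fail for the extreme founder; the across-founder mean is exactly 12.5%.
* **Arrays**: genotype calls are drawn from the state's multinomial with
  configurable error (default 0.01), baseline no-call (0.01) and
  state-specific no-call overrides; intensities are drawn from per-state
  polar-coordinate clusters, with a configurable fraction (default 0.15) of
  "nonconforming" markers whose off-target variant splits the three
  canonical clusters into up to ~6, several states sharing each center.
  What the generator does **not** emulate: batch effects, per-sample
  intensity scaling, probe failure patterns correlated along the genome, or
  linked SDP structure among nearby SNPs. A green reconstruction test
  therefore establishes correctness of the inference machinery under the
  model's own assumptions, not robustness to real-array artifacts.
* **Phenotypes**: y = QTL + polygenic + error. The QTL adds +a to one
  homozygote class and -a to the other (0 for heterozygotes) with the minor
  allele assigned to `maf` of the 8 founders; the polygenic term is
  multivariate normal with covariance equal to the kinship of the simulated
  cohort; the error is iid N(0,1). Both background components default to
  unit variance, so the background totals 2.

# Simulation studies and their honest discrepancies

Power cells draw n genomes from a fixed simulated pool of 1129 G8 genomes
(standing in for the real reconstructions the original study sampled), plant
a biallelic QTL at a random founder-SNP with the requested minor-allele
founder count, scan with the kinship-adjusted model, and score detection
when the maximum autosomal LOD exceeds the sample-size-specific threshold
AND lies within 5 Mb of the truth. Thresholds are computed once per sample
size from 300 null scans of iid N(0,1) phenotypes fit without the kinship
term. Scaled-down defaults (500 markers, 200 replicates, 300 null scans)
keep each study in minutes on one CPU; full-scale values are plain
arguments.

Two discrepancies with the printed reference values are expected and
deliberate:

1. **Variance explained.** The n=600 / MAF 2 / effect 0.5 cell explains
   Var_QTL / (Var_QTL + 2) with Var_QTL = 2p(1-p)a^2 = 0.094, i.e. ~4.5% of
   phenotypic variance -- not 9%, which would require a background variance
   of 1. The package simulates the stated unit-variance components and
   reports the empirical share; the printed 0.94 (haplotype) and 0.91 (SNP)
   powers are only consistent with the ~9% figure, so the faithful
   simulation lands well below them (~0.4 and ~0.65). The
   variance-explained-matched cells (20% at n=200, 5% at n=1000) do not
   depend on this ambiguity and meet their >= 90% power targets.
2. **Localization at 500 markers.** With ~5 Mb marker spacing, roughly a
   third of true detections peak at a marker more than 5 Mb from the causal
   position; at the real arrays' density this loss is negligible. This
   further depresses the scaled-down power cells, and conversely *raises*
   full-model "power" relative to the printed near-zero value, because a
   sparser map offers the 35-df model fewer noise loci to out-peak the
   signal.

Type I error of the kinship-adjusted additive haplotype scan at the
permutation-style threshold is the fraction of null-phenotype replicates
with any autosomal LOD above it; it sits near the nominal 0.05 regardless
of the above, which is the property the thresholds exist to guarantee.

# Numerical choices

* Forward-backward uses per-step scaling (log-space scaling constants for
  intensity emissions); posteriors renormalize to 1 within 1e-8.
* Emission floors: variance 1e-4, multinomial 1e-4 renormalized.
* Kinship eigenvalues clamped at 1e-6 in the mixed model (the cosine
  kinship is not guaranteed PSD).
* Argmax ties: lowest state index, flagged.
* Normal-equation locus fits fall back to a 1e-8-scaled ridge when the
  Cholesky fails (aliased or absent states in the full model).
* The polar transform maps (0,0) to theta = 0.5 and flags it.
* All generators take explicit seeds; identical seeds give identical output.

# Known limitations

* Marginal (per-locus) reconstruction only; no globally optimal joint path.
* Transition parameters fixed, not estimated; no interference in meiosis.
* X-chromosome significance and dosage compensation are out of scope;
  scans and maxima use autosomes.
* The cosine kinship saturates at high baseline relatedness when dosages
  are heavily smoothed (posterior uncertainty inflates similarity); LOCO
  mitigates proximal contamination but no IBD-segment kinship is provided.
* Permutation thresholds assume exchangeability that kinship violates; the
  simulations show the resulting conservatism is mild at DO-like
  relatedness, but the guarantee is empirical, not exact.
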
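---
title: "Models and design choices in boagblup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in boagblup}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(boagblup)
```

## The problem

Pig and poultry breeding programs select purebred (PB) sires, but the
animals that matter commercially are crossbreds (CB). When the genetic
correlation between purebred and crossbred performance, $r_{pc}$, is below
one, genomic estimated breeding values (GEBV) computed from PB records are
an imperfect guide to CB performance, and it may pay to build the reference
population from CB records instead — possibly while restricting the genomic
relationships of CB animals to the alleles they inherited from the sire
line (their breed-of-origin, BOA).

`boagblup` implements the full evaluation loop for a three-way terminal
cross $A(B \times C)$: simulation of the cross with configurable $r_{pc}$
and per-allele origin truth, the standard data-cleaning filters, four kinds
of genomic relationship matrix (GRM), GBLUP animal and sire models with
EM-REML variance components, and a replicated cross-validation comparison
of reference/validation scenarios scored by reliability-weighted validation
correlations and dispersion bias.

## Statistical models

### GBLUP animal model

Phenotypes are modelled as

$$\mathbf{y} = \mathbf{Xb} + \mathbf{Lm} + \mathbf{Za} + \mathbf{e},$$

with one fixed-effect level per observed batch $\times$ pen $\times$ sex
$\times$ age class, maternal permanent-environment effects
$\mathbf{m} \sim N(0, \mathbf{I}\sigma^2_m)$, additive genetic effects
$\mathbf{a} \sim N(0, \mathbf{G}\sigma^2_a)$ and residuals
$\mathbf{e} \sim N(0, \mathbf{I}\sigma^2_e)$. Solutions come from
Henderson's mixed-model equations; animals present in $\mathbf{G}$ without
records (selection candidates) receive GEBV through their genomic
covariances with the phenotyped animals.

### Relationship matrices

* **Single-breed** (`single_breed_grm`):
  $\mathbf{G} = \mathbf{MM}'/\sum_j 2p_j(1-p_j)$ with $\mathbf{M}$ the
  genotype matrix centred at $2p_j$.
* **Multi-breed** (`multibreed_grm`): block matrix with group-specific
  frequencies; the PB and CB diagonal blocks each use their own
  denominator, the off-diagonal block the geometric mean of the two. The
  implementation scales each animal's centred row by the square root of
  its group denominator and forms one cross-product, so the matrix is
  symmetric positive semidefinite by construction, and it reduces exactly
  to the single-breed matrix when the two groups share frequencies.
* **Sire-line BOA partial** (`boa_partial_grm`): relationships involving
  CB animals use only the allele inherited from the sire line. The CB rows
  are $T_{ij} = h_{ij} - p_j$, where $h_{ij} \in \{0, 1\}$ indicates
  whether the counted allele sat on the sire-origin gamete, and $p_j$ is
  the sire-line allele frequency pooled over the PB sires (two alleles
  each) and the sire-origin alleles of the CB animals (one each). PB rows
  are centred at $2p_j$ and the whole matrix is scaled by
  $\sum_j 2p_j(1-p_j)$. Because a CB animal contributes one allele where a
  PB animal contributes two, the expected CB diagonal is 0.5.
* **Dam-line partial** (`dam_line_partial_grm`): the mirror image built
  from the dam-origin alleles, used to probe how much predictive value the
  dam alleles carry for sire evaluation.

We construct the BOA matrix directly from the definition of the centred
allele matrix together with the requirement that the whole matrix be a
single cross-product; that requirement pins down the PB block and the
cross-block centring at the sire-line frequencies and guarantees positive
semidefiniteness. A switch chooses whether the sire-line frequency pools
only the PB sires (the default, matching how the frequency is defined
above) or all PB animals.

### Validation statistics

Corrected phenotypes come from a sire model
$\mathbf{y} = \mathbf{Xb} + \mathbf{Lm} + \mathbf{Ts} + \mathbf{e}$ fitted
once per trait on **all** CB records;
$\mathbf{y}_c = \mathbf{y} - \mathbf{X\hat b} - \mathbf{L\hat m}
= \mathbf{T\hat s} + \hat{\mathbf{e}}$. Validation on offspring averages
correlates sire GEBV with the mean $\bar{y}_c$ of each sire's CB
offspring, weighting sires by the reliability of an $n$-offspring mean,
$w = \tfrac{1}{4} n h^2_{CB} / (1 + \tfrac{1}{4}(n-1) h^2_{CB})$, and
multiplies the weighted regression slope by two because an offspring
average represents half the sire's breeding value. Validation on
individual records uses unweighted correlations and slopes. Correlations
from the two record types can be placed on one scale by dividing by
$\sqrt{h^2_{CB}}$ (individual) or by the square root of the mean
reliability (averages).

## EM-REML

Variance components are estimated by expectation-maximization REML.
For the animal model, each record's animal is distinct, so the iterations
run in the eigenbasis of the (record-subsetted, ridge-regularized)
relationship matrix: the additive block of the mixed-model equations is
then diagonal, each iteration absorbs it analytically, and only a matrix
of dimension (fixed + maternal levels) is factorized per iteration. The
EM updates are the standard Henderson forms

$$\hat\sigma^2_a = \frac{\hat{\mathbf a}'\mathbf{G}^{-1}\hat{\mathbf a} +
\sigma^2_e\,\mathrm{tr}(\mathbf{G}^{-1}\mathbf{C}^{aa})}{q_a}, \qquad
\hat\sigma^2_e = \frac{\mathbf{y}'\hat{\mathbf e}}{n - \mathrm{rank}(X)},$$

which cannot decrease the restricted likelihood; the iteration stops when
the log-likelihood changes by less than `tol` (default `1e-8`, maximum 500
iterations). Eigenvalues are floored at `1e-8` and a diagonal ridge
(`regularize()`, default `1e-6`) keeps the system definite; both choices
only matter for rank-deficient marker sets. The sire model (both random
terms with identity covariance) uses a dense variant of the same
iteration. The restricted likelihood reported by `solve_mme()` was checked
against the direct $\log|\mathbf V| + \log|\mathbf X'\mathbf V^{-1}\mathbf
X| + \mathbf y'\mathbf P\mathbf y$ computation in the tests.

## The synthetic-data generator

The generator emulates the data structure of a commercial broiler
evaluation in which one generation of PB and CB offspring of a shared set
of line-A sires was raised in a common environment:

* **Lines.** Three lines with allele frequencies drifted from a shared
  ancestral frequency under a Balding–Nichols model; the per-line
  divergence parameter is a tunable Fst analogue. The qualitative
  requirement is only that the lines be genetically distant; 0.15 per
  line is the default we fixed once as a realistic differentiation for
  long-separated commercial lines (the zero-divergence limit returns
  identical lines).
* **Genome.** Ten 1-Morgan autosomes, markers uniformly placed, crossover
  counts Poisson per chromosome without interference; sex chromosomes are
  never simulated (the data-cleaning rules would remove them). QTL are a
  random subset of markers (optionally hidden from the panel).
* **Population.** 161 sires (135 with both PB and CB offspring, 5
  PB-only, 21 CB-only), 628 PB dams, 1028 F1 dams from lines B $\times$
  C, about 4700 PB and 4500 CB phenotyped offspring. Full-sib family
  sizes are zero-truncated Poisson with means 1.7 (PB) and 1.6 (CB),
  giving the small-family structure typical of multi-sire broiler
  matings.
* **Traits.** Two body weights: BW7 with $(h^2_{PB}, h^2_{CB}, r_{pc}) =
  (0.09, 0.18, 0.80)$ and BW35 with $(0.22, 0.23, 0.96)$. Per-QTL PB and
  CB allele-substitution effects are drawn from a zero-mean bivariate
  normal with correlation $r_{pc}$ and each effect vector is rescaled so
  the realized additive variance in the corresponding offspring group hits
  the target exactly (phenotypic variance 1); scaling by a positive
  scalar leaves the correlation untouched. The same CB effect applies to
  B- and C-origin alleles: the model is purely additive, and line
  differences arise only through allele frequencies.
* **Phenotypes.** Record = trait mean + class effect (batch $\times$ pen
  $\times$ sex $\times$ age, one normal effect per level, sd 0.5) +
  own-trait breeding value + dam permanent-environment effect (variance
  0.10, a value we fixed once as typical for early body weight in
  broilers) + residual completing the phenotypic variance to 1. Pens are filled so most pens hold
  predominantly one genetic group and a sire's offspring concentrate in
  one pen; ages get $\pm1$ day jitter; 4% of BW35 records are dropped to
  emulate mortality between the two weighings.

What the generator does **not** emulate: linkage-disequilibrium structure
beyond what gene drop from drifted founder frequencies produces, selection
history, genotype-by-environment interaction, non-additive gene action,
and genotyping or phasing error (origin labels are exact truth). Passing
tests therefore demonstrate internal consistency of the estimation
machinery under the stated generative model, not robustness to the many
ways real data violate it.

## Experimental design

Each replicate draws a family-matched CB subset — for every full-sib
family size, as many CB families as there are PB families of that size
(all of them when fewer exist) — and a fresh random partition of the
sires into five near-even cross-validation groups (32/32/32/32/33 at the
default 161 sires). All offspring follow their sire's group, so no
validation sire has offspring, and no validation animal has a paternal
half-sib, in the reference set; this is asserted at run time. The same
subset and partition serve all scenarios and traits of a replicate, making
scenario contrasts paired. Replicate $r$ derives its random stream from
`base_seed` and $r$ through a multiplicative hash, so consecutive base
seeds do not share streams between stages.

Because the published group sizes (32, 32, 32, 32, 33) sum to 161 while
only 156 sires have CB offspring, we partition **all** sires and validate,
per fold, only those fold sires that have CB offspring; the offspring of
sires without CB offspring remain in every PB reference set. This
reproduces the published sizes and the stated always-in-reference rule
simultaneously.

Variance components are estimated once per trait (and reference type) and
reused across replicates and folds — re-estimating per fold is possible
and exposed, but it changes nothing structurally while multiplying the
runtime by the fold and replicate counts.

## Numerical choices and degenerate inputs

* Outlier filtering uses a single pass (mean and sample sd computed once
  per recording-day $\times$ genetic-group; no re-estimation), removal
  beyond 3.5 sd; groups of fewer than two records pass through with a
  warning.
* Call-rate and MAF boundaries are kept (strictly-lower removal), and the
  BOA-file MAF is computed over the sire-origin alleles, since those are
  the alleles entering the partial matrix — whether the original analysis
  did the same is unknowable from the text, so this is exposed as the
  definition we chose.
* Mendelian checks treat a pair as inconsistent only for opposing
  homozygotes; both members of an inconsistent pair are masked, and
  missing calls are then mode-imputed per marker within genetic group
  (deterministic, ties to the lower dosage) — a simple
  frequency-preserving completion; pedigree-aware imputation is out of
  scope.
* Fully monomorphic frequency vectors give a zero relationship matrix
  with a warning (the centred rows are zero); per-block monomorphic
  denominators in the multi-breed matrix are an error.
* Unassigned BOA codes (9) enter the partial matrix as zero after
  centring, i.e. imputed at the sire-line mean frequency; the simulator
  never emits them.
* Rank-deficient fixed-effect matrices are reduced by pivoted QR (the
  combined-class coding makes this a no-op in practice).

## Problem sizes in the tests

The shipped tests run the whole machinery at reduced scale: a few hundred
markers and animals for the unit tests; 20 seeds of ~3000 CB records for
heritability recovery; 30 seeds of 161-sire populations for the realized
$r_{pc}$; and 30 replicates of an 800 + 800 offspring population for the
dam-allele inflation contrast (the mean CB-I validation correlation
exceeding CB-I-BOA when validating on individual records). These sizes
were chosen as the smallest at which the Monte-Carlo error is comfortably
below the tested tolerances.

## Known limitations

* The bivariate PB/CB REML model used to *estimate* $r_{pc}$ from data is
  out of scope; $r_{pc}$ enters only as a simulation parameter.
* Phasing and BOA assignment are not implemented; simulation provides
  exact origin labels, and real-data mode expects a BOA file.
* The solver is dense Cholesky on the full mixed-model equations,
  appropriate up to roughly ten thousand equations; no iterative solver
  or single-step (pedigree-blended) matrices.
* Univariate models only; no dominance, no metafounders.
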
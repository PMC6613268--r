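# boagblup

Genomic prediction of **purebred sires for crossbred performance**, with
and without breed-of-origin of alleles (BOA), in a three-way terminal
cross.

## The problem

Broiler (and pig) breeding programs select purebred (PB) sires of a
nucleus line A, but profit comes from three-way crossbred (CB) offspring
A(B×C). When the purebred–crossbred genetic correlation `r_pc < 1`, GEBV
computed from PB records imperfectly rank sires for CB performance, so one
may prefer a CB reference population — and possibly restrict the genomic
relationships of CB animals to the alleles they inherited from the sire
line (their BOA). Whether either choice helps depends on `r_pc`, on the
validation record used (CB offspring averages of sires versus individual
CB records), and on how much predictive value the dam-line alleles carry.
This package implements the full evaluation loop for that question, for
people working on crossbred genomic evaluation who want a tested,
simulation-backed reference implementation.

## What it computes

* **Simulator** (`sim_config()`, `simulate_population()`): gene drop
  through a three-way cross with Balding–Nichols line divergence,
  per-allele origin truth, two body-weight traits with configurable
  `(h2_PB, h2_CB, r_pc)` — defaults (0.09, 0.18, 0.80) and
  (0.22, 0.23, 0.96) — maternal permanent-environment variance, and
  batch×pen×sex×age class effects.
* **QC** (`run_qc()`): 3.5-sd outlier rule per recording day and genetic
  group; marker/animal call-rate ≥ 0.90; Mendelian-consistency filter
  (opposing homozygotes; >1% markers removed, surviving inconsistencies
  masked, mode-imputed); MAF ≥ 0.005 in both the genotype and BOA data;
  sex/MT/unknown-location removal.
* **Relationship matrices** (`single_breed_grm()`, `multibreed_grm()`,
  `boa_partial_grm()`, `dam_line_partial_grm()`): VanRaden single-breed
  `G = MM'/Σ2p(1−p)`, the Wientjes multi-breed block matrix, and
  sire-line/dam-line partial matrices built from origin-labelled alleles
  (expected CB diagonal 0.5). All are cross-products, hence PSD.
* **Mixed models** (`build_design()`, `solve_mme()`, `reml_estimate()`,
  `corrected_phenotypes()`): Henderson equations for the GBLUP animal
  model `y = Xb + Lm + Za + e` and the sire model `y = Xb + Lm + Ts + e`,
  EM-REML variance components (eigen-rotated fast path for the animal
  model), GEBV for unphenotyped candidates, and corrected phenotypes
  `y_c = Tŝ + ê`.
* **Scenario engine** (`run_replicates()`, `summarize_replicates()`):
  family-matched CB subsets, five CV groups of sires with a
  no-offspring/no-paternal-half-sib guarantee, the six scenarios
  PB-A, CB-A, CB-A-BOA, PB-I, CB-I, CB-I-BOA (plus a dam-line probe
  CB-A-DAM), reliability-weighted validation correlations and ×2-corrected
  dispersion-bias regressions.

## Worked example

Simulate a reduced population, clean it, and compare a crossbred
reference population with and without BOA on individual-record validation:

```r
library(boagblup)

cfg <- sim_config(
  n_markers = 500, n_qtl = 150, n_sires = 40, n_sires_both = 34,
  n_sires_pb_only = 2, n_sires_cb_only = 4, n_pb_dams = 80,
  n_cb_dams = 120, n_founders_b = 40, n_founders_c = 40,
  n_pb_offspring = 800, n_cb_offspring = 800,
  traits = list(BW7 = trait_spec(0.09, 0.18, 0.80, day = 7)))
pop  <- simulate_population(cfg, seed = 99)
data <- as_dataset(pop)
data$phenotypes$sire_id <-
  data$pedigree$sire[match(data$phenotypes$animal_id, data$pedigree$id)]

cb   <- subset(data$phenotypes, genetic_group == "CB")
geno <- data$geno[cb$animal_id, ]
G    <- regularize(single_breed_grm(geno, colMeans(geno) / 2), 1e-6)
# EM-REML components (slow boundary components may hit max_iter; the
# estimates are stable well before the likelihood tolerance)
vc <- suppressWarnings(
  reml_estimate(build_design(cb, rownames(geno), "animal"), G,
                tol = 1e-6, max_iter = 200))
vs <- suppressWarnings(
  reml_estimate(build_design(cb, model = "sire"),
                tol = 1e-6, max_iter = 200))

res <- run_replicates(
  data, c("CB-I", "CB-I-BOA"), n_replicates = 30,
  components      = list(BW7 = vc[c("sigma2_a", "sigma2_m", "sigma2_e")]),
  sire_components = list(BW7 = vs[c("sigma2_s", "sigma2_m", "sigma2_e")]),
  base_seed = 7)
summarize_replicates(res)
```

```
  scenario trait mean_correlation sd_correlation mean_regression sd_regression
1     CB-I   BW7       0.09563451     0.02834921       0.6351984     0.1828631
2 CB-I-BOA   BW7       0.04605642     0.02692466       0.6135693     0.3565477
  n_replicates
1           30
2           30
```

Read: with individual-record validation, the plain crossbred reference
(CB-I) shows a *higher* mean validation correlation than the BOA model
(CB-I-BOA) — not because it ranks sires better, but because the dam-line
alleles of the CB animals predict the dam genetic component sitting in the
validation records. That inflation is exactly why sire evaluations should
be validated on offspring averages, or on individual records only with
BOA accounted for.

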
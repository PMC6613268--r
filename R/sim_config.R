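#' Trait settings for the simulator
#'
#' Bundles the genetic parameters of one body-weight trait: the purebred and
#' crossbred heritabilities, the purebred-crossbred genetic correlation
#' (`r_pc`), the nominal age at measurement and the record dropout fraction
#' (emulating mortality before the later weighing).
#'
#' @param h2_pb,h2_cb Narrow-sense heritabilities of the purebred and
#'   crossbred trait definitions, in (0, 1). Phenotypic variance is 1, so
#'   these are also the additive variances.
#' @param r_pc Genetic correlation between the purebred and crossbred
#'   allele-substitution effects, in \[-1, 1\].
#' @param day Nominal age at measurement in days.
#' @param mean Trait mean added to every record (cosmetic, grams scale).
#' @param dropout Fraction of records dropped at random (mortality).
#' @return A list of class `trait_spec`.
#' @export
trait_spec <- function(h2_pb, h2_cb, r_pc, day, mean = 0, dropout = 0) {
  stopifnot(h2_pb > 0, h2_pb < 1, h2_cb > 0, h2_cb < 1)
  if (abs(r_pc) > 1) stop("r_pc must be in [-1, 1]", call. = FALSE)
  stopifnot(day >= 1, dropout >= 0, dropout < 1)
  structure(list(h2_pb = h2_pb, h2_cb = h2_cb, r_pc = r_pc,
                 day = as.integer(day), mean = mean, dropout = dropout),
            class = "trait_spec")
}

#' Simulation configuration for a three-way cross
#'
#' Defines the population and genome simulated by [simulate_population()]:
#' a purebred sire line A mated both within line (purebred offspring) and to
#' F1 dams from two dam lines B and C (three-way crossbred offspring).
#' Defaults describe a commercial broiler setting: 161 sires of which 135
#' have both purebred and crossbred offspring, 5 purebred-only and 21
#' crossbred-only; 628 purebred dams; 1028 F1 dams; about 4700 purebred and
#' 4500 crossbred phenotyped offspring; and two body-weight traits measured
#' around 7 and 35 days with (h2_pb, h2_cb, r_pc) of (0.09, 0.18, 0.80) and
#' (0.22, 0.23, 0.96).
#'
#' @param n_chromosomes Number of autosomes.
#' @param chrom_length_morgans Map length of each chromosome, in Morgans.
#' @param n_markers Total biallelic markers, placed uniformly over the genome.
#' @param n_qtl Number of causal loci, drawn as a random subset of the
#'   markers (set `hidden_qtl = TRUE` to exclude them from the marker panel).
#' @param n_sires Total line-A sires.
#' @param n_sires_both,n_sires_pb_only,n_sires_cb_only Sires with both
#'   purebred and crossbred offspring, purebred offspring only, and
#'   crossbred offspring only. Must sum to `n_sires`.
#' @param n_pb_dams Line-A dams of the purebred offspring.
#' @param n_cb_dams F1 (B x C) dams of the crossbred offspring.
#' @param n_founders_b,n_founders_c Founder animals of the two dam lines
#'   used as parents of the F1 dams.
#' @param n_pb_offspring,n_cb_offspring Phenotyped offspring per group.
#' @param mean_family_size_pb,mean_family_size_cb Mean full-sib family size
#'   (same sire and same dam); sizes are drawn from a zero-truncated Poisson
#'   around these means.
#' @param traits Named list of [trait_spec()] objects.
#' @param var_maternal Maternal permanent-environment variance as a fraction
#'   of the phenotypic variance (which is 1).
#' @param n_batches,pens_per_batch Levels of the housing design.
#' @param pen_purity Target fraction of a pen's animals from one genetic
#'   group for the majority of pens.
#' @param sigma_fixed Standard deviation of the batch x pen x sex x age
#'   class effects.
#' @param age_jitter Maximum absolute integer jitter (days) around the
#'   nominal measurement age.
#' @param divergence Named numeric of per-line divergence parameters in
#'   (0, 1\] or 0, controlling the drift of line allele frequencies from a
#'   shared ancestral frequency (a per-line Fst analogue).
#' @param ancestral_freq_range Range the ancestral allele frequencies are
#'   sampled from; must be bounded away from 0 and 1.
#' @param hidden_qtl If `TRUE`, QTL are removed from the marker panel seen
#'   by downstream analyses.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 10,
                       chrom_length_morgans = 1,
                       n_markers = 2000,
                       n_qtl = 500,
                       n_sires = 161,
                       n_sires_both = 135,
                       n_sires_pb_only = 5,
                       n_sires_cb_only = 21,
                       n_pb_dams = 628,
                       n_cb_dams = 1028,
                       n_founders_b = 250,
                       n_founders_c = 250,
                       n_pb_offspring = 4700,
                       n_cb_offspring = 4500,
                       mean_family_size_pb = 1.7,
                       mean_family_size_cb = 1.6,
                       traits = list(
                         BW7  = trait_spec(0.09, 0.18, 0.80, day = 7,  mean = 180),
                         BW35 = trait_spec(0.22, 0.23, 0.96, day = 35, mean = 2080,
                                           dropout = 0.04)),
                       var_maternal = 0.10,
                       n_batches = 5,
                       pens_per_batch = 4,
                       pen_purity = 0.9,
                       sigma_fixed = 0.5,
                       age_jitter = 1,
                       divergence = c(A = 0.15, B = 0.15, C = 0.15),
                       ancestral_freq_range = c(0.1, 0.9),
                       hidden_qtl = FALSE) {
  cfg <- as.list(environment())
  counts <- c(cfg$n_markers, cfg$n_qtl, cfg$n_sires, cfg$n_pb_dams,
              cfg$n_cb_dams, cfg$n_founders_b, cfg$n_founders_c,
              cfg$n_pb_offspring, cfg$n_cb_offspring, cfg$n_chromosomes,
              cfg$n_batches, cfg$pens_per_batch)
  if (any(counts < 1)) stop("all counts must be positive", call. = FALSE)
  if (cfg$n_sires_both + cfg$n_sires_pb_only + cfg$n_sires_cb_only != cfg$n_sires)
    stop("n_sires_both + n_sires_pb_only + n_sires_cb_only must equal n_sires",
         call. = FALSE)
  if (cfg$n_qtl > cfg$n_markers)
    stop("n_qtl cannot exceed n_markers", call. = FALSE)
  if (!all(c("A", "B", "C") %in% names(cfg$divergence)))
    stop("divergence must be named for lines A, B and C", call. = FALSE)
  if (any(cfg$divergence < 0) || any(cfg$divergence >= 1))
    stop("divergence parameters must lie in [0, 1)", call. = FALSE)
  r <- cfg$ancestral_freq_range
  if (length(r) != 2 || r[1] <= 0 || r[2] >= 1 || r[1] > r[2])
    stop("ancestral_freq_range must be within (0, 1)", call. = FALSE)
  if (cfg$var_maternal < 0 || cfg$var_maternal >= 1)
    stop("var_maternal must be in [0, 1)", call. = FALSE)
  for (tr in cfg$traits) {
    if (!inherits(tr, "trait_spec")) stop("traits must be trait_spec objects",
                                          call. = FALSE)
    if (tr$h2_cb + cfg$var_maternal >= 1 || tr$h2_pb + cfg$var_maternal >= 1)
      stop("h2 + var_maternal must be < 1 so the residual variance is positive",
           call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}
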
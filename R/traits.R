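# QTL effects and phenotypes. The purebred (PB) and crossbred (CB)
# definitions of a trait are modelled as two sets of allele-substitution
# effects at shared QTL, drawn from a zero-mean bivariate normal with
# correlation r_pc; line differences beyond that arise only through allele
# frequencies (a purely additive model, no line-specific dominance).

#' Assign QTL effects and compute true breeding values
#'
#' QTL are a random subset of the markers. Paired per-QTL effects
#' `(alpha_pb, alpha_cb)` are drawn with correlation `r_pc`, then each
#' vector is rescaled so the realized variance of the true breeding values
#' equals the target additive variance exactly (`h2` under phenotypic
#' variance 1): `alpha_pb` on the PB offspring, `alpha_cb` on the CB
#' offspring (falling back to all animals when a group is absent).
#' Rescaling by a positive scalar leaves the effect correlation untouched.
#'
#' @param pop A `cbp_pop` object.
#' @param n_qtl Number of causal loci.
#' @param h2_pb,h2_cb Target additive variances of the two trait
#'   definitions.
#' @param r_pc Genetic correlation between the PB and CB effects.
#' @param seed Integer seed.
#' @return A list of class `trait_arch` with `qtl_idx`, `alpha_pb`,
#'   `alpha_cb`, `r_pc`, and `tbv`: a data frame of per-animal true breeding
#'   values `tbv_pb`, `tbv_cb` (both alleles) and, for CB animals, the
#'   sire-line (`tbv_cb_sire`, A-origin alleles only) and dam-line
#'   (`tbv_cb_dam`) components.
#' @export
assign_qtl_effects <- function(pop, n_qtl, h2_pb, h2_cb, r_pc, seed = 1L) {
  if (abs(r_pc) > 1) stop("r_pc must be in [-1, 1]", call. = FALSE)
  m <- nrow(pop$map)
  if (n_qtl > m) stop("n_qtl cannot exceed the number of markers", call. = FALSE)
  set.seed(seed)
  qtl_idx <- sort(sample.int(m, n_qtl))
  z1 <- stats::rnorm(n_qtl)
  z2 <- stats::rnorm(n_qtl)
  alpha_pb <- z1
  alpha_cb <- r_pc * z1 + sqrt(max(0, 1 - r_pc^2)) * z2

  ped <- pop$pedigree
  gq <- (pop$h1 + pop$h2)[, qtl_idx, drop = FALSE]
  pb_ids <- ped$id[ped$genetic_group == "PB"]
  cb_ids <- ped$id[ped$genetic_group == "CB"]
  ref_pb <- if (length(pb_ids) > 1) pb_ids else ped$id
  ref_cb <- if (length(cb_ids) > 1) cb_ids else ped$id

  tbv_pb <- drop(gq %*% alpha_pb)
  v <- stats::var(tbv_pb[ped$id %in% ref_pb])
  s_pb <- if (v > 0) sqrt(h2_pb / v) else 1
  alpha_pb <- alpha_pb * s_pb

  tbv_cb <- drop(gq %*% alpha_cb)
  v <- stats::var(tbv_cb[ped$id %in% ref_cb])
  s_cb <- if (v > 0) sqrt(h2_cb / v) else 1
  alpha_cb <- alpha_cb * s_cb

  tbv <- data.frame(id = ped$id,
                    tbv_pb = drop(gq %*% alpha_pb),
                    tbv_cb = drop(gq %*% alpha_cb),
                    tbv_cb_sire = NA_real_, tbv_cb_dam = NA_real_,
                    stringsAsFactors = FALSE)
  if (length(cb_ids)) {
    aq <- boa_sire_dosage(pop, cb_ids)[, qtl_idx, drop = FALSE]
    sire_part <- drop(aq %*% alpha_cb)
    i <- match(cb_ids, tbv$id)
    tbv$tbv_cb_sire[i] <- sire_part
    tbv$tbv_cb_dam[i] <- tbv$tbv_cb[i] - sire_part
  }
  structure(list(qtl_idx = qtl_idx, alpha_pb = alpha_pb, alpha_cb = alpha_cb,
                 r_pc = r_pc, tbv = tbv), class = "trait_arch")
}

#' Simulate phenotypes for all configured traits
#'
#' Each phenotyped animal (PB and CB offspring) receives one record per
#' trait: trait mean + a batch x pen x sex x age class effect (one effect
#' drawn per observed level) + its own true breeding value (PB animals
#' express the PB trait definition, CB animals the CB definition) + a
#' maternal permanent-environment effect of its dam + a residual. Residual
#' variance completes the phenotypic variance to 1 within a class. Pens are
#' filled so that most pens hold predominantly one genetic group and a
#' sire's offspring are concentrated in one pen; ages get an integer jitter
#' around the nominal day; a configurable fraction of records of
#' later-measured traits is dropped to emulate mortality.
#'
#' @param pop A `cbp_pop` object with `traits` assigned.
#' @param config The [sim_config()] used to build the population.
#' @param seed Integer seed.
#' @return Data frame with columns `animal_id`, `trait`, `value`, `batch`,
#'   `pen`, `sex`, `age`, `day`, `dam_id`, `genetic_group`.
#' @export
simulate_phenotypes <- function(pop, config, seed = 1L) {
  set.seed(seed)
  ped <- pop$pedigree
  off <- ped[ped$genetic_group %in% c("PB", "CB"), ]
  if (anyNA(off$dam)) stop("phenotyped animal without a dam", call. = FALSE)
  n <- nrow(off)

  # housing: batch by sire family, pens within batch mostly one group
  sires <- unique(off$sire)
  # spread each sire's offspring over batches, but keep one home pen per
  # sire within a batch
  batch <- sample.int(config$n_batches, n, replace = TRUE)
  half <- max(1L, config$pens_per_batch %/% 2L)
  pb_pens <- seq_len(half)
  cb_pens <- seq(half + 1L, config$pens_per_batch)
  # one home pen per sire x batch x group; PB and CB groups use disjoint
  # pen ranges so most pens end up dominated by one group
  key <- paste(off$sire, batch, off$genetic_group)
  uk <- unique(key)
  is_pb <- grepl("PB$", uk)
  home <- integer(length(uk))
  home[is_pb] <- sample(pb_pens, sum(is_pb), replace = TRUE)
  home[!is_pb] <- sample(cb_pens, sum(!is_pb), replace = TRUE)
  pen <- home[match(key, uk)]
  # contaminate a fraction 1 - pen_purity of animals into a random pen
  stray <- stats::runif(n) > config$pen_purity
  pen[stray] <- sample.int(config$pens_per_batch, sum(stray), replace = TRUE)
  sex <- sample(c("M", "F"), n, replace = TRUE)

  tbv_of <- function(arch) {
    i <- match(off$id, arch$tbv$id)
    ifelse(off$genetic_group == "PB", arch$tbv$tbv_pb[i], arch$tbv$tbv_cb[i])
  }

  out <- vector("list", length(config$traits))
  ti <- 0L
  for (tn in names(config$traits)) {
    ti <- ti + 1L
    ts <- config$traits[[tn]]
    age <- ts$day + sample(seq(-config$age_jitter, config$age_jitter), n,
                           replace = TRUE)
    combo <- interaction(batch, pen, sex, age, drop = TRUE)
    fx <- stats::rnorm(nlevels(combo), 0, config$sigma_fixed)
    dams <- unique(off$dam)
    mat <- stats::rnorm(length(dams), 0, sqrt(config$var_maternal))
    names(mat) <- dams
    h2_own <- ifelse(off$genetic_group == "PB", ts$h2_pb, ts$h2_cb)
    sd_e <- sqrt(1 - h2_own - config$var_maternal)
    value <- ts$mean + fx[as.integer(combo)] + tbv_of(pop$traits[[tn]]) +
      mat[off$dam] + stats::rnorm(n, 0, sd_e)
    rec <- data.frame(animal_id = off$id, trait = tn, value = value,
                      batch = batch, pen = pen, sex = sex, age = age,
                      day = sprintf("b%d_d%d", batch, ts$day),
                      dam_id = off$dam, genetic_group = off$genetic_group,
                      stringsAsFactors = FALSE)
    if (ts$dropout > 0) {
      keep <- stats::runif(n) > ts$dropout
      rec <- rec[keep, ]
    }
    out[[ti]] <- rec
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
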
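# The experimental design: a crossbred (CB) subset with a family structure
# matched to the purebred (PB) data, five cross-validation groups of sires
# with a no-offspring / no-paternal-half-sib guarantee, the six
# reference/validation scenarios (plus the dam-line probe), and
# reliability-weighted validation correlations and dispersion bias.

#' Full-sib families of a genetic group
#'
#' A full-sib family is the set of offspring sharing both sire and dam.
#'
#' @param pedigree Pedigree data frame (`id`, `sire`, `dam`,
#'   `genetic_group`).
#' @param group Genetic group to tabulate (`"PB"` or `"CB"`).
#' @param ids Optional restriction to these animal ids.
#' @return List with `members` (list of id vectors per family), `sire`,
#'   `dam`, `size` (vectors per family).
#' @export
full_sib_families <- function(pedigree, group, ids = NULL) {
  ped <- pedigree[pedigree$genetic_group == group, ]
  if (!is.null(ids)) ped <- ped[ped$id %in% ids, ]
  key <- paste(ped$sire, ped$dam, sep = "|")
  members <- split(ped$id, key)
  first <- !duplicated(key)
  ord <- match(names(members), key[first])
  list(members = members,
       sire = ped$sire[first][ord], dam = ped$dam[first][ord],
       size = lengths(members))
}

#' Family-matched selection of crossbred families
#'
#' For every family size `s`, counts the PB full-sib families of that size
#' and selects, uniformly at random, the same number of CB families of size
#' `s`; when fewer CB families of a size exist, all of them are selected.
#'
#' @param pb_sizes Integer vector of PB family sizes (one entry per
#'   family).
#' @param cb_sizes Integer vector of CB family sizes.
#' @param seed Integer seed (NULL: use the current RNG state).
#' @return List with `selected` (indices into `cb_sizes`) and `table`, the
#'   per-size bookkeeping: `size`, `n_pb_families`, `n_cb_available`,
#'   `n_selected`, `n_animals_selected`.
#' @export
sample_matched_families <- function(pb_sizes, cb_sizes, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sizes <- sort(unique(c(pb_sizes, cb_sizes)))
  sel <- integer(0)
  tab <- data.frame(size = sizes, n_pb_families = 0L, n_cb_available = 0L,
                    n_selected = 0L, n_animals_selected = 0L)
  for (i in seq_along(sizes)) {
    s <- sizes[i]
    n_pb <- sum(pb_sizes == s)
    avail <- which(cb_sizes == s)
    n_sel <- min(n_pb, length(avail))
    tab$n_pb_families[i] <- n_pb
    tab$n_cb_available[i] <- length(avail)
    tab$n_selected[i] <- n_sel
    tab$n_animals_selected[i] <- n_sel * s
    if (n_sel > 0)
      sel <- c(sel, if (length(avail) == 1L) avail
               else sample(avail, n_sel))
  }
  list(selected = sort(sel), table = tab)
}

#' Family-matched crossbred subset of a dataset
#'
#' Applies [sample_matched_families()] to the actual PB and CB full-sib
#' families of a pedigree and returns the member animals of the selected CB
#' families.
#'
#' @param pedigree Pedigree data frame.
#' @param seed Integer seed.
#' @param pb_ids,cb_ids Optional restrictions (e.g. phenotyped animals
#'   only).
#' @return List with `animals` (selected CB ids) and `table` as in
#'   [sample_matched_families()].
#' @export
sample_matched_cb_subset <- function(pedigree, seed = NULL, pb_ids = NULL,
                                     cb_ids = NULL) {
  pb <- full_sib_families(pedigree, "PB", pb_ids)
  cb <- full_sib_families(pedigree, "CB", cb_ids)
  res <- sample_matched_families(pb$size, cb$size, seed)
  list(animals = unlist(cb$members[res$selected], use.names = FALSE),
       table = res$table)
}

#' Expected and measured subset overlap
#'
#' `expected_overlap()` is the expected fraction of selected units that two
#' independent uniform draws of `n_selected` out of `n_available` share
#' (the hypergeometric membership expectation `n_selected / n_available`).
#' `measure_overlap()` is the observed fraction `|A intersect B| / |A|` for
#' two equally sized sets.
#'
#' @param n_selected,n_available Counts per draw.
#' @return Fraction in \[0, 1\].
#' @export
expected_overlap <- function(n_selected, n_available) {
  ifelse(n_available == 0, NA_real_, n_selected / n_available)
}

#' @rdname expected_overlap
#' @param setA,setB Vectors of unit identifiers of equal length.
#' @export
measure_overlap <- function(setA, setB) {
  if (length(setA) == 0) return(0)
  length(intersect(setA, setB)) / length(setA)
}

#' Monte-Carlo overlap of replicate family-matched subsets
#'
#' Draws independent pairs of family-matched subsets and measures, per
#' family size, the mean fraction of animals the two subsets share, plus
#' the animal-weighted overall fraction
#' `sum_s s n_s overlap_s / sum_s s n_s`.
#'
#' @param pb_sizes,cb_sizes Family-size vectors as in
#'   [sample_matched_families()].
#' @param n_pairs Number of independent subset pairs (default 100).
#' @param seed Integer seed.
#' @return List with `per_size` (data frame `size`, `n_selected`,
#'   `n_available`, `overlap`, `expected`) and `overall` (animal-weighted
#'   mean).
#' @export
overlap_experiment <- function(pb_sizes, cb_sizes, n_pairs = 100L,
                               seed = 1L) {
  set.seed(seed)
  sizes <- sort(unique(c(pb_sizes, cb_sizes)))
  n_pb <- vapply(sizes, function(s) sum(pb_sizes == s), integer(1))
  n_av <- vapply(sizes, function(s) sum(cb_sizes == s), integer(1))
  n_sel <- pmin(n_pb, n_av)
  acc <- matrix(0, n_pairs, length(sizes))
  for (k in seq_len(n_pairs)) {
    a <- sample_matched_families(pb_sizes, cb_sizes)$selected
    b <- sample_matched_families(pb_sizes, cb_sizes)$selected
    for (i in seq_along(sizes)) {
      ia <- intersect(a, which(cb_sizes == sizes[i]))
      ib <- intersect(b, which(cb_sizes == sizes[i]))
      acc[k, i] <- if (length(ia)) length(intersect(ia, ib)) / length(ia)
                   else NA_real_
    }
  }
  per_size <- data.frame(size = sizes, n_selected = n_sel,
                         n_available = n_av,
                         overlap = colMeans(acc, na.rm = TRUE),
                         expected = expected_overlap(n_sel, n_av))
  w <- sizes * n_sel
  overall_k <- apply(acc, 1, function(r) {
    ok <- !is.na(r) & w > 0
    sum(w[ok] * r[ok]) / sum(w[ok])
  })
  list(per_size = per_size, overall = mean(overall_k))
}

#' Random cross-validation groups of sires
#'
#' Partitions the sires into `n_groups` near-even groups (sizes differ by
#' at most one; e.g. 161 sires in 5 groups give sizes 32, 32, 32, 32, 33).
#' All offspring follow their sire's group, so for every fold no validation
#' sire has offspring in the reference set and no validation animal has a
#' paternal half-sib there.
#'
#' @param sires Character vector of sire ids.
#' @param n_groups Number of groups (default 5).
#' @param seed Integer seed (NULL: current RNG state).
#' @return List of class `cv_partition`: `groups` (list of sire-id
#'   vectors).
#' @export
make_cv_groups <- function(sires, n_groups = 5L, seed = NULL) {
  if (length(sires) < n_groups)
    stop("fewer sires than groups", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  perm <- sample(sires)
  base <- length(sires) %/% n_groups
  extra <- length(sires) %% n_groups
  sizes <- c(rep(base, n_groups - extra), rep(base + 1L, extra))
  groups <- split(perm, rep(seq_len(n_groups), sizes))
  structure(list(groups = unname(groups)), class = "cv_partition")
}

#' Assert the reference/validation leakage guarantee of a partition
#'
#' Checks, for every fold, that no validation sire has offspring among the
#' reference animals and that no validation animal shares a sire with a
#' reference animal.
#'
#' @param partition A `cv_partition`.
#' @param pedigree Pedigree data frame.
#' @param candidate_ids Animals that can enter reference sets.
#' @param validation_sires Sires eligible for validation (those with
#'   crossbred offspring); defaults to all partitioned sires.
#' @return TRUE invisibly; stops on violation.
#' @export
check_no_leakage <- function(partition, pedigree, candidate_ids,
                             validation_sires = NULL) {
  ped <- pedigree[pedigree$id %in% candidate_ids, ]
  if (is.null(validation_sires))
    validation_sires <- unlist(partition$groups)
  for (g in partition$groups) {
    g_val <- intersect(g, validation_sires)
    ref <- ped$id[!(ped$sire %in% g_val)]
    val <- ped$id[ped$sire %in% g_val]
    ref_sires <- unique(ped$sire[ped$id %in% ref])
    if (length(intersect(ref_sires, g_val)))
      stop("leakage: validation sire has offspring in the reference set",
           call. = FALSE)
    val_sires <- unique(ped$sire[ped$id %in% val])
    if (length(intersect(val_sires, ref_sires)))
      stop("leakage: validation animal has a paternal half-sib in the ",
           "reference set", call. = FALSE)
  }
  invisible(TRUE)
}

#' Reliability of a sire's offspring-average record
#'
#' `(n h2 / 4) / (1 + (n - 1) h2 / 4)` for `n` crossbred offspring and
#' crossbred heritability `h2`; 0 < weight < 1, increasing in `n`, tending
#' to 1 as `n` grows.
#'
#' @param n Offspring count (vectorized).
#' @param h2_cb Crossbred heritability.
#' @return Reliability weight(s).
#' @export
reliability_weight <- function(n, h2_cb) {
  (0.25 * n * h2_cb) / (1 + 0.25 * (n - 1) * h2_cb)
}

#' Weighted Pearson correlation
#'
#' Weighted means and central second moments normalized by the weight sum:
#' `r = sum(w (x - xw)(y - yw)) / sqrt(sum(w (x - xw)^2) sum(w (y - yw)^2))`.
#' Equal weights reduce to the ordinary Pearson correlation.
#'
#' @param x,y Numeric vectors.
#' @param w Positive weights (default equal).
#' @return Correlation in \[-1, 1\].
#' @export
weighted_correlation <- function(x, y, w = rep(1, length(x))) {
  stopifnot(length(x) == length(y), length(w) == length(x), all(w > 0))
  xm <- sum(w * x) / sum(w); ym <- sum(w * y) / sum(w)
  sxy <- sum(w * (x - xm) * (y - ym))
  sxy / sqrt(sum(w * (x - xm)^2) * sum(w * (y - ym)^2))
}

#' Weighted regression (dispersion bias) of records on GEBV
#'
#' Weighted least-squares slope of the validation records on the GEBV,
#' multiplied by `multiplier` (2 when the records are offspring averages,
#' because an offspring average represents half the sire's breeding value;
#' 1 for individual records). A slope of 1 means no dispersion bias; below
#' 1, the GEBV are over-dispersed.
#'
#' @param gebv,records Numeric vectors.
#' @param w Positive weights.
#' @param multiplier Slope multiplier (1 or 2).
#' @return Bias coefficient.
#' @export
weighted_regression_bias <- function(gebv, records, w = rep(1, length(gebv)),
                                     multiplier = 1) {
  stopifnot(length(gebv) == length(records), all(w > 0))
  xm <- sum(w * gebv) / sum(w); ym <- sum(w * records) / sum(w)
  slope <- sum(w * (gebv - xm) * (records - ym)) / sum(w * (gebv - xm)^2)
  slope * multiplier
}

#' Put validation correlations of the two record types on one scale
#'
#' Correlations from individual-record validation are divided by the square
#' root of the crossbred heritability; correlations from offspring-average
#' validation by the square root of the mean reliability of the validation
#' sires' offspring averages.
#'
#' @param corr Validation correlation.
#' @param mode `"individual"` or `"average"`.
#' @param h2_cb Crossbred heritability (individual mode).
#' @param mean_reliability Mean reliability weight (average mode).
#' @return Scaled correlation.
#' @export
scale_validation_correlation <- function(corr,
                                         mode = c("individual", "average"),
                                         h2_cb = NULL,
                                         mean_reliability = NULL) {
  mode <- match.arg(mode)
  s <- if (mode == "individual") sqrt(h2_cb) else sqrt(mean_reliability)
  corr / s
}

#' The scenario grid
#'
#' The six evaluated scenarios plus the dam-line probe: reference
#' population (PB or CB offspring), validation record (sire GEBV against CB
#' offspring averages, `-A`; or CB GEBV against individual corrected
#' records, `-I`), and the relationship matrix used (multi-breed /
#' single-breed `G`, sire-line partial `G_BOA`, or dam-line partial).
#'
#' @param names Optional subset of scenario names.
#' @return Data frame `scenario`, `reference`, `validation`, `grm_kind`.
#' @export
scenario_specs <- function(names = NULL) {
  tab <- data.frame(
    scenario = c("PB-A", "CB-A", "CB-A-BOA", "PB-I", "CB-I", "CB-I-BOA",
                 "CB-A-DAM"),
    reference = c("PB", "CB", "CB", "PB", "CB", "CB", "CB"),
    validation = c("average", "average", "average", "individual",
                   "individual", "individual", "average"),
    grm_kind = c("single", "multibreed", "boa_sire", "multibreed", "single",
                 "boa_sire", "boa_dam"),
    stringsAsFactors = FALSE)
  if (!is.null(names)) {
    bad <- setdiff(names, tab$scenario)
    if (length(bad)) stop("unknown scenario(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    tab <- tab[match(names, tab$scenario), ]
  }
  tab
}

# GRM for one scenario over the analysis set of a replicate.
# pred_pb: ids of PB animals needing GEBV (sires for -A scenarios);
# for -I scenarios with a CB reference no PB side is needed at all.
.scenario_grm <- function(spec, data, ref_ids, target_ids, sires) {
  geno <- data$geno
  groups <- stats::setNames(data$pedigree$genetic_group, data$pedigree$id)
  # anything that is not a crossbred (PB offspring, line-A sires) sits on
  # the purebred side of the matrix
  line_a <- ifelse(groups == "CB", "CB", "PB")
  names(line_a) <- names(groups)
  all_ids <- unique(c(ref_ids, target_ids))
  pb_ids <- all_ids[line_a[all_ids] == "PB"]
  cb_ids <- all_ids[line_a[all_ids] == "CB"]
  fr <- compute_allele_frequencies(
    geno[c(pb_ids, cb_ids), , drop = FALSE],
    boa = if (length(cb_ids)) data$boa[cb_ids, , drop = FALSE] else NULL,
    groups = line_a, sires = intersect(sires, pb_ids))
  g <- switch(spec$grm_kind,
    single = {
      ids <- c(pb_ids, cb_ids)
      p <- if (length(cb_ids) && !length(pb_ids)) fr$p_cb else fr$p_pb
      single_breed_grm(geno[ids, , drop = FALSE], p)
    },
    multibreed = multibreed_grm(geno[pb_ids, , drop = FALSE],
                                geno[cb_ids, , drop = FALSE],
                                fr$p_pb, fr$p_cb),
    boa_sire = boa_partial_grm(data$boa[cb_ids, , drop = FALSE],
                               if (length(pb_ids))
                                 geno[pb_ids, , drop = FALSE] else NULL,
                               fr$p_sireline),
    boa_dam = dam_line_partial_grm(
      geno[cb_ids, , drop = FALSE] - data$boa[cb_ids, , drop = FALSE],
      if (length(pb_ids)) geno[pb_ids, , drop = FALSE] else NULL,
      fr$p_damline),
    stop("unknown grm_kind ", spec$grm_kind, call. = FALSE))
  regularize(g, 1e-6)
}

#' Run one scenario for one replicate
#'
#' Fits the GBLUP animal model fold by fold on the scenario's reference
#' records and collects the GEBV of the validation units of every fold,
#' then computes the (reliability-weighted) validation correlation and the
#' dispersion-bias regression coefficient against corrected phenotypes.
#'
#' @param spec One row of [scenario_specs()] (data frame or list).
#' @param data A `cbp_dataset` after QC, with phenotypes carrying a
#'   `sire_id` column.
#' @param trait Trait name to analyse.
#' @param cb_subset Ids of the replicate's family-matched CB subset.
#' @param partition A `cv_partition` of the sires.
#' @param components Animal-model variance components for the GBLUP fits.
#' @param corrected Corrected phenotypes of the trait (all CB records),
#'   from [corrected_phenotypes()].
#' @param h2_cb Crossbred heritability used in the reliability weights.
#' @return One-row data frame: `scenario`, `trait`,
#'   `validation_correlation`, `regression_coefficient`, `n_units`.
#' @export
run_scenario <- function(spec, data, trait, cb_subset, partition, components,
                         corrected, h2_cb) {
  spec <- as.list(spec)
  ped <- data$pedigree
  ph <- data$phenotypes
  ph <- ph[ph$trait == trait, ]
  if (is.null(ph$sire_id))
    ph$sire_id <- ped$sire[match(ph$animal_id, ped$id)]
  groups <- stats::setNames(ped$genetic_group, ped$id)
  sires <- unique(ped$sire[ped$genetic_group %in% c("PB", "CB")])
  cb_ph <- ph[ph$genetic_group == "CB" & ph$animal_id %in% cb_subset, ]
  pb_ph <- ph[ph$genetic_group == "PB", ]
  ref_pool <- if (spec$reference == "PB") pb_ph else cb_ph

  # analysis set shared by the folds: reference pool + prediction targets
  target_all <- if (spec$validation == "average") {
    cb_sires <- unique(ped$sire[ped$genetic_group == "CB"])
    intersect(unlist(partition$groups), cb_sires)
  } else unique(cb_ph$animal_id)
  ref_all <- unique(ref_pool$animal_id)
  grm <- .scenario_grm(spec, data,
                       ref_ids = ref_all,
                       target_ids = setdiff(target_all, ref_all),
                       sires = sires)
  cb_sires <- unique(ped$sire[ped$genetic_group == "CB"])
  gebv <- numeric(0)
  for (g in partition$groups) {
    # only the fold's sires WITH crossbred offspring are validated; the
    # offspring of sires without any stay in every reference set
    g_val <- intersect(g, cb_sires)
    ref <- ref_pool[!(ref_pool$sire_id %in% g_val), ]
    val <- if (spec$validation == "average") intersect(g_val, target_all)
           else cb_ph$animal_id[cb_ph$sire_id %in% g_val]
    if (!length(val) || !nrow(ref)) next
    design <- build_design(ref, grm_ids = grm$ids, model = "animal")
    fit <- solve_mme(design, grm, components)
    gebv <- c(gebv, fit$u[val])
  }
  yc <- corrected[corrected$trait == trait, ]
  if (spec$validation == "average") {
    by_sire <- split(yc$y_corrected, yc$sire_id)
    sire_ids <- intersect(names(gebv), names(by_sire))
    rec <- vapply(by_sire[sire_ids], mean, numeric(1))
    nn <- lengths(by_sire[sire_ids])
    w <- reliability_weight(nn, h2_cb)
    x <- gebv[sire_ids]
    vc <- weighted_correlation(x, rec, w)
    bias <- weighted_regression_bias(x, rec, w, multiplier = 2)
    n_units <- length(sire_ids)
  } else {
    ids <- intersect(names(gebv), yc$animal_id)
    rec <- yc$y_corrected[match(ids, yc$animal_id)]
    x <- gebv[ids]
    vc <- weighted_correlation(x, rec)
    bias <- weighted_regression_bias(x, rec, multiplier = 1)
    n_units <- length(ids)
  }
  data.frame(scenario = spec$scenario, trait = trait,
             validation_correlation = vc, regression_coefficient = bias,
             n_units = n_units, stringsAsFactors = FALSE)
}

#' Run replicated scenario comparisons
#'
#' For each replicate: draw a family-matched CB subset and a fresh CV
#' partition of the sires (replicate `r` uses seed `base_seed + r`), then
#' run every requested scenario and trait on that shared subset and
#' partition, so scenario contrasts are paired within replicates.
#'
#' @param data A `cbp_dataset` after QC.
#' @param scenarios Character vector of scenario names
#'   (see [scenario_specs()]).
#' @param traits Trait names (default: all in the phenotypes).
#' @param n_replicates Number of replicates.
#' @param components Named list per trait of animal-model variance
#'   components.
#' @param sire_components Named list per trait of sire-model components for
#'   the corrected phenotypes (NULL: EM-REML here, once per trait).
#' @param h2_cb Named numeric per trait for the reliability weights
#'   (default: derived from `components`).
#' @param base_seed Integer base seed.
#' @return Data frame of class `replicate_results`: one row per replicate x
#'   scenario x trait.
#' @export
run_replicates <- function(data, scenarios, traits = NULL, n_replicates = 10L,
                           components, sire_components = NULL, h2_cb = NULL,
                           base_seed = 1L) {
  ped <- data$pedigree
  ph <- data$phenotypes
  if (is.null(ph$sire_id))
    data$phenotypes$sire_id <- ph$sire_id <-
      ped$sire[match(ph$animal_id, ped$id)]
  if (is.null(traits)) traits <- unique(ph$trait)
  specs <- scenario_specs(scenarios)
  all_sires <- unique(ped$sire[ped$genetic_group %in% c("PB", "CB")])
  phen_cb_ids <- unique(ph$animal_id[ph$genetic_group == "CB"])

  corrected <- list(); h2 <- numeric(0)
  for (tr in traits) {
    cb <- ph[ph$trait == tr & ph$genetic_group == "CB", ]
    corrected[[tr]] <- corrected_phenotypes(cb, sire_components[[tr]])
    h2[tr] <- if (!is.null(h2_cb)) h2_cb[[tr]] else {
      cc <- components[[tr]]
      cc$sigma2_a / (cc$sigma2_a + (cc$sigma2_m %||% 0) + cc$sigma2_e)
    }
  }
  empty <- data.frame(replicate = integer(), scenario = character(),
                      trait = character(), validation_correlation = numeric(),
                      regression_coefficient = numeric(),
                      n_units = integer(), stringsAsFactors = FALSE)
  if (n_replicates == 0) {
    class(empty) <- c("replicate_results", class(empty))
    return(empty)
  }
  out <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    set.seed(derive_seed(base_seed, 1000L + r))
    sub <- sample_matched_cb_subset(ped, pb_ids = NULL, cb_ids = phen_cb_ids)
    part <- make_cv_groups(all_sires, 5L)
    check_no_leakage(part, ped,
                     c(unique(ph$animal_id[ph$genetic_group == "PB"]),
                       sub$animals),
                     validation_sires =
                       unique(ped$sire[ped$genetic_group == "CB"]))
    rows <- list()
    for (i in seq_len(nrow(specs))) for (tr in traits) {
      res <- run_scenario(specs[i, ], data, tr, sub$animals, part,
                          components[[tr]], corrected[[tr]], h2[[tr]])
      res$replicate <- r
      rows[[length(rows) + 1L]] <- res
    }
    out[[r]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  res <- res[, c("replicate", "scenario", "trait", "validation_correlation",
                 "regression_coefficient", "n_units")]
  class(res) <- c("replicate_results", class(res))
  res
}

#' Summaries over replicates
#'
#' Mean and standard deviation of the validation correlation and the
#' regression coefficient per scenario x trait.
#'
#' @param results A `replicate_results` data frame.
#' @return Data frame with one row per scenario x trait.
#' @export
summarize_replicates <- function(results) {
  agg <- function(v) c(mean = mean(v), sd = stats::sd(v))
  sp <- split(results, list(results$scenario, results$trait), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(scenario = d$scenario[1], trait = d$trait[1],
               mean_correlation = mean(d$validation_correlation),
               sd_correlation = stats::sd(d$validation_correlation),
               mean_regression = mean(d$regression_coefficient),
               sd_regression = stats::sd(d$regression_coefficient),
               n_replicates = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$trait, out$scenario), ]
}

#' Fraction of replicates in which one scenario beats another
#'
#' Per trait, the fraction of replicates where scenario `x`'s validation
#' correlation exceeds scenario `y`'s; ties count as half.
#'
#' @param results A `replicate_results` data frame.
#' @param x,y Scenario names.
#' @param trait Trait name.
#' @return Fraction in \[0, 1\].
#' @export
win_fraction <- function(results, x, y, trait) {
  rx <- results[results$scenario == x & results$trait == trait, ]
  ry <- results[results$scenario == y & results$trait == trait, ]
  m <- merge(rx[, c("replicate", "validation_correlation")],
             ry[, c("replicate", "validation_correlation")],
             by = "replicate", suffixes = c("_x", "_y"))
  if (!nrow(m)) stop("no paired replicates", call. = FALSE)
  mean((m$validation_correlation_x > m$validation_correlation_y) +
         0.5 * (m$validation_correlation_x == m$validation_correlation_y))
}
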
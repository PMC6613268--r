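# Data-cleaning filters for phenotypes and genotypes. The pipeline applies
# them in a fixed order -- marker location, call rate, Mendelian
# consistency, minor allele frequency -- because the outcome of each filter
# depends on what the previous ones removed.

qc_report_row <- function(entity_type, id, reason) {
  data.frame(entity_type = entity_type, id = id, reason = reason,
             stringsAsFactors = FALSE)
}

empty_report <- function() qc_report_row(character(), character(), character())

#' Remove phenotype outliers within recording-day groups
#'
#' Within each group (by default day of recording x genetic group), records
#' deviating more than `k` standard deviations from the group mean are
#' removed. Mean and sample standard deviation are computed once on the
#' unfiltered group (a single pass, no re-estimation after removal). Groups
#' with fewer than two records pass through untouched with a warning.
#'
#' @param records Phenotype data frame with a `value` column.
#' @param group_keys Column names defining the outlier groups.
#' @param k Deviation threshold in standard deviations (default 3.5).
#' @return List with `records` (kept rows) and `report` (removed record
#'   keys with reason `outlier`).
#' @export
filter_phenotype_outliers <- function(records,
                                      group_keys = c("day", "genetic_group"),
                                      k = 3.5) {
  if (!all(group_keys %in% names(records)))
    stop("group_keys missing from records", call. = FALSE)
  g <- interaction(records[group_keys], drop = TRUE)
  drop <- logical(nrow(records))
  small <- FALSE
  for (ix in split(seq_len(nrow(records)), g)) {
    if (length(ix) < 2) { small <- TRUE; next }
    v <- records$value[ix]
    s <- stats::sd(v)
    if (is.na(s) || s == 0) next
    drop[ix] <- abs(v - mean(v)) > k * s
  }
  if (small) warning("groups with fewer than 2 records were left untouched")
  rep <- if (any(drop))
    qc_report_row("phenotype",
                  paste(records$animal_id[drop], records$trait[drop], sep = ":"),
                  "outlier") else empty_report()
  list(records = records[!drop, , drop = FALSE], report = rep)
}

#' Call-rate filters for markers and animals
#'
#' A marker (or animal) is kept iff its fraction of non-missing genotypes is
#' at least `threshold`; only strictly lower call rates are removed.
#'
#' @param geno Dosage matrix with NA for missing calls.
#' @param threshold Minimum call rate (default 0.90).
#' @return List with `geno` (filtered matrix) and `report`.
#' @export
filter_marker_callrate <- function(geno, threshold = 0.90) {
  cr <- 1 - colMeans(is.na(geno))
  drop <- cr < threshold
  rep <- if (any(drop)) qc_report_row("marker", colnames(geno)[drop], "callrate")
         else empty_report()
  list(geno = geno[, !drop, drop = FALSE], report = rep)
}

#' @rdname filter_marker_callrate
#' @export
filter_animal_callrate <- function(geno, threshold = 0.90) {
  cr <- 1 - rowMeans(is.na(geno))
  drop <- cr < threshold
  rep <- if (any(drop)) qc_report_row("animal", rownames(geno)[drop], "callrate")
         else empty_report()
  list(geno = geno[!drop, , drop = FALSE], report = rep)
}

#' Mendelian-consistency filter over parent-offspring pairs
#'
#' A genotyped parent-offspring pair is inconsistent at a marker iff the two
#' dosages are opposing homozygotes (0 and 2). Markers whose inconsistency
#' fraction over all evaluable pairs exceeds `marker_threshold` are removed;
#' at the surviving markers, both members of each inconsistent pair are set
#' to missing. Animals with more than `animal_threshold` inconsistencies
#' across markers are flagged in the report (reason `mendelian_flag`).
#'
#' @param geno Dosage matrix (NA allowed).
#' @param pedigree Data frame with `id`, `sire`, `dam`.
#' @param marker_threshold Maximum tolerated inconsistency fraction per
#'   marker (default 0.01, strictly-greater removal).
#' @param animal_threshold Flagging fraction per animal (default 0.01).
#' @return List with `geno` (markers removed, inconsistent calls masked) and
#'   `report` (removed markers, flagged animals, masked calls as
#'   `animal:marker` entries).
#' @export
mendelian_consistency <- function(geno, pedigree, marker_threshold = 0.01,
                                  animal_threshold = 0.01) {
  ids <- rownames(geno)
  pairs <- rbind(
    data.frame(parent = pedigree$sire, offspring = pedigree$id,
               stringsAsFactors = FALSE),
    data.frame(parent = pedigree$dam, offspring = pedigree$id,
               stringsAsFactors = FALSE))
  pairs <- pairs[!is.na(pairs$parent) & pairs$parent %in% ids &
                   pairs$offspring %in% ids, ]
  if (nrow(pairs) == 0) {
    warning("no genotyped parent-offspring pairs; nothing to check")
    return(list(geno = geno, report = empty_report()))
  }
  gp <- geno[pairs$parent, , drop = FALSE]
  go <- geno[pairs$offspring, , drop = FALSE]
  inc <- (gp == 0L & go == 2L) | (gp == 2L & go == 0L)
  evaluable <- !is.na(inc)
  inc[!evaluable] <- FALSE
  frac_marker <- colSums(inc) / pmax(colSums(evaluable), 1L)
  drop_marker <- frac_marker > marker_threshold
  rep <- if (any(drop_marker))
    qc_report_row("marker", colnames(geno)[drop_marker], "mendelian")
  else empty_report()

  # per-animal inconsistency fraction (either role), over all markers
  tot_anim <- stats::setNames(numeric(length(ids)), ids)
  inc_anim <- stats::setNames(numeric(length(ids)), ids)
  for (role in c("parent", "offspring")) {
    cnt <- rowsum(rowSums(inc), pairs[[role]])
    ev <- rowsum(rowSums(evaluable), pairs[[role]])
    inc_anim[rownames(cnt)] <- inc_anim[rownames(cnt)] + cnt[, 1]
    tot_anim[rownames(ev)] <- tot_anim[rownames(ev)] + ev[, 1]
  }
  flag <- tot_anim > 0 & inc_anim / pmax(tot_anim, 1) > animal_threshold
  if (any(flag))
    rep <- rbind(rep, qc_report_row("animal", ids[flag], "mendelian_flag"))

  keep <- !drop_marker
  geno <- geno[, keep, drop = FALSE]
  inc <- inc[, keep, drop = FALSE]
  masked <- character(0)
  if (any(inc)) {
    w <- which(inc, arr.ind = TRUE)
    mk <- colnames(geno)[w[, 2]]
    for (role in c("parent", "offspring")) {
      an <- pairs[[role]][w[, 1]]
      geno[cbind(match(an, rownames(geno)), w[, 2])] <- NA_integer_
      masked <- c(masked, paste(an, mk, sep = ":"))
    }
    rep <- rbind(rep, qc_report_row("genotype", unique(masked), "mendelian_mask"))
  }
  list(geno = geno, report = rep)
}

#' Impute missing genotypes by the within-group marker mode
#'
#' Deterministic fallback imputation: each missing call is replaced by the
#' most frequent dosage of that marker within the animal's genetic group
#' (ties broken toward the lower dosage; an all-missing group falls back to
#' the overall mode, then to 0). Approximately preserves group allele
#' frequencies.
#'
#' @param geno Dosage matrix with NA for missing calls.
#' @param groups Named character vector mapping animal id to genetic group.
#' @return Completed integer matrix.
#' @export
impute_mode <- function(geno, groups) {
  if (!anyNA(geno)) return(geno)
  grp <- groups[rownames(geno)]
  mode_of <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_integer_)
    tb <- tabulate(v + 1L, 3L)
    which.max(tb) - 1L   # which.max takes the first (lowest dosage) on ties
  }
  for (g in unique(grp)) {
    rows <- which(grp == g)
    sub <- geno[rows, , drop = FALSE]
    nas <- which(is.na(sub), arr.ind = TRUE)
    if (!nrow(nas)) next
    for (j in unique(nas[, 2])) {
      fill <- mode_of(sub[, j])
      if (is.na(fill)) fill <- mode_of(geno[, j])
      if (is.na(fill)) fill <- 0L
      r <- nas[nas[, 2] == j, 1]
      geno[rows[r], j] <- fill
    }
  }
  geno
}

#' Minor-allele-frequency filter on genotype and BOA files
#'
#' A marker is removed iff its minor allele frequency is strictly below
#' `threshold` in either the genotype data (counted-allele frequency over
#' all genotyped animals) or the BOA data (frequency among the sire-line
#' origin alleles of the CB animals); markers at exactly the threshold are
#' kept.
#'
#' @param geno Dosage matrix.
#' @param boa Sire-origin dosage matrix (0/1) for CB animals over the same
#'   markers, or NULL to apply the genotype-file rule only.
#' @param threshold Minimum minor allele frequency (default 0.005).
#' @return List with `keep` (logical per marker), `geno`, `boa`, `report`.
#' @export
maf_filter <- function(geno, boa = NULL, threshold = 0.005) {
  p_g <- colMeans(geno, na.rm = TRUE) / 2
  maf_g <- pmin(p_g, 1 - p_g)
  bad <- maf_g < threshold
  reason <- rep("maf_geno", ncol(geno))
  if (!is.null(boa)) {
    if (!identical(colnames(boa), colnames(geno)))
      stop("boa and geno marker sets differ", call. = FALSE)
    p_b <- colMeans(boa == 1L, na.rm = TRUE)
    maf_b <- pmin(p_b, 1 - p_b)
    bad_b <- maf_b < threshold
    reason[!bad & bad_b] <- "maf_boa"
    bad <- bad | bad_b
  }
  rep <- if (any(bad)) qc_report_row("marker", colnames(geno)[bad], reason[bad])
         else empty_report()
  list(keep = !bad, geno = geno[, !bad, drop = FALSE],
       boa = if (is.null(boa)) NULL else boa[, !bad, drop = FALSE],
       report = rep)
}

#' Remove markers on sex chromosomes, the mitochondrial genome, or with
#' unknown location
#'
#' @param map Marker-info data frame with `marker_id`, `chromosome`,
#'   `position_morgans`.
#' @return List with `keep` (logical), `map`, `report`.
#' @export
marker_location_filter <- function(map) {
  chrom <- as.character(map$chromosome)
  bad <- is.na(chrom) | chrom %in% c("sexZ", "sexW", "Z", "W", "MT",
                                     "unknown") |
    is.na(map$position_morgans)
  rep <- if (any(bad)) qc_report_row("marker", map$marker_id[bad], "location")
         else empty_report()
  list(keep = !bad, map = map[!bad, , drop = FALSE], report = rep)
}

#' Run the full QC pipeline on a dataset
#'
#' Fixed order: phenotype outliers; marker location; marker call rate;
#' animal call rate; Mendelian consistency (marker removal + masking);
#' mode imputation of missing genotypes; minor-allele-frequency filter on
#' the genotype and BOA data. The order matters and is enforced here.
#'
#' @param dataset A `cbp_dataset` (see [read_dataset()]).
#' @param k_outlier,callrate,mendelian,maf Filter thresholds.
#' @return List with `dataset` (filtered, genotypes completed) and `report`
#'   (all removals, one reason each).
#' @export
run_qc <- function(dataset, k_outlier = 3.5, callrate = 0.90,
                   mendelian = 0.01, maf = 0.005) {
  stopifnot(inherits(dataset, "cbp_dataset"))
  reports <- list()
  ph <- filter_phenotype_outliers(dataset$phenotypes, k = k_outlier)
  reports$outliers <- ph$report
  loc <- marker_location_filter(dataset$map)
  reports$location <- loc$report
  geno <- dataset$geno[, loc$keep, drop = FALSE]
  boa <- dataset$boa[, loc$keep, drop = FALSE]
  mc <- filter_marker_callrate(geno, callrate)
  reports$marker_callrate <- mc$report
  geno <- mc$geno
  ac <- filter_animal_callrate(geno, callrate)
  reports$animal_callrate <- ac$report
  geno <- ac$geno
  me <- mendelian_consistency(geno, dataset$pedigree, mendelian)
  reports$mendelian <- me$report
  geno <- me$geno
  groups <- stats::setNames(dataset$pedigree$genetic_group, dataset$pedigree$id)
  geno <- impute_mode(geno, groups)
  boa <- boa[rownames(boa) %in% rownames(geno), colnames(geno), drop = FALSE]
  mf <- maf_filter(geno, boa, maf)
  reports$maf <- mf$report
  map <- loc$map[loc$map$marker_id %in% colnames(mf$geno), , drop = FALSE]
  out <- dataset
  out$geno <- mf$geno
  out$boa <- mf$boa
  out$map <- map
  out$phenotypes <- ph$records[ph$records$animal_id %in% rownames(mf$geno) |
                                 !ph$records$animal_id %in% rownames(dataset$geno), ,
                               drop = FALSE]
  list(dataset = out, report = do.call(rbind, reports))
}

#' Write a QC report as CSV
#' @param report Data frame from [run_qc()] or an individual filter.
#' @param path Output file.
#' @export
write_qc_report <- function(report, path) {
  data.table::fwrite(report, path)
  invisible(path)
}
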
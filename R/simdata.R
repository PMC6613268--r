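# Gene-drop simulator for a three-way terminal cross: a purebred sire line A
# mated within line (PB offspring) and to F1 (B x C) dams (CB offspring),
# with per-allele line-of-origin tracked through every meiosis.

LINE_CODES <- c(A = 1L, B = 2L, C = 3L)

# Sub-seed derivation: stage k of a run seeded with `seed` uses a scrambled
# seed, so that runs with consecutive base seeds (replicate loops) do not
# share random streams between stages. Lehmer-style multiplicative hash on
# the 2^31 - 1 field, computed in doubles to avoid integer overflow.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + k * 104729) %%
               2147483629) + 1L
}

#' Sample per-line allele frequencies around a shared ancestral frequency
#'
#' Ancestral frequencies are drawn uniformly from `ancestral_freq_range`;
#' each line's frequencies then drift from the ancestral value under a
#' Balding-Nichols model, `p_line ~ Beta(p(1-F)/F, (1-p)(1-F)/F)`, where `F`
#' is the line's divergence parameter. `F = 0` returns the ancestral
#' frequencies unchanged; between two lines with divergence `F` the expected
#' Hudson-type Fst is `F`.
#'
#' @param n_markers Number of markers.
#' @param divergence Named numeric (lines A, B, C) of divergence parameters
#'   in \[0, 1).
#' @param ancestral_freq_range Length-2 range within (0, 1).
#' @param seed Integer seed.
#' @return List with `ancestral` (numeric vector) and `lines` (named list of
#'   per-line frequency vectors).
#' @export
sample_line_frequencies <- function(n_markers,
                                    divergence = c(A = 0.15, B = 0.15, C = 0.15),
                                    ancestral_freq_range = c(0.1, 0.9),
                                    seed = 1L) {
  if (n_markers < 1) stop("n_markers must be >= 1", call. = FALSE)
  if (any(divergence < 0) || any(divergence >= 1))
    stop("divergence parameters must lie in [0, 1)", call. = FALSE)
  r <- ancestral_freq_range
  if (length(r) != 2 || r[1] <= 0 || r[2] >= 1 || r[1] > r[2])
    stop("ancestral_freq_range must be within (0, 1)", call. = FALSE)
  set.seed(seed)
  anc <- stats::runif(n_markers, r[1], r[2])
  lines <- lapply(divergence, function(f) {
    if (f == 0) return(anc)
    p <- stats::rbeta(n_markers, anc * (1 - f) / f, (1 - anc) * (1 - f) / f)
    # keep frequencies strictly inside (0,1) so founder draws stay polymorphic
    pmin(pmax(p, 1e-6), 1 - 1e-6)
  })
  list(ancestral = anc, lines = lines)
}

#' Hudson-type Fst between two allele-frequency vectors
#'
#' Ratio-of-sums estimator `sum((p1-p2)^2) / sum(p1(1-p2) + p2(1-p1))` over
#' markers, computed on population frequencies (no sample-size correction).
#'
#' @param p1,p2 Allele-frequency vectors of equal length.
#' @return Scalar differentiation estimate.
#' @export
hudson_fst <- function(p1, p2) {
  sum((p1 - p2)^2) / sum(p1 * (1 - p2) + p2 * (1 - p1))
}

# Uniformly spaced marker map over n_chromosomes of equal length.
make_marker_map <- function(n_markers, n_chromosomes, chrom_length_morgans) {
  chrom <- rep(seq_len(n_chromosomes), length.out = n_markers)
  chrom <- sort(chrom)
  pos <- unlist(lapply(split(seq_along(chrom), chrom), function(ix) {
    k <- length(ix)
    chrom_length_morgans * (seq_len(k) - 0.5) / k
  }), use.names = FALSE)
  map <- data.frame(marker_id = sprintf("M%05d", seq_len(n_markers)),
                    chromosome = chrom, position_morgans = pos,
                    counted_allele = "B", stringsAsFactors = FALSE)
  attr(map, "chrom_length") <- chrom_length_morgans
  map
}

# Draw founder haplotypes: Bernoulli(p) per allele at the line frequencies.
draw_founder_haplotypes <- function(n, p) {
  m <- length(p)
  h1 <- matrix(stats::rbinom(n * m, 1L, rep(p, each = n)), n, m)
  h2 <- matrix(stats::rbinom(n * m, 1L, rep(p, each = n)), n, m)
  storage.mode(h1) <- "integer"; storage.mode(h2) <- "integer"
  list(h1 = h1, h2 = h2)
}

# index structure reused across meioses; chromosome length comes from the
# map's "chrom_length" attribute when present, else the largest position
.chrom_index <- function(map) {
  L <- attr(map, "chrom_length")
  lapply(split(seq_len(nrow(map)), map$chromosome), function(ix) {
    pos <- map$position_morgans[ix]
    list(idx = ix, pos = pos,
         len = if (is.null(L)) max(pos) else L)
  })
}

#' Drop genes through a pedigree
#'
#' Generates offspring haplotypes by Mendelian transmission with
#' recombination, propagating the line-of-origin label of every allele from
#' the founder lines through each meiosis. Founders carry phased haplotypes
#' and a line label; matings are processed in order, so parents must appear
#' (as founders or earlier offspring) before their offspring.
#'
#' @param founders List with `ids`, `line` (one of "A","B","C" per founder),
#'   `h1`, `h2` (founder haplotype matrices, rows in `ids` order).
#' @param matings Data frame with columns `id`, `sire`, `dam`,
#'   `genetic_group`; offspring are generated row by row.
#' @param map Marker map as produced by the simulator (columns `chromosome`,
#'   `position_morgans`).
#' @param seed Integer seed.
#' @return A `cbp_pop` object: pedigree, phased haplotypes (`h1` paternal,
#'   `h2` maternal), origin-label matrices (`o1`, `o2`; 1 = A, 2 = B,
#'   3 = C), and the marker map.
#' @export
gene_drop <- function(founders, matings, map, seed = 1L) {
  set.seed(seed)
  nf <- length(founders$ids)
  no <- nrow(matings)
  n <- nf + no
  m <- nrow(map)
  ids <- c(founders$ids, matings$id)
  if (anyDuplicated(ids)) stop("duplicate animal ids", call. = FALSE)
  h1 <- matrix(0L, n, m); h2 <- matrix(0L, n, m)
  o1 <- matrix(0L, n, m); o2 <- matrix(0L, n, m)
  h1[seq_len(nf), ] <- founders$h1
  h2[seq_len(nf), ] <- founders$h2
  fl <- LINE_CODES[founders$line]
  o1[seq_len(nf), ] <- matrix(fl, nf, m)
  o2[seq_len(nf), ] <- matrix(fl, nf, m)
  row_of <- stats::setNames(seq_len(n), ids)
  ci <- .chrom_index(map)
  for (k in seq_len(no)) {
    s <- row_of[matings$sire[k]]
    d <- row_of[matings$dam[k]]
    if (is.na(s) || is.na(d))
      stop("mating references unknown parent: ", matings$id[k], call. = FALSE)
    r <- nf + k
    if (s >= r || d >= r)
      stop("parents must precede offspring: ", matings$id[k], call. = FALSE)
    # one recombination pattern per gamete; origin labels travel with their
    # alleles through the same pattern
    pat <- .meiosis_with_labels(h1[s, ], h2[s, ], o1[s, ], o2[s, ], ci)
    mat <- .meiosis_with_labels(h1[d, ], h2[d, ], o1[d, ], o2[d, ], ci)
    h1[r, ] <- pat$h; o1[r, ] <- pat$o
    h2[r, ] <- mat$h; o2[r, ] <- mat$o
  }
  ped <- data.frame(
    id = ids,
    sire = c(rep(NA_character_, nf), matings$sire),
    dam = c(rep(NA_character_, nf), matings$dam),
    genetic_group = c(paste0("founder", founders$line), matings$genetic_group),
    stringsAsFactors = FALSE)
  rownames(h1) <- rownames(h2) <- rownames(o1) <- rownames(o2) <- ids
  colnames(h1) <- colnames(h2) <- colnames(o1) <- colnames(o2) <- map$marker_id
  structure(list(pedigree = ped, h1 = h1, h2 = h2, o1 = o1, o2 = o2,
                 map = map), class = "cbp_pop")
}

# One gamete from parent haplotypes. Crossover counts are Poisson per
# chromosome (map length in Morgans, no interference), crossover positions
# uniform, starting strand random; the drawn pattern is applied to the
# allele vectors and the origin-label vectors alike.
.meiosis_with_labels <- function(h1, h2, o1, o2, ci) {
  m <- length(h1)
  out_h <- integer(m); out_o <- integer(m)
  for (e in ci) {
    ix <- e$idx
    nxo <- stats::rpois(1L, e$len)
    strand <- stats::rbinom(1L, 1L, 0.5)
    if (nxo == 0L) {
      if (strand == 0L) { out_h[ix] <- h1[ix]; out_o[ix] <- o1[ix] }
      else              { out_h[ix] <- h2[ix]; out_o[ix] <- o2[ix] }
    } else {
      xo <- sort(stats::runif(nxo, 0, e$len))
      seg <- (strand + findInterval(e$pos, xo)) %% 2L
      first <- seg == 0L
      out_h[ix] <- ifelse(first, h1[ix], h2[ix])
      out_o[ix] <- ifelse(first, o1[ix], o2[ix])
    }
  }
  list(h = out_h, o = out_o)
}

#' Genotype dosages of a simulated population
#'
#' @param pop A `cbp_pop` object.
#' @param ids Optional subset of animal ids.
#' @return Integer matrix of counted-allele dosages in \{0, 1, 2\}.
#' @export
genotypes <- function(pop, ids = NULL) {
  g <- pop$h1 + pop$h2
  if (!is.null(ids)) g <- g[ids, , drop = FALSE]
  g
}

#' Sire-line-origin allele dosage of crossbred animals
#'
#' For each crossbred animal and marker, the counted-allele dosage carried on
#' the gamete that descended from sire line A (0 or 1; a crossbred animal has
#' exactly one A-origin allele per locus).
#'
#' @param pop A `cbp_pop` object.
#' @param ids Crossbred animal ids (default: all CB animals).
#' @return Integer matrix (animals x markers).
#' @export
boa_sire_dosage <- function(pop, ids = NULL) {
  if (is.null(ids)) ids <- pop$pedigree$id[pop$pedigree$genetic_group == "CB"]
  a1 <- pop$o1[ids, , drop = FALSE] == LINE_CODES["A"]
  a2 <- pop$o2[ids, , drop = FALSE] == LINE_CODES["A"]
  if (any(a1 + a2 != 1L))
    stop("animals must carry exactly one A-origin allele per locus; ",
         "are these crossbreds?", call. = FALSE)
  d <- pop$h1[ids, , drop = FALSE] * a1 + pop$h2[ids, , drop = FALSE] * a2
  storage.mode(d) <- "integer"
  d
}

# zero-truncated Poisson family sizes summing to ~ n_offspring
.family_sizes <- function(n_offspring, mean_size) {
  lam <- max(mean_size - 0.3, 0.05)  # rough zero-truncation compensation
  sizes <- integer(0)
  while (sum(sizes) < n_offspring) {
    draw <- stats::rpois(ceiling(n_offspring / max(mean_size, 1)), lam)
    sizes <- c(sizes, draw[draw > 0L])
  }
  keep <- cumsum(sizes) <= n_offspring
  sizes <- sizes[keep]
  short <- n_offspring - sum(sizes)
  if (short > 0L) sizes <- c(sizes, short)
  sizes
}

#' Simulate a complete three-way-cross population
#'
#' Samples line allele frequencies, draws founders (line-A sires and dams,
#' line-B and line-C founders), creates F1 dams and the purebred and
#' crossbred offspring generations by gene drop, assigns QTL effects for
#' every configured trait, and simulates phenotypes.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer base seed; all randomness derives from it.
#' @return A `cbp_pop` object with elements `traits` (per-trait
#'   architecture and true breeding values) and `phenotypes` (record table)
#'   added.
#' @export
simulate_population <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  freqs <- sample_line_frequencies(config$n_markers, config$divergence,
                                   config$ancestral_freq_range,
                                   seed = derive_seed(seed, 1L))
  map <- make_marker_map(config$n_markers, config$n_chromosomes,
                         config$chrom_length_morgans)
  set.seed(derive_seed(seed, 2L))
  sire_ids <- sprintf("SA%04d", seq_len(config$n_sires))
  pbdam_ids <- sprintf("DA%04d", seq_len(config$n_pb_dams))
  bf_ids <- sprintf("FB%04d", seq_len(config$n_founders_b))
  cf_ids <- sprintf("FC%04d", seq_len(config$n_founders_c))
  fa <- draw_founder_haplotypes(config$n_sires + config$n_pb_dams,
                                freqs$lines$A)
  fb <- draw_founder_haplotypes(config$n_founders_b, freqs$lines$B)
  fc <- draw_founder_haplotypes(config$n_founders_c, freqs$lines$C)
  founders <- list(
    ids = c(sire_ids, pbdam_ids, bf_ids, cf_ids),
    line = c(rep("A", config$n_sires + config$n_pb_dams),
             rep("B", config$n_founders_b), rep("C", config$n_founders_c)),
    h1 = rbind(fa$h1, fb$h1, fc$h1),
    h2 = rbind(fa$h2, fb$h2, fc$h2))

  # sire roles
  role <- rep(c("both", "pb_only", "cb_only"),
              c(config$n_sires_both, config$n_sires_pb_only,
                config$n_sires_cb_only))
  role <- sample(role)
  pb_sires <- sire_ids[role != "cb_only"]
  cb_sires <- sire_ids[role != "pb_only"]

  # F1 dams: B sire x C dam
  f1_ids <- sprintf("F1%04d", seq_len(config$n_cb_dams))
  f1_mat <- data.frame(id = f1_ids,
                       sire = sample(bf_ids, config$n_cb_dams, replace = TRUE),
                       dam = sample(cf_ids, config$n_cb_dams, replace = TRUE),
                       genetic_group = "F1", stringsAsFactors = FALSE)

  # full-sib families: one (sire, dam) pair per family; dams may appear in
  # families of several sires, as in commercial multi-sire mating
  make_offspring <- function(prefix, n_off, mean_size, sires, dams, group) {
    sizes <- .family_sizes(n_off, mean_size)
    fam_sire <- sample(sires, length(sizes), replace = TRUE)
    fam_dam <- sample(dams, length(sizes), replace = TRUE)
    # ensure every sire gets at least one family where possible
    missing <- setdiff(sires, unique(fam_sire))
    if (length(missing) && length(missing) <= length(sizes))
      fam_sire[sample(seq_along(sizes), length(missing))] <- missing
    data.frame(id = sprintf("%s%05d", prefix, seq_len(sum(sizes))),
               sire = rep(fam_sire, sizes), dam = rep(fam_dam, sizes),
               genetic_group = group, stringsAsFactors = FALSE)
  }
  pb_mat <- make_offspring("PB", config$n_pb_offspring,
                           config$mean_family_size_pb, pb_sires, pbdam_ids, "PB")
  cb_mat <- make_offspring("CB", config$n_cb_offspring,
                           config$mean_family_size_cb, cb_sires, f1_ids, "CB")
  matings <- rbind(f1_mat, pb_mat, cb_mat)

  pop <- gene_drop(founders, matings, map, seed = derive_seed(seed, 3L))
  pop$config <- config
  pop$line_freqs <- freqs
  pop$sire_ids <- sire_ids
  pop$traits <- list()
  ti <- 0L
  for (tn in names(config$traits)) {
    ti <- ti + 1L
    ts <- config$traits[[tn]]
    pop$traits[[tn]] <- assign_qtl_effects(pop, config$n_qtl, ts$h2_pb,
                                           ts$h2_cb, ts$r_pc,
                                           seed = derive_seed(seed, 10L + ti))
  }
  pop$phenotypes <- simulate_phenotypes(pop, config,
                                        seed = derive_seed(seed, 100L))
  pop
}
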
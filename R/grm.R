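# Genomic relationship matrices (GRM). Four kinds are supported:
#   single    : G = MM' / sum 2 p_j (1 - p_j), M centred at 2 p_j (VanRaden)
#   multibreed: block form with group-specific frequencies and denominators;
#               equal to WW' where each animal's centred row is divided by
#               the square root of its group's denominator
#   boa_sire  : partial GRM using, for crossbred animals, only the allele
#               inherited from the sire line; the CB rows are the centred
#               sire-origin allele dosages (1 - p if the counted allele came
#               from the sire line, 0 - p otherwise)
#   boa_dam   : the complementary partial GRM built from dam-origin alleles
# All four are cross-products WW' and therefore symmetric positive
# semidefinite by construction.

new_grm <- function(mat, kind, denom, freqs = NULL) {
  structure(list(mat = mat, ids = rownames(mat), kind = kind,
                 denom = denom, freqs = freqs), class = "grm")
}

#' @export
as.matrix.grm <- function(x, ...) x$mat

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("<grm kind=%s, %d animals, denominator %.4g>\n",
              x$kind, length(x$ids), x$denom[1]))
  invisible(x)
}

#' Allele frequencies for GRM construction
#'
#' Computes, per marker, the counted-allele frequency in the purebred group
#' (`p_pb`), in the crossbred group (`p_cb`), among the sire-line alleles
#' (`p_sireline`: the total number of counted alleles carried by the PB
#' sires plus those inherited by the CB offspring from these sires, divided
#' by the total number of such alleles, i.e. 2 per sire and 1 per CB
#' animal), and among the dam-origin alleles of the CB offspring
#' (`p_damline`).
#'
#' @param geno Dosage matrix for all animals in the analysis set.
#' @param boa Sire-origin dosage matrix (0/1) of the CB animals, or NULL.
#' @param groups Named character vector (animal id -> "PB"/"CB"); animals
#'   not listed are ignored for the group frequencies.
#' @param sires Ids of the PB sires entering the sire-line pool. With
#'   `pb_pool = "all"`, all PB-group animals are pooled instead.
#' @param pb_pool Either "sires" (default) or "all".
#' @return List with `p_pb`, `p_cb`, `p_sireline`, `p_damline` (NULL when
#'   the inputs needed for a variant are absent).
#' @export
compute_allele_frequencies <- function(geno, boa = NULL, groups,
                                       sires = NULL,
                                       pb_pool = c("sires", "all")) {
  pb_pool <- match.arg(pb_pool)
  ids <- rownames(geno)
  grp <- groups[ids]
  p_pb <- p_cb <- p_sire <- p_dam <- NULL
  pb_ids <- ids[!is.na(grp) & grp == "PB"]
  cb_ids <- ids[!is.na(grp) & grp == "CB"]
  if (length(pb_ids)) p_pb <- colMeans(geno[pb_ids, , drop = FALSE]) / 2
  if (length(cb_ids)) p_cb <- colMeans(geno[cb_ids, , drop = FALSE]) / 2
  if (!is.null(boa)) {
    boa_ids <- rownames(boa)
    pool <- if (pb_pool == "sires") {
      if (is.null(sires)) stop("sires must be given for pb_pool = 'sires'",
                               call. = FALSE)
      intersect(sires, ids)
    } else pb_ids
    if (length(pool) || nrow(boa)) {
      cnt <- 0; tot <- 0
      if (length(pool)) {
        cnt <- cnt + colSums(geno[pool, , drop = FALSE])
        tot <- tot + 2 * length(pool)
      }
      if (nrow(boa)) {
        cnt <- cnt + colSums(boa == 1L)
        tot <- tot + nrow(boa)
      }
      p_sire <- cnt / tot
    }
    if (nrow(boa) && length(cb_ids)) {
      dam_dos <- geno[rownames(boa), , drop = FALSE] - (boa == 1L)
      p_dam <- colMeans(dam_dos)
    }
  }
  for (p in list(p_pb, p_cb, p_sire, p_dam)) {
    if (is.null(p)) next
    bad <- is.na(p) | p < 0 | p > 1
    if (any(bad))
      stop("no informative alleles (or invalid frequency) at marker(s): ",
           paste(utils::head(colnames(geno)[bad], 5), collapse = ", "),
           call. = FALSE)
  }
  list(p_pb = p_pb, p_cb = p_cb, p_sireline = p_sire, p_damline = p_dam)
}

# cross-product scaled by the frequency denominator; a fully monomorphic
# frequency vector (denominator 0) yields the all-zero matrix, since the
# centred rows are then zero as well
.scaled_cp <- function(W, denom) {
  if (denom == 0) {
    warning("all markers monomorphic; relationship matrix is all zero")
    return(matrix(0, nrow(W), nrow(W), dimnames = list(rownames(W),
                                                       rownames(W))))
  }
  tcrossprod(W) / denom
}

#' Single-breed genomic relationship matrix
#'
#' `G = MM' / sum 2 p_j (1 - p_j)` with `M` the genotype matrix centred at
#' `2 p_j`.
#'
#' @param geno Dosage matrix (animals x markers).
#' @param p Counted-allele frequencies used both for centring and the
#'   denominator.
#' @return A `grm` object of kind `"single"`.
#' @export
single_breed_grm <- function(geno, p) {
  stopifnot(ncol(geno) == length(p))
  M <- sweep(geno, 2, 2 * p)
  denom <- sum(2 * p * (1 - p))
  new_grm(.scaled_cp(M, denom), "single", c(denom = denom), list(p = p))
}

#' Multi-breed genomic relationship matrix
#'
#' Block matrix with breed-specific centring and denominators: the PB block
#' is `M_PB M_PB' / sum 2 p^PB q^PB`, the CB block `M_CB M_CB' / sum 2 p^CB
#' q^CB`, and the cross block is divided by the geometric mean of the two
#' denominators. Implemented as `WW'` with each animal's centred row scaled
#' by its group's root denominator, which guarantees symmetry and positive
#' semidefiniteness.
#'
#' @param geno_pb,geno_cb Dosage matrices of the two groups over identical
#'   marker sets.
#' @param p_pb,p_cb Group allele frequencies.
#' @return A `grm` object of kind `"multibreed"` (PB animals first).
#' @export
multibreed_grm <- function(geno_pb, geno_cb, p_pb, p_cb) {
  if (ncol(geno_pb) != ncol(geno_cb) ||
      !identical(colnames(geno_pb), colnames(geno_cb)))
    stop("PB and CB genotype matrices must cover the same markers",
         call. = FALSE)
  stopifnot(length(p_pb) == ncol(geno_pb), length(p_cb) == ncol(geno_cb))
  d_pb <- sum(2 * p_pb * (1 - p_pb))
  d_cb <- sum(2 * p_cb * (1 - p_cb))
  if (d_pb == 0 || d_cb == 0)
    stop("a group's markers are all monomorphic; cannot scale the ",
         "multi-breed blocks", call. = FALSE)
  W <- rbind(sweep(geno_pb, 2, 2 * p_pb) / sqrt(d_pb),
             sweep(geno_cb, 2, 2 * p_cb) / sqrt(d_cb))
  new_grm(tcrossprod(W), "multibreed", c(pb = d_pb, cb = d_cb),
          list(p_pb = p_pb, p_cb = p_cb))
}

#' Sire-line breed-of-origin partial genomic relationship matrix
#'
#' Relationships involving crossbred animals use only the allele each CB
#' animal inherited from the sire line: the CB rows of the centred matrix
#' are `T_CB`, with entry `1 - p_j` when the counted allele came from the
#' sire line and `0 - p_j` otherwise, where `p_j` is the sire-line allele
#' frequency (`p_sireline`). The PB rows are genotypes centred at `2 p_j`.
#' The whole matrix is `WW' / sum 2 p_j (1 - p_j)` with `W = [M_PB; T_CB]`,
#' one common scaling, so the expected diagonal for CB animals is 0.5 (half
#' the genome) while PB diagonals centre on 1.
#'
#' @param boa Sire-origin counted-allele dosage of the CB animals (0/1;
#'   code 9 or NA = unassigned, treated as dosage at the mean, i.e. a
#'   centred value of 0).
#' @param geno_pb Dosage matrix of the PB animals, or NULL for the CB-only
#'   reduction `T_CB T_CB' / sum 2 p q`.
#' @param p Sire-line allele frequencies (`p_sireline`).
#' @return A `grm` object of kind `"boa_sire"` (PB animals first).
#' @export
boa_partial_grm <- function(boa, geno_pb = NULL, p) {
  stopifnot(ncol(boa) == length(p))
  tcb <- matrix(as.numeric(boa), nrow(boa), ncol(boa),
                dimnames = dimnames(boa))
  tcb[tcb == 9] <- NA
  Tcb <- sweep(tcb, 2, p)
  Tcb[is.na(Tcb)] <- 0
  W <- if (is.null(geno_pb)) Tcb else {
    if (!identical(colnames(geno_pb), colnames(boa)))
      stop("PB genotypes and BOA matrix must cover the same markers",
           call. = FALSE)
    if (any(rownames(geno_pb) %in% rownames(boa)))
      stop("animals cannot appear in both the PB genotype and BOA matrices",
           call. = FALSE)
    rbind(sweep(geno_pb, 2, 2 * p), Tcb)
  }
  denom <- sum(2 * p * (1 - p))
  new_grm(.scaled_cp(W, denom), "boa_sire", c(denom = denom), list(p = p))
}

#' Dam-line partial genomic relationship matrix
#'
#' Mirror image of [boa_partial_grm()]: relationships involving crossbred
#' animals use only their dam-origin allele, centred at the dam-line allele
#' frequency (`p_damline`); PB rows (when supplied) are centred at
#' `2 p_damline` so the whole matrix remains a single cross-product.
#'
#' @param dam_dosage Dam-origin counted-allele dosage (0/1) of the CB
#'   animals, i.e. total dosage minus the sire-origin dosage.
#' @param geno_pb Optional PB dosage matrix.
#' @param p Dam-line allele frequencies.
#' @return A `grm` object of kind `"boa_dam"`.
#' @export
dam_line_partial_grm <- function(dam_dosage, geno_pb = NULL, p) {
  g <- boa_partial_grm(dam_dosage, geno_pb, p)
  g$kind <- "boa_dam"
  g
}

#' Add a ridge to a GRM diagonal
#'
#' @param grm A `grm` object.
#' @param epsilon Non-negative value added to every diagonal element before
#'   inversion-dependent steps (default 1e-6); recorded in the object.
#' @return The regularized `grm`.
#' @export
regularize <- function(grm, epsilon = 1e-6) {
  stopifnot(inherits(grm, "grm"))
  if (epsilon < 0) stop("epsilon must be non-negative", call. = FALSE)
  if (epsilon > 0) diag(grm$mat) <- diag(grm$mat) + epsilon
  grm$epsilon <- (if (is.null(grm$epsilon)) 0 else grm$epsilon) + epsilon
  grm
}

#' Export a GRM as a long-format table
#' @param grm A `grm` object.
#' @return Data frame `id1,id2,value` (upper triangle incl. diagonal).
#' @export
grm_to_long <- function(grm) {
  m <- grm$mat
  ut <- upper.tri(m, diag = TRUE)
  w <- which(ut, arr.ind = TRUE)
  data.frame(id1 = rownames(m)[w[, 1]], id2 = colnames(m)[w[, 2]],
             value = m[ut], stringsAsFactors = FALSE)
}
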
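#' Family-size distribution of a commercial broiler dataset
#'
#' Published per-size counts of purebred and crossbred full-sib families
#' from a commercial broiler breeding program (body weight at around 7
#' days): for each family size, the number of purebred families and the
#' number of available crossbred families. Running the family-matched
#' selection rule on these counts selects 4655 crossbred animals. Used in
#' examples and in the package's validation of the sampling arithmetic.
#'
#' @return Data frame with columns `size`, `n_pb_families`,
#'   `n_cb_families`.
#' @export
example_family_counts <- function() {
  data.frame(
    size = 1:11,
    n_pb_families = c(1699L, 653L, 276L, 117L, 46L, 13L, 3L, 2L, 1L, 0L, 1L),
    n_cb_families = c(4406L, 1610L, 607L, 177L, 60L, 14L, 3L, 2L, 1L, 0L, 0L))
}

#' Expand per-size family counts into a vector of family sizes
#'
#' @param sizes Family sizes.
#' @param counts Number of families of each size.
#' @return Integer vector with one entry per family.
#' @export
family_sizes_from_counts <- function(sizes, counts) {
  rep(as.integer(sizes), as.integer(counts))
}
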
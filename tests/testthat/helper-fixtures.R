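# Small populations and matrices used across test files. Everything is
# generated in code at test time; sizes are kept small so the whole suite
# runs quickly.

tiny_config <- function(...) {
  defaults <- list(
    n_markers = 300, n_qtl = 80, n_sires = 20, n_sires_both = 16,
    n_sires_pb_only = 1, n_sires_cb_only = 3, n_pb_dams = 40,
    n_cb_dams = 60, n_founders_b = 30, n_founders_c = 30,
    n_pb_offspring = 150, n_cb_offspring = 150,
    traits = list(BW7 = trait_spec(0.09, 0.18, 0.80, day = 7)))
  dots <- list(...)
  args <- utils::modifyList(defaults, dots)
  if (!is.null(dots$traits)) args$traits <- dots$traits  # replace, not merge
  do.call(sim_config, args)
}

tiny_pop <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_population(tiny_config(), seed = 42)
    cache
  }
})

# genotype matrix with controlled allele frequencies, HWE
random_geno <- function(n, m, p = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(p)) p <- runif(m, 0.1, 0.9)
  g <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m,
              dimnames = list(sprintf("A%03d", seq_len(n)),
                              sprintf("M%04d", seq_len(m))))
  g
}
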
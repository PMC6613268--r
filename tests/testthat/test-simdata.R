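# The simulator: line frequencies, gene drop, trait architecture,
# phenotypes, dataset round trip.

test_that("zero divergence returns the ancestral frequencies exactly", {
  fr <- sample_line_frequencies(200, c(A = 0, B = 0, C = 0),
                                c(0.2, 0.8), seed = 3)
  expect_identical(fr$lines$A, fr$ancestral)
  expect_identical(fr$lines$B, fr$ancestral)
  fr2 <- sample_line_frequencies(50, c(A = 0, B = 0, C = 0),
                                 c(0.5, 0.5), seed = 3)
  expect_true(all(fr2$lines$C == 0.5))
})

test_that("line divergence matches a Hudson-type Fst oracle", {
  fr <- sample_line_frequencies(2000, c(A = 0.15, B = 0.15, C = 0.15),
                                seed = 11)
  fsts <- c(hudson_fst(fr$lines$A, fr$lines$B),
            hudson_fst(fr$lines$A, fr$lines$C),
            hudson_fst(fr$lines$B, fr$lines$C))
  expect_true(all(abs(fsts - 0.15) < 0.05))
})

test_that("invalid frequency configurations error", {
  expect_error(sample_line_frequencies(0, c(A = 0.1, B = 0.1, C = 0.1)),
               "n_markers")
  expect_error(sample_line_frequencies(10, c(A = 1.2, B = 0.1, C = 0.1)),
               "divergence")
  expect_error(sim_config(n_sires = 10, n_sires_both = 5, n_sires_pb_only = 1,
                          n_sires_cb_only = 1), "must equal n_sires")
})

test_that("crossbreds carry exactly half sire-line-origin alleles", {
  pop <- tiny_pop()
  ped <- pop$pedigree
  cb <- ped$id[ped$genetic_group == "CB"]
  n_a <- (pop$o1[cb, ] == 1) + (pop$o2[cb, ] == 1)
  expect_true(all(n_a == 1))          # per animal AND per locus
  expect_true(all(pop$o1[cb, ] == 1)) # the whole paternal gamete is line A
  d <- boa_sire_dosage(pop, cb)
  expect_true(all(d %in% 0:1))
  g <- genotypes(pop, cb)
  expect_true(all(g - d >= 0 & g - d <= 1)) # dam allele is the complement
})

test_that("gene drop transmits recombinant parental haplotypes", {
  pop <- tiny_pop()
  ped <- pop$pedigree
  off <- ped[ped$genetic_group == "PB", ][1:20, ]
  for (k in seq_len(nrow(off))) {
    s <- off$sire[k]
    pat <- pop$h1[off$id[k], ]
    # every transmitted allele equals one of the sire's two alleles
    expect_true(all(pat == pop$h1[s, ] | pat == pop$h2[s, ]))
  }
})

test_that("a zero-length chromosome gives an unrecombined gamete copy", {
  map <- data.frame(marker_id = paste0("M", 1:30), chromosome = 1L,
                    position_morgans = 0)
  attr(map, "chrom_length") <- 0
  set.seed(4)
  founders <- list(ids = c("F1", "F2"), line = c("A", "A"),
                   h1 = rbind(rep(1L, 30), rep(0L, 30)),
                   h2 = rbind(rep(0L, 30), rep(1L, 30)))
  mat <- data.frame(id = "X", sire = "F1", dam = "F2",
                    genetic_group = "PB", stringsAsFactors = FALSE)
  pop <- gene_drop(founders, mat, map, seed = 9)
  # each gamete is a pure copy of one parental haplotype
  expect_true(all(pop$h1["X", ] == 1) || all(pop$h1["X", ] == 0))
  expect_true(all(pop$h2["X", ] == 1) || all(pop$h2["X", ] == 0))
})

test_that("crossover counts on a 1-Morgan chromosome are Poisson(1)", {
  map <- data.frame(marker_id = sprintf("M%03d", 1:101), chromosome = 1L,
                    position_morgans = seq(0, 1, length.out = 101))
  attr(map, "chrom_length") <- 1
  # heterozygous-everywhere parent: haplotype switches are observable
  founders <- list(ids = c("P1", "P2"), line = c("A", "A"),
                   h1 = rbind(rep(1L, 101), rep(1L, 101)),
                   h2 = rbind(rep(0L, 101), rep(0L, 101)))
  mat <- data.frame(id = sprintf("O%03d", 1:500), sire = "P1", dam = "P2",
                    genetic_group = "PB", stringsAsFactors = FALSE)
  pop <- gene_drop(founders, mat, map, seed = 5)
  # observed switch count along the gamete lower-bounds the crossover count;
  # with 101 markers on 1 M, double crossovers within an interval are rare
  switches <- rowSums(abs(pop$h1[mat$id, -1] - pop$h1[mat$id, -101]))
  expect_lt(abs(mean(switches) - 1.0), 3 * sqrt(1 / 500) + 0.05)
})

test_that("mating referencing an unknown parent errors", {
  founders <- list(ids = "F1", line = "A",
                   h1 = matrix(1L, 1, 5), h2 = matrix(0L, 1, 5))
  map <- data.frame(marker_id = paste0("M", 1:5), chromosome = 1L,
                    position_morgans = seq(0.1, 0.5, by = 0.1))
  mat <- data.frame(id = "X", sire = "F1", dam = "NOPE",
                    genetic_group = "PB", stringsAsFactors = FALSE)
  expect_error(gene_drop(founders, mat, map), "unknown parent")
})

test_that("QTL effect correlation and variance targets are honoured", {
  pop <- tiny_pop()
  cfg <- pop$config
  ped <- pop$pedigree
  tb <- pop$traits$BW7$tbv
  pb <- ped$id[ped$genetic_group == "PB"]
  cb <- ped$id[ped$genetic_group == "CB"]
  expect_equal(var(tb$tbv_pb[match(pb, tb$id)]), 0.09, tolerance = 1e-10)
  expect_equal(var(tb$tbv_cb[match(cb, tb$id)]), 0.18, tolerance = 1e-10)
  # sire + dam components partition the crossbred breeding value
  i <- match(cb, tb$id)
  expect_equal(tb$tbv_cb_sire[i] + tb$tbv_cb_dam[i], tb$tbv_cb[i])
  # r_pc = 1 gives perfectly correlated breeding values
  arch1 <- assign_qtl_effects(pop, 80, 0.2, 0.3, 1, seed = 8)
  expect_equal(cor(arch1$tbv$tbv_pb, arch1$tbv$tbv_cb), 1, tolerance = 1e-8)
  expect_error(assign_qtl_effects(pop, 80, 0.2, 0.3, 1.2), "r_pc")
})

test_that("realized sire-level effect correlation tracks configured r_pc", {
  # Monte-Carlo over seeds at a small scale; independence case
  r0 <- sapply(1:30, function(s) {
    pop <- simulate_population(tiny_config(
      traits = list(T1 = trait_spec(0.2, 0.2, 0, day = 7)),
      n_markers = 250, n_qtl = 150, n_sires = 60, n_sires_both = 50,
      n_sires_pb_only = 4, n_sires_cb_only = 6,
      n_pb_offspring = 80, n_cb_offspring = 80), seed = 300 + s)
    tb <- pop$traits$T1$tbv
    i <- match(pop$sire_ids, tb$id)
    cor(tb$tbv_pb[i], tb$tbv_cb[i])
  })
  # per-seed sd of the realized correlation is about 0.15 at this scale
  expect_lt(abs(mean(r0)), 3 * 0.15 / sqrt(30) + 0.01)
})

test_that("phenotypes decompose as designed", {
  # no noise: phenotype equals the animal's own true breeding value
  cfg0 <- tiny_config(var_maternal = 1e-12, sigma_fixed = 0,
                      traits = list(T1 = trait_spec(0.9999, 0.9999, 1,
                                                    day = 7, mean = 0)))
  pop0 <- simulate_population(cfg0, seed = 13)
  ph <- pop0$phenotypes
  tb <- pop0$traits$T1$tbv
  own <- ifelse(ph$genetic_group == "PB",
                tb$tbv_pb[match(ph$animal_id, tb$id)],
                tb$tbv_cb[match(ph$animal_id, tb$id)])
  expect_lt(max(abs(ph$value - own)), 0.05)
  # mortality dropout reduces record counts
  cfgd <- tiny_config(traits = list(T1 = trait_spec(0.2, 0.2, 0.8, day = 35,
                                                    dropout = 0.5)))
  popd <- simulate_population(cfgd, seed = 14)
  expect_lt(nrow(popd$phenotypes), 250)
})

test_that("identical config and seed give identical populations", {
  cfg <- tiny_config(n_markers = 120, n_pb_offspring = 40,
                     n_cb_offspring = 40)
  a <- simulate_population(cfg, seed = 77)
  b <- simulate_population(cfg, seed = 77)
  expect_identical(a$h1, b$h1)
  expect_identical(a$o2, b$o2)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$traits$BW7$alpha_cb, b$traits$BW7$alpha_cb)
})

test_that("dataset files round-trip bit-identically", {
  pop <- tiny_pop()
  dir <- withr::local_tempdir()
  write_dataset(pop, dir)
  ds <- read_dataset(dir)
  expect_identical(ds$geno, genotypes(pop))
  cb <- pop$pedigree$id[pop$pedigree$genetic_group == "CB"]
  expect_identical(ds$boa, boa_sire_dosage(pop, cb))
  expect_equal(nrow(ds$pedigree), nrow(pop$pedigree))
  expect_equal(ds$phenotypes$value, pop$phenotypes$value)
  # row counts match animal counts
  expect_equal(nrow(ds$geno), nrow(pop$pedigree))
  expect_equal(nrow(ds$boa), length(cb))
})
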
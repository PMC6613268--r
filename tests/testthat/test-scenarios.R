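# Experimental design: family-matched subsampling, replicate overlap,
# CV groups with the leakage guarantee, and the validation statistics.

test_that("family-matched sampling honours the per-size min rule", {
  counts <- example_family_counts()
  pb <- family_sizes_from_counts(counts$size, counts$n_pb_families)
  cb <- family_sizes_from_counts(counts$size, counts$n_cb_families)
  res <- sample_matched_families(pb, cb, seed = 1)
  # sizes where fewer CB families exist: all of them are selected
  t7 <- res$table[res$table$size == 7, ]
  expect_equal(t7$n_selected, 3L)
  expect_equal(t7$n_cb_available, 3L)
  t11 <- res$table[res$table$size == 11, ]
  expect_equal(t11$n_selected, 0L)        # one PB family, no CB available
  # min rule everywhere
  expect_equal(res$table$n_selected,
               pmin(res$table$n_pb_families, res$table$n_cb_available))
  # identical PB and CB structures select everything
  res2 <- sample_matched_families(cb, cb, seed = 2)
  expect_equal(sort(res2$selected), seq_along(cb))
})

test_that("subset overlap matches the hypergeometric expectation", {
  expect_equal(expected_overlap(117, 177), 117 / 177)
  expect_equal(expected_overlap(60, 60), 1)
  expect_equal(measure_overlap(character(0), character(0)), 0)
  expect_equal(measure_overlap(c("a", "b"), c("b", "c")), 0.5)
  # Monte-Carlo overlap of repeated draws agrees with n_sel / n_avail
  pb <- rep(4L, 117); cb <- rep(4L, 177)
  ov <- overlap_experiment(pb, cb, n_pairs = 120, seed = 3)
  expect_equal(round(ov$per_size$overlap, 2), 0.66)
  se3 <- 3 * sqrt(0.66 * 0.34 / 117) / sqrt(120)
  expect_lt(abs(ov$per_size$overlap - 117 / 177), se3 + 0.01)
})

test_that("CV groups are near-even and follow-the-sire by construction", {
  g161 <- make_cv_groups(sprintf("S%03d", 1:161), 5, seed = 4)
  expect_equal(sort(lengths(g161$groups)), c(32, 32, 32, 32, 33))
  g10 <- make_cv_groups(sprintf("S%02d", 1:10), 5, seed = 5)
  expect_equal(lengths(g10$groups), rep(2L, 5))
  expect_error(make_cv_groups(c("a", "b"), 5), "fewer sires")
  # no sire in two groups, none lost
  expect_equal(sort(unlist(g161$groups)), sprintf("S%03d", 1:161))
})

test_that("the leakage guarantee holds on a simulated pedigree", {
  pop <- tiny_pop()
  ped <- pop$pedigree
  sires <- unique(ped$sire[ped$genetic_group %in% c("PB", "CB")])
  part <- make_cv_groups(sires, 5, seed = 6)
  cb_sires <- unique(ped$sire[ped$genetic_group == "CB"])
  cand <- ped$id[ped$genetic_group %in% c("PB", "CB")]
  expect_true(check_no_leakage(part, ped, cand, cb_sires))
  # and explicitly: per fold, reference and validation share no sires
  for (g in part$groups) {
    g_val <- intersect(g, cb_sires)
    ref <- ped$id[ped$genetic_group %in% c("PB", "CB") &
                    !(ped$sire %in% g_val)]
    val <- ped$id[ped$genetic_group == "CB" & ped$sire %in% g_val]
    expect_length(intersect(unique(ped$sire[ped$id %in% ref]),
                            unique(ped$sire[ped$id %in% val])), 0)
  }
})

test_that("reliability weights follow the offspring-mean formula", {
  expect_equal(reliability_weight(1, 0.2), 0.05)
  expect_equal(reliability_weight(10, 0.23), 0.575 / 1.5175)
  expect_equal(reliability_weight(1e9, 0.23), 1, tolerance = 1e-6)
  w <- reliability_weight(1:50, 0.18)
  expect_true(all(diff(w) > 0))
  expect_true(all(w > 0 & w < 1))
})

test_that("weighted correlation and regression match their formulas", {
  x <- c(1, 2, 3); y <- c(2, 4, 6); w <- c(1, 1, 2)
  expect_equal(weighted_correlation(x, y, w), 1)
  expect_equal(weighted_regression_bias(x, y, w, multiplier = 1), 2)
  # equal weights reduce to ordinary Pearson / OLS
  set.seed(30)
  a <- rnorm(40); b <- 0.5 * a + rnorm(40)
  expect_equal(weighted_correlation(a, b), cor(a, b))
  expect_equal(weighted_regression_bias(a, b),
               unname(coef(lm(b ~ a))[2]))
  # offspring averages at exactly half the sire breeding value: bias 1 after x2
  gebv <- rnorm(20)
  expect_equal(weighted_regression_bias(gebv, gebv / 2,
                                        w = runif(20, 0.2, 0.9),
                                        multiplier = 2), 1)
})

test_that("scale_validation_correlation applies the right denominator", {
  expect_equal(scale_validation_correlation(0.16, "individual",
                                            h2_cb = 0.2304), 1 / 3)
  expect_equal(scale_validation_correlation(0, "average",
                                            mean_reliability = 0.4), 0)
  expect_equal(scale_validation_correlation(0.25, "average",
                                            mean_reliability = 1), 0.25)
})

test_that("replicate summaries and win fractions behave", {
  res <- data.frame(replicate = rep(1:4, 2),
                    scenario = rep(c("CB-I", "CB-I-BOA"), each = 4),
                    trait = "BW7",
                    validation_correlation = c(rep(0.2, 4), rep(0.1, 4)),
                    regression_coefficient = 1, n_units = 10)
  s <- summarize_replicates(res)
  expect_equal(s$sd_correlation, c(0, 0))
  expect_equal(win_fraction(res, "CB-I", "CB-I-BOA", "BW7"), 1)
  expect_equal(win_fraction(res, "CB-I", "CB-I", "BW7"), 0.5)  # ties
  # Bernoulli(0.7) wins recovered from synthetic replicate pairs
  set.seed(33)
  n <- 400
  win <- rbinom(n, 1, 0.7)
  res2 <- data.frame(replicate = rep(1:n, 2),
                     scenario = rep(c("A", "B"), each = n), trait = "t",
                     validation_correlation = c(win, rep(0.5, n)),
                     regression_coefficient = 1, n_units = 1)
  res2$scenario[1:n] <- "A"
  wf <- win_fraction(res2, "A", "B", "t")
  expect_lt(abs(wf - 0.7), 3 * sqrt(0.7 * 0.3 / n))
})

test_that("offspring-average scenarios and the dam-line probe run end to
           end", {
  pop <- tiny_pop()
  data <- as_dataset(pop)
  ped <- data$pedigree
  data$phenotypes$sire_id <- ped$sire[match(data$phenotypes$animal_id,
                                            ped$id)]
  comp <- list(BW7 = list(sigma2_a = 0.18, sigma2_m = 0.10,
                          sigma2_e = 0.72))
  scomp <- list(BW7 = list(sigma2_s = 0.045, sigma2_m = 0.10,
                           sigma2_e = 0.855))
  res <- run_replicates(data, c("PB-A", "CB-A", "CB-A-BOA", "CB-A-DAM"),
                        n_replicates = 1, components = comp,
                        sire_components = scomp, base_seed = 11)
  expect_equal(nrow(res), 4)
  expect_true(all(is.finite(res$validation_correlation)))
  expect_true(all(abs(res$validation_correlation) <= 1))
  expect_true(all(is.finite(res$regression_coefficient)))
  # sire-GEBV validation counts sires, not offspring
  expect_true(all(res$n_units <= length(pop$sire_ids)))
})

test_that("scenario grid matches the design table", {
  s <- scenario_specs()
  expect_equal(nrow(s), 7)
  expect_equal(s$grm_kind[s$scenario == "CB-I-BOA"], "boa_sire")
  expect_equal(s$reference[s$scenario == "PB-A"], "PB")
  expect_equal(s$validation[s$scenario == "PB-I"], "individual")
  expect_error(scenario_specs("XX"), "unknown scenario")
})
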
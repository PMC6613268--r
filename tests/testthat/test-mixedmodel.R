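# Mixed models: design construction, Henderson-equation solutions against
# a dense GLS/BLUP oracle, candidate projection, EM-REML behaviour, and
# corrected phenotypes.

make_records <- function(n, ids, seed = 1, n_dams = 8, batches = 2) {
  set.seed(seed)
  data.frame(animal_id = ids,
             value = rnorm(n),
             batch = sample(seq_len(batches), n, TRUE),
             pen = sample(1:2, n, TRUE),
             sex = sample(c("M", "F"), n, TRUE),
             age = 7L,
             dam_id = sample(sprintf("D%02d", seq_len(n_dams)), n, TRUE),
             stringsAsFactors = FALSE)
}

test_that("design matrices have the stated structure", {
  ph <- make_records(30, sprintf("A%03d", 1:30), seed = 2)
  ph$batch <- 1; ph$pen <- 1; ph$sex <- "M"; ph$age <- 7
  d <- build_design(ph, grm_ids = ph$animal_id, model = "animal")
  expect_equal(d$p, 1)                     # single class = intercept column
  ph2 <- make_records(40, sprintf("A%03d", 1:40), seed = 3)
  ph2$pen <- 1; ph2$age <- 7
  d2 <- build_design(ph2, grm_ids = ph2$animal_id, model = "animal")
  expect_equal(d2$p, 4)                    # 2 batches x 2 sexes, fully crossed
  expect_equal(qr(d2$X)$rank, 4)
  # a dam with a single record still gets a maternal level
  expect_equal(d2$qm, nlevels(factor(ph2$dam_id)))
  # record whose animal is missing from the GRM index
  expect_error(build_design(ph2, grm_ids = ph2$animal_id[-1],
                            model = "animal"), "missing from")
})

test_that("MME solutions equal the dense GLS/BLUP oracle", {
  set.seed(7)
  n <- 150; qa <- 170
  ids <- sprintf("A%03d", seq_len(qa))
  geno <- random_geno(qa, 250, seed = 7)
  rownames(geno) <- ids
  G <- regularize(single_breed_grm(geno, colMeans(geno) / 2), 1e-3)
  ph <- make_records(n, ids[seq_len(n)], seed = 8, n_dams = 12)
  d <- build_design(ph, grm_ids = ids, model = "animal")
  cm <- list(sigma2_a = 0.3, sigma2_m = 0.1, sigma2_e = 0.6)
  fit <- solve_mme(d, G, cm)
  X <- d$X; y <- d$y
  L <- matrix(0, n, d$qm); L[cbind(1:n, as.integer(d$dam))] <- 1
  Z <- matrix(0, n, qa); Z[cbind(1:n, d$animal_index)] <- 1
  V <- Z %*% (G$mat * cm$sigma2_a) %*% t(Z) + tcrossprod(L) * cm$sigma2_m +
    diag(n) * cm$sigma2_e
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  a_or <- cm$sigma2_a * (G$mat %*% t(Z)) %*% Vi %*% r
  m_or <- cm$sigma2_m * t(L) %*% Vi %*% r
  expect_lt(max(abs(fit$b - b)), 1e-8)
  expect_lt(max(abs(fit$u - a_or)), 1e-8)
  expect_lt(max(abs(fit$m - m_or)), 1e-8)
  # restricted log-likelihood agrees with the direct V-based formula
  P <- Vi - Vi %*% X %*% solve(t(X) %*% Vi %*% X) %*% t(X) %*% Vi
  m2l <- (n - ncol(X)) * log(2 * pi) +
    as.numeric(determinant(V)$modulus) +
    as.numeric(determinant(t(X) %*% Vi %*% X)$modulus) +
    drop(t(y) %*% P %*% y)
  expect_equal(fit$logl, -0.5 * m2l, tolerance = 1e-8)
})

test_that("identity GRM reduces GEBV to ridge regression", {
  set.seed(10)
  n <- 5
  ids <- paste0("A", 1:n)
  y <- rnorm(5)
  ph <- data.frame(animal_id = ids, value = y, batch = 1, pen = 1,
                   sex = "M", age = 7, dam_id = "D1")
  G <- new_grm_for_test <- structure(
    list(mat = diag(n), ids = ids, kind = "single", denom = 1),
    class = "grm")
  rownames(G$mat) <- colnames(G$mat) <- ids
  cm <- list(sigma2_a = 0.5, sigma2_e = 1)
  d <- build_design(ph, grm_ids = ids, model = "animal")
  fit <- solve_mme(d, G, c(cm, list(sigma2_m = NULL)))
  lambda <- cm$sigma2_e / cm$sigma2_a
  # closed-form two-block inverse: intercept + ridge of animal indicators
  Xf <- cbind(1)
  Cm <- rbind(cbind(n, t(rep(1, n))), cbind(rep(1, n), diag(1 + lambda, n)))
  sol <- solve(Cm, c(sum(y), y))
  expect_equal(unname(fit$u), unname(sol[-1]), tolerance = 1e-10)
})

test_that("unphenotyped candidates get the projected GEBV", {
  set.seed(12)
  qa <- 60; n <- 45
  ids <- sprintf("A%03d", seq_len(qa))
  geno <- random_geno(qa, 200, seed = 12); rownames(geno) <- ids
  G <- regularize(single_breed_grm(geno, colMeans(geno) / 2), 1e-3)
  ph <- make_records(n, ids[seq_len(n)], seed = 13)
  d <- build_design(ph, grm_ids = ids, model = "animal")
  cm <- list(sigma2_a = 0.4, sigma2_m = 0.08, sigma2_e = 0.6)
  fit <- solve_mme(d, G, cm)
  ref <- ids[seq_len(n)]; cand <- ids[(n + 1):qa]
  proj <- G$mat[cand, ref] %*% solve(G$mat[ref, ref], fit$u[ref])
  expect_lt(max(abs(fit$u[cand] - proj)), 1e-8)
})

test_that("GEBV shrink to zero as the additive variance vanishes", {
  ids <- sprintf("A%02d", 1:20)
  geno <- random_geno(20, 100, seed = 14); rownames(geno) <- ids
  G <- regularize(single_breed_grm(geno, colMeans(geno) / 2), 1e-3)
  ph <- make_records(20, ids, seed = 15)
  d <- build_design(ph, grm_ids = ids, model = "animal")
  fit <- solve_mme(d, G, list(sigma2_a = 1e-10, sigma2_m = 0.1,
                              sigma2_e = 1))
  expect_lt(max(abs(fit$u)), 1e-6)
})

test_that("GEBV are invariant to batch-level shifts", {
  ids <- sprintf("A%02d", 1:40)
  geno <- random_geno(40, 150, seed = 16); rownames(geno) <- ids
  G <- regularize(single_breed_grm(geno, colMeans(geno) / 2), 1e-3)
  ph <- make_records(40, ids, seed = 17)
  d1 <- build_design(ph, grm_ids = ids, model = "animal")
  cm <- list(sigma2_a = 0.3, sigma2_m = 0.1, sigma2_e = 0.6)
  f1 <- solve_mme(d1, G, cm)
  ph2 <- ph
  ph2$value[ph2$batch == 1] <- ph2$value[ph2$batch == 1] + 100
  d2 <- build_design(ph2, grm_ids = ids, model = "animal")
  f2 <- solve_mme(d2, G, cm)
  expect_equal(f1$u, f2$u, tolerance = 1e-7)
})

test_that("EM-REML likelihood is monotone and both paths are consistent", {
  set.seed(18)
  n <- 200
  ids <- sprintf("A%03d", 1:n)
  geno <- random_geno(n, 300, seed = 18); rownames(geno) <- ids
  G <- regularize(single_breed_grm(geno, colMeans(geno) / 2), 1e-4)
  ch <- chol(G$mat * 0.3)
  dam <- sample(sprintf("D%02d", 1:25), n, TRUE)
  me <- stats::setNames(rnorm(25, 0, sqrt(0.1)), sprintf("D%02d", 1:25))
  y <- 1 + drop(rnorm(n) %*% ch) + me[dam] + rnorm(n, 0, sqrt(0.6))
  ph <- data.frame(animal_id = ids, value = y, batch = 1, pen = 1, sex = "M",
                   age = 7, dam_id = dam)
  d <- build_design(ph, grm_ids = ids, model = "animal")
  vc <- reml_estimate(d, G, tol = 1e-8, max_iter = 400)
  expect_true(all(diff(vc$logl_trace) > -1e-7))
  expect_true(vc$sigma2_a > 0 && vc$sigma2_e > 0 && vc$sigma2_m >= 0)
  expect_true(vc$h2 >= 0 && vc$h2 <= 1)
  # the final likelihood matches the general MME formula at the estimates
  fit <- solve_mme(d, G, list(sigma2_a = vc$sigma2_a, sigma2_m = vc$sigma2_m,
                              sigma2_e = vc$sigma2_e))
  expect_equal(vc$logl, fit$logl, tolerance = 1e-6)
})

test_that("maternal variance estimates hit the boundary when absent", {
  set.seed(19)
  n <- 300
  ids <- sprintf("A%03d", 1:n)
  geno <- random_geno(n, 300, seed = 19); rownames(geno) <- ids
  G <- regularize(single_breed_grm(geno, colMeans(geno) / 2), 1e-4)
  ch <- chol(G$mat * 0.3)
  y <- drop(rnorm(n) %*% ch) + rnorm(n, 0, sqrt(0.7))  # no maternal effect
  ph <- data.frame(animal_id = ids, value = y, batch = 1, pen = 1, sex = "M",
                   age = 7, dam_id = sample(sprintf("D%02d", 1:30), n, TRUE))
  d <- build_design(ph, grm_ids = ids, model = "animal")
  vc <- suppressWarnings(reml_estimate(d, G, tol = 1e-8, max_iter = 500))
  # true value 0: the estimate sits at the boundary up to sampling noise
  expect_lt(vc$sigma2_m, 0.06)
})

test_that("sire-model EM-REML recovers a planted sire variance", {
  set.seed(20)
  n <- 1500
  sire <- sample(sprintf("S%02d", 1:50), n, TRUE)
  dam <- sample(sprintf("D%03d", 1:150), n, TRUE)
  sv <- stats::setNames(rnorm(50, 0, sqrt(0.06)), sprintf("S%02d", 1:50))
  mv <- stats::setNames(rnorm(150, 0, sqrt(0.10)), sprintf("D%03d", 1:150))
  y <- sv[sire] + mv[dam] + rnorm(n, 0, sqrt(0.84))
  ph <- data.frame(animal_id = sprintf("A%04d", 1:n), value = y, batch = 1,
                   pen = 1, sex = "M", age = 35, dam_id = dam, sire_id = sire)
  d <- build_design(ph, model = "sire")
  vc <- suppressWarnings(reml_estimate(d, tol = 1e-7, max_iter = 300))
  expect_true(all(diff(vc$logl_trace) > -1e-7))
  expect_lt(abs(vc$sigma2_s - 0.06), 0.04)
  expect_lt(abs(vc$sigma2_e - 0.84), 0.08)
})

test_that("corrected phenotypes equal sire solution plus residual and are
           invariant to batch shifts", {
  set.seed(22)
  n <- 400
  sire <- sample(sprintf("S%02d", 1:30), n, TRUE)
  dam <- sample(sprintf("D%03d", 1:80), n, TRUE)
  sv <- stats::setNames(rnorm(30, 0, 0.3), sprintf("S%02d", 1:30))
  batch <- sample(1:3, n, TRUE)
  y <- c(0, 2, 5)[batch] + sv[sire] + rnorm(n)
  ph <- data.frame(animal_id = sprintf("A%04d", 1:n), trait = "T1",
                   value = y, batch = batch, pen = 1, sex = "M", age = 35,
                   dam_id = dam, sire_id = sire, stringsAsFactors = FALSE)
  cm <- list(sigma2_s = 0.09, sigma2_m = 0.01, sigma2_e = 1)
  yc <- corrected_phenotypes(ph, cm)
  d <- build_design(ph, model = "sire")
  fit <- solve_mme(d, components = cm)
  expect_equal(yc$y_corrected,
               unname(fit$u[as.integer(d$sire)] + fit$e), tolerance = 1e-9)
  # shifting one batch leaves corrected records unchanged
  ph2 <- ph; ph2$value[ph2$batch == 2] <- ph2$value[ph2$batch == 2] + 50
  yc2 <- corrected_phenotypes(ph2, cm)
  expect_equal(yc$y_corrected, yc2$y_corrected, tolerance = 1e-8)
  # sire means of corrected records track the sire solutions
  ybar <- tapply(yc$y_corrected, yc$sire_id, mean)
  expect_gt(cor(ybar[names(fit$u)], fit$u), 0.95)
})
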
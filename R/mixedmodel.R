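# GBLUP animal model  y = Xb + Lm + Za + e,  a ~ N(0, G sigma2_a),
# m ~ N(0, I sigma2_m), e ~ N(0, I sigma2_e); and the sire model
# y = Xb + Lm + Ts + e, s ~ N(0, I sigma2_s). Solutions come from
# Henderson's mixed-model equations; variance components from EM-REML.
# For the animal model with one record per animal the REML iterations run
# in the eigenbasis of G, where the additive block of the equations is
# diagonal and each iteration reduces to work on the (fixed + maternal)
# dimensions.

#' Build the design for the animal or sire model
#'
#' The fixed effect is the combined batch x pen x sex x age class (one
#' level per observed combination; a pivoted-QR check drops any confounded
#' columns deterministically). Maternal levels are the distinct dams with
#' records. For the animal model, additive levels are the GRM's animal
#' index and every record's animal must appear there; for the sire model, a
#' `sire_id` column is required.
#'
#' @param phenotypes Phenotype records (one trait): columns `animal_id`,
#'   `value`, `batch`, `pen`, `sex`, `age`, `dam_id`, and `sire_id` for the
#'   sire model.
#' @param grm_ids Animal index of the relationship matrix (animal model);
#'   may include unphenotyped candidates, which then receive GEBV.
#' @param model `"animal"` or `"sire"`.
#' @return A list of class `mm_design`.
#' @export
build_design <- function(phenotypes, grm_ids = NULL,
                         model = c("animal", "sire")) {
  model <- match.arg(model)
  ph <- phenotypes
  n <- nrow(ph)
  if (n == 0) stop("no records", call. = FALSE)
  combo <- interaction(ph$batch, ph$pen, ph$sex, ph$age, drop = TRUE)
  X <- .indicator(combo)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) X <- X[, qrx$pivot[seq_len(qrx$rank)], drop = FALSE]
  dam <- factor(ph$dam_id)
  d <- list(y = ph$value, X = X, n = n, p = ncol(X),
            dam = dam, qm = nlevels(dam), model = model,
            animal_id = as.character(ph$animal_id))
  if (model == "animal") {
    if (is.null(grm_ids)) stop("grm_ids required for the animal model",
                               call. = FALSE)
    ai <- match(d$animal_id, grm_ids)
    if (anyNA(ai))
      stop("records for animals missing from the relationship matrix: ",
           paste(utils::head(d$animal_id[is.na(ai)]), collapse = ", "),
           call. = FALSE)
    d$animal_index <- ai
    d$grm_ids <- grm_ids
  } else {
    if (is.null(ph$sire_id)) stop("sire_id column required for the sire model",
                                  call. = FALSE)
    d$sire <- factor(ph$sire_id)
    d$qs <- nlevels(d$sire)
  }
  class(d) <- "mm_design"
  d
}

# dense indicator (design) matrix of a factor, one column per level
.indicator <- function(fac) {
  out <- matrix(0, length(fac), nlevels(fac),
                dimnames = list(NULL, levels(fac)))
  out[cbind(seq_along(fac), as.integer(fac))] <- 1
  out
}

# t(F) %*% X (nlev x p) for the indicator matrix F of a factor, keeping
# rows for unobserved levels (all-zero) so candidate animals stay in the
# equations
.xt_fac <- function(X, fac) {
  X <- as.matrix(X)
  out <- matrix(0, nlevels(fac), ncol(X))
  rs <- rowsum(X, fac)
  out[match(rownames(rs), levels(fac)), ] <- rs
  out
}

#' Solve the mixed-model equations at given variance components
#'
#' Builds Henderson's equations for the design and solves them by Cholesky
#' factorization. Unphenotyped animals present in the relationship matrix
#' receive GEBV through their genomic covariances with the phenotyped
#' animals. The returned log-likelihood is the restricted likelihood at the
#' supplied components.
#'
#' @param design An `mm_design` from [build_design()].
#' @param grm A `grm` object covering `design$grm_ids` (animal model);
#'   ignored for the sire model.
#' @param components List with `sigma2_e` and, as applicable, `sigma2_a`,
#'   `sigma2_m`, `sigma2_s`; set `sigma2_m = NULL` to omit the maternal
#'   term.
#' @return List of class `mme_fit`: `b` (fixed-effect solutions), `m`
#'   (maternal), `u` (GEBV for every GRM animal, or sire solutions), `e`
#'   (residuals), `logl`, `components`.
#' @export
solve_mme <- function(design, grm = NULL, components) {
  stopifnot(inherits(design, "mm_design"))
  cm <- components
  if (is.null(cm$sigma2_e) || cm$sigma2_e <= 0)
    stop("sigma2_e must be positive", call. = FALSE)
  use_m <- !is.null(cm$sigma2_m) && design$qm > 0
  if (use_m && cm$sigma2_m <= 0) stop("sigma2_m must be positive", call. = FALSE)
  y <- design$y; X <- design$X; n <- design$n; p <- design$p
  if (design$model == "animal") {
    if (is.null(grm)) stop("grm required for the animal model", call. = FALSE)
    if (is.null(cm$sigma2_a) || cm$sigma2_a <= 0)
      stop("sigma2_a must be positive", call. = FALSE)
    qa <- length(design$grm_ids)
    G <- grm$mat
    if (!identical(grm$ids, design$grm_ids))
      G <- G[design$grm_ids, design$grm_ids]
    ch <- tryCatch(chol(G), error = function(e)
      stop("relationship matrix is not positive definite; regularize() it ",
           "first (", conditionMessage(e), ")", call. = FALSE))
    Ginv <- chol2inv(ch)
    ldetG <- 2 * sum(log(diag(ch)))
    ui <- design$animal_index
    ku <- cm$sigma2_e / cm$sigma2_a
    qu <- qa
  } else {
    if (is.null(cm$sigma2_s) || cm$sigma2_s <= 0)
      stop("sigma2_s must be positive", call. = FALSE)
    qu <- design$qs
    ui <- as.integer(design$sire)
    Ginv <- NULL
    ldetG <- 0
    ku <- cm$sigma2_e / cm$sigma2_s
  }
  km <- if (use_m) cm$sigma2_e / cm$sigma2_m else NULL
  qm <- if (use_m) design$qm else 0L
  di <- if (use_m) as.integer(design$dam) else NULL

  dim_c <- p + qm + qu
  C <- matrix(0, dim_c, dim_c)
  rhs <- numeric(dim_c)
  iF <- seq_len(p); iM <- p + seq_len(qm); iU <- p + qm + seq_len(qu)
  C[iF, iF] <- crossprod(X)
  rhs[iF] <- crossprod(X, y)
  cnt_u <- tabulate(ui, qu)
  if (use_m) {
    fm <- factor(di, levels = seq_len(qm))
    XtL <- t(rowsum(X, fm))                     # p x qm
    C[iF, iM] <- XtL; C[iM, iF] <- t(XtL)
    C[iM, iM] <- diag(tabulate(di, qm), qm)
    rhs[iM] <- as.numeric(rowsum(y, fm))
    LtZ <- matrix(0, qm, qu)
    tt <- table(factor(di, levels = seq_len(qm)),
                factor(ui, levels = seq_len(qu)))
    LtZ[] <- tt
    C[iM, iU] <- LtZ; C[iU, iM] <- t(LtZ)
    C[iM, iM] <- C[iM, iM] + diag(km, qm)
  }
  fu <- factor(ui, levels = seq_len(qu))
  XtZ <- t(.xt_fac(X, fu))                      # p x qu; candidate columns 0
  C[iF, iU] <- XtZ; C[iU, iF] <- t(XtZ)
  C[iU, iU] <- diag(cnt_u, qu) + if (is.null(Ginv)) diag(ku, qu) else ku * Ginv
  rhs[iU] <- .xt_fac(y, fu)
  chC <- tryCatch(chol(C), error = function(e)
    stop("mixed-model equations are singular: ", conditionMessage(e),
         call. = FALSE))
  sol <- backsolve(chC, backsolve(chC, rhs, transpose = TRUE))
  b <- stats::setNames(sol[iF], colnames(X))
  mhat <- if (use_m) stats::setNames(sol[iM], levels(design$dam)) else NULL
  u <- sol[iU]
  names(u) <- if (design$model == "animal") design$grm_ids
              else levels(design$sire)
  fitted <- as.numeric(X %*% b) + (if (use_m) mhat[di] else 0) + u[ui]
  e <- y - fitted
  ldetC <- 2 * sum(log(diag(chC)))
  se <- cm$sigma2_e
  ypy <- (sum(y^2) - sum(sol * rhs)) / se
  ldetGplus <- ldetG + qu * log(if (design$model == "animal") cm$sigma2_a
                                else cm$sigma2_s) +
    (if (use_m) qm * log(cm$sigma2_m) else 0)
  m2l <- (n - p) * log(2 * pi) + n * log(se) + ldetGplus +
    (ldetC - dim_c * log(se)) + ypy
  structure(list(b = b, m = mhat, u = u, e = as.numeric(e),
                 logl = -0.5 * m2l, components = cm, model = design$model),
            class = "mme_fit")
}

#' EM-REML variance-component estimation
#'
#' Expectation-maximization REML for the animal model (additive, maternal,
#' residual) or the sire model (sire, maternal, residual). Iterations stop
#' when the change in restricted log-likelihood falls below `tol` or after
#' `max_iter` iterations (then the best iterate is returned with a
#' warning). The EM updates cannot decrease the restricted likelihood. For
#' the animal model each record's animal must be distinct; the iterations
#' then run in the eigenbasis of the (record-subsetted) relationship
#' matrix, where the additive equations are diagonal.
#'
#' @param design An `mm_design`.
#' @param grm A `grm` object (animal model).
#' @param init Optional list of starting values (`sigma2_a`/`sigma2_s`,
#'   `sigma2_m`, `sigma2_e`); default splits the phenotypic variance.
#' @param max_iter Maximum EM iterations (default 500).
#' @param tol Convergence tolerance on the log-likelihood change
#'   (default 1e-8).
#' @param maternal Include the maternal permanent-environment term
#'   (default TRUE when dams are present).
#' @return List of class `varcomp`: the component estimates, `h2`
#'   (`sigma2_a / (sigma2_a + sigma2_m + sigma2_e)` for the animal model),
#'   `logl`, `logl_trace`, `iterations`, `converged`.
#' @export
reml_estimate <- function(design, grm = NULL, init = NULL, max_iter = 500L,
                          tol = 1e-8, maternal = design$qm > 0) {
  stopifnot(inherits(design, "mm_design"))
  if (design$model == "animal") {
    .reml_animal_eigen(design, grm, init, max_iter, tol, maternal)
  } else {
    .reml_sire_dense(design, init, max_iter, tol, maternal)
  }
}

.reml_animal_eigen <- function(design, grm, init, max_iter, tol, maternal) {
  if (is.null(grm)) stop("grm required for the animal model", call. = FALSE)
  n <- design$n; p <- design$p
  ids <- design$animal_id
  if (anyDuplicated(ids))
    stop("animal-model REML requires one record per animal", call. = FALSE)
  G <- grm$mat[ids, ids]
  eg <- eigen(G, symmetric = TRUE)
  d <- pmax(eg$values, 1e-8)   # floor keeps the rotated system definite
  U <- eg$vectors
  y <- design$y; X <- design$X
  yt <- crossprod(U, y)[, 1]
  Xt <- crossprod(U, X)
  qm <- if (maternal) design$qm else 0L
  if (maternal) {
    L <- .indicator(design$dam)
    Lt <- crossprod(U, L)
    C1a <- t(cbind(Xt, Lt))            # (p+qm) x n
    C11f <- rbind(cbind(crossprod(X), t(rowsum(X, design$dam))),
                  cbind(rowsum(X, design$dam),
                        diag(as.numeric(table(design$dam)), qm)))
    rhs1 <- c(crossprod(X, y), rowsum(y, design$dam))
  } else {
    C1a <- t(Xt)
    C11f <- crossprod(X)
    rhs1 <- as.numeric(crossprod(X, y))
  }
  yty <- sum(y^2)
  vp <- stats::var(y)
  sa <- init$sigma2_a %||% (0.3 * vp)
  sm <- if (maternal) init$sigma2_m %||% (0.1 * vp) else NULL
  se <- init$sigma2_e %||% (vp - sa - (sm %||% 0))
  if (se <= 0) se <- 0.5 * vp
  trace <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  iM <- p + seq_len(qm)
  for (it in seq_len(max_iter)) {
    ka <- se / sa
    Da <- 1 + ka / d
    A <- sweep(C1a, 2, Da, "/")
    C11 <- C11f
    if (maternal) C11[iM, iM] <- C11[iM, iM] + diag(se / sm, qm)
    S <- C11 - tcrossprod(A, C1a)
    chS <- chol(S)
    Sinv <- chol2inv(chS)
    x1 <- Sinv %*% (rhs1 - A %*% yt)
    alpha <- (yt - as.numeric(crossprod(C1a, x1))) / Da
    # E-step traces
    tr_caa <- sum(1 / (d * Da)) +
      sum(Sinv * (C1a %*% (t(C1a) / (d * Da^2))))
    ssq_fit <- sum(x1 * rhs1) + sum(alpha * yt)
    se_new <- (yty - ssq_fit) / (n - p)
    sa_new <- (sum(alpha^2 / d) + se * tr_caa) / n
    if (maternal) {
      mhat <- x1[iM]
      tr_cmm <- sum(diag(Sinv)[iM])
      sm_new <- max((sum(mhat^2) + se * tr_cmm) / qm, 1e-12)
    }
    # restricted log-likelihood at the current (pre-update) components
    m2l <- (n - p) * log(2 * pi) + sum(log(d * sa)) +
      (if (maternal) qm * log(sm) else 0) + n * log(se) +
      (sum(log(Da)) + 2 * sum(log(diag(chS)))) - (p + qm + n) * log(se) +
      (yty - ssq_fit) / se
    ll <- -0.5 * m2l
    trace <- c(trace, ll)
    if (is.finite(prev) && abs(ll - prev) < tol) { converged <- TRUE; break }
    prev <- ll
    sa <- max(sa_new, 1e-12); se <- max(se_new, 1e-12)
    if (maternal) sm <- sm_new
  }
  if (!converged)
    warning("EM-REML did not converge in ", max_iter,
            " iterations; returning the last iterate")
  h2 <- sa / (sa + (sm %||% 0) + se)
  structure(list(sigma2_a = sa, sigma2_m = sm, sigma2_e = se, h2 = h2,
                 logl = trace[length(trace)], logl_trace = trace,
                 iterations = length(trace), converged = converged,
                 model = "animal"),
            class = "varcomp")
}

.reml_sire_dense <- function(design, init, max_iter, tol, maternal) {
  n <- design$n; p <- design$p
  y <- design$y; X <- design$X
  qs <- design$qs
  qm <- if (maternal) design$qm else 0L
  si <- as.integer(design$sire)
  di <- if (maternal) as.integer(design$dam) else NULL
  dim_c <- p + qm + qs
  iF <- seq_len(p); iM <- p + seq_len(qm); iS <- p + qm + seq_len(qs)
  Cf <- matrix(0, dim_c, dim_c)
  rhs <- numeric(dim_c)
  Cf[iF, iF] <- crossprod(X); rhs[iF] <- crossprod(X, y)
  fs <- factor(si, levels = seq_len(qs))
  if (maternal) {
    fm <- design$dam
    Cf[iF, iM] <- t(rowsum(X, fm)); Cf[iM, iF] <- t(Cf[iF, iM])
    Cf[iM, iM] <- diag(as.numeric(table(fm)), qm)
    rhs[iM] <- rowsum(y, fm)
    tt <- table(fm, fs)
    Cf[iM, iS] <- tt; Cf[iS, iM] <- t(tt)
  }
  Cf[iF, iS] <- t(rowsum(X, fs)); Cf[iS, iF] <- t(Cf[iF, iS])
  Cf[iS, iS] <- diag(tabulate(si, qs), qs)
  rhs[iS] <- rowsum(y, fs)
  yty <- sum(y^2)
  vp <- stats::var(y)
  ss <- init$sigma2_s %||% (0.1 * vp)
  sm <- if (maternal) init$sigma2_m %||% (0.1 * vp) else NULL
  se <- init$sigma2_e %||% (vp - ss - (sm %||% 0))
  if (se <= 0) se <- 0.5 * vp
  trace <- numeric(0); prev <- -Inf; converged <- FALSE
  for (it in seq_len(max_iter)) {
    C <- Cf
    if (maternal) C[iM, iM] <- C[iM, iM] + diag(se / sm, qm)
    C[iS, iS] <- C[iS, iS] + diag(se / ss, qs)
    chC <- chol(C)
    Cinv <- chol2inv(chC)
    sol <- Cinv %*% rhs
    ssq_fit <- sum(sol * rhs)
    shat <- sol[iS]
    se_new <- (yty - ssq_fit) / (n - p)
    ss_new <- (sum(shat^2) + se * sum(diag(Cinv)[iS])) / qs
    if (maternal) {
      mhat <- sol[iM]
      sm_new <- max((sum(mhat^2) + se * sum(diag(Cinv)[iM])) / qm, 1e-12)
    }
    m2l <- (n - p) * log(2 * pi) + qs * log(ss) +
      (if (maternal) qm * log(sm) else 0) + n * log(se) +
      (2 * sum(log(diag(chC))) - dim_c * log(se)) + (yty - ssq_fit) / se
    ll <- -0.5 * m2l
    trace <- c(trace, ll)
    if (is.finite(prev) && abs(ll - prev) < tol) { converged <- TRUE; break }
    prev <- ll
    ss <- max(ss_new, 1e-12); se <- max(se_new, 1e-12)
    if (maternal) sm <- sm_new
  }
  if (!converged)
    warning("EM-REML did not converge in ", max_iter,
            " iterations; returning the last iterate")
  structure(list(sigma2_s = ss, sigma2_m = sm, sigma2_e = se,
                 logl = trace[length(trace)], logl_trace = trace,
                 iterations = length(trace), converged = converged,
                 model = "sire"),
            class = "varcomp")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Corrected phenotypes from the sire model
#'
#' Fits the sire model to all available crossbred phenotypes of one trait
#' and returns records corrected for the systematic environmental effects:
#' `y_c = y - X b_hat - L m_hat`, which equals the sire solution plus the
#' residual for each record. Fitted once per trait on the full crossbred
#' data, not per replicate.
#'
#' @param phenotypes Crossbred phenotype records of one trait, with a
#'   `sire_id` column (merge from the pedigree if needed).
#' @param components Sire-model variance components (`sigma2_s`,
#'   `sigma2_m`, `sigma2_e`), e.g. from [reml_estimate()]; NULL estimates
#'   them here.
#' @param ... Passed to [reml_estimate()] when `components` is NULL.
#' @return Data frame `animal_id`, `sire_id`, `trait`, `y_corrected`.
#' @export
corrected_phenotypes <- function(phenotypes, components = NULL, ...) {
  if (length(unique(phenotypes$trait)) > 1)
    stop("corrected_phenotypes expects records of a single trait",
         call. = FALSE)
  design <- build_design(phenotypes, model = "sire")
  if (is.null(components)) components <- reml_estimate(design, ...)
  fit <- solve_mme(design, components = components)
  yc <- design$y - as.numeric(design$X %*% fit$b) -
    (if (!is.null(fit$m)) fit$m[as.integer(design$dam)] else 0)
  data.frame(animal_id = phenotypes$animal_id,
             sire_id = phenotypes$sire_id,
             trait = phenotypes$trait,
             y_corrected = as.numeric(yc),
             stringsAsFactors = FALSE)
}
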
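# NIPALS latent-variable models: PCA (missing-tolerant), two-class PLS-DA,
# OPLS-DA, VIP, cross-validated Q2, permutation testing and a PRESS-based
# CV-ANOVA. All inputs are expected column-centered (and scaled); see
# scale_for_model().

# Encode a two-class response as a centered 0/1 dummy.
encode_y <- function(y) {
  f <- factor(y)
  if (nlevels(f) != 2L)
    stopf("response must have exactly 2 classes, got %d", nlevels(f))
  yn <- as.numeric(f) - 1
  list(y = yn - mean(yn), levels = levels(f), mean = mean(yn), raw = yn)
}

#' NIPALS principal component analysis
#'
#' Iterative NIPALS with missing-value skipping: each weight/score update
#' uses only observed cells, so moderately incomplete matrices are handled
#' without imputation. Components are ordered by decreasing explained
#' variance; the sign convention makes the largest-magnitude loading entry
#' positive.
#'
#' @param X centered (and scaled) numeric matrix; `NA` allowed
#' @param A number of components, `<= min(dim(X)) - 1`
#' @param tol relative convergence tolerance on the score vector
#' @param max_iter maximum NIPALS iterations per component
#' @return a `latent_model` with scores `T`, loadings `P`, per-component
#'   explained variance `R2X_per_component` and total `R2X`
#' @export
fit_pca <- function(X, A, tol = 1e-12, max_iter = 2000L) {
  X <- as.matrix(X)
  if (A > min(dim(X)) - 1L) stopf("A must be <= min(dim(X)) - 1")
  M <- !is.na(X)
  X0 <- X; X0[!M] <- 0
  ss_tot <- sum(X0^2)
  Tm <- matrix(0, nrow(X), A); P <- matrix(0, ncol(X), A)
  r2 <- numeric(A)
  Mnum <- 1 * M
  for (a in seq_len(A)) {
    j0 <- which.max(colSums(X0^2))
    t <- X0[, j0]
    if (all(t == 0)) stopf("component %d: residual matrix is zero", a)
    for (it in seq_len(max_iter)) {
      p <- crossprod(X0, t) / crossprod(Mnum, t^2)
      p[!is.finite(p)] <- 0
      p <- p / sqrt(sum(p^2))
      t_new <- (X0 %*% p) / (Mnum %*% p^2)
      t_new[!is.finite(t_new)] <- 0
      if (sqrt(sum((t_new - t)^2)) < tol * sqrt(sum(t_new^2) + 1e-300)) {
        t <- as.numeric(t_new); break
      }
      t <- as.numeric(t_new)
      if (it == max_iter)
        stopf("NIPALS PCA did not converge for component %d", a)
    }
    jmax <- which.max(abs(p))
    if (p[jmax] < 0) { p <- -p; t <- -t }
    ss_before <- sum(X0^2)
    X0 <- X0 - (t %*% t(p)) * Mnum
    r2[a] <- (ss_before - sum(X0^2)) / ss_tot
    Tm[, a] <- t; P[, a] <- as.numeric(p)
  }
  o <- order(r2, decreasing = TRUE)
  structure(list(kind = "pca", A = A, T = Tm[, o, drop = FALSE],
                 P = P[, o, drop = FALSE], R2X_per_component = r2[o],
                 R2X = sum(r2)),
            class = "latent_model")
}

#' Two-class PLS-DA by NIPALS PLS1
#'
#' The group factor is encoded as a centered 0/1 dummy and regressed on X
#' by NIPALS PLS1 with X- and y-deflation. Weight vectors are unit-norm and
#' score vectors mutually orthogonal.
#'
#' @param X centered/scaled complete matrix
#' @param y two-class factor (or vector coercible to one)
#' @param A number of predictive components
#' @return a `latent_model` with weights `W`, loadings `P`, scores `T`,
#'   y-loadings `C`, per-component y-variance `SS_y`, `R2X`, `R2Y`,
#'   regression coefficients `B` and the response encoding
#' @export
fit_plsda <- function(X, y, A) {
  X <- as.matrix(X)
  if (anyNA(X)) stopf("fit_plsda requires complete data (impute or use fit_pca)")
  enc <- encode_y(y)
  yc <- enc$y
  n <- nrow(X); p <- ncol(X)
  if (A > min(n - 1L, p)) stopf("A must be <= min(n - 1, p)")
  E <- X; f <- yc
  W <- matrix(0, p, A); P <- matrix(0, p, A); Tm <- matrix(0, n, A)
  cvec <- numeric(A); ss_y <- numeric(A); r2x <- numeric(A)
  ssx_tot <- sum(X^2); ssy_tot <- sum(yc^2)
  for (a in seq_len(A)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-300) stopf("component %d: response residual uncorrelated with X", a)
    w <- w / nw
    t <- as.numeric(E %*% w)
    tt <- sum(t^2)
    cc <- sum(t * f) / tt
    pv <- crossprod(E, t) / tt
    E <- E - t %*% t(pv)
    f <- f - t * cc
    W[, a] <- w; P[, a] <- pv; Tm[, a] <- t; cvec[a] <- cc
    ss_y[a] <- cc^2 * tt
    r2x[a] <- tt * sum(pv^2) / ssx_tot
  }
  yfit <- as.numeric(Tm %*% cvec)
  R2Y <- 1 - sum((yc - yfit)^2) / ssy_tot
  # B: X-coefficients such that yc_hat = X %*% B
  B <- W %*% solve(crossprod(P, W), cvec)
  structure(list(kind = "plsda", A = A, W = W, P = P, T = Tm, C = cvec,
                 SS_y = ss_y, R2X = sum(r2x), R2X_per_component = r2x,
                 R2Y = R2Y, B = as.numeric(B),
                 y_levels = enc$levels, y_mean = enc$mean),
            class = "latent_model")
}

#' Predict the (uncoded) response for new scaled rows
#' @param object a plsda `latent_model`
#' @param newdata matrix on the same scale as the training X
#' @param ... unused
#' @return numeric predictions on the 0/1 dummy scale
#' @export
predict.latent_model <- function(object, newdata, ...) {
  if (is.null(object$B)) stopf("model has no regression coefficients")
  as.numeric(as.matrix(newdata) %*% object$B) + object$y_mean
}

#' Two-class OPLS-DA
#'
#' Iteratively extracts `n_orthogonal` components orthogonal to the
#' response from the PLS weight structure, deflates X, then fits a single
#' predictive component. With `n_orthogonal = 0` the model equals
#' `fit_plsda(X, y, A = 1)` exactly.
#'
#' @param X centered/scaled complete matrix
#' @param y two-class factor
#' @param n_orthogonal number of orthogonal components (>= 0, < rank(X))
#' @return a `latent_model` of kind `"oplsda"`; predictive score in `T`,
#'   orthogonal scores in `T_ortho`
#' @export
fit_oplsda <- function(X, y, n_orthogonal = 1L) {
  X <- as.matrix(X)
  if (anyNA(X)) stopf("fit_oplsda requires complete data")
  rk <- qr(X)$rank
  if (n_orthogonal >= rk)
    stopf("n_orthogonal (%d) must be < rank(X) (%d)", n_orthogonal, rk)
  enc <- encode_y(y)
  yc <- enc$y
  n <- nrow(X); p <- ncol(X)
  E <- X
  Wo <- matrix(0, p, n_orthogonal); Po <- matrix(0, p, n_orthogonal)
  To <- matrix(0, n, n_orthogonal)
  for (k in seq_len(n_orthogonal)) {
    w <- crossprod(E, yc); w <- w / sqrt(sum(w^2))
    t <- as.numeric(E %*% w)
    pv <- crossprod(E, t) / sum(t^2)
    wo <- pv - as.numeric(crossprod(w, pv)) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12)
      stopf("orthogonal component %d: no systematic orthogonal variation left", k)
    wo <- wo / nwo
    to <- as.numeric(E %*% wo)
    po <- crossprod(E, to) / sum(to^2)
    E <- E - to %*% t(po)
    Wo[, k] <- wo; Po[, k] <- po; To[, k] <- to
  }
  core <- fit_plsda(E, y, A = 1L)
  structure(list(kind = "oplsda", A = 1L, n_orthogonal = n_orthogonal,
                 W = core$W, P = core$P, T = core$T, C = core$C,
                 SS_y = core$SS_y, R2Y = core$R2Y, R2X = core$R2X,
                 W_ortho = Wo, P_ortho = Po, T_ortho = To,
                 B = core$B, y_levels = core$y_levels, y_mean = core$y_mean),
            class = "latent_model")
}

#' Variable importance in projection
#'
#' `VIP_j = sqrt(p * sum_a SS_a w_ja^2 / sum_a SS_a)` with unit-norm weight
#' vectors and `SS_a` the response variance explained by component `a`.
#' The mean of `VIP^2` over features is exactly 1. For OPLS-DA only the
#' predictive component enters.
#'
#' @param model a plsda or oplsda `latent_model`
#' @return named numeric vector of VIPs
#' @export
compute_vip <- function(model) {
  if (!inherits(model, "latent_model") || model$kind == "pca")
    stopf("VIP is defined for plsda/oplsda models")
  W <- model$W; ss <- model$SS_y
  p <- nrow(W)
  w2 <- sweep(W^2, 2L, colSums(W^2), "/")  # guard: weights are unit-norm already
  vip <- sqrt(p * as.numeric(w2 %*% ss) / sum(ss))
  stats::setNames(vip, rownames(W))
}

# Stratified fold assignment: within each class, shuffle and deal
# round-robin. Returns an integer fold id per sample.
make_folds <- function(y, n_folds, seed) {
  f <- factor(y)
  for (attempt in seq_len(10L)) {
    fold <- integer(length(y))
    with_seed(child_seed(seed, attempt - 1L), {
      for (lv in levels(f)) {
        idx <- which(f == lv)
        fold[idx] <- (sample(seq_along(idx)) %% n_folds) + 1L
      }
    })
    ok <- all(vapply(seq_len(n_folds), function(k)
      nlevels(droplevels(f[fold != k])) == 2L, logical(1)))
    if (ok) return(fold)
  }
  stopf("could not build %d folds retaining both classes", n_folds)
}

#' Cross-validated Q2 of a PLS-DA model
#'
#' Stratified random folds; each training fold is re-centered and
#' re-scaled (unit variance) and its model predicts the held-out samples,
#' accumulating PRESS. `Q2 = 1 - PRESS / SS_tot`.
#'
#' @param X unscaled (or scaled; it is re-scaled per fold) complete matrix
#'   of study rows
#' @param y two-class factor
#' @param A number of components
#' @param n_folds number of folds (>= 2)
#' @param seed fold-assignment seed
#' @param scale_mode `"unit_variance"`, `"pareto"` or `"none"`
#' @return a `validation_result` with `Q2`, `PRESS`, `SS_tot`, per-fold
#'   PRESS, per-sample held-out residuals and the fold assignment
#' @export
cross_validate <- function(X, y, A, n_folds = 7L, seed = 1L,
                           scale_mode = c("unit_variance", "pareto", "none")) {
  scale_mode <- match.arg(scale_mode)
  X <- as.matrix(X)
  if (n_folds < 2L) stopf("n_folds must be >= 2")
  enc <- encode_y(y)
  yn <- enc$raw
  fold <- make_folds(y, n_folds, seed)
  resid <- numeric(length(yn))
  press_fold <- numeric(n_folds)
  for (k in seq_len(n_folds)) {
    tr <- fold != k; te <- !tr
    if (!any(te)) next
    ctr <- colMeans(X[tr, , drop = FALSE])
    scl <- switch(scale_mode,
                  unit_variance = apply(X[tr, , drop = FALSE], 2L, stats::sd),
                  pareto = sqrt(apply(X[tr, , drop = FALSE], 2L, stats::sd)),
                  none = rep(1, ncol(X)))
    scl[!is.finite(scl) | scl == 0] <- 1
    Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2L, ctr, "-"), 2L, scl, "/")
    Xte <- sweep(sweep(X[te, , drop = FALSE], 2L, ctr, "-"), 2L, scl, "/")
    Atr <- min(A, nrow(Xtr) - 1L, ncol(Xtr))
    m <- fit_plsda(Xtr, y[tr], Atr)
    pred <- as.numeric(Xte %*% m$B) + mean(yn[tr])
    resid[te] <- yn[te] - pred
    press_fold[k] <- sum((yn[te] - pred)^2)
  }
  press <- sum(press_fold)
  ss_tot <- sum((yn - mean(yn))^2)
  structure(list(Q2 = 1 - press / ss_tot, PRESS = press, SS_tot = ss_tot,
                 press_per_fold = press_fold, residuals = resid,
                 folds = fold, n = length(yn), A = A, seed = seed),
            class = "validation_result")
}

#' Permutation test of a PLS-DA model
#'
#' Relabels `y` `n_permutations` times, recomputes the cross-validated Q2
#' (and full-fit R2Y) each time, and reports the add-one permutation
#' p-value `p = (1 + #\{Q2_perm >= Q2_obs\}) / (n_permutations + 1)`.
#'
#' @inheritParams cross_validate
#' @param n_permutations number of relabelings (>= 1)
#' @return a `validation_result` with observed `Q2`, null distributions
#'   `Q2_null` and `R2Y_null`, and `p_value`
#' @export
permutation_test <- function(X, y, A, n_permutations = 200L, seed = 1L,
                             n_folds = 7L,
                             scale_mode = c("unit_variance", "pareto", "none")) {
  scale_mode <- match.arg(scale_mode)
  if (n_permutations < 1L) stopf("n_permutations must be >= 1")
  obs <- cross_validate(X, y, A, n_folds, seed, scale_mode)
  q2_null <- numeric(n_permutations)
  r2_null <- numeric(n_permutations)
  sc <- scale_matrix_simple(X, scale_mode)
  for (b in seq_len(n_permutations)) {
    yp <- with_seed(child_seed(seed, b), sample(as.character(y)))
    cvp <- cross_validate(X, yp, A, n_folds, child_seed(seed, b + n_permutations),
                          scale_mode)
    q2_null[b] <- cvp$Q2
    r2_null[b] <- fit_plsda(sc, yp, min(A, nrow(X) - 1L, ncol(X)))$R2Y
  }
  p <- (1 + sum(q2_null >= obs$Q2)) / (n_permutations + 1)
  structure(list(Q2 = obs$Q2, PRESS = obs$PRESS, SS_tot = obs$SS_tot,
                 Q2_null = q2_null, R2Y_null = r2_null, p_value = p,
                 n_permutations = n_permutations, n = obs$n, A = A),
            class = "validation_result")
}

scale_matrix_simple <- function(X, mode) {
  ctr <- colMeans(X)
  scl <- switch(mode, unit_variance = apply(X, 2L, stats::sd),
                pareto = sqrt(apply(X, 2L, stats::sd)),
                none = rep(1, ncol(X)))
  scl[!is.finite(scl) | scl == 0] <- 1
  sweep(sweep(X, 2L, ctr, "-"), 2L, scl, "/")
}

#' PRESS-based CV-ANOVA
#'
#' `F = ((SS_tot - PRESS)/A) / (PRESS/(n - A - 1))`, referred to an
#' F(A, n - A - 1) distribution; an approximation to the cross-validated
#' ANOVA used with PLS models. Negative numerators clamp F at 0 (p = 1).
#'
#' @param result a `validation_result` from [cross_validate()]
#' @param n number of samples (defaults to the stored value)
#' @param A number of components (defaults to the stored value)
#' @return list with `F`, `df1`, `df2`, `p_value`
#' @export
cv_anova <- function(result, n = result$n, A = result$A) {
  df1 <- A; df2 <- n - A - 1L
  if (df2 <= 0L) stopf("cv_anova needs n - A - 1 > 0")
  Fv <- max(0, ((result$SS_tot - result$PRESS) / df1) / (result$PRESS / df2))
  list(F = Fv, df1 = df1, df2 = df2,
       p_value = stats::pf(Fv, df1, df2, lower.tail = FALSE))
}

#' Choose the number of PLS components by incremental Q2
#'
#' Returns the largest `A <= A_max` whose Q2 improves on the previous
#' component's (with Q2 at zero components taken as 0); at least 1.
#'
#' @inheritParams cross_validate
#' @param A_max maximum components considered (default 5)
#' @return integer number of components
#' @export
select_components <- function(X, y, A_max = 5L, n_folds = 7L, seed = 1L,
                              scale_mode = "unit_variance") {
  A_max <- min(A_max, nrow(X) - 2L, ncol(X))
  q_prev <- 0; A_sel <- 1L
  for (a in seq_len(A_max)) {
    q <- cross_validate(X, y, a, n_folds, seed, scale_mode)$Q2
    if (a == 1L || q > q_prev) { A_sel <- a; q_prev <- q } else break
  }
  A_sel
}
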
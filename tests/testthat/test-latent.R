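# NIPALS PCA / PLS-DA / OPLS-DA, VIP, cross-validation, permutation test
# and CV-ANOVA.

scaled_gauss <- function(n, p, seed) {
  set.seed(seed)
  scale(matrix(rnorm(n * p), n, p), scale = FALSE)
}

test_that("NIPALS PCA matches an eigendecomposition oracle on complete data", {
  X <- scaled_gauss(30, 8, 1)
  m <- fit_pca(X, A = 4)
  sv <- svd(X)
  for (a in 1:4) {
    # up to sign
    s <- sign(sum(m$P[, a] * sv$v[, a]))
    expect_lt(max(abs(m$P[, a] - s * sv$v[, a])), 1e-8)
    expect_lt(max(abs(m$T[, a] - s * sv$u[, a] * sv$d[a])), 1e-8)
  }
  # explained variance ordered and consistent with singular values
  expect_equal(m$R2X_per_component, sv$d[1:4]^2 / sum(sv$d^2), tolerance = 1e-8)
  # scores mutually orthogonal
  G <- crossprod(m$T)
  expect_lt(max(abs(G[upper.tri(G)])) /
              max(diag(G)), 1e-8)
})

test_that("PCA handles rank-1 and missing-data cases", {
  # rank 1: one component explains everything
  set.seed(2)
  u <- rnorm(25); v <- rnorm(6)
  X1 <- u %*% t(v)
  m1 <- fit_pca(X1, A = 1)
  expect_gte(m1$R2X, 1 - 1e-10)

  # 5% missing from a rank-2 matrix: recovered subspace within 2 degrees
  set.seed(3)
  U <- matrix(rnorm(80 * 2), 80, 2); V <- matrix(rnorm(2 * 12), 2, 12)
  X2 <- U %*% V + matrix(rnorm(80 * 12, sd = 0.01), 80, 12)
  X2m <- X2
  X2m[sample(length(X2), round(0.05 * length(X2)))] <- NA
  m2 <- fit_pca(scale(X2m, scale = FALSE), A = 2)
  Vtrue <- svd(scale(X2, scale = FALSE))$v[, 1:2]
  # principal angle between the two 2-d loading subspaces
  ang <- acos(min(svd(crossprod(Vtrue, qr.Q(qr(m2$P))))$d, 1)) * 180 / pi
  expect_lt(ang, 2)
})

test_that("PLS-DA recovers constructed signal and matches OLS at full rank", {
  set.seed(4)
  n <- 40
  y <- factor(rep(c("a", "b"), n / 2))
  yc <- as.numeric(y) - 1.5
  X <- cbind(yc, matrix(rnorm(n * 5, sd = 0.05), n, 5))
  X <- scale(X, scale = FALSE)
  m <- fit_plsda(X, y, A = 1)
  expect_gt(m$R2Y, 0.99)

  # at full rank the fitted response equals the least-squares fit
  X2 <- scaled_gauss(50, 6, 5)
  y2 <- factor(rep(c("a", "b"), 25))
  m2 <- fit_plsda(X2, y2, A = 6)
  yc2 <- as.numeric(y2) - mean(as.numeric(y2))
  ols <- stats::lm.fit(X2, yc2)$fitted.values
  pls_fit <- as.numeric(X2 %*% m2$B)
  expect_lt(max(abs(pls_fit - ols)), 1e-8)

  # weight vectors unit norm, scores orthogonal, deflation conserves energy
  expect_equal(unname(colSums(m2$W^2)), rep(1, 6), tolerance = 1e-10)
  G <- crossprod(m2$T)
  expect_lt(max(abs(G[upper.tri(G)])) / max(diag(G)), 1e-8)
  recon <- Reduce(`+`, lapply(1:6, function(a)
    m2$T[, a] %*% t(m2$P[, a])))
  resid <- X2 - recon
  expect_equal(sum(X2^2), sum(recon^2) + sum(resid^2) +
                 2 * sum(recon * resid), tolerance = 1e-8)
  expect_lt(abs(sum(recon * resid)) / sum(X2^2), 1e-8)
  expect_error(fit_plsda(X2, factor(rep("a", 50)), 2), "2 classes")
})

test_that("OPLS-DA reduces to PLS-DA without orthogonal components and separates structured noise", {
  X <- scaled_gauss(30, 10, 6)
  y <- factor(rep(c("a", "b"), 15))
  m0 <- fit_oplsda(X, y, n_orthogonal = 0)
  m1 <- fit_plsda(X, y, A = 1)
  expect_lt(max(abs(m0$T[, 1] - m1$T[, 1])), 1e-10)
  expect_lt(max(abs(m0$W[, 1] - m1$W[, 1])), 1e-10)

  # y-signal plus strong structured variation orthogonal to y
  set.seed(7)
  n <- 60
  y2 <- factor(rep(c("a", "b"), n / 2))
  yc <- as.numeric(y2) - 1.5
  conf <- rnorm(n)
  conf <- residuals(lm(conf ~ yc))  # exactly orthogonal to y
  dir_y <- rnorm(12); dir_c <- rnorm(12)
  X2 <- outer(yc, dir_y) + 6 * outer(conf, dir_c) +
    matrix(rnorm(n * 12, sd = 0.3), n, 12)
  X2 <- scale(X2, scale = FALSE)
  mo <- fit_oplsda(X2, y2, n_orthogonal = 1)
  mp <- fit_plsda(X2, y2, A = 1)
  expect_gt(abs(cor(mo$T[, 1], yc)), abs(cor(mp$T[, 1], yc)))
  # predictive score orthogonal to every orthogonal score
  expect_lt(abs(sum(mo$T[, 1] * mo$T_ortho[, 1])), 1e-8)
  expect_error(fit_oplsda(X[, 1:3], y, n_orthogonal = 5), "rank")
})

test_that("VIP follows its closed form and the mean-one identity", {
  # hand-made 1-component model with weights (1, 0)
  fake <- structure(list(kind = "plsda", A = 1L,
                         W = matrix(c(1, 0), 2, 1), SS_y = 1),
                    class = "latent_model")
  expect_equal(unname(compute_vip(fake)), c(sqrt(2), 0))
  # symmetric weights give VIP 1 everywhere
  fake2 <- structure(list(kind = "plsda", A = 1L,
                          W = matrix(rep(1 / sqrt(4), 4), 4, 1), SS_y = 2),
                     class = "latent_model")
  expect_equal(unname(compute_vip(fake2)), rep(1, 4))
  # identity on fitted models
  X <- scaled_gauss(40, 15, 8)
  y <- factor(rep(c("a", "b"), 20))
  for (A in c(1, 3)) {
    v <- compute_vip(fit_plsda(X, y, A))
    expect_lt(abs(mean(v^2) - 1), 1e-10)
  }
  expect_error(compute_vip(fit_pca(X, 2)), "plsda")
})

test_that("cross-validation is deterministic, rewards signal, and stays null-calibrated", {
  set.seed(9)
  n <- 60
  y <- factor(rep(c("a", "b"), n / 2))
  yc <- as.numeric(y) - 1.5
  X <- outer(yc, rnorm(10)) + matrix(rnorm(n * 10, sd = 0.1), n, 10)
  cv1 <- cross_validate(X, y, A = 2, n_folds = 7, seed = 5)
  cv2 <- cross_validate(X, y, A = 2, n_folds = 7, seed = 5)
  expect_identical(cv1$Q2, cv2$Q2)
  expect_gt(cv1$Q2, 0.9)
  expect_lte(cv1$Q2, fit_plsda(scale(X), y, 2)$R2Y)

  # pure noise: Q2 <= 0 in at least 90% of seeds
  q2s <- vapply(1:20, function(s) {
    set.seed(100 + s)
    Xn <- matrix(rnorm(100 * 20), 100, 20)
    yn <- factor(rep(c("a", "b"), 50))
    cross_validate(Xn, yn, A = 2, n_folds = 7, seed = s)$Q2
  }, numeric(1))
  expect_gte(mean(q2s <= 0), 0.9)
})

test_that("permutation test honors the add-one estimator and its bound", {
  set.seed(10)
  n <- 40
  y <- factor(rep(c("a", "b"), n / 2))
  yc <- as.numeric(y) - 1.5
  X <- outer(yc, rnorm(8)) + matrix(rnorm(n * 8, sd = 0.1), n, 8)
  pt <- permutation_test(X, y, A = 1, n_permutations = 99, seed = 3)
  expect_equal(pt$p_value, 1 / 100)  # strong signal beats every permutation
  expect_length(pt$Q2_null, 99)
  expect_gte(pt$p_value, 1 / (99 + 1))
})

test_that("CV-ANOVA follows the PRESS-based F form", {
  # PRESS == SS_tot: F = 0, p = 1
  fake <- structure(list(PRESS = 10, SS_tot = 10, n = 30, A = 2),
                    class = "validation_result")
  a <- cv_anova(fake)
  expect_equal(a$F, 0)
  expect_equal(a$p_value, 1)
  # p decreases monotonically as PRESS shrinks
  ps <- vapply(c(8, 4, 1, 0.1), function(pr) {
    cv_anova(structure(list(PRESS = pr, SS_tot = 10, n = 30, A = 2),
                       class = "validation_result"))$p_value
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(cv_anova(structure(list(PRESS = 1, SS_tot = 2, n = 3, A = 2),
                                  class = "validation_result")), "n - A - 1")
  # F recomputable from stored per-fold residuals
  set.seed(11)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- factor(rep(c("a", "b"), 20))
  cv <- cross_validate(X, y, A = 2, seed = 7)
  press_manual <- sum(cv$residuals^2)
  expect_equal(cv$PRESS, press_manual, tolerance = 1e-12)
  a2 <- cv_anova(cv)
  f_manual <- max(0, ((cv$SS_tot - press_manual) / 2) / (press_manual / (40 - 3)))
  expect_equal(a2$F, f_manual)
})
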
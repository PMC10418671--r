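# Block maps, Ward lipid clustering, composite scores, weighting, the
# hierarchical model and block selection.

test_that("block maps validate, round-trip, and reject bad references", {
  sim <- generate_table(small_spec(seed = 1))
  ft <- sim$table
  bm <- block_map(sim$truth$block_map, "functional")
  dir <- withr::local_tempdir()
  p <- file.path(dir, "map.tsv")
  write_block_map(bm, p)
  back <- load_block_map(p, ft)
  expect_identical(back$blocks, bm$blocks)
  expect_length(attr(back, "unassigned"), 0L)

  # all features in one block
  one <- block_map(data.frame(feature_id = ft$feature_meta$feature_id,
                              block_id = "all"), "functional")
  expect_length(one$blocks, 1L)

  # unknown feature named in the error
  writeLines(c("feature_id\tblock_id", "GHOST\tF01"), p)
  expect_error(load_block_map(p, ft), "GHOST")
  # a feature mapped twice is rejected
  expect_error(block_map(data.frame(feature_id = c("a", "a"),
                                    block_id = c("b1", "b2"))), "more than one")
})

test_that("Ward clustering recovers planted groups and matches the brute-force oracle", {
  # two tight correlation groups: exact recovery at k = 2
  set.seed(2)
  n <- 40
  f1 <- rnorm(n); f2 <- rnorm(n)
  x <- cbind(sapply(1:5, function(i) f1 + rnorm(n, sd = 0.1)),
             sapply(1:5, function(i) f2 + rnorm(n, sd = 0.1)))
  x <- exp(scale(x) / 3 + 6)  # positive intensities
  sm <- data.frame(sample_id = sprintf("s%d", 1:n), role = "study",
                   injection_order = 1:n, group = rep(c("a", "b"), n / 2),
                   stringsAsFactors = FALSE)
  fm <- data.frame(feature_id = sprintf("L%02d", 1:10), assay = "lipidomics",
                   stringsAsFactors = FALSE)
  ft <- feature_table(x, sm, fm)
  bm <- cluster_lipids(ft, k = 2)
  memb <- rep(names(bm$blocks), lengths(bm$blocks))[
    order(match(unlist(bm$blocks), fm$feature_id))]
  expect_true(same_partition(memb, rep(1:2, each = 5)))
  # k = 1 puts everything together
  bm1 <- cluster_lipids(ft, k = 1)
  expect_length(bm1$blocks, 1L)
  expect_error(cluster_lipids(ft, k = 11), "k must be")

  # Ward merge heights never decrease
  tree <- attr(bm, "tree")
  expect_true(all(diff(tree$height) >= -1e-12))

  # agreement with the first-principles greedy Ward oracle on all cuts
  set.seed(3)
  n2 <- 15
  x2 <- exp(matrix(rnorm(n2 * 12), n2, 12) / 3 + 6)
  sm2 <- data.frame(sample_id = sprintf("s%d", 1:n2), role = "study",
                    injection_order = 1:n2,
                    group = rep(c("a", "b"), length.out = n2),
                    stringsAsFactors = FALSE)
  fm2 <- data.frame(feature_id = sprintf("L%02d", 1:12), assay = "lipidomics",
                    stringsAsFactors = FALSE)
  ft2 <- feature_table(x2, sm2, fm2)
  sc2 <- scale_for_model(ft2, "unit_variance")
  oracle <- ward_oracle(t(sc2$X))
  tree2 <- attr(cluster_lipids(ft2, k = 2), "tree")
  for (k in 2:11) {
    expect_true(same_partition(stats::cutree(tree2, k), oracle[[k]]),
                label = sprintf("partition at k=%d matches oracle", k))
  }
})

test_that("block scores standardize, reduce correctly, and project", {
  set.seed(4)
  n <- 40
  y <- factor(rep(c("a", "b"), n / 2))
  yc <- as.numeric(y) - 1.5
  X <- cbind(s1 = yc + rnorm(n, sd = 0.5),
             t1 = rnorm(n), t2 = rnorm(n), t3 = rnorm(n))
  X <- scale(X)
  colnames(X) <- c("f1", "f2", "f3", "f4")
  # single-feature block: score is the scaled column up to sign
  bm <- block_map(data.frame(feature_id = c("f1", "f2", "f3", "f4"),
                             block_id = c("b1", "b2", "b2", "b2")))
  bs <- block_scores(X, y, bm, n_orthogonal = 1)
  expect_equal(abs(cor(bs$scores[, "b1"], X[, "f1"])), 1, tolerance = 1e-12)
  expect_gte(cor(bs$scores[, "b1"], yc), 0)
  # every score has unit variance
  expect_equal(unname(apply(bs$scores, 2, var)), rep(1, 2), tolerance = 1e-10)
  # a block of two identical columns is not degenerate
  X2 <- cbind(X[, 1:2], dup1 = X[, "f3"], dup2 = X[, "f3"])
  colnames(X2) <- c("f1", "f2", "g1", "g2")
  bm2 <- block_map(data.frame(feature_id = colnames(X2),
                              block_id = c("a", "a", "twin", "twin")))
  bs2 <- block_scores(X2, y, bm2, n_orthogonal = 0)
  expect_equal(abs(cor(bs2$scores[, "twin"], X[, "f3"])), 1, tolerance = 1e-10)
  # projection of the training rows reproduces the training scores
  proj <- project_blocks(bs, X)
  expect_equal(proj[, colnames(bs$scores)], bs$scores, tolerance = 1e-10)
})

test_that("block weighting follows the sqrt-size convention", {
  set.seed(5)
  S <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  S <- scale(S)
  bs <- structure(list(scores = S,
                       weights = setNames(rep(1, 3), colnames(S)),
                       sizes = c(a = 4L, b = 4L, c = 4L),
                       y = factor(rep(c("x", "y"), 10))),
                  class = "block_scores")
  # equal sizes: weighting is a no-op
  w <- weight_blocks(bs, "sqrt_size")
  expect_equal(unname(w$weights), rep(1, 3))
  expect_equal(w$scores, S)
  # sizes 1 and 4: weights in ratio 1:2
  bs$sizes <- c(a = 1L, b = 4L, c = 4L)
  w2 <- weight_blocks(bs, "sqrt_size")
  expect_equal(unname(w2$weights["b"] / w2$weights["a"]), 2)
  expect_equal(sum(w2$weights^2), 3)
  # none: identity
  w3 <- weight_blocks(bs, "none")
  expect_equal(w3$scores, S)
})

test_that("the hierarchical model ranks an informative block first and respects symmetry", {
  set.seed(6)
  n <- 80
  y <- factor(rep(c("a", "b"), n / 2))
  yc <- as.numeric(y) - 1.5
  p <- 20  # 10 blocks x 2 features
  X <- matrix(rnorm(n * p), n, p)
  X[, 1:2] <- X[, 1:2] + yc  # block 1 informative
  colnames(X) <- sprintf("f%02d", 1:p)
  bm <- block_map(data.frame(feature_id = colnames(X),
                             block_id = rep(sprintf("b%02d", 1:10), each = 2)))
  bs <- weight_blocks(block_scores(scale(X), y, bm, 1), "none")
  hier <- fit_hierarchical(bs, y, A = 2)
  expect_equal(names(which.max(hier$vip)), "b01")
  expect_gt(max(hier$vip), 1)

  # blocks that are copies of each other get equal VIPs
  Xc <- cbind(X[, 1:2], X[, 1:2])
  colnames(Xc) <- c("f1", "f2", "g1", "g2")
  bmc <- block_map(data.frame(feature_id = colnames(Xc),
                              block_id = c("c1", "c1", "c2", "c2")))
  bsc <- weight_blocks(block_scores(scale(Xc), y, bmc, 0), "none")
  hc <- fit_hierarchical(bsc, y, A = 1)
  expect_lt(abs(hc$vip["c1"] - hc$vip["c2"]), 1e-8)

  # single-feature blocks without weighting reduce to a flat PLS-DA
  bm1 <- block_map(data.frame(feature_id = colnames(X),
                              block_id = colnames(X)))
  bs1 <- weight_blocks(block_scores(scale(X), y, bm1, 0), "none")
  h1 <- fit_hierarchical(bs1, y, A = 2)
  flat <- fit_plsda(scale(X)[, colnames(bs1$scores)], y, A = 2)
  expect_lt(max(abs(abs(h1$model$T[, 1]) - abs(flat$T[, 1]))), 1e-8)
})

test_that("block selection needs both VIP and adjusted significance", {
  set.seed(7)
  n <- 194
  y <- factor(rep(c("a", "b"), n / 2))
  yc <- as.numeric(y) - 1.5
  X <- matrix(rnorm(n * 12), n, 12)
  X[, 1] <- X[, 1] + yc  # planted block, standardized effect d = 1
  colnames(X) <- sprintf("f%02d", 1:12)
  bm <- block_map(data.frame(feature_id = colnames(X), block_id = colnames(X)))
  bs <- weight_blocks(block_scores(scale(X), y, bm, 0), "none")
  hier <- fit_hierarchical(bs, y, A = 2)
  selected <- select_blocks(hier$vip, bs, y, vip_threshold = 1, alpha = 0.05)
  expect_true(selected$selected[selected$block_id == "f01"])
  expect_true(all(c("VIP", "t", "p", "q", "direction") %in% names(selected)))
  # an infinite threshold empties the selection
  none <- select_blocks(hier$vip, bs, y, vip_threshold = Inf, alpha = 0.05)
  expect_equal(sum(none$selected), 0L)
})

test_that("hierarchical CV stays honest on null data and the planted-effect model validates", {
  # null: fold-honest Q2 non-positive in >= 90% of seeds
  q2 <- vapply(1:10, function(s) {
    sim <- suppressWarnings(generate_table(small_spec(
      seed = 200 + s, affected_block_fraction = 0, drift_amplitude = 0)))
    ft <- sim$table
    scn <- scale_for_model(ft, "unit_variance")
    bmn <- block_map(sim$truth$block_map, "functional")
    hierarchical_cv(scn$X, study_groups(ft), bmn, A = 2, seed = s)$Q2
  }, numeric(1))
  expect_gte(mean(q2 <= 0), 0.9)

  # with planted effects the permutation p hits the add-one floor
  sim <- generate_table(small_spec(seed = 31, n_per_group = 50L,
                                   effect_fold_changes = c(1.4, 1.9),
                                   drift_amplitude = 0))
  ft <- sim$table
  scp <- scale_for_model(ft, "unit_variance")
  bmp <- block_map(sim$truth$block_map, "functional")
  pt <- hierarchical_permutation_test(scp$X, study_groups(ft), bmp, A = 2,
                                      n_permutations = 19, seed = 5)
  expect_equal(pt$p_value, 1 / 20)
  expect_gt(pt$Q2, 0)
})
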
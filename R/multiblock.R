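# Multiblock machinery: functional block maps, Ward lipid clustering,
# per-block OPLS-DA composite scores, size weighting, and the hierarchical
# PLS-DA on block scores.

#' Construct a block map
#'
#' @param assignments data.frame with columns `feature_id`, `block_id`
#' @param kind `"functional"` (curated biology) or `"statistical"`
#'   (data-driven clusters)
#' @return a `block_map`: list of feature-id vectors named by block, with
#'   `kind` and per-block `sizes`
#' @export
block_map <- function(assignments, kind = c("functional", "statistical")) {
  kind <- match.arg(kind)
  if (anyDuplicated(assignments$feature_id))
    stopf("feature(s) mapped to more than one block: %s",
          paste(unique(assignments$feature_id[duplicated(assignments$feature_id)]),
                collapse = ", "))
  blocks <- split(as.character(assignments$feature_id),
                  as.character(assignments$block_id))
  if (any(lengths(blocks) == 0L)) stopf("empty block in map")
  structure(list(blocks = blocks, kind = kind, sizes = lengths(blocks)),
            class = "block_map")
}

#' @export
print.block_map <- function(x, ...) {
  cat(sprintf("block_map (%s): %d blocks, %d features\n",
              x$kind, length(x$blocks), sum(x$sizes)))
  invisible(x)
}

#' Load a feature-to-block map from a two-column file
#'
#' Accepts TSV or CSV with columns `feature_id`, `block_id`. Features of
#' the table absent from the file are collected into the `unassigned`
#' attribute and excluded from multiblock analysis; features in the file
#' but not in the table are an error.
#'
#' @param path path to the map file
#' @param table the `feature_table` the map refers to
#' @param kind passed to [block_map()]
#' @return a `block_map` with attribute `unassigned`
#' @export
load_block_map <- function(path, table, kind = "functional") {
  if (!file.exists(path)) stopf("block map file not found: %s", path)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!all(c("feature_id", "block_id") %in% names(df)))
    stopf("block map needs columns feature_id, block_id")
  unknown <- setdiff(df$feature_id, table$feature_meta$feature_id)
  if (length(unknown))
    stopf("block map references unknown feature(s): %s",
          paste(utils::head(unknown, 5L), collapse = ", "))
  bm <- block_map(df, kind)
  attr(bm, "unassigned") <- setdiff(table$feature_meta$feature_id, df$feature_id)
  bm
}

#' Write a block map to TSV
#' @param bm a `block_map`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_block_map <- function(bm, path) {
  df <- data.frame(
    feature_id = unlist(bm$blocks, use.names = FALSE),
    block_id = rep(names(bm$blocks), lengths(bm$blocks)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cluster lipid features into statistical blocks (Ward)
#'
#' Features are points, study samples are dimensions: agglomerative
#' clustering with Euclidean distance and Ward linkage (`hclust`,
#' `ward.D2`), tree cut at `k` clusters. Cluster labels are assigned in
#' feature order (first feature of a cluster fixes its label), making the
#' result deterministic.
#'
#' @param ft a `feature_table`; its lipidomics columns are clustered
#' @param k number of clusters (>= 1, <= number of lipid features)
#' @param scale_mode scaling applied to study rows before clustering
#' @return a statistical `block_map`; the `hclust` tree is attached as
#'   attribute `tree`
#' @export
cluster_lipids <- function(ft, k, scale_mode = "unit_variance") {
  lip <- which(ft$feature_meta$assay == "lipidomics")
  if (!length(lip)) stopf("table has no lipidomics features")
  if (k < 1L || k > length(lip))
    stopf("k must be in 1..%d (number of lipid features)", length(lip))
  sub <- subset_table(ft, features = lip)
  sc <- scale_for_model(sub, scale_mode)
  hc <- stats::hclust(stats::dist(t(sc$X)), method = "ward.D2")
  memb <- stats::cutree(hc, k = k)
  # relabel clusters in order of first appearance along feature order
  first <- order(match(seq_len(k), memb))
  relab <- match(memb, sort(unique(memb))[first])
  df <- data.frame(feature_id = colnames(sc$X),
                   block_id = sprintf("LB%02d", relab),
                   stringsAsFactors = FALSE)
  bm <- block_map(df, "statistical")
  attr(bm, "tree") <- hc
  bm
}

#' Composite block scores by per-block OPLS-DA
#'
#' Each block's columns are compressed to the predictive score of an
#' OPLS-DA against the group labels; scores are standardized to unit
#' variance. Blocks with fewer than 3 features use 0 orthogonal components;
#' single-feature blocks return the scaled feature itself, sign-aligned to
#' correlate positively with the response. Blocks whose model fails are
#' dropped with a warning and recorded.
#'
#' @param X scaled study-row matrix (columns named by feature id)
#' @param y two-class factor over the rows of `X`
#' @param map a `block_map`
#' @param n_orthogonal orthogonal components per block (default 1)
#' @return a `block_scores` object: `scores` (samples x blocks), `weights`
#'   (all 1 until [weight_blocks()]), `sizes`, `models`, `dropped`
#' @export
block_scores <- function(X, y, map, n_orthogonal = 1L) {
  X <- as.matrix(X)
  enc <- encode_y(y)
  blocks <- map$blocks
  miss <- setdiff(unlist(blocks), colnames(X))
  if (length(miss))
    stopf("block map references feature(s) absent from X: %s",
          paste(utils::head(miss, 5L), collapse = ", "))
  scores <- matrix(NA_real_, nrow(X), length(blocks),
                   dimnames = list(rownames(X), names(blocks)))
  models <- vector("list", length(blocks)); names(models) <- names(blocks)
  dropped <- character(0)
  for (b in names(blocks)) {
    cols <- blocks[[b]]
    Xb <- X[, cols, drop = FALSE]
    s <- NULL
    sgn <- 1
    if (length(cols) == 1L) {
      s <- Xb[, 1L]
      if (stats::cor(s, enc$y) < 0) { s <- -s; sgn <- -1 }
      models[[b]] <- list(single = TRUE, cols = cols, sign = sgn)
    } else {
      no <- if (length(cols) < 3L) 0L else n_orthogonal
      m <- try(fit_oplsda(Xb, y, n_orthogonal = min(no, qr(Xb)$rank - 1L)),
               silent = TRUE)
      if (inherits(m, "try-error")) {
        m <- try(fit_oplsda(Xb, y, n_orthogonal = 0L), silent = TRUE)
      }
      if (inherits(m, "try-error")) {
        warnf("block '%s' dropped: OPLS-DA failed", b)
        dropped <- c(dropped, b)
        next
      }
      s <- m$T[, 1L]
      if (stats::cor(s, enc$y) < 0) { s <- -s; sgn <- -1 }
      models[[b]] <- list(single = FALSE, cols = cols, sign = sgn, fit = m)
    }
    sdv <- stats::sd(s)
    if (!is.finite(sdv) || sdv == 0) {
      warnf("block '%s' dropped: degenerate score", b)
      dropped <- c(dropped, b)
      next
    }
    models[[b]]$sd <- sdv
    scores[, b] <- s / sdv
  }
  keep <- setdiff(names(blocks), dropped)
  structure(list(scores = scores[, keep, drop = FALSE],
                 weights = stats::setNames(rep(1, length(keep)), keep),
                 sizes = map$sizes[keep], kind = map$kind,
                 models = models[keep], dropped = dropped, y = y),
            class = "block_scores")
}

#' Project new samples onto fitted block compressions
#'
#' Applies each block's stored OPLS-DA (orthogonal removal followed by the
#' predictive weight), sign alignment and score standardization to new
#' rows, yielding composite scores comparable with the training scores.
#'
#' @param bs a `block_scores` object
#' @param Xnew matrix of new rows on the same (scaled) feature space
#' @return matrix of block scores for the new rows
#' @export
project_blocks <- function(bs, Xnew) {
  Xnew <- as.matrix(Xnew)
  out <- matrix(NA_real_, nrow(Xnew), length(bs$models),
                dimnames = list(rownames(Xnew), names(bs$models)))
  for (b in names(bs$models)) {
    m <- bs$models[[b]]
    Xb <- Xnew[, m$cols, drop = FALSE]
    s <- if (isTRUE(m$single)) {
      Xb[, 1L]
    } else {
      f <- m$fit
      E <- Xb
      if (f$n_orthogonal > 0L) {
        for (k in seq_len(f$n_orthogonal)) {
          to <- E %*% f$W_ortho[, k]
          E <- E - to %*% t(f$P_ortho[, k])
        }
      }
      as.numeric(E %*% f$W[, 1L])
    }
    out[, b] <- m$sign * s / m$sd
  }
  out
}

#' Fold-honest cross-validation of the hierarchical model
#'
#' Unlike [cross_validate()] on a fixed score matrix, this re-derives the
#' supervised block compression inside every training fold (block OPLS-DA
#' models, sign alignment, weights, and the hierarchical PLS-DA are all
#' fitted on training rows only, then applied to the held-out rows). This
#' removes the circularity of validating on scores that have already seen
#' the labels, so Q2 behaves honestly on null data.
#'
#' @param X scaled study-row matrix
#' @param y two-class factor
#' @param map a `block_map`
#' @param A hierarchical components
#' @param n_folds folds (default 7)
#' @param seed fold seed
#' @param n_orthogonal orthogonal components per block
#' @param weight_scheme passed to [weight_blocks()]
#' @return a `validation_result` (see [cross_validate()])
#' @export
hierarchical_cv <- function(X, y, map, A = 2L, n_folds = 7L, seed = 1L,
                            n_orthogonal = 1L, weight_scheme = "sqrt_size") {
  X <- as.matrix(X)
  enc <- encode_y(y)
  yn <- enc$raw
  fold <- make_folds(y, n_folds, seed)
  resid <- numeric(length(yn))
  press_fold <- numeric(n_folds)
  for (k in seq_len(n_folds)) {
    tr <- fold != k; te <- !tr
    ctr <- colMeans(X[tr, , drop = FALSE])
    scl <- apply(X[tr, , drop = FALSE], 2L, stats::sd)
    scl[!is.finite(scl) | scl == 0] <- 1
    Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2L, ctr, "-"), 2L, scl, "/")
    Xte <- sweep(sweep(X[te, , drop = FALSE], 2L, ctr, "-"), 2L, scl, "/")
    bs_tr <- suppressWarnings(block_scores(Xtr, y[tr], map, n_orthogonal))
    S_te_raw <- project_blocks(bs_tr, Xte)
    bs_trw <- weight_blocks(bs_tr, weight_scheme)
    S_te <- sweep(S_te_raw[, colnames(bs_trw$scores), drop = FALSE], 2L,
                  bs_trw$weights, "*")
    sctr <- colMeans(bs_trw$scores)
    ssd <- apply(bs_trw$scores, 2L, stats::sd); ssd[ssd == 0] <- 1
    Str <- sweep(sweep(bs_trw$scores, 2L, sctr, "-"), 2L, ssd, "/")
    Ste <- sweep(sweep(S_te, 2L, sctr, "-"), 2L, ssd, "/")
    Atr <- min(A, nrow(Str) - 1L, ncol(Str))
    m <- fit_plsda(Str, y[tr], Atr)
    pred <- as.numeric(Ste %*% m$B) + mean(yn[tr])
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

#' Permutation test of the hierarchical model
#'
#' Relabels the response and re-runs the entire fold-honest hierarchical
#' cross-validation ([hierarchical_cv()]) per permutation, so the null
#' distribution reflects the full supervised compression, not just the
#' final regression.
#'
#' @inheritParams hierarchical_cv
#' @param n_permutations number of relabelings
#' @return a `validation_result` with `Q2`, `Q2_null`, `p_value`
#' @export
hierarchical_permutation_test <- function(X, y, map, A = 2L,
                                          n_permutations = 200L,
                                          n_folds = 7L, seed = 1L,
                                          n_orthogonal = 1L,
                                          weight_scheme = "sqrt_size") {
  obs <- hierarchical_cv(X, y, map, A, n_folds, seed, n_orthogonal, weight_scheme)
  q2_null <- numeric(n_permutations)
  for (b in seq_len(n_permutations)) {
    yp <- with_seed(child_seed(seed, b), sample(as.character(y)))
    q2_null[b] <- hierarchical_cv(X, yp, map, A, n_folds,
                                  child_seed(seed, b + n_permutations),
                                  n_orthogonal, weight_scheme)$Q2
  }
  p <- (1 + sum(q2_null >= obs$Q2)) / (n_permutations + 1)
  structure(list(Q2 = obs$Q2, PRESS = obs$PRESS, SS_tot = obs$SS_tot,
                 Q2_null = q2_null, p_value = p,
                 n_permutations = n_permutations, n = obs$n, A = A),
            class = "validation_result")
}

#' Weight block scores by block size
#'
#' `sqrt_size` multiplies block k's score column by `sqrt(n_k)`, normalized
#' so the squared weights sum to the number of blocks (equal sizes leave
#' everything unchanged); `inverse_sqrt_size` is the dominance-suppressing
#' opposite; `none` is the identity.
#'
#' @param bs a `block_scores` object
#' @param scheme weighting scheme
#' @return the weighted `block_scores` (weights recorded)
#' @export
weight_blocks <- function(bs, scheme = c("sqrt_size", "inverse_sqrt_size", "none")) {
  scheme <- match.arg(scheme)
  G <- ncol(bs$scores)
  w <- switch(scheme,
              sqrt_size = sqrt(bs$sizes),
              inverse_sqrt_size = 1 / sqrt(bs$sizes),
              none = rep(1, G))
  w <- w * sqrt(G / sum(w^2))
  bs$scores <- sweep(bs$scores, 2L, w, "*")
  bs$weights <- stats::setNames(as.numeric(w), colnames(bs$scores))
  bs$weight_scheme <- scheme
  bs
}

#' Hierarchical (multiblock) PLS-DA on block scores
#'
#' Fits a PLS-DA on the (weighted) block-score matrix and returns the model
#' together with per-block VIPs. Validation (Q2, permutations, CV-ANOVA)
#' runs through the latent module on the same matrix.
#'
#' @param bs a `block_scores` object (>= 2 blocks)
#' @param y two-class factor (defaults to the one stored in `bs`)
#' @param A number of components (default 2)
#' @return list with `model` (a `latent_model`) and `vip` (named per block)
#' @export
fit_hierarchical <- function(bs, y = bs$y, A = 2L) {
  if (ncol(bs$scores) < 2L) stopf("hierarchical model needs >= 2 blocks")
  S <- scale_matrix_simple(bs$scores, "unit_variance")
  m <- fit_plsda(S, y, A)
  rownames(m$W) <- colnames(bs$scores)
  list(model = m, vip = compute_vip(m), scores_scaled = S)
}

#' Select differential blocks by VIP and t-test
#'
#' A block is selected iff its hierarchical VIP exceeds `vip_threshold`
#' and a two-sided Welch t-test on its composite score between the groups
#' survives Benjamini-Yekutieli adjustment at `alpha`. Both criteria are
#' reported per block. Composite scores are supervised, so the t-test
#' p-values are optimistic (circular); the permutation test of the
#' hierarchical model is the honest global check.
#'
#' @param vips named per-block VIP vector
#' @param bs the `block_scores` the VIPs came from
#' @param y two-class factor
#' @param vip_threshold VIP cutoff (default 1.0)
#' @param alpha significance level for the adjusted q (default 0.05)
#' @return data.frame: block_id, size, VIP, t, p, q, direction, selected
#' @export
select_blocks <- function(vips, bs, y = bs$y, vip_threshold = 1.0, alpha = 0.05) {
  f <- factor(y)
  ids <- colnames(bs$scores)
  tt <- lapply(ids, function(b) {
    s <- bs$scores[, b]
    stats::t.test(s[f == levels(f)[2L]], s[f == levels(f)[1L]])
  })
  p <- vapply(tt, function(z) z$p.value, numeric(1))
  tstat <- vapply(tt, function(z) unname(z$statistic), numeric(1))
  q <- adjust_by(p, method = "BY")
  df <- data.frame(block_id = ids, size = as.integer(bs$sizes[ids]),
                   VIP = as.numeric(vips[ids]), t = tstat, p = p, q = q,
                   direction = ifelse(tstat >= 0, "up", "down"),
                   selected = as.numeric(vips[ids]) > vip_threshold & q < alpha,
                   stringsAsFactors = FALSE)
  df[order(-df$VIP), ]
}
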
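# Block-level Gaussian graphical model: shrinkage partial correlations
# (correlation matrix shrunk toward identity with the analytic
# variance-minimizing intensity), edge tests, thresholded network,
# betweenness centrality and graph export.

#' Shrinkage partial correlations
#'
#' The sample correlation matrix is shrunk toward the identity,
#' `R* = (1 - lambda) R + lambda I`, with the analytic intensity
#' `lambda = sum Var(r_ij) / sum r_ij^2` over off-diagonal entries
#' (clamped to `[0, 1]`), which minimizes the estimator's expected squared
#' error and keeps `R*` positive definite even when blocks outnumber
#' samples. Partial correlations come from the inverse:
#' `pc_ij = -W_ij / sqrt(W_ii W_jj)` with `W = solve(R*)`. Edge p-values
#' use the t-statistic `pc * sqrt(df / (1 - pc^2))` with `df = n - G`
#' when positive, else a Fisher-z normal approximation.
#'
#' @param scores samples x blocks matrix (n >= 3, G >= 2, no constant
#'   column)
#' @return list with `pcor` (G x G), `lambda`, `p_values` (G x G, NA on
#'   the diagonal), `n`, `df`
#' @export
partial_correlations <- function(scores) {
  X <- as.matrix(scores)
  n <- nrow(X); G <- ncol(X)
  if (n < 3L) stopf("partial_correlations needs >= 3 samples")
  if (G < 2L) stopf("partial_correlations needs >= 2 blocks")
  sds <- apply(X, 2L, stats::sd)
  if (any(!is.finite(sds) | sds == 0))
    stopf("constant block score column: %s",
          paste(colnames(X)[!is.finite(sds) | sds == 0], collapse = ", "))
  Xs <- scale(X)  # unit-variance standardization
  R <- crossprod(Xs) / (n - 1)
  # analytic shrinkage intensity (unbiased variance of the r_ij)
  S2 <- crossprod(Xs^2)                       # sum_k x_ki^2 x_kj^2
  wbar <- R * (n - 1) / n
  varr <- n / (n - 1)^3 * (S2 - n * wbar^2)
  off <- upper.tri(R)
  denom <- sum(R[off]^2)
  lambda <- if (denom <= 0) 1 else min(1, max(0, sum(varr[off]) / denom))
  Rs <- (1 - lambda) * R
  diag(Rs) <- 1
  W <- solve(Rs)
  d <- sqrt(diag(W))
  pc <- -W / outer(d, d)
  diag(pc) <- 1
  dimnames(pc) <- list(colnames(X), colnames(X))
  df <- n - G
  pmat <- matrix(NA_real_, G, G, dimnames = dimnames(pc))
  r <- pc[off]
  r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  if (df > 0) {
    tv <- r * sqrt(df / (1 - r^2))
    pv <- 2 * stats::pt(-abs(tv), df)
  } else {
    z <- atanh(r) * sqrt(max(n - 3, 1))
    pv <- 2 * stats::pnorm(-abs(z))
  }
  pmat[off] <- pv
  pmat[lower.tri(pmat)] <- t(pmat)[lower.tri(pmat)]
  list(pcor = pc, lambda = lambda, p_values = pmat, n = n, df = df)
}

#' Build the thresholded partial-correlation network
#'
#' Keeps an edge iff its p-value is `<= p_threshold`; isolated nodes are
#' retained; the edge sign is the sign of the partial correlation. Node
#' attributes (e.g. the block's group-difference q-value) can be attached.
#'
#' @param pc result of [partial_correlations()]
#' @param p_threshold edge p cutoff in (0, 1] (default 0.25, the
#'   permissive "initial network" convention)
#' @param node_stats optional data.frame with column `block_id` plus
#'   per-node columns (e.g. `p`, `q`) to carry as attributes
#' @return a `pcor_network`: `graph` (igraph), `nodes`, `edges` data.frames
#' @export
build_network <- function(pc, p_threshold = 0.25, node_stats = NULL) {
  if (p_threshold <= 0 || p_threshold > 1) stopf("p_threshold must be in (0, 1]")
  ids <- colnames(pc$pcor)
  off <- which(upper.tri(pc$pcor), arr.ind = TRUE)
  edges <- data.frame(from = ids[off[, 1L]], to = ids[off[, 2L]],
                      pcor = pc$pcor[off], p = pc$p_values[off],
                      stringsAsFactors = FALSE)
  edges <- edges[edges$p <= p_threshold, , drop = FALSE]
  edges$sign <- ifelse(edges$pcor >= 0, "+", "-")
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  nodes <- data.frame(block_id = ids, stringsAsFactors = FALSE)
  if (!is.null(node_stats)) {
    nodes <- merge(nodes, node_stats, by = "block_id", all.x = TRUE, sort = FALSE)
    nodes <- nodes[match(ids, nodes$block_id), , drop = FALSE]
    for (col in setdiff(names(nodes), "block_id"))
      g <- igraph::set_vertex_attr(g, col, value = nodes[[col]])
  }
  structure(list(graph = g, nodes = nodes, edges = edges,
                 lambda = pc$lambda, p_threshold = p_threshold),
            class = "pcor_network")
}

#' Betweenness centrality of network nodes
#'
#' Unweighted shortest-path betweenness
#' `g(v) = sum_{s != v != t} sigma_st(v) / sigma_st`, unnormalized, with
#' all shortest paths counted and disconnected pairs contributing 0.
#'
#' @param net a `pcor_network`
#' @return named numeric vector of betweenness values
#' @export
node_betweenness <- function(net) {
  b <- igraph::betweenness(net$graph, directed = FALSE, weights = NA,
                           normalized = FALSE)
  stats::setNames(as.numeric(b), igraph::V(net$graph)$name)
}

#' Export a network to GraphML and SIF
#'
#' Writes GraphML with all node/edge attributes (partial correlation, edge
#' p, plus any node statistics) and a simple interaction-format text file
#' (`node TAB sign TAB node`).
#'
#' @param net a `pcor_network`
#' @param path output path for the GraphML; the SIF file gets the same
#'   path with extension `.sif`
#' @return named vector of the two paths, invisibly
#' @export
export_graph <- function(net, path) {
  g <- net$graph
  if (nrow(net$edges)) {
    g <- igraph::set_edge_attr(g, "pcor", value = net$edges$pcor)
    g <- igraph::set_edge_attr(g, "p", value = net$edges$p)
  }
  bt <- node_betweenness(net)
  g <- igraph::set_vertex_attr(g, "betweenness",
                               value = as.numeric(bt[igraph::V(g)$name]))
  igraph::write_graph(g, path, format = "graphml")
  sif <- sub("\\.[^.]*$", ".sif", path)
  if (identical(sif, path)) sif <- paste0(path, ".sif")
  lines <- if (nrow(net$edges)) {
    sprintf("%s\t%s\t%s", net$edges$from, net$edges$sign, net$edges$to)
  } else character(0)
  writeLines(lines, sif)
  invisible(c(graphml = path, sif = sif))
}
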
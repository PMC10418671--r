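# Independent brute-force oracles used to cross-check the fast
# implementations. These stay deliberately naive.

# Greedy Ward agglomeration from first principles: at each step merge the
# pair of clusters minimizing the increase of within-cluster sum of squares
# Delta(A,B) = |A||B|/(|A|+|B|) * ||centroid_A - centroid_B||^2.
# Returns the membership vector at every cluster count k = n..1.
ward_oracle <- function(X) {
  n <- nrow(X)
  clusters <- lapply(seq_len(n), identity)
  partitions <- list()
  memb <- seq_len(n)
  partitions[[n]] <- memb
  while (length(clusters) > 1L) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      a <- clusters[[i]]; b <- clusters[[j]]
      ca <- colMeans(X[a, , drop = FALSE]); cb <- colMeans(X[b, , drop = FALSE])
      d <- length(a) * length(b) / (length(a) + length(b)) * sum((ca - cb)^2)
      if (d < best[1L]) best <- c(d, i, j)
    }
    i <- best[2L]; j <- best[3L]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
    memb <- integer(n)
    for (k in seq_along(clusters)) memb[clusters[[k]]] <- k
    partitions[[length(clusters)]] <- memb
  }
  partitions
}

# Are two membership vectors the same partition (up to label names)?
same_partition <- function(a, b) {
  identical(match(a, unique(a)), match(b, unique(b)))
}

# Betweenness by exhaustive simple-path enumeration (tiny graphs only).
# adj: symmetric logical adjacency matrix without self loops.
betweenness_oracle <- function(adj) {
  n <- nrow(adj)
  g <- numeric(n)
  all_paths <- function(s, t) {
    paths <- list()
    walk <- function(v, visited) {
      if (v == t) { paths[[length(paths) + 1L]] <<- visited; return(invisible()) }
      for (w in which(adj[v, ])) if (!(w %in% visited)) walk(w, c(visited, w))
    }
    walk(s, s)
    paths
  }
  for (s in seq_len(n - 1L)) for (t in (s + 1L):n) {
    paths <- all_paths(s, t)
    if (!length(paths)) next
    lens <- lengths(paths)
    shortest <- paths[lens == min(lens)]
    sigma <- length(shortest)
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      through <- sum(vapply(shortest, function(p) v %in% p, logical(1)))
      g[v] <- g[v] + through / sigma
    }
  }
  g
}

# Exact hypergeometric tail by enumerating all C(N, n) selections.
hyper_oracle <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  inpath <- seq_len(K)  # the pathway is the first K elements
  hits <- apply(draws, 2L, function(d) sum(d %in% inpath))
  mean(hits >= k)
}

# Benjamini-Yekutieli step-up computed directly from the definition.
by_oracle <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  ps <- p[o]
  raw <- ps * m * cm / seq_len(m)
  q <- rev(cummin(rev(raw)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Wrap a plain node-count + edge-list graph as a pcor_network so the
# package's betweenness/export functions can run on hand-made graphs.
build_edges_graph <- function(n_nodes, edge_pairs) {
  verts <- data.frame(name = sprintf("n%d", seq_len(n_nodes)))
  edges <- if (length(edge_pairs)) {
    data.frame(from = sprintf("n%d", edge_pairs[, 1]),
               to = sprintf("n%d", edge_pairs[, 2]),
               stringsAsFactors = FALSE)
  } else data.frame(from = character(0), to = character(0))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
  structure(list(graph = g, edges = edges), class = "pcor_network")
}
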
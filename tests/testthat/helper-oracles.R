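# Independent brute-force oracles. These deliberately avoid the code paths
# they check: enumeration instead of closed forms, edge-list tallies
# instead of graph libraries.

# Upper-tail hypergeometric by exhaustive enumeration of all C(N, n) draws.
oracle_hypergeom <- function(k, n, K, N) {
  if (n == 0) return(if (k == 0) 1 else 0)
  draws <- utils::combn(N, n)
  marked <- seq_len(K)  # items 1..K are the successes
  hits <- apply(draws, 2, function(d) sum(d %in% marked))
  mean(hits >= k)
}

# Benjamini-Hochberg step-up by literal rule evaluation.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, p[ord[i]] * m / i)
    adj[ord[i]] <- min(1, running)
  }
  adj
}

# Degree by direct incidence tally over an edge-list data.frame (a, b).
oracle_degree <- function(nodes, edges) {
  d <- stats::setNames(integer(length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    d[edges$a[i]] <- d[edges$a[i]] + 1L
    d[edges$b[i]] <- d[edges$b[i]] + 1L
  }
  d
}

# Betweenness by exhaustive enumeration of all shortest paths per pair.
# Each unordered pair counts once; endpoints are not credited.
oracle_betweenness <- function(nodes, edges) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    adj[[edges$a[i]]] <- c(adj[[edges$a[i]]], edges$b[i])
    adj[[edges$b[i]]] <- c(adj[[edges$b[i]]], edges$a[i])
  }
  bfs_dist <- function(s) {
    d <- stats::setNames(rep(Inf, length(nodes)), nodes)
    d[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- character(0)
      for (u in frontier) for (v in adj[[u]]) if (is.infinite(d[v])) {
        d[v] <- d[u] + 1
        nxt <- c(nxt, v)
      }
      frontier <- unique(nxt)
    }
    d
  }
  all_shortest <- function(s, t, d_to_t) {
    # walk from s along edges that strictly decrease distance to t
    if (s == t) return(list(s))
    paths <- list()
    for (v in adj[[s]]) {
      if (d_to_t[v] == d_to_t[s] - 1) {
        for (tail in all_shortest(v, t, d_to_t)) {
          paths[[length(paths) + 1L]] <- c(s, tail)
        }
      }
    }
    paths
  }
  btw <- stats::setNames(numeric(length(nodes)), nodes)
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (i >= j) next
    s <- nodes[i]; t <- nodes[j]
    d_to_t <- bfs_dist(t)
    if (is.infinite(d_to_t[s])) next
    paths <- all_shortest(s, t, d_to_t)
    for (p in paths) {
      interior <- setdiff(p, c(s, t))
      for (v in interior) btw[v] <- btw[v] + 1 / length(paths)
    }
  }
  btw
}

# Naive comparison sort on (-p_weight, p_value, set_id) for re-ranking.
oracle_rerank_order <- function(rows) {
  keys <- lapply(seq_len(nrow(rows)), function(i) {
    list(w = rows$p_weight[i], p = rows$p_value[i], id = rows$set_id[i])
  })
  idx <- seq_len(nrow(rows))
  # insertion sort, deliberately naive
  for (i in seq_along(idx)[-1]) {
    j <- i
    while (j > 1) {
      a <- keys[[idx[j - 1]]]; b <- keys[[idx[j]]]
      before <- (a$w > b$w) || (a$w == b$w && a$p < b$p) ||
        (a$w == b$w && a$p == b$p && a$id <= b$id)
      if (before) break
      tmp <- idx[j - 1]; idx[j - 1] <- idx[j]; idx[j] <- tmp
      j <- j - 1
    }
  }
  idx
}

# Random small graph as an edge-list data.frame over LETTERS nodes.
random_graph_edges <- function(n_nodes, p = 0.4) {
  nodes <- LETTERS[seq_len(n_nodes)]
  pairs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(pairs)) < p
  list(nodes = nodes,
       edges = data.frame(a = pairs[1, keep], b = pairs[2, keep],
                          stringsAsFactors = FALSE))
}

edges_to_igraph <- function(nodes, edges, scores = NULL) {
  g <- igraph::make_empty_graph(length(nodes), directed = FALSE)
  igraph::V(g)$name <- nodes
  if (nrow(edges)) g <- igraph::add_edges(g, rbind(edges$a, edges$b))
  if (!is.null(scores)) igraph::E(g)$score <- scores
  g
}
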
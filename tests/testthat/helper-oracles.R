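# Independent brute-force oracles used to cross-check the package's
# network algorithms on small instances.

# All shortest paths between two nodes by exhaustive backward DFS over a
# BFS distance labelling. Returns a list of node-id vectors.
oracle_shortest_paths <- function(edges, s, t) {
  nodes <- sort(unique(c(edges)))
  adj <- lapply(setNames(nodes, nodes), function(v)
    unique(c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1])))
  dist <- setNames(rep(Inf, length(nodes)), nodes)
  dist[s] <- 0
  queue <- s
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (is.infinite(dist[w])) {
      dist[w] <- dist[v] + 1
      queue <- c(queue, w)
    }
  }
  if (is.infinite(dist[t])) return(list())
  walk <- function(v) {
    if (v == s) return(list(s))
    out <- list()
    for (u in adj[[v]]) if (dist[u] == dist[v] - 1)
      out <- c(out, lapply(walk(u), function(p) c(p, v)))
    out
  }
  walk(t)
}

# Edge betweenness by explicit path enumeration over all unordered pairs.
oracle_edge_betweenness <- function(edges) {
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]),
               sep = "|")
  eb <- setNames(numeric(nrow(edges)), key)
  nodes <- sort(unique(c(edges)))
  if (length(nodes) < 2) return(eb)
  for (i in seq_len(length(nodes) - 1)) for (j in seq((i + 1), length(nodes))) {
    paths <- oracle_shortest_paths(edges, nodes[i], nodes[j])
    if (length(paths) == 0) next
    for (p in paths) {
      if (length(p) < 2) next
      for (e in seq_len(length(p) - 1)) {
        k <- paste(min(p[e], p[e + 1]), max(p[e], p[e + 1]), sep = "|")
        eb[k] <- eb[k] + 1 / length(paths)
      }
    }
  }
  eb
}

# Enumerate all set partitions of n items as restricted-growth strings.
oracle_all_partitions <- function(n) {
  out <- list()
  grow <- function(prefix) {
    k <- length(prefix)
    if (k == n) { out[[length(out) + 1]] <<- prefix; return(invisible()) }
    top <- if (k == 0) 0 else max(prefix)
    for (v in seq_len(top + 1)) grow(c(prefix, v))
  }
  grow(integer())
  out
}

# Best-modularity partition by exhaustive search (small graphs only).
oracle_best_partition <- function(g) {
  n <- length(g$nodes)
  best_q <- -Inf; best <- NULL
  for (p in oracle_all_partitions(n)) {
    memb <- setNames(p, g$nodes)
    q <- rejuvsig::modularity_q(g, memb)
    if (q > best_q) { best_q <- q; best <- memb }
  }
  list(membership = best, Q = best_q)
}

# Two partitions agree up to relabelling iff they induce the same
# co-membership relation.
same_partition <- function(a, b) {
  nodes <- names(a)
  co <- function(m) outer(m[nodes], m[nodes], "==")
  identical(co(a), co(b))
}

random_small_graph <- function(n_nodes, p_edge = 0.4) {
  nodes <- LETTERS[seq_len(n_nodes)]
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p_edge
  pairs[keep, , drop = FALSE]
}

make_bead <- function(signals, controls, groups) {
  structure(list(signals = signals, neg_controls = controls,
                 gene_ids = rownames(signals), sample_ids = colnames(signals),
                 groups = groups),
            class = "bead_summary")
}
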
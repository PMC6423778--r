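#' Simple undirected protein graph
#'
#' Internal container for protein-association networks: a character node
#' vector, a deduplicated two-column edge matrix (endpoints sorted within
#' each row, no self-loops), and a per-node seed flag marking proteins coded
#' by signature genes.
#'
#' @param edges two-column character matrix or data.frame of endpoints.
#' @param seeds character vector of seed symbols (may include symbols with
#'   no surviving edge).
#' @param nodes optional explicit node set; defaults to the edge endpoints.
#' @return object of class `pan_graph` with `nodes`, `edges`, `is_seed`.
#' @export
pan_graph <- function(edges, seeds = character(), nodes = NULL) {
  em <- as.matrix(edges)
  if (length(em) == 0L) {
    em <- matrix(character(), 0, 2)
  } else {
    storage.mode(em) <- "character"
    keep <- em[, 1] != em[, 2]
    em <- em[keep, , drop = FALSE]
    em <- t(apply(em, 1, sort))
    if (nrow(em) > 0) em <- unique(em)
  }
  if (is.null(nodes)) nodes <- sort(unique(c(em)))
  colnames(em) <- c("a", "b")
  structure(list(nodes = nodes, edges = em,
                 is_seed = stats::setNames(nodes %in% seeds, nodes)),
            class = "pan_graph")
}

#' @export
print.pan_graph <- function(x, ...) {
  cat("pan_graph:", length(x$nodes), "nodes,", nrow(x$edges), "edges,",
      sum(x$is_seed), "seed(s)\n")
  invisible(x)
}

edge_labels <- function(g) paste(g$edges[, 1], g$edges[, 2], sep = "|")

adjacency_list <- function(g) {
  adj <- stats::setNames(vector("list", length(g$nodes)), g$nodes)
  for (i in seq_len(nrow(g$edges))) {
    a <- g$edges[i, 1]; b <- g$edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

#' Connected components of a pan_graph
#' @param g a `pan_graph`.
#' @return named integer vector node -> component id; components are numbered
#'   in order of their lexicographically smallest node.
#' @export
graph_components <- function(g) {
  adj <- adjacency_list(g)
  comp <- stats::setNames(rep(NA_integer_, length(g$nodes)), g$nodes)
  cid <- 0L
  for (start in sort(g$nodes)) {
    if (!is.na(comp[start])) next
    cid <- cid + 1L
    queue <- start
    comp[start] <- cid
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (is.na(comp[w])) {
        comp[w] <- cid
        queue <- c(queue, w)
      }
    }
  }
  comp
}

#' Parse a BioGRID-style tab-delimited interaction file
#'
#' Keeps rows where both interactors carry the requested taxonomy id,
#' uppercases symbols, drops self-interactions and collapses duplicate pairs
#' (orientation-insensitive). Filtering counts are recorded in a
#' `provenance` attribute.
#'
#' @param path TSV file path, or a data.frame already read.
#' @param taxid taxonomy id both endpoints must match (9606 = Homo sapiens).
#' @param colmap named character vector mapping the roles
#'   `symbol_a`, `symbol_b`, `taxid_a`, `taxid_b` to column names in the
#'   file. Defaults match this package's generator output
#'   (`official_symbol_a` etc.); BioGRID TAB column names can be supplied.
#' @return two-column character edge matrix with attribute `provenance`
#'   (named counts: `rows`, `taxid_filtered`, `self_loops`, `duplicates`).
#' @export
parse_biogrid <- function(path, taxid = 9606,
                          colmap = c(symbol_a = "official_symbol_a",
                                     symbol_b = "official_symbol_b",
                                     taxid_a = "taxid_a",
                                     taxid_b = "taxid_b")) {
  df <- if (is.data.frame(path)) path else
    utils::read.delim(path, check.names = FALSE,
                      colClasses = "character")
  missing_cols <- setdiff(unname(colmap), names(df))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  n_rows <- nrow(df)
  ok_tax <- df[[colmap["taxid_a"]]] == as.character(taxid) &
    df[[colmap["taxid_b"]]] == as.character(taxid)
  df <- df[ok_tax, , drop = FALSE]
  a <- toupper(df[[colmap["symbol_a"]]])
  b <- toupper(df[[colmap["symbol_b"]]])
  not_self <- a != b
  a <- a[not_self]; b <- b[not_self]
  em <- cbind(pmin(a, b), pmax(a, b))
  n_before <- nrow(em)
  em <- unique(em)
  colnames(em) <- c("a", "b")
  attr(em, "provenance") <- c(rows = n_rows,
                              taxid_filtered = n_rows - sum(ok_tax),
                              self_loops = sum(!not_self),
                              duplicates = n_before - nrow(em))
  em
}

#' Seed-anchored signature network
#'
#' Keeps exactly the interactions with at least one endpoint in the seed
#' set (the proteins coded by a gene signature); nodes are the endpoints of
#' the kept edges, flagged by seed membership.
#'
#' @param edges two-column character edge matrix (e.g. [parse_biogrid()]).
#' @param seeds character vector of seed protein symbols.
#' @return a `pan_graph`.
#' @export
extract_signature_network <- function(edges, seeds) {
  seeds <- toupper(seeds)
  em <- as.matrix(edges)
  if (nrow(em) > 0) {
    keep <- em[, 1] %in% seeds | em[, 2] %in% seeds
    em <- em[keep, , drop = FALSE]
  }
  pan_graph(em, seeds = seeds)
}

#' Reduce a signature network to the top-n most seed-connected interactors
#'
#' Non-seed proteins are ranked by their number of distinct seed interaction
#' partners (default) or by their global degree in the full interaction
#' table, ties broken lexicographically by symbol; only the top
#' `n_interactors` are retained. The final node set is the seeds that have
#' edges plus the retained interactors; the final edge set is all
#' interactions among that node set (or only seed-touching ones when
#' `seed_edges_only`).
#'
#' @param graph a `pan_graph` from [extract_signature_network()].
#' @param all_edges the full edge matrix the graph was extracted from.
#' @param seeds the same seed set used for extraction.
#' @param n_interactors how many non-seed interactors to keep (default 30).
#' @param rank_by `"seed_partners"` or `"degree"`.
#' @param seed_edges_only drop interactor-interactor edges.
#' @return a `pan_graph`.
#' @export
augment_top_interactors <- function(graph, all_edges, seeds,
                                    n_interactors = 30,
                                    rank_by = c("seed_partners", "degree"),
                                    seed_edges_only = FALSE) {
  rank_by <- match.arg(rank_by)
  seeds <- toupper(seeds)
  em <- graph$edges
  interactors <- setdiff(graph$nodes, seeds)
  if (length(interactors) > 0 && n_interactors > 0) {
    score <- if (rank_by == "seed_partners") {
      vapply(interactors, function(v) {
        partners <- c(em[em[, 1] == v, 2], em[em[, 2] == v, 1])
        length(unique(intersect(partners, seeds)))
      }, integer(1))
    } else {
      ae <- as.matrix(all_edges)
      vapply(interactors, function(v)
        sum(ae[, 1] == v) + sum(ae[, 2] == v), integer(1))
    }
    ord <- order(-score, interactors)
    kept <- interactors[ord][seq_len(min(n_interactors, length(interactors)))]
  } else kept <- character()
  final_nodes <- union(intersect(seeds, graph$nodes), kept)
  ae <- as.matrix(all_edges)
  keep <- ae[, 1] %in% final_nodes & ae[, 2] %in% final_nodes
  if (seed_edges_only)
    keep <- keep & (ae[, 1] %in% seeds | ae[, 2] %in% seeds)
  pan_graph(ae[keep, , drop = FALSE], seeds = seeds)
}

#' Edge betweenness by Brandes' accumulation
#'
#' For every edge, the number of unordered node pairs (s, t), endpoints
#' included, whose shortest paths traverse the edge, counted fractionally
#' when a pair has several shortest paths: each edge receives
#' `sum over pairs of (#shortest s-t paths through the edge) /
#' (#shortest s-t paths)`. Paths are unweighted.
#'
#' @param g a `pan_graph`.
#' @return named numeric vector `"A|B"` -> betweenness.
#' @export
edge_betweenness <- function(g) {
  nodes <- g$nodes
  adj <- adjacency_list(g)
  eb <- stats::setNames(numeric(nrow(g$edges)), edge_labels(g))
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  for (s in nodes) {
    # BFS from s: sigma = #shortest paths, preds, order of settling
    dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
    sigma <- stats::setNames(rep(0, length(nodes)), nodes)
    preds <- stats::setNames(vector("list", length(nodes)), nodes)
    dist[s] <- 0; sigma[s] <- 1
    queue <- s; settled <- character()
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      settled <- c(settled, v)
      for (w in adj[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- stats::setNames(rep(0, length(nodes)), nodes)
    for (w in rev(settled)) {
      for (v in preds[[w]]) {
        c_vw <- sigma[v] / sigma[w] * (1 + delta[w])
        eb[ekey(v, w)] <- eb[ekey(v, w)] + c_vw
        delta[v] <- delta[v] + c_vw
      }
    }
  }
  eb / 2  # each unordered pair was counted from both endpoints
}

#' Newman-Girvan modularity of a partition
#'
#' `Q = sum over communities c of (m_c / m - (d_c / 2m)^2)` where m is the
#' edge count, m_c the intra-community edge count and d_c the total degree
#' of community c. An edgeless graph has Q = 0 by convention.
#'
#' @param g a `pan_graph`.
#' @param membership named vector node -> community id covering every node.
#' @return Q in [-0.5, 1].
#' @export
modularity_q <- function(g, membership) {
  if (!all(g$nodes %in% names(membership)))
    stop("membership must cover every node")
  m <- nrow(g$edges)
  if (m == 0L) return(0)
  ca <- membership[g$edges[, 1]]
  cb <- membership[g$edges[, 2]]
  deg_by_comm <- tapply(c(ca, cb), c(ca, cb), length)
  intra <- tapply(ca == cb, ca, sum)
  q <- 0
  for (comm in names(deg_by_comm)) {
    mc <- if (comm %in% names(intra)) intra[[comm]] else 0
    q <- q + mc / m - (deg_by_comm[[comm]] / (2 * m))^2
  }
  q
}

#' Girvan-Newman community detection by iterative edge removal
#'
#' Repeatedly removes the edge of highest betweenness (recomputed after
#' every removal; ties broken by lexicographic `"A|B"` edge label), tracking
#' the connected-component partition after each removal. Returns the
#' partition along the removal sequence with maximum Newman-Girvan
#' modularity, computed on the original graph; the initial partition
#' (components before any removal) competes as well. Deterministic.
#'
#' @param g a `pan_graph` with >= 1 node.
#' @return a `community_partition`: list with `membership` (node ->
#'   community id), `Q`, and `removal_sequence` (edge labels in removal
#'   order).
#' @export
girvan_newman_communities <- function(g) {
  if (length(g$nodes) == 0L) stop("graph has no nodes")
  original <- g
  best_membership <- graph_components(g)
  best_q <- modularity_q(original, best_membership)
  removal <- character()
  work <- g
  while (nrow(work$edges) > 0) {
    eb <- edge_betweenness(work)
    labs <- names(eb)
    top <- labs[eb == max(eb)]
    victim <- sort(top)[1]
    removal <- c(removal, victim)
    work$edges <- work$edges[edge_labels(work) != victim, , drop = FALSE]
    memb <- graph_components(work)
    q <- modularity_q(original, memb)
    if (q > best_q + 1e-12) {
      best_q <- q
      best_membership <- memb
    }
  }
  structure(list(membership = best_membership, Q = best_q,
                 removal_sequence = removal),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat("community_partition:", length(unique(x$membership)), "communities, Q =",
      round(x$Q, 4), "\n")
  invisible(x)
}

#' Write a pan_graph as edge-list and membership TSVs
#'
#' @param g a `pan_graph`.
#' @param partition optional `community_partition`.
#' @param prefix file path prefix; writes `<prefix>_edges.tsv` and, given a
#'   partition, `<prefix>_membership.tsv`.
#' @return invisibly, the file paths written.
#' @export
write_pan_graph <- function(g, partition = NULL, prefix) {
  paths <- character()
  ef <- paste0(prefix, "_edges.tsv")
  utils::write.table(as.data.frame(g$edges), ef, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- ef
  if (!is.null(partition)) {
    mf <- paste0(prefix, "_membership.tsv")
    utils::write.table(
      data.frame(node = names(partition$membership),
                 community = unname(partition$membership),
                 is_seed = unname(g$is_seed[names(partition$membership)])),
      mf, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, mf)
  }
  invisible(paths)
}
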
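test_that("pan_graph canonicalizes edges: no self-loops, no duplicates", {
  g <- pan_graph(rbind(c("B", "A"), c("A", "B"), c("C", "C"), c("A", "C")),
                 seeds = "A")
  expect_equal(nrow(g$edges), 2)
  expect_true(all(g$edges[, 1] < g$edges[, 2]))
  expect_equal(unname(g$is_seed), c(TRUE, FALSE, FALSE))
})

test_that("BioGRID parsing filters taxid, self-loops, and duplicates", {
  df <- data.frame(official_symbol_a = c("a", "A", "C", "D"),
                   official_symbol_b = c("B", "b", "C", "E"),
                   taxid_a = c(9606, 9606, 9606, 10090),
                   taxid_b = c(9606, 9606, 9606, 10090))
  em <- parse_biogrid(df)
  expect_equal(unname(em), rbind(c("A", "B")), ignore_attr = TRUE)
  prov <- attr(em, "provenance")
  expect_equal(unname(prov[c("duplicates", "self_loops", "taxid_filtered")]),
               c(1, 1, 1))
  expect_equal(nrow(parse_biogrid(df[0, ])), 0)
  expect_error(parse_biogrid(df[, 1:3]), "taxid_b")
})

test_that("signature-network extraction keeps exactly seed-touching edges", {
  expect_equal(length(extract_signature_network(
    rbind(c("A", "B")), character())$nodes), 0)
  star <- rbind(c("HUB", "X"), c("HUB", "Y"), c("HUB", "Z"))
  g <- extract_signature_network(star, "HUB")
  expect_equal(nrow(g$edges), 3)
  # brute-force per-edge check on a random graph
  set.seed(51)
  nodes <- sprintf("N%03d", 1:60)
  em <- cbind(sample(nodes, 200, TRUE), sample(nodes, 200, TRUE))
  em <- em[em[, 1] != em[, 2], ]
  seeds <- sample(nodes, 10)
  g2 <- extract_signature_network(em, seeds)
  canon <- unique(t(apply(em, 1, sort)))
  expected <- canon[canon[, 1] %in% seeds | canon[, 2] %in% seeds, ,
                    drop = FALSE]
  expect_setequal(paste(g2$edges[, 1], g2$edges[, 2]),
                  paste(expected[, 1], expected[, 2]))
})

test_that("top-interactor augmentation ranks by distinct seed partners", {
  # X touches 3 seeds, Y touches 1; n = 1 keeps X only
  em <- rbind(c("S1", "X"), c("S2", "X"), c("S3", "X"), c("S1", "Y"),
              c("X", "Y"), c("S1", "S2"))
  seeds <- c("S1", "S2", "S3")
  g <- extract_signature_network(em, seeds)
  aug <- augment_top_interactors(g, em, seeds, n_interactors = 1)
  expect_true("X" %in% aug$nodes)
  expect_false("Y" %in% aug$nodes)
  # n = 0 leaves only seed-seed edges
  aug0 <- augment_top_interactors(g, em, seeds, n_interactors = 0)
  expect_equal(unname(aug0$edges), rbind(c("S1", "S2")))
  # brute-force sort-and-slice with lexicographic ties on a random instance
  set.seed(52)
  seeds2 <- sprintf("S%02d", 1:8)
  inter <- sprintf("I%02d", 1:50)
  em2 <- unique(rbind(
    cbind(sample(seeds2, 150, TRUE), sample(inter, 150, TRUE)),
    cbind(sample(inter, 60, TRUE), sample(inter, 60, TRUE))))
  em2 <- em2[em2[, 1] != em2[, 2], ]
  g2 <- extract_signature_network(em2, seeds2)
  aug2 <- augment_top_interactors(g2, em2, seeds2, n_interactors = 30)
  score <- vapply(inter, function(v) {
    prt <- unique(c(em2[em2[, 1] == v, 2], em2[em2[, 2] == v, 1]))
    length(intersect(prt, seeds2))
  }, integer(1))
  present <- intersect(inter, g2$nodes)
  ord <- present[order(-score[present], present)]
  expect_setequal(setdiff(aug2$nodes, seeds2), ord[1:30])
  # interactor-interactor edges present unless seed_edges_only
  augS <- augment_top_interactors(g2, em2, seeds2, 30, seed_edges_only = TRUE)
  expect_true(all(augS$edges[, 1] %in% seeds2 | augS$edges[, 2] %in% seeds2))
})

test_that("edge betweenness matches hand-enumerated small cases", {
  path <- pan_graph(rbind(c("A", "B"), c("B", "C")))
  expect_equal(edge_betweenness(path), c("A|B" = 2, "B|C" = 2))
  tri <- pan_graph(rbind(c("A", "B"), c("B", "C"), c("A", "C")))
  eb <- edge_betweenness(tri)
  expect_equal(eb[c("A|B", "A|C", "B|C")],
               c("A|B" = 1, "A|C" = 1, "B|C" = 1))
})

test_that("edge betweenness equals brute-force path enumeration on random graphs", {
  set.seed(53)
  for (i in 1:40) {
    em <- random_small_graph(sample(4:8, 1))
    if (nrow(em) == 0) next
    g <- pan_graph(em)
    eb <- edge_betweenness(g)
    oracle <- oracle_edge_betweenness(g$edges)
    expect_equal(eb[sort(names(eb))], oracle[sort(names(oracle))],
                 tolerance = 1e-10)
  }
})

test_that("edge betweenness agrees with igraph", {
  set.seed(54)
  em <- random_small_graph(8, 0.5)
  g <- pan_graph(em)
  ig <- igraph::graph_from_edgelist(g$edges, directed = FALSE)
  expect_equal(unname(edge_betweenness(g)[paste(g$edges[, 1], g$edges[, 2],
                                                sep = "|")]),
               igraph::edge_betweenness(ig), tolerance = 1e-10)
})

test_that("modularity worked examples and igraph agreement", {
  g1 <- pan_graph(rbind(c("A", "B")))
  expect_equal(modularity_q(g1, c(A = 1, B = 1)), 0)
  g2 <- pan_graph(rbind(c("A", "B"), c("C", "D")))
  expect_equal(modularity_q(g2, c(A = 1, B = 1, C = 2, D = 2)), 0.5)
  # all-singleton partition with no intra edges is negative
  set.seed(55)
  em <- random_small_graph(7, 0.5)
  g <- pan_graph(em)
  singles <- setNames(seq_along(g$nodes), g$nodes)
  expect_lt(modularity_q(g, singles), 0)
  ig <- igraph::graph_from_edgelist(g$edges, directed = FALSE)
  memb <- setNames(sample(1:3, length(g$nodes), TRUE), g$nodes)
  expect_equal(modularity_q(g, memb),
               igraph::modularity(ig, memb[igraph::V(ig)$name]),
               tolerance = 1e-12)
  expect_error(modularity_q(g, memb[-1]), "cover")
})

test_that("Girvan-Newman: bridge removed first, best split = the triangles", {
  tt <- pan_graph(rbind(c("A", "B"), c("B", "C"), c("A", "C"),
                        c("D", "E"), c("E", "F"), c("D", "F"), c("C", "D")))
  part <- girvan_newman_communities(tt)
  expect_equal(part$removal_sequence[1], "C|D")
  expect_true(same_partition(part$membership,
                             c(A = 1, B = 1, C = 1, D = 2, E = 2, F = 2)))
  # brute-force over all partitions of the 6 nodes confirms the optimum
  oracle <- oracle_best_partition(tt)
  expect_true(same_partition(part$membership, oracle$membership))
  expect_equal(part$Q, oracle$Q, tolerance = 1e-12)
})

test_that("Girvan-Newman on K5 keeps a single community", {
  k5 <- pan_graph(t(combn(LETTERS[1:5], 2)))
  part <- girvan_newman_communities(k5)
  expect_equal(length(unique(part$membership)), 1)
  expect_equal(part$Q, 0)
  oracle <- oracle_best_partition(k5)
  expect_equal(part$Q, oracle$Q, tolerance = 1e-12)
})

test_that("Girvan-Newman never merges components and beats the trivial split", {
  g <- pan_graph(rbind(c("A", "B"), c("B", "C"), c("X", "Y"), c("Y", "Z"),
                       c("X", "Z")))
  part <- girvan_newman_communities(g)
  comp <- graph_components(g)
  # community labels refine components
  for (cm in unique(part$membership)) {
    nodes <- names(part$membership)[part$membership == cm]
    expect_length(unique(comp[nodes]), 1)
  }
  expect_gte(part$Q, 0 - 1e-12)
  expect_equal(modularity_q(g, part$membership), part$Q)
  # determinism
  part2 <- girvan_newman_communities(g)
  expect_identical(part$membership, part2$membership)
  expect_identical(part$removal_sequence, part2$removal_sequence)
})

test_that("planted-partition fixtures are recovered up to relabelling", {
  gi <- generate_interaction_file(2, c(8, 8), p_in = 0.9, p_out = 0.02,
                                  seed = 61)
  g <- pan_graph(parse_biogrid(gi$records))
  part <- girvan_newman_communities(g)
  expect_true(same_partition(part$membership,
                             gi$community_label[names(part$membership)]))
})
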
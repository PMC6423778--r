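make_group_p <- function(msc, imsc, ipsc) {
  genes <- sprintf("g%02d", seq_along(msc))
  list(MSC = setNames(msc, genes), iMSC = setNames(imsc, genes),
       iPSC = setNames(ipsc, genes))
}

test_that("signature rules apply the printed strict thresholds", {
  gp <- make_group_p(msc  = c(0.0005, 0.5,  0.001, 0.0005, 0.05),
                     imsc = c(0.2,    1e-4, 0.5,   0.0005, 0.5),
                     ipsc = c(0.15,   1e-5, 0.5,   0.2,    0.5))
  res <- extract_signatures(gp)
  expect_equal(res$aging, "g01")          # 0.0005 / 0.2 / 0.15
  expect_equal(res$rejuvenation, "g02")   # 0.5 / 1e-4 / 1e-5
  # g03: p_MSC = 0.001 exactly -> neither (strict <)
  # g04: expressed in MSC and iMSC but iPSC dead zone fails both rules
  # g05: 0.05 is in the dead zone [0.001, 0.1] -> neither
  expect_false(any(c("g03", "g04", "g05") %in%
                     c(res$aging, res$rejuvenation)))
  expect_error(extract_signatures(gp[c("MSC", "iMSC")]), "iPSC")
  expect_error(extract_signatures(gp, 0.2, 0.1), "below")
})

test_that("aging and rejuvenation sets are disjoint on random inputs", {
  set.seed(17)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    gp <- make_group_p(10^runif(n, -5, 0), 10^runif(n, -5, 0),
                       10^runif(n, -5, 0))
    res <- extract_signatures(gp)
    expect_length(intersect(res$aging, res$rejuvenation), 0)
  }
})

test_that("planted signatures are recovered with few false positives", {
  planted_a <- sprintf("G%04d", 1:50)
  planted_r <- sprintf("G%04d", 51:100)
  cfg <- sim_config(n_genes = 1000, n_neg_controls = 1000,
                    planted_aging = planted_a,
                    planted_rejuvenation = planted_r, seed = 23)
  sim <- generate_bead_summary(cfg)
  res <- run_signature_pipeline(sim$bead)
  sc <- score_signatures(res, sim$truth)
  expect_gte(sc$aging_recovery, 0.95)
  expect_gte(sc$rejuvenation_recovery, 0.95)
  expect_lte(sc$false_positive_rate, 0.01)
})

test_that("pearson distance: affine invariance, anticorrelation, hand check", {
  m <- cbind(s1 = c(1, 2, 3, 5), s2 = 2 * c(1, 2, 3, 5) + 3,
             s3 = -c(1, 2, 3, 5))
  d <- pearson_distance(m)
  expect_equal(d["s1", "s2"], 0)
  expect_equal(d["s1", "s3"], 2)
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_equal(d, t(d))
  # hand computation on small values
  h <- cbind(a = c(1, 2, 4, 3), b = c(2, 1, 5, 4), c = c(9, 7, 2, 1))
  dh <- pearson_distance(h)
  expect_equal(dh["a", "b"], 1 - stats::cor(h[, "a"], h[, "b"]))
  expect_equal(dh["a", "c"], 1 - stats::cor(h[, "a"], h[, "c"]))
  expect_error(pearson_distance(cbind(a = c(1, 1, 1), b = c(1, 2, 3))),
               "zero-variance")
})

test_that("hierarchical clustering merges identical samples first and cuts cleanly", {
  m <- cbind(s1 = c(1, 5, 2, 8), s2 = c(1, 5, 2, 8) * 1.5 + 2,
             s3 = c(7, 1, 6, 0))
  hc <- hierarchical_cluster(pearson_distance(m))
  expect_equal(hc$height[1], 0)
  expect_setequal(hc$labels[-hc$merge[1, ]], c("s1", "s2"))
  expect_match(tree_newick(hc), "^\\(")
  # average-linkage merge heights on a 4-point metric, vs direct computation
  dm <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  dm["a", "b"] <- dm["b", "a"] <- 0.1
  dm["c", "d"] <- dm["d", "c"] <- 0.2
  dm["a", "c"] <- dm["c", "a"] <- 1.0; dm["a", "d"] <- dm["d", "a"] <- 1.2
  dm["b", "c"] <- dm["c", "b"] <- 1.1; dm["b", "d"] <- dm["d", "b"] <- 1.3
  hc2 <- hierarchical_cluster(dm)
  expect_equal(sort(hc2$height), c(0.1, 0.2, mean(c(1.0, 1.1, 1.2, 1.3))))
  expect_equal(unname(cut_clusters(hc2, 2)), c(1, 1, 2, 2))
})

test_that("planted group structure separates on cutting the sample tree", {
  cfg <- sim_config(n_genes = 600, n_neg_controls = 200,
                    planted_aging = sprintf("G%04d", 1:60),
                    planted_rejuvenation = sprintf("G%04d", 61:120), seed = 29)
  sim <- generate_bead_summary(cfg)
  m <- normalized_log2_matrix(sim$bead)
  hc <- hierarchical_cluster(pearson_distance(m))
  k2 <- cut_clusters(hc, 2)
  grp <- sim$bead$groups[names(k2)]
  # MSC-like vs pluripotent-like split, as in the study's dendrograms
  msc_side <- unique(k2[grp %in% c("fMSC", "aMSC")])
  plur_side <- unique(k2[grp %in% c("iPSC", "ESC")])
  expect_length(msc_side, 1)
  expect_length(plur_side, 1)
  expect_false(msc_side == plur_side)
})

test_that("gene-subset heatmap matrices report missing genes explicitly", {
  m <- matrix(rnorm(40), 10, 4,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("s%d", 1:4)))
  sub <- subset_heatmap_matrix(m, c("g01", "g05", "g99", "g88"))
  expect_equal(rownames(sub$matrix), c("g01", "g05"))
  expect_setequal(sub$missing, c("g99", "g88"))
  full <- subset_heatmap_matrix(m, sprintf("g%02d", 1:10))
  expect_equal(nrow(full$matrix), 10)
  expect_length(full$missing, 0)
  expect_error(subset_heatmap_matrix(m, c("x1", "x2")), "no requested genes")
})

test_that("hypergeometric enrichment matches the closed-form tail", {
  bg <- sprintf("g%02d", 1:20)
  ann <- list(hit = bg[1:5], null = bg[6:15])
  res <- hypergeom_enrichment(bg[1:5], ann, bg)
  hit <- res[res$term == "hit", ]
  expect_equal(hit$p, 1 / choose(20, 5), tolerance = 1e-10)
  # query = term = background -> p = 1
  res2 <- hypergeom_enrichment(bg, list(all = bg), bg)
  expect_equal(res2$p, 1)
  # overlap at expectation is unremarkable
  set.seed(41)
  bg2 <- sprintf("h%03d", 1:200)
  res3 <- hypergeom_enrichment(sample(bg2, 50), list(t = sample(bg2, 40)), bg2)
  expect_gt(res3$p, 0.05)
  expect_warning(hypergeom_enrichment(bg[1:2], list(x = c(bg[1], "alien")), bg),
                 "clipped")
  expect_error(hypergeom_enrichment(c("alien"), ann, bg), "subset")
})
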
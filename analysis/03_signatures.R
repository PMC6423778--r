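#!/usr/bin/env Rscript
# Step 3: extract the aging and rejuvenation signatures, score them against
# the planted truth, and validate the sample structure by correlation-based
# hierarchical clustering.

library(rejuvsig)

bead <- read_bead_summary("results/simulated/bead")
truth_tab <- utils::read.delim("results/simulated/planted_labels.tsv")

res <- run_signature_pipeline(bead)  # p < 0.001 expressed, p > 0.1 absent
print(res)

label <- stats::setNames(truth_tab$label, truth_tab$gene_id)
sc <- score_signatures(res, list(signature_label = label))
message(sprintf("recovery: aging %.1f%%, rejuvenation %.1f%%, FP %.2f%%",
                100 * sc$aging_recovery, 100 * sc$rejuvenation_recovery,
                100 * sc$false_positive_rate))

utils::write.table(
  data.frame(gene_id = c(res$aging, res$rejuvenation),
             signature = rep(c("aging", "rejuvenation"),
                             c(length(res$aging), length(res$rejuvenation)))),
  "results/signatures.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

# sample dendrogram on normalized log2 signals (1 - Pearson r distance)
m <- normalized_log2_matrix(bead)
hc <- hierarchical_cluster(pearson_distance(m), linkage = "average")
writeLines(tree_newick(hc), "results/sample_dendrogram.nwk")
k2 <- cut_clusters(hc, 2)
message("two-cluster cut of the sample tree:")
print(split(names(k2), k2))

# heatmap submatrix over the recovered aging signature
sub <- subset_heatmap_matrix(m, res$aging)
message(nrow(sub$matrix), " aging-signature genes in the heatmap matrix; ",
        length(sub$missing), " missing")
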
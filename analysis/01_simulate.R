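#!/usr/bin/env Rscript
# Step 1: simulate every input the pipeline consumes, with planted truth.
#
# Emulates the study design: five sample groups (fetal MSCs, adult MSCs,
# iPSCs, iMSCs, ESCs) on a bead array with negative-control beads; a
# BioGRID-style interaction table with decoy taxids; three cytokine-array
# membranes. All downstream steps read these outputs.

library(rejuvsig)

dir.create("results/simulated", showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(n_genes = 1000, n_neg_controls = 1000,
                  planted_aging = sprintf("G%04d", 1:50),
                  planted_rejuvenation = sprintf("G%04d", 51:100),
                  seed = 2026L)
sim <- generate_bead_summary(cfg)
write_bead_summary(sim$bead, "results/simulated/bead")
utils::write.table(
  data.frame(gene_id = names(sim$truth$signature_label),
             label = unname(sim$truth$signature_label)),
  "results/simulated/planted_labels.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
message("bead data: ", length(sim$bead$gene_ids), " genes x ",
        length(sim$bead$sample_ids), " samples written")

gi <- generate_interaction_file(2, c(8, 8), p_in = 0.9, p_out = 0.02,
                                seed = 2027L,
                                path = "results/simulated/interactions.tsv")
utils::write.table(
  data.frame(protein = names(gi$community_label),
             community = unname(gi$community_label)),
  "results/simulated/planted_communities.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
message("interaction file: ", gi$n_edges, " genuine edges + decoys written")

lay <- membrane_layout(c("ANG", "DKK1", "IL8", "PDGFAA", "OPN", "SERPINE1",
                         "VEGF", "IL6", "MIF"), n_rows = 4, n_cols = 4)
write_membrane_layout(lay, "results/simulated/membrane_layout.csv")
profiles <- list(
  fMSC = c(ANG = 0.9, DKK1 = 0.6, IL8 = 0.5, PDGFAA = 0.4, OPN = 0.35,
           SERPINE1 = 0.8, VEGF = 0.45, IL6 = 0.5, MIF = 0.3),
  iMSC = c(ANG = 0.8, DKK1 = 0.5, IL8 = 0.55, PDGFAA = 0.3, OPN = 0.4,
           SERPINE1 = 0.7, VEGF = 0.5, IL6 = 0.45, MIF = 0.25),
  aMSC = c(ANG = 0.1, DKK1 = 0.04, IL8 = 0.45, PDGFAA = 0.03, OPN = 0.08,
           SERPINE1 = 0.15, VEGF = 0.07, IL6 = 0.5, MIF = 0.12))
for (nm in names(profiles)) {
  img <- generate_membrane(profiles[[nm]], lay, seed = match(nm, names(profiles)))
  write_membrane_image(img, sprintf("results/simulated/membrane_%s.tif", nm))
}
message("membranes written for: ", paste(names(profiles), collapse = ", "))
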
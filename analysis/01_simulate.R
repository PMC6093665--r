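#!/usr/bin/env Rscript
# Stage 0 of the worked analysis: build the synthetic study matrices.
#
# Two matrices are produced under results/:
#   * sim_matrix.tnt          -- the working matrix the downstream scripts
#                                analyse: 12 OTUs x 40 characters, two change
#                                events per character, 25% missing cells.
#                                Small enough that the whole two-stage
#                                analysis reruns in minutes on one core.
#   * standin_28x83_synthetic.tnt -- a synthetic stand-in with the shape of
#                                the published aetosaur matrix (28 OTUs x 83
#                                characters, 7 additive characters, ~30%
#                                missing). It demonstrates the I/O layer at
#                                full scale; it is NOT the published matrix.
# The generating trees are written next to the matrices as ground truth.

library(mpsearch)
library(jsonlite)

dir.create("results", showWarnings = FALSE)
seed <- 20260925

message("simulating the working matrix (12 x 40) ...")
tr <- simulate_tree(12, seed = seed)
sim <- simulate_matrix(tr, sim_config(n_characters = 40, events_per_char = 2,
                                      missing_frac = 0.25, poly_frac = 0.02),
                       seed = seed + 1)
write_matrix(sim$matrix, "tnt", path = "results/sim_matrix.tnt")
ape::write.tree(sim$truth$tree, "results/sim_truth.nwk")
write_json(list(seed = seed, n_taxa = 12, n_characters = 40,
                events_per_char = 2, missing_frac = 0.25,
                ordered_characters = which(sim$truth$ordered)),
           "results/sim_truth.json", auto_unbox = TRUE, pretty = TRUE)

message("simulating the full-scale synthetic stand-in (28 x 83) ...")
tr28 <- simulate_tree(28, labels = sprintf("otu_%02d", 1:28), seed = seed + 2)
sim28 <- simulate_matrix(tr28, sim_config(), seed = seed + 3)
write_matrix(sim28$matrix, "tnt", path = "results/standin_28x83_synthetic.tnt")
ape::write.tree(sim28$truth$tree, "results/standin_28x83_synthetic_truth.nwk")

cm <- read_matrix("results/sim_matrix.tnt")
stopifnot(dim(cm) == c(12L, 40L))
message(sprintf("working matrix: %d taxa x %d characters, %d additive, %.0f%% missing",
                nrow(cm$cells), ncol(cm$cells), sum(cm$ordered),
                100 * mean(cm$cells == 0L)))
message("wrote results/sim_matrix.tnt and results/standin_28x83_synthetic.tnt")
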
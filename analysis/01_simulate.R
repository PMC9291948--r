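#!/usr/bin/env Rscript
# Step 1 — generate the reference synthetic dataset.
#
# Two species (chicken / turtle stand-ins), 12,000 orthologous genes,
# three mid-embryonic tissues x two AP levels x 3 replicates, plus a
# late-stage whole-embryo comparison; planted signals: a 46-gene
# conserved set (hedgehog-pathway analogue), a 40-gene term conserved in
# all tissues but divergent late (centriole analogue), ~600 housekeeping
# stand-ins conserved late. Writes TSVs under results/dataset/.

library(orthoconserv)

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1

config <- sim_config(seed = seed)
sim <- simulate_dataset(config)
print(sim)

dir <- "results/dataset"
write_dataset(sim, dir)
message(sprintf("dataset written to %s (%d + %d genes, %d samples/species)",
                dir, nrow(sim$expr_a), nrow(sim$expr_b), ncol(sim$expr_a)))
message(sprintf("planted: %d-gene conserved set, %d-gene late-divergent term, %d housekeeping stand-ins",
                length(sim$planted_set$members), length(sim$planted_term_units),
                length(sim$late_conserved_truth$members)))
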
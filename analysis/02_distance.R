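#!/usr/bin/env Rscript
# Step 2 — cross-species expression distances per tissue (1 - Spearman
# over 1:1 orthologs, matched replicate pairs) and Dunnett comparison of
# each tissue against the notochord. Reads results/dataset/, writes
# results/distances*.tsv and results/dunnett.tsv.

library(orthoconserv)

md <- read_sample_metadata("results/dataset/sample_metadata.tsv")
sp <- unique(md$species)
expr_a <- read_expression_matrix(sprintf("results/dataset/expression_%s.tsv", sp[1]), md)
expr_b <- read_expression_matrix(sprintf("results/dataset/expression_%s.tsv", sp[2]), md)
pairs <- read_ortholog_pairs("results/dataset/ortholog_pairs.tsv")

paired <- pair_one_to_one(pairs, expr_a, expr_b)
print(paired)

tissues <- setdiff(unique(md$tissue), "whole_embryo")
d <- tissue_distances(paired, md, pairing_mode = "matched", tissues = tissues)
s <- distance_summary(d)
dn <- distance_dunnett(d, reference_tissue = "notochord")

write.table(d, "results/distances.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
write.table(s, "results/distance_summary.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
write.table(dn, "results/dunnett.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

message("mean 1 - Spearman distance per tissue/AP cell:")
print(s)
message("Dunnett vs notochord (two-tailed, family-wise adjusted):")
print(dn)
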
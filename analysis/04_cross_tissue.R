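#!/usr/bin/env Rscript
# Step 4 — genes conserved in all three structures per AP level, then
# subtraction of genes also within-twofold in the late whole-embryo
# comparison. Writes results/conserved_genes.tsv.

library(orthoconserv)

md <- read_sample_metadata("results/dataset/sample_metadata.tsv")
sp <- unique(md$species)
expr_a <- read_expression_matrix(sprintf("results/dataset/expression_%s.tsv", sp[1]), md)
expr_b <- read_expression_matrix(sprintf("results/dataset/expression_%s.tsv", sp[2]), md)
paired <- pair_one_to_one(read_ortholog_pairs("results/dataset/ortholog_pairs.tsv"),
                          expr_a, expr_b)

late_idx <- expressed_unit_filter(paired, md, "whole_embryo", "none", min_mean_tpm = 0)
late_calls <- classify_conserved(
  log_ratios(paired, md, "whole_embryo", "none", units = late_idx))

tissues <- setdiff(unique(md$tissue), "whole_embryo")
rows <- list()
for (ap in c("anterior", "posterior")) {
  calls <- lapply(tissues, function(t)
    classify_conserved(log_ratios(paired, md, t, ap)))
  all3 <- intersect_conserved(calls)
  final <- subtract_late_stage(all3, late_calls)
  print(all3); print(final)
  units <- sort(unique(unlist(all3$provenance[tissues])))
  rows[[ap]] <- data.frame(
    ap_level = ap, unit_id = units,
    conserved_notochord = units %in% all3$provenance$notochord,
    conserved_neural_tube = units %in% all3$provenance$neural_tube,
    conserved_somites = units %in% all3$provenance$somites,
    conserved_late = units %in% final$provenance$late,
    in_final_list = units %in% final$units)
}
write.table(do.call(rbind, rows), "results/conserved_genes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
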
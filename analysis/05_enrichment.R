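#!/usr/bin/env Rscript
# Step 5 — GO-term enrichment of the late-filtered conserved gene lists
# against the expressed background, per AP level, with Holm correction
# and the anterior/posterior consistency report. Writes
# results/enrichment_{anterior,posterior}.tsv and
# results/consistent_terms.tsv.

library(orthoconserv)

md <- read_sample_metadata("results/dataset/sample_metadata.tsv")
sp <- unique(md$species)
expr_a <- read_expression_matrix(sprintf("results/dataset/expression_%s.tsv", sp[1]), md)
expr_b <- read_expression_matrix(sprintf("results/dataset/expression_%s.tsv", sp[2]), md)
paired <- pair_one_to_one(read_ortholog_pairs("results/dataset/ortholog_pairs.tsv"),
                          expr_a, expr_b)
uann <- unit_annotations(paired, read_annotations("results/dataset/annotations.tsv"))

cons <- read.delim("results/conserved_genes.tsv")
tissues <- setdiff(unique(md$tissue), "whole_embryo")
enr <- list()
for (ap in c("anterior", "posterior")) {
  background <- Reduce(intersect, lapply(tissues, function(t)
    names(expressed_unit_filter(paired, md, t, ap))))
  lst <- cons$unit_id[cons$ap_level == ap & cons$in_final_list]
  enr[[ap]] <- fisher_enrichment(lst, background, uann)
  message(sprintf("%s: %d list units vs %d background; %d terms tested, %d Holm-significant",
                  ap, length(lst), length(background), nrow(enr[[ap]]),
                  sum(enr[[ap]]$significant)))
  write.table(as.data.frame(enr[[ap]]),
              sprintf("results/enrichment_%s.tsv", ap),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

ct <- consistent_terms(enr$anterior, enr$posterior)
message("terms Holm-significant in both anterior and posterior lists:")
print(ct)
write.table(ct, "results/consistent_terms.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
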
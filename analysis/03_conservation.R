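#!/usr/bin/env Rscript
# Step 3 — twofold conservation of the hedgehog-pathway gene set and of
# its first member against the genomic background, per tissue/AP cell
# (species means for calls; all 9 cross-species replicate pairs for the
# fraction tests). Writes results/set_tests.tsv and results/gene_test.tsv.

library(orthoconserv)

md <- read_sample_metadata("results/dataset/sample_metadata.tsv")
sp <- unique(md$species)
expr_a <- read_expression_matrix(sprintf("results/dataset/expression_%s.tsv", sp[1]), md)
expr_b <- read_expression_matrix(sprintf("results/dataset/expression_%s.tsv", sp[2]), md)
paired <- pair_one_to_one(read_ortholog_pairs("results/dataset/ortholog_pairs.tsv"),
                          expr_a, expr_b)
ann <- read_annotations("results/dataset/annotations.tsv")
gene_set <- extract_gene_set(ann, "GO:0007224", paired)
print(gene_set)

rows <- list()
for (ap in c("anterior", "posterior")) {
  for (tissue in setdiff(unique(md$tissue), "whole_embryo")) {
    rp <- log_ratios(paired, md, tissue, ap, basis = "replicate_pair")
    st <- set_conservation_test(gene_set, classify_conserved(rp))
    print(st)
    rows[[paste(ap, tissue)]] <- data.frame(
      set = st$name, tissue = tissue, ap_level = ap, n_pairs = st$n_pairs,
      mean_frac_set = st$mean_frac_set, sd_set = st$sd_set,
      mean_frac_bg = st$mean_frac_bg, sd_bg = st$sd_bg,
      t = st$t, p = st$p.value)
  }
}
write.table(do.call(rbind, rows), "results/set_tests.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# single-gene test in the posterior notochord, the shh-style focal context
rp <- log_ratios(paired, md, "notochord", "posterior", basis = "replicate_pair")
focal <- intersect(gene_set$members, rownames(rp))[1]
g <- gene_conservation_test(rp, focal)
print(g)
write.table(data.frame(unit_id = g$unit_id, W = g$statistic, p = g$p.value,
                       n_focal = g$n_focal, n_background = g$n_background),
            "results/gene_test.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
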
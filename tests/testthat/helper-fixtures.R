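# Shared fixture builders: everything is constructed in code at test time.

# Metadata for two species over given tissue/AP cells.
make_metadata <- function(tissues = "notochord", ap_levels = "posterior",
                          n_reps = 3, species = c("chicken", "turtle"),
                          stages = c("HH16", "TK11")) {
  rows <- list()
  for (t in tissues) for (ap in ap_levels) for (s in seq_along(species)) {
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sprintf("%s_%s_%s_%d", species[s], t, ap, seq_len(n_reps)),
      species = species[s], tissue = t, ap_level = ap,
      replicate = seq_len(n_reps), stage = stages[s],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# A small PairedExpression built from explicit per-unit species values:
# every replicate of a species carries the unit's value (plus optional
# per-replicate offsets), so species means are exactly the given values.
make_paired <- function(vals_a, vals_b, metadata = make_metadata(),
                        offsets_a = NULL, offsets_b = NULL) {
  n <- length(vals_a)
  units <- names(vals_a) %||% sprintf("u%02d", seq_len(n))
  ga <- paste0("A_", units); gb <- paste0("B_", units)
  md_a <- metadata[metadata$species == unique(metadata$species)[1], ]
  md_b <- metadata[metadata$species == unique(metadata$species)[2], ]
  ma <- matrix(rep(vals_a, times = nrow(md_a)), nrow = n,
               dimnames = list(ga, md_a$sample_id))
  mb <- matrix(rep(vals_b, times = nrow(md_b)), nrow = n,
               dimnames = list(gb, md_b$sample_id))
  if (!is.null(offsets_a)) ma <- ma + offsets_a
  if (!is.null(offsets_b)) mb <- mb + offsets_b
  pair_one_to_one(data.frame(gene_a = ga, gene_b = gb), ma, mb)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Conservation-call matrix built directly from a logical vector.
make_calls <- function(units, conserved, tissue, ap_level = "posterior",
                       basis = "species_mean") {
  m <- matrix(conserved, ncol = 1, dimnames = list(units, basis))
  structure(m, class = c("ConservationCall", "matrix"), tissue = tissue,
            ap_level = ap_level, basis = basis, pseudocount = 1,
            fold_threshold = 2)
}

# Small simulated dataset reused by several files.
small_sim <- function(n_genes = 600, seed = 42, ...) {
  simulate_dataset(sim_config(n_genes = n_genes, seed = seed, ...))
}

# Independent mid-rank computation (sorting + tie averaging, no rank()).
oracle_midranks <- function(x) {
  o <- order(x)
  r <- numeric(length(x))
  i <- 1L
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && x[o[j + 1L]] == x[o[i]]) j <- j + 1L
    r[o[i:j]] <- mean(i:j)
    i <- j + 1L
  }
  r
}

# Spearman distance oracle: Pearson product-moment formula on oracle
# mid-ranks, written out explicitly.
oracle_spearman_distance <- function(x, y) {
  rx <- oracle_midranks(x); ry <- oracle_midranks(y)
  n <- length(x)
  sxy <- sum((rx - mean(rx)) * (ry - mean(ry)))
  sxx <- sum((rx - mean(rx))^2); syy <- sum((ry - mean(ry))^2)
  1 - sxy / sqrt(sxx * syy)
}

# Exhaustive rank-sum enumeration oracle: two-sided p of the rank-sum of
# x over all C(n1+n2, n1) assignments of the pooled mid-ranks.
oracle_rank_sum_p <- function(x, y) {
  pooled <- c(x, y)
  r <- oracle_midranks(pooled)
  n1 <- length(x)
  w <- sum(r[seq_len(n1)])
  sums <- combn(length(pooled), n1, FUN = function(i) sum(r[i]))
  eps <- 1e-9
  p_le <- mean(sums <= w + eps)
  p_ge <- mean(sums >= w - eps)
  min(1, 2 * min(p_le, p_ge))
}
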
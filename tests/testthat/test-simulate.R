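test_that("configuration validation names the offending field", {
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(background_conserved_prob = 1.2),
               "background_conserved_prob")
  expect_error(sim_config(dup_rate = 0.7, loss_rate = 0.6), "rates sum")
  expect_error(sim_config(n_genes = 40, planted_set_size = 30,
                          planted_term_size = 20), "planted_set_size")
  expect_error(sim_config(tissues = c(0.5, 0.8)), "tissues")
  expect_error(sim_config(tissues = c(notochord = 1.5)), "tissues")
})

test_that("identical config and seed give identical datasets and files", {
  s1 <- small_sim(n_genes = 200, seed = 11)
  s2 <- small_sim(n_genes = 200, seed = 11)
  expect_identical(s1, s2)
  s3 <- small_sim(n_genes = 200, seed = 12)
  expect_false(identical(s3$expr_a, s1$expr_a))

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(s1, d1); write_dataset(s2, d2)
  for (f in list.files(d1))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
})

test_that("generated matrices are non-negative and fully described by metadata", {
  sim <- small_sim(n_genes = 300, seed = 5)
  expect_true(all(sim$expr_a >= 0) && all(sim$expr_b >= 0))
  expect_false(anyNA(sim$expr_a) || anyNA(sim$expr_b))
  samples <- c(colnames(sim$expr_a), colnames(sim$expr_b))
  expect_setequal(samples, sim$metadata$sample_id)
  expect_equal(anyDuplicated(sim$metadata$sample_id), 0L)
  validate_sample_metadata(sim$metadata)
  validate_expression_matrix(sim$expr_a, sim$metadata)
  validate_expression_matrix(sim$expr_b, sim$metadata)
  # expected cells: 3 tissues x 2 AP + late, 3 replicates, 2 species
  expect_equal(nrow(sim$metadata), (3 * 2 + 1) * 3 * 2)
})

test_that("without duplications and losses the group table collapses to the 1:1 pairs", {
  sim <- small_sim(n_genes = 150, dup_rate = 0, loss_rate = 0)
  expect_equal(nrow(sim$pairs), 150L)
  per_group <- table(sim$groups$group_id, sim$groups$species)
  expect_true(all(per_group == 1))
  expect_setequal(sim$groups$gene_id[sim$groups$species == "chicken"],
                  sim$pairs$gene_a)
})

test_that("duplications and losses perturb only the group table structure", {
  sim <- small_sim(n_genes = 400, seed = 9, dup_rate = 0.1, loss_rate = 0.1)
  tr <- sim$truth
  expect_gt(sum(tr$duplicated), 0)
  expect_gt(sum(tr$lost), 0)
  # strict 1:1 pair table excludes every duplicated or lost gene
  expect_equal(nrow(sim$pairs), sum(tr$duplicated == 0 & tr$lost == 0))
  # a duplicated gene has two members in one species
  gdup <- sprintf("OG%05d", which(tr$duplicated == 1)[1])
  expect_equal(sum(sim$groups$group_id == gdup), 3L)
  # a lost gene is absent from one species' matrix and group rows
  glost <- which(tr$lost == 1)[1]
  expect_equal(sum(sim$groups$group_id == sprintf("OG%05d", glost)), 1L)
  expect_false(tr$gene_a[glost] %in% rownames(sim$expr_a) &&
                 tr$gene_b[glost] %in% rownames(sim$expr_b))
})

test_that("realized species-mean Spearman correlation hits the per-tissue targets", {
  targets <- c(notochord = 0.85, neural_tube = 0.80, somites = 0.70)
  sim <- simulate_dataset(sim_config(n_genes = 5000, tissues = targets,
                                     n_replicates = 3, seed = 1))
  paired <- pair_one_to_one(sim$pairs, sim$expr_a, sim$expr_b)
  for (t in names(targets)) for (ap in c("anterior", "posterior")) {
    cs <- orthoconserv:::cell_samples(paired, sim$metadata, t, ap)
    rho <- cor(rowMeans(paired$values_a[, cs$a]),
               rowMeans(paired$values_b[, cs$b]), method = "spearman")
    expect_lt(abs(rho - targets[[t]]), 0.05, label = paste(t, ap))
  }
})

test_that("lower target rho gives larger expected distances, over many seeds", {
  targets <- c(notochord = 0.9, neural_tube = 0.75, somites = 0.6)
  mean_d <- matrix(NA_real_, nrow = 50, ncol = 3,
                   dimnames = list(NULL, names(targets)))
  for (s in seq_len(50)) {
    sim <- simulate_dataset(sim_config(
      n_genes = 600, tissues = targets, ap_levels = "posterior",
      dup_rate = 0, loss_rate = 0, seed = 1000 + s))
    paired <- pair_one_to_one(sim$pairs, sim$expr_a, sim$expr_b)
    d <- tissue_distances(paired, sim$metadata, "matched",
                          tissues = names(targets))
    mean_d[s, ] <- tapply(d$distance, d$tissue, mean)[names(targets)]
  }
  avg <- colMeans(mean_d)
  expect_lt(avg["notochord"], avg["neural_tube"])
  expect_lt(avg["neural_tube"], avg["somites"])
})

test_that("the planted set is visibly more within-twofold than the background", {
  diffs <- vapply(1:10, function(s) {
    sim <- simulate_dataset(sim_config(
      n_genes = 800, tissues = c(notochord = 0.8),
      ap_levels = "posterior", planted_set_size = 46,
      planted_set_conserved_prob = 0.9, background_conserved_prob = 0.5,
      dup_rate = 0, loss_rate = 0, seed = 200 + s))
    paired <- pair_one_to_one(sim$pairs, sim$expr_a, sim$expr_b)
    r <- log_ratios(paired, sim$metadata, "notochord", "posterior",
                    basis = "species_mean", min_mean_tpm = 0)
    calls <- classify_conserved(r)
    set <- sim$planted_set$members
    bg <- setdiff(rownames(calls), set)
    mean(calls[intersect(set, rownames(calls)), 1]) - mean(calls[bg, 1])
  }, numeric(1))
  # expected gap at least half the planted probability difference
  expect_gt(mean(diffs), (0.9 - 0.5) / 2)
})
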
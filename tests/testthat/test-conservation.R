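test_that("log2 ratios follow the pseudocount formula on both bases", {
  md <- make_metadata()
  p <- make_paired(c(u1 = 10, u2 = 31, u3 = 0, u4 = 7),
                   c(u1 = 10, u2 = 7, u3 = 0, u4 = 31), md)
  r <- log_ratios(p, md, "notochord", "posterior", basis = "species_mean",
                  pseudocount = 1, min_mean_tpm = 0)
  expect_equal(unname(r[1, 1]), 0)                      # a = b = 10
  expect_equal(unname(r[2, 1]), log2(32 / 8))           # = 2.0 exactly
  expect_equal(unname(r[3, 1]), 0)                      # (0, 0): conserved by convention
  expect_equal(unname(r[4, 1]), -2)                     # swap symmetry of the example
  expect_error(log_ratios(p, md, "notochord", "posterior", pseudocount = 0),
               "pseudocount")

  rp <- log_ratios(p, md, "notochord", "posterior", basis = "replicate_pair",
                   min_mean_tpm = 0)
  expect_equal(dim(rp), c(4L, 9L))
  expect_true(all(rp[2, ] == 2))   # replicates are identical in this fixture
})

test_that("twofold classification is inclusive at the boundary", {
  md <- make_metadata()
  # printed species-mean TPM; with c = 1, |r| <= 1 exactly for the first six
  a <- c(u01 = 10, u02 = 31, u03 = 3, u04 = 0, u05 = 19, u06 = 5,
         u07 = 63, u08 = 1, u09 = 99, u10 = 7)
  b <- c(u01 = 10, u02 = 15, u03 = 7, u04 = 1, u05 = 9, u06 = 11,
         u07 = 15, u08 = 7, u09 = 24, u10 = 34)
  p <- make_paired(a, b, md)
  r <- log_ratios(p, md, "notochord", "posterior", min_mean_tpm = 0)
  calls <- classify_conserved(r, fold_threshold = 2)
  got <- unname(calls[, 1])
  # by hand: |log2((a+1)/(b+1))| = 0, 1, 1, 1, 1, 1, 2, 3, 2, ~2.13
  expect_equal(got, c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE,
                      FALSE, FALSE))
  expect_equal(sum(got), 6L)
  expect_error(classify_conserved(r, fold_threshold = 1), "fold_threshold")
  # widening the threshold can only add units
  wider <- classify_conserved(r, fold_threshold = 4.3)
  expect_true(all(wider[got, 1]))
  expect_equal(sum(wider[, 1]), 9L)
})

test_that("swapping the species negates ratios and preserves every call and test", {
  sim <- small_sim(n_genes = 250, seed = 21, dup_rate = 0, loss_rate = 0)
  md <- sim$metadata
  p_ab <- pair_one_to_one(sim$pairs, sim$expr_a, sim$expr_b)
  p_ba <- pair_one_to_one(data.frame(gene_a = sim$pairs$gene_b,
                                     gene_b = sim$pairs$gene_a),
                          sim$expr_b, sim$expr_a)
  for (basis in c("species_mean", "replicate_pair")) {
    r1 <- log_ratios(p_ab, md, "notochord", "posterior", basis = basis)
    r2 <- log_ratios(p_ba, md, "notochord", "posterior", basis = basis)
    # replicate pair i|j of the swapped analysis corresponds to j|i
    swap_cols <- if (basis == "species_mean") colnames(r2) else
      vapply(strsplit(colnames(r1), "|", fixed = TRUE),
             function(v) paste(rev(v), collapse = "|"), character(1))
    expect_equal(unname(unclass(r2[, swap_cols, drop = FALSE])),
                 -unname(unclass(r1)), tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(unname(unclass(classify_conserved(r2)[, swap_cols, drop = FALSE])),
                 unname(unclass(classify_conserved(r1))), ignore_attr = TRUE)
  }
  # set and gene tests are invariant under the swap
  cp1 <- classify_conserved(log_ratios(p_ab, md, "notochord", "posterior",
                                       basis = "replicate_pair"))
  cp2 <- classify_conserved(log_ratios(p_ba, md, "notochord", "posterior",
                                       basis = "replicate_pair"))
  set1 <- sim$planted_set$members
  set2 <- paste0(sim$pairs$gene_b, "|", sim$pairs$gene_a)[
    match(set1, paste0(sim$pairs$gene_a, "|", sim$pairs$gene_b))]
  s1 <- set_conservation_test(set1, cp1)
  s2 <- set_conservation_test(set2, cp2)
  expect_equal(s2$p.value, s1$p.value, tolerance = 1e-12)
  expect_equal(s2$mean_frac_set, s1$mean_frac_set, tolerance = 1e-12)
  rp1 <- log_ratios(p_ab, md, "notochord", "posterior", basis = "replicate_pair")
  rp2 <- log_ratios(p_ba, md, "notochord", "posterior", basis = "replicate_pair")
  u <- rownames(rp1)[5]
  u_swap <- rownames(rp2)[5]
  g1 <- gene_conservation_test(rp1, u)
  g2 <- gene_conservation_test(rp2, u_swap)
  expect_equal(g2$p.value, g1$p.value, tolerance = 1e-12)
})

test_that("exact rank-sum p matches exhaustive enumeration, ties included", {
  # worked case: complete separation 3 vs 5 gives two-sided p = 2/56
  x <- c(0.1, 0.2, 0.3); y <- c(0.5, 0.6, 0.7, 0.8, 0.9)
  r <- rank_sum_test(x, y)
  expect_true(r$exact)
  expect_equal(r$p.value, 2 / 56, tolerance = 1e-12)
  expect_equal(r$p.value, oracle_rank_sum_p(x, y), tolerance = 1e-12)

  # identical multisets sit at the null mean: p = 1
  z <- c(1, 2, 2, 3)
  expect_equal(rank_sum_test(z, z)$p.value, 1)

  withr::local_seed(31)
  sizes <- list(c(3, 3), c(4, 6), c(5, 5), c(2, 9), c(7, 8), c(6, 10))
  for (sz in sizes) {
    x <- sample(6, sz[1], replace = TRUE)  # heavy ties
    y <- sample(6, sz[2], replace = TRUE)
    r <- rank_sum_test(x, y)
    expect_true(r$exact)
    expect_equal(r$p.value, oracle_rank_sum_p(x, y), tolerance = 1e-12,
                 label = paste(sz, collapse = "v"))
  }
  # untied data also agrees with the exact path of stats::wilcox.test
  for (i in 1:5) {
    x <- runif(6); y <- runif(7)
    expect_equal(rank_sum_test(x, y)$p.value,
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
  }
})

test_that("large-sample rank-sum p uses the tie-corrected normal approximation", {
  withr::local_seed(32)
  x <- sample(10, 15, replace = TRUE)
  y <- sample(10, 400, replace = TRUE)
  r <- rank_sum_test(x, y)
  expect_false(r$exact)
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(r$p.value, ref$p.value, tolerance = 1e-10)
  # statistic is the rank-sum; wilcox.test reports U = W - n1(n1+1)/2
  expect_equal(r$statistic - length(x) * (length(x) + 1) / 2,
               unname(ref$statistic))
})

test_that("gene conservation test ranks a planted gene against the background pool", {
  sim <- simulate_dataset(sim_config(
    n_genes = 2000, tissues = c(notochord = 0.8), ap_levels = "posterior",
    dup_rate = 0, loss_rate = 0, seed = 33))
  paired <- pair_one_to_one(sim$pairs, sim$expr_a, sim$expr_b)
  rp <- log_ratios(paired, sim$metadata, "notochord", "posterior",
                   basis = "replicate_pair")
  forced_units <- sim$planted_set$members[
    sim$truth$forced_conserved[match(sim$planted_set$members,
      paste0(sim$truth$gene_a, "|", sim$truth$gene_b))] == 1]
  focal <- intersect(forced_units, rownames(rp))[1]
  g <- gene_conservation_test(rp, focal)
  expect_equal(g$n_focal, 9)
  expect_equal(g$n_background, (nrow(rp) - 1) * 9)
  expect_lt(g$p.value, 0.05)
  expect_error(gene_conservation_test(rp, "absent|unit"), "not expressed")
  rm_ <- log_ratios(paired, sim$metadata, "notochord", "posterior")
  expect_error(gene_conservation_test(rm_, focal), "replicate_pair")
})

test_that("set conservation test behaves at its degenerate and strong limits", {
  units <- sprintf("u%03d", 1:120)
  set <- units[1:20]
  # fractions identical between set and background in every pair: t = 0, p = 1
  calls_eq <- matrix(rep(c(TRUE, FALSE), each = 10, times = 9 * 6), 120, 9,
                     dimnames = list(units, NULL))
  attr(calls_eq, "basis") <- "replicate_pair"
  s0 <- set_conservation_test(set, calls_eq)
  expect_equal(s0$t, 0)
  expect_equal(s0$p.value, 1)

  # constant +0.2 difference with tiny per-pair variance: p << 0.001
  frac_set <- c(0.7, rep(0.7, 7), 0.75)
  frac_bg <- c(0.5, rep(0.5, 7), 0.55)
  calls_diff <- matrix(FALSE, 120, 9, dimnames = list(units, NULL))
  for (j in 1:9) {
    calls_diff[seq_len(round(frac_set[j] * 20)), j] <- TRUE
    calls_diff[20 + seq_len(round(frac_bg[j] * 100)), j] <- TRUE
  }
  s1 <- set_conservation_test(set, calls_diff)
  expect_equal(s1$n_pairs, 9)
  expect_lt(s1$p.value, 0.001)
  expect_gt(s1$t, 0)

  # unpaired mode on the same data is also significant here
  s1u <- set_conservation_test(set, calls_diff, paired = FALSE)
  expect_lt(s1u$p.value, 0.001)

  expect_error(set_conservation_test(character(0), calls_diff), "empty")
  expect_error(set_conservation_test("not_a_unit", calls_diff),
               "no expressed units")
  expect_error(set_conservation_test(set, calls_diff[, 1, drop = FALSE]),
               "replicate pairs")
})

test_that("including the set in the background moves fractions by at most |set|/|bg|", {
  withr::local_seed(34)
  units <- sprintf("u%03d", 1:200)
  calls <- matrix(runif(200 * 9) < 0.6, 200, 9, dimnames = list(units, NULL))
  set <- units[1:25]
  s_ex <- set_conservation_test(set, calls, exclude_set = TRUE)
  s_in <- set_conservation_test(set, calls, exclude_set = FALSE)
  bound <- length(set) / s_ex$n_bg_units
  expect_true(all(abs(s_in$frac_bg - s_ex$frac_bg) <= bound + 1e-12))
  expect_equal(s_in$frac_set, s_ex$frac_set)
})
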
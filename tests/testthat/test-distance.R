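test_that("spearman distance matches the exact rank formula and its limits", {
  expect_equal(spearman_distance(c(2, 5, 9, 1), c(2, 5, 9, 1)), 0)
  expect_equal(spearman_distance(c(1, 2, 3), c(3, 2, 1)), 2)
  # rho = 1 - 6 * sum(d^2) / (n (n^2 - 1)) with d = (0, 1, 1, 0): rho = 0.8
  expect_equal(spearman_distance(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.2,
               tolerance = 1e-12)
})

test_that("spearman distance is symmetric and monotone-transform invariant", {
  withr::local_seed(1)
  for (i in 1:20) {
    x <- sample(50, 12, replace = TRUE)  # ties likely
    y <- sample(50, 12, replace = TRUE)
    d <- spearman_distance(x, y)
    expect_equal(spearman_distance(y, x), d)
    expect_equal(spearman_distance(exp(x / 10), y), d, tolerance = 1e-12)
    expect_equal(spearman_distance(x, 3 * y + 7), d, tolerance = 1e-12)
    expect_gte(d, 0); expect_lte(d, 2)
  }
})

test_that("spearman distance rejects degenerate input", {
  expect_error(spearman_distance(c(1, 1, 1), c(1, 2, 3)), "constant vector")
  expect_error(spearman_distance(1:3, c(2, 2, 2)), "constant vector")
  expect_error(spearman_distance(1:2, 1:2), "at least 3")
  expect_error(spearman_distance(1:4, 1:3), "differ in length")
})

test_that("expression filter keeps units above threshold in at least one species", {
  md <- make_metadata()
  means_a <- c(u1 = 0.0, u2 = 0.0, u3 = 1.0, u4 = 0.4, u5 = 12,
               u6 = 0.99, u7 = 3, u8 = 0.2, u9 = 1.01, u10 = 0)
  means_b <- c(u1 = 0.0, u2 = 5.0, u3 = 0.3, u4 = 0.6, u5 = 9,
               u6 = 0.98, u7 = 2, u8 = 0.9, u9 = 0, u10 = 0.5)
  p <- make_paired(means_a, means_b, md)
  idx <- expressed_unit_filter(p, md, "notochord", "posterior", min_mean_tpm = 1)
  # u1 (0,0) excluded; u2 (0,5) kept by the one-species rule; u6 (.99,.98) out
  expect_setequal(names(idx), paste0("A_", c("u2", "u3", "u5", "u7", "u9"),
                                     "|B_", c("u2", "u3", "u5", "u7", "u9")))
  expect_error(expressed_unit_filter(p, md, "somites", "posterior"),
               "absent from metadata")
  expect_error(expressed_unit_filter(p, md, "notochord", "posterior",
                                     min_mean_tpm = 1000),
               "no units pass")
})

test_that("replicate pairing yields n records matched and n_A x n_B all_pairs", {
  md <- make_metadata(tissues = c("notochord", "neural_tube"),
                      ap_levels = c("anterior", "posterior"), n_reps = 3)
  withr::local_seed(2)
  vals <- runif(40, 1, 100)
  p <- make_paired(stats::setNames(vals, sprintf("u%02d", 1:40)),
                   vals + runif(40, -1, 1), md,
                   offsets_a = matrix(runif(40 * 12), 40),
                   offsets_b = matrix(runif(40 * 12), 40))
  dm <- tissue_distances(p, md, "matched")
  expect_equal(nrow(dm), 4 * 3)
  expect_true(all(table(dm$tissue, dm$ap_level) == 3))
  da <- tissue_distances(p, md, "all_pairs")
  expect_true(all(table(da$tissue, da$ap_level) == 9))
  expect_true(all(da$distance >= 0 & da$distance <= 2))
  s <- distance_summary(dm)
  expect_equal(nrow(s), 4)
  expect_true(all(is.finite(s$sd_distance)))
})

test_that("matched pairing with unequal replicate counts points to all_pairs", {
  md <- make_metadata(n_reps = 3)
  md <- md[!(md$species == "turtle" & md$replicate == 3), ]
  withr::local_seed(3)
  vals <- runif(30, 1, 50)
  p <- make_paired(stats::setNames(vals, sprintf("u%02d", 1:30)), vals, md,
                   offsets_a = matrix(runif(30 * 3), 30),
                   offsets_b = matrix(runif(30 * 2), 30))
  expect_error(tissue_distances(p, md, "matched"), "all_pairs")
  da <- tissue_distances(p, md, "all_pairs")
  expect_equal(nrow(da), 3 * 2)
})

test_that("Dunnett with two groups reduces to the pooled two-sample t test", {
  withr::local_seed(4)
  for (i in 1:25) {
    x <- rnorm(3 + i %% 3, 0.3, 0.05)
    y <- rnorm(3 + (i + 1) %% 3, 0.25, 0.05)
    r <- dunnett_test(c(x, y), rep(c("ref", "b"), c(length(x), length(y))), "ref")
    tt <- t.test(y, x, var.equal = TRUE)
    expect_equal(r$p_adjusted, tt$p.value, tolerance = 1e-6)
    expect_equal(r$mean_diff, mean(y) - mean(x), tolerance = 1e-12)
  }
})

test_that("Dunnett on identical groups is non-significant, and detects a shifted group", {
  vals <- c(0.30, 0.31, 0.29)
  r0 <- dunnett_test(rep(vals, 3), rep(c("notochord", "neural_tube", "somites"),
                                       each = 3), "notochord")
  expect_true(all(r0$p_adjusted >= 0.999))

  r <- dunnett_test(c(0.30, 0.31, 0.29, 0.10, 0.11, 0.09, 0.30, 0.29, 0.31),
                    rep(c("notochord", "a", "b"), each = 3), "notochord")
  expect_lt(r$p_adjusted[r$comparison == "a"], 0.05)
  expect_gt(r$p_adjusted[r$comparison == "b"], 0.05)
  expect_error(dunnett_test(1:6, rep(c("a", "b"), 3), "zz"), "absent")
})

test_that("Dunnett adjusted p is never below the per-comparison t-test p", {
  withr::local_seed(5)
  for (i in 1:20) {
    g <- rep(c("r", "a", "b", "c"), each = 4)
    v <- rnorm(16, mean = rep(runif(4, 0, 0.5), each = 4), sd = 0.1)
    r <- dunnett_test(v, g, "r")
    expect_true(all(r$p_adjusted >= r$p_unadjusted - 1e-9))
    expect_true(all(r$p_adjusted >= 0 & r$p_adjusted <= 1))
  }
})

test_that("Dunnett agrees with the multcomp reference implementation", {
  withr::local_seed(6)
  v <- rnorm(12, mean = rep(c(0.3, 0.2, 0.35, 0.28), each = 3), sd = 0.04)
  g <- factor(rep(c("notochord", "a", "b", "c"), each = 3))
  g <- relevel(g, "notochord")
  ours <- dunnett_test(v, as.character(g), "notochord")
  fit <- stats::aov(v ~ g)
  mc <- summary(multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett")),
                test = multcomp::adjusted("single-step"))
  ref <- as.numeric(mc$test$pvalues)
  names(ref) <- sub("^(.*) - notochord$", "\\1", names(mc$test$coefficients))
  expect_equal(ours$p_adjusted[match(names(ref), ours$comparison)], ref,
               tolerance = 2e-3, ignore_attr = TRUE)
})

test_that("per-AP Dunnett wrapper compares every tissue against the reference", {
  sim <- small_sim(n_genes = 400, seed = 8)
  paired <- pair_one_to_one(sim$pairs, sim$expr_a, sim$expr_b)
  d <- tissue_distances(paired, sim$metadata, "matched",
                        tissues = names(sim$config$tissues))
  dn <- distance_dunnett(d, "notochord")
  expect_equal(nrow(dn), 2 * 2)  # 2 AP levels x (3 tissues - 1)
  expect_setequal(unique(dn$comparison), c("neural_tube", "somites"))
  expect_true(all(dn$p_adjusted >= dn$p_unadjusted - 1e-9))
})
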
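# Synthetic two-species expression data with planted conservation signal.
#
# The generator emulates the sampling design of the study: two species,
# three mid-embryonic tissues (notochord, neural tube, somites) at two
# anteroposterior levels with three biological replicates each, plus a
# late-stage whole-embryo comparison. Expression is log-normal on the TPM
# scale; cross-species divergence is additive noise on the true log2
# level whose variance is solved numerically (against a Monte-Carlo rank
# correlation estimator) so the species-mean Spearman correlation per
# tissue hits a configurable target. Conservation ground truth is planted
# by zeroing divergence (up to a sub-twofold jitter) for selected genes.

#' Simulation configuration
#'
#' Builds and validates the configuration for [simulate_dataset()]. The
#' defaults describe the reference design: 12,000 orthologous genes, three
#' tissues with cross-species Spearman targets 0.85 / 0.80 / 0.70, two AP
#' levels, three replicates per species/tissue/level, a 46-gene planted
#' set with elevated conservation (the hedgehog-pathway analogue), and a
#' planted term annotating genes conserved in all three tissues but
#' divergent at the late stage (the centriole analogue).
#'
#' @param n_genes number of ancestral 1:1 ortholog units.
#' @param tissues named numeric vector: target cross-species Spearman rho
#'   per tissue (each in \[0, 1\]).
#' @param ap_levels anteroposterior level labels.
#' @param n_replicates biological replicates per species/tissue/level.
#' @param noise_sd SD of i.i.d. replicate noise on the log2-TPM scale.
#' @param baseline_log2tpm_mean,baseline_log2tpm_sd gene baseline
#'   distribution (log2 TPM), i.e. log-normal TPM.
#' @param dup_rate,loss_rate per-gene probabilities of a duplication
#'   (two members in one species, ortholog-group table only) or a loss
#'   (absent from one species).
#' @param planted_set_size,planted_set_conserved_prob size of the planted
#'   conserved gene set and its per-gene probability of enforced
#'   within-twofold conservation in all tissues.
#' @param background_conserved_prob same probability for background genes.
#' @param planted_term_id,planted_term_size annotation term planted on
#'   genes engineered to be conserved in all tissues but not late.
#' @param n_terms total number of annotation terms (planted ones included).
#' @param late_conserved_frac fraction of genes acting as housekeeping
#'   stand-ins: within-twofold in the late whole-embryo comparison.
#' @param late_divergence_sd SD of late-stage log2 divergence for genes
#'   that are not late-conserved.
#' @param species,mid_stages,late_stages labels for the two species and
#'   their mid/late developmental stages.
#' @param calibration_mc Monte-Carlo panel size used to calibrate the
#'   divergence SD against the rho targets (accuracy/speed trade-off).
#' @param seed master seed; all sub-streams are derived from it.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 12000,
                       tissues = c(notochord = 0.85, neural_tube = 0.80,
                                   somites = 0.70),
                       ap_levels = c("anterior", "posterior"),
                       n_replicates = 3,
                       noise_sd = 0.25,
                       baseline_log2tpm_mean = 3,
                       baseline_log2tpm_sd = 2,
                       dup_rate = 0.05,
                       loss_rate = 0.05,
                       planted_set_size = 46,
                       planted_set_conserved_prob = 0.9,
                       background_conserved_prob = 0.5,
                       planted_term_id = "GO:0005814",
                       planted_term_size = 40,
                       n_terms = 50,
                       late_conserved_frac = 0.05,
                       late_divergence_sd = 2,
                       species = c("chicken", "turtle"),
                       mid_stages = c("HH16", "TK11"),
                       late_stages = c("HH38", "TK27"),
                       calibration_mc = 40000,
                       seed = 1) {
  cfg <- as.list(environment())
  chk_num <- function(field, lo = -Inf, hi = Inf, len = 1L) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != len || anyNA(v) || any(v < lo) || any(v > hi))
      stopf("invalid config field '%s'", field)
  }
  chk_num("n_genes", lo = 1)
  if (!is.numeric(tissues) || is.null(names(tissues)) || !length(tissues) ||
      any(tissues < 0) || any(tissues > 1) || anyNA(tissues))
    stopf("invalid config field 'tissues' (named rho targets in [0, 1])")
  if (!is.character(ap_levels) || !length(ap_levels))
    stopf("invalid config field 'ap_levels'")
  chk_num("n_replicates", lo = 1)
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || noise_sd <= 0)
    stopf("invalid config field 'noise_sd' (must be > 0)")
  chk_num("baseline_log2tpm_mean")
  chk_num("baseline_log2tpm_sd", lo = 0)
  for (f in c("dup_rate", "loss_rate", "planted_set_conserved_prob",
              "background_conserved_prob", "late_conserved_frac"))
    chk_num(f, lo = 0, hi = 1)
  if (cfg$dup_rate + cfg$loss_rate > 1)
    stopf("invalid config field 'dup_rate'/'loss_rate': rates sum above 1")
  chk_num("planted_set_size", lo = 0)
  chk_num("planted_term_size", lo = 0)
  chk_num("n_terms", lo = 2)
  chk_num("late_divergence_sd", lo = 0)
  chk_num("calibration_mc", lo = 1000)
  chk_num("seed")
  if (n_genes < planted_set_size + planted_term_size)
    stopf("invalid config field 'planted_set_size': n_genes too small for the planted blocks")
  if (length(species) != 2 || anyDuplicated(species))
    stopf("invalid config field 'species' (two distinct labels)")
  cfg$n_genes <- as.integer(n_genes)
  cfg$n_replicates <- as.integer(n_replicates)
  structure(cfg, class = "sim_config")
}

# Spread of the true log2 level around the gene baseline within one
# tissue/AP cell (shared by both species; does not affect divergence).
TISSUE_EFFECT_SD <- 1

# Sub-twofold jitter bound for planted-conserved genes (log2); small
# enough that replicate noise rarely pushes a planted gene past twofold.
CONSERVED_JITTER <- 0.3

# Late-stage jitter for housekeeping stand-ins: tighter still, so the
# whole planted cohort stays within twofold under replicate noise.
LATE_HK_JITTER <- 0.15

#' Solve the divergence-noise SD for a target Spearman correlation
#'
#' Monte-Carlo calibration: simulates the full observation chain (gene
#' baseline + cell effect, divergence for the non-forced fraction,
#' replicate noise, TPM averaging of replicates) on a fixed random panel
#' and root-finds the divergence SD `tau` whose realized species-mean
#' Spearman correlation matches `rho_target`. Reusing one panel across
#' root iterations makes the objective smooth and the solution
#' deterministic for a given seed.
#'
#' @param rho_target target Spearman rho between species-mean TPM vectors.
#' @param forced_frac fraction of genes with divergence forced to a
#'   sub-twofold jitter.
#' @param config a [sim_config()] (noise, baseline and replicate fields).
#' @param n_mc Monte-Carlo panel size.
#' @param seed RNG seed for the panel.
#' @return divergence SD on the log2 scale (0 if the target is at or
#'   above what zero divergence can realize given replicate noise).
#' @export
calibrate_divergence_sd <- function(rho_target, forced_frac, config,
                                    n_mc = 40000, seed = 1L) {
  stopifnot(rho_target >= 0, rho_target <= 1)
  R <- config$n_replicates
  sd_mu <- sqrt(config$baseline_log2tpm_sd^2 + TISSUE_EFFECT_SD^2)
  with_seed(seed, {
    mu <- rnorm(n_mc, config$baseline_log2tpm_mean, sd_mu)
    forced <- runif(n_mc) < forced_frac
    z_div <- rnorm(n_mc)
    jit <- runif(n_mc, -CONSERVED_JITTER, CONSERVED_JITTER)
    na <- matrix(rnorm(n_mc * R, 0, config$noise_sd), n_mc, R)
    nb <- matrix(rnorm(n_mc * R, 0, config$noise_sd), n_mc, R)
    realized <- function(tau) {
      delta <- ifelse(forced, jit, z_div * tau)
      a <- rowMeans(2^(mu + na))
      b <- rowMeans(2^(mu + delta + nb))
      stats::cor(a, b, method = "spearman")
    }
    if (realized(0) <= rho_target) return(0)
    f <- function(log_tau) realized(exp(log_tau)) - rho_target
    # heavily planted configs keep rho above the target at any divergence;
    # the divergence SD then saturates at the upper bracket
    if (f(3) > 0) return(exp(3))
    exp(stats::uniroot(f, c(-5, 3), tol = 1e-3)$root)
  })
}

#' Generate a synthetic two-species conservation dataset
#'
#' Produces everything the downstream pipeline consumes — two TPM
#' matrices (mid-stage tissue samples plus late whole-embryo samples),
#' sample metadata, a strict 1:1 ortholog pair table, an orthoMCL-style
#' group table perturbed by duplications and losses, a gene-to-term
#' annotation table — together with the planted ground truth: a gene set
#' with elevated conservation, a planted term annotating genes conserved
#' in all tissues but divergent late, and housekeeping stand-ins
#' conserved at the late stage.
#'
#' Identical config + seed give identical output, element for element.
#'
#' @param config a [sim_config()].
#' @return list of class `ConservationSim` with elements `expr_a`,
#'   `expr_b`, `metadata`, `pairs`, `groups`, `annotations`,
#'   `planted_set` (GeneSet of 1:1 unit ids), `late_conserved_truth`
#'   (GeneSet), `truth` (per-gene data.frame), `divergence_sd` (per
#'   tissue) and `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  n <- config$n_genes
  seed <- config$seed

  gene_a <- sprintf("%s_g%05d", config$species[1], seq_len(n))
  gene_b <- sprintf("%s_g%05d", config$species[2], seq_len(n))

  # -- roles ----------------------------------------------------------------
  S <- config$planted_set_size
  Tm <- config$planted_term_size
  idx_set <- seq_len(S)
  idx_term <- S + seq_len(Tm)
  pool <- setdiff(seq_len(n), c(idx_set, idx_term))
  n_hk <- round(config$late_conserved_frac * n)
  idx_hk <- with_seed(substream_seed(seed, 1),
                      sort(sample(pool, min(n_hk, length(pool)))))

  forced <- with_seed(substream_seed(seed, 2), {
    f <- runif(n) < config$background_conserved_prob
    f[idx_set] <- runif(S) < config$planted_set_conserved_prob
    f[idx_term] <- TRUE
    f
  })

  baseline <- with_seed(substream_seed(seed, 3), {
    b <- rnorm(n, config$baseline_log2tpm_mean, config$baseline_log2tpm_sd)
    # planted-term genes sit in the upper half of the baseline
    # distribution: their engineered late-stage divergence must stay
    # visible through the pseudocount, which compresses ratios of
    # near-zero TPM toward 0
    b[idx_term] <- config$baseline_log2tpm_mean +
      abs(rnorm(Tm, 0, config$baseline_log2tpm_sd))
    b
  })

  # -- divergence calibration (per tissue) ----------------------------------
  tau <- vapply(seq_along(config$tissues), function(i)
    calibrate_divergence_sd(config$tissues[i], mean(forced), config,
                            n_mc = config$calibration_mc,
                            seed = substream_seed(seed, 100 + i)),
    numeric(1))
  names(tau) <- names(config$tissues)

  # -- mid-stage tissue cells -----------------------------------------------
  R <- config$n_replicates
  expr_a <- list(); expr_b <- list(); md <- list()
  cell_i <- 0L
  for (t_i in seq_along(config$tissues)) {
    tissue <- names(config$tissues)[t_i]
    for (ap in config$ap_levels) {
      cell_i <- cell_i + 1L
      cs <- substream_seed(seed, 1000 + cell_i)
      cell <- with_seed(cs, {
        eff <- rnorm(n, 0, TISSUE_EFFECT_SD)
        delta <- ifelse(forced,
                        runif(n, -CONSERVED_JITTER, CONSERVED_JITTER),
                        rnorm(n, 0, tau[t_i]))
        mu_a <- baseline + eff
        mu_b <- mu_a + delta
        la <- matrix(rnorm(n * R, 0, config$noise_sd), n, R) + mu_a
        lb <- matrix(rnorm(n * R, 0, config$noise_sd), n, R) + mu_b
        list(a = 2^la, b = 2^lb)
      })
      sa <- sprintf("%s_%s_%s_%d", config$species[1], tissue, ap, seq_len(R))
      sb <- sprintf("%s_%s_%s_%d", config$species[2], tissue, ap, seq_len(R))
      colnames(cell$a) <- sa; colnames(cell$b) <- sb
      expr_a[[length(expr_a) + 1L]] <- cell$a
      expr_b[[length(expr_b) + 1L]] <- cell$b
      md[[length(md) + 1L]] <- data.frame(
        sample_id = c(sa, sb),
        species = rep(config$species, each = R),
        tissue = tissue, ap_level = ap,
        replicate = rep(seq_len(R), 2),
        stage = rep(config$mid_stages, each = R),
        stringsAsFactors = FALSE)
    }
  }

  # -- late whole-embryo cell -----------------------------------------------
  late <- with_seed(substream_seed(seed, 5), {
    eff <- rnorm(n, 0, TISSUE_EFFECT_SD)
    delta <- rnorm(n, 0, config$late_divergence_sd)
    delta[idx_hk] <- runif(length(idx_hk), -LATE_HK_JITTER, LATE_HK_JITTER)
    # planted-term genes engineered to diverge late (> twofold)
    delta[idx_term] <- sample(c(-1, 1), Tm, replace = TRUE) *
      (2 + abs(rnorm(Tm, 0, 0.5)))
    mu_a <- baseline + eff
    la <- matrix(rnorm(n * R, 0, config$noise_sd), n, R) + mu_a
    lb <- matrix(rnorm(n * R, 0, config$noise_sd), n, R) + mu_a + delta
    list(a = 2^la, b = 2^lb)
  })
  sa <- sprintf("%s_whole_embryo_none_%d", config$species[1], seq_len(R))
  sb <- sprintf("%s_whole_embryo_none_%d", config$species[2], seq_len(R))
  colnames(late$a) <- sa; colnames(late$b) <- sb
  expr_a[[length(expr_a) + 1L]] <- late$a
  expr_b[[length(expr_b) + 1L]] <- late$b
  md[[length(md) + 1L]] <- data.frame(
    sample_id = c(sa, sb),
    species = rep(config$species, each = R),
    tissue = "whole_embryo", ap_level = "none",
    replicate = rep(seq_len(R), 2),
    stage = rep(config$late_stages, each = R),
    stringsAsFactors = FALSE)

  mat_a <- do.call(cbind, expr_a); rownames(mat_a) <- gene_a
  mat_b <- do.call(cbind, expr_b); rownames(mat_b) <- gene_b
  metadata <- do.call(rbind, md)

  # -- duplications and losses ----------------------------------------------
  dl <- with_seed(substream_seed(seed, 6), {
    cand <- setdiff(pool, idx_hk)
    u <- runif(n); u[-cand] <- 1  # planted blocks kept strictly 1:1
    is_dup <- u < config$dup_rate
    is_loss <- !is_dup & u < config$dup_rate + config$loss_rate
    side <- sample(1:2, n, replace = TRUE)
    list(dup = which(is_dup), loss = which(is_loss), side = side,
         dup_shift = matrix(rnorm(sum(is_dup) * ncol(mat_a), -1, 0.3),
                            nrow = sum(is_dup)))
  })

  groups <- data.frame(group_id = rep(sprintf("OG%05d", seq_len(n)), 2),
                       species = rep(config$species, each = n),
                       gene_id = c(gene_a, gene_b),
                       stringsAsFactors = FALSE)
  if (length(dl$dup)) {
    for (s in 1:2) {
      g <- dl$dup[dl$side[dl$dup] == s]
      if (!length(g)) next
      k <- match(g, dl$dup)
      parent <- if (s == 1) gene_a[g] else gene_b[g]
      nid <- paste0(parent, "b")
      if (s == 1) {
        newr <- mat_a[parent, , drop = FALSE] * 2^dl$dup_shift[k, , drop = FALSE]
        rownames(newr) <- nid
        mat_a <- rbind(mat_a, newr)
      } else {
        newr <- mat_b[parent, , drop = FALSE] * 2^dl$dup_shift[k, , drop = FALSE]
        rownames(newr) <- nid
        mat_b <- rbind(mat_b, newr)
      }
      groups <- rbind(groups, data.frame(
        group_id = sprintf("OG%05d", g), species = config$species[s],
        gene_id = nid, stringsAsFactors = FALSE))
    }
  }
  if (length(dl$loss)) {
    lost_a <- dl$loss[dl$side[dl$loss] == 1]
    lost_b <- dl$loss[dl$side[dl$loss] == 2]
    if (length(lost_a)) mat_a <- mat_a[!rownames(mat_a) %in% gene_a[lost_a], , drop = FALSE]
    if (length(lost_b)) mat_b <- mat_b[!rownames(mat_b) %in% gene_b[lost_b], , drop = FALSE]
    groups <- groups[!(groups$gene_id %in% c(gene_a[lost_a], gene_b[lost_b])), ]
  }
  strict <- setdiff(seq_len(n), c(dl$dup, dl$loss))
  pairs <- data.frame(gene_a = gene_a[strict], gene_b = gene_b[strict],
                      stringsAsFactors = FALSE)

  # -- annotations ----------------------------------------------------------
  annotations <- with_seed(substream_seed(seed, 7), {
    ann <- list()
    if (S > 0)
      ann[[1]] <- data.frame(gene_id = gene_a[idx_set], term_id = "GO:0007224",
                             term_name = "smoothened signaling pathway",
                             stringsAsFactors = FALSE)
    if (Tm > 0)
      ann[[length(ann) + 1L]] <- data.frame(
        gene_id = gene_a[idx_term], term_id = config$planted_term_id,
        term_name = "centriole", stringsAsFactors = FALSE)
    n_null <- max(config$n_terms - 2L, 0L)
    for (k in seq_len(n_null)) {
      sz <- sample(10:60, 1)
      ann[[length(ann) + 1L]] <- data.frame(
        gene_id = gene_a[sample(n, sz)],
        term_id = sprintf("GO:9%06d", k),
        term_name = sprintf("synthetic term %d", k),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, ann)
  })
  annotations <- annotations[annotations$gene_id %in% rownames(mat_a), ]

  unit_of <- function(i) paste0(gene_a[i], "|", gene_b[i])
  truth <- data.frame(
    gene_a = gene_a, gene_b = gene_b,
    planted_set = as.integer(seq_len(n) %in% idx_set),
    planted_term = as.integer(seq_len(n) %in% idx_term),
    late_conserved = as.integer(seq_len(n) %in% idx_hk),
    forced_conserved = as.integer(forced),
    duplicated = as.integer(seq_len(n) %in% dl$dup),
    lost = as.integer(seq_len(n) %in% dl$loss),
    stringsAsFactors = FALSE)

  structure(list(
    expr_a = mat_a, expr_b = mat_b, metadata = metadata,
    pairs = pairs, groups = groups, annotations = annotations,
    planted_set = structure(list(name = "GO:0007224",
                                 members = unit_of(idx_set)),
                            class = "GeneSet"),
    planted_term_units = unit_of(idx_term),
    late_conserved_truth = structure(list(name = "late_conserved",
                                          members = unit_of(idx_hk)),
                                     class = "GeneSet"),
    truth = truth, divergence_sd = tau, config = config),
    class = "ConservationSim")
}

#' Write a simulated dataset to a directory of TSV files
#'
#' Emits the exact input formats the pipeline readers consume, plus the
#' per-gene `truth.tsv` used by validation tests. Writes are atomic and
#' contain no timestamps, so identical config + seed give byte-identical
#' files.
#'
#' @param sim a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_expression_matrix(sim$expr_a, p(sprintf("expression_%s.tsv", sim$config$species[1])))
  write_expression_matrix(sim$expr_b, p(sprintf("expression_%s.tsv", sim$config$species[2])))
  write_sample_metadata(sim$metadata, p("sample_metadata.tsv"))
  write_ortholog_pairs(sim$pairs, p("ortholog_pairs.tsv"))
  write_ortholog_groups(sim$groups, p("ortholog_groups.tsv"))
  write_annotations(sim$annotations, p("annotations.tsv"))
  write_tsv(sim$truth, p("truth.tsv"))
  invisible(dir)
}

#' @export
print.ConservationSim <- function(x, ...) {
  cat(sprintf("ConservationSim: %d genes, %d samples/species, seed %d\n",
              x$config$n_genes, ncol(x$expr_a), x$config$seed))
  cat(sprintf("  divergence SD per tissue: %s\n",
              paste(sprintf("%s=%.3f", names(x$divergence_sd),
                            x$divergence_sd), collapse = ", ")))
  invisible(x)
}
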
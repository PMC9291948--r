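# Cross-species expression distance: 1 - Spearman rank correlation of
# orthologous units, per tissue / AP level, with Dunnett many-to-one
# comparison of tissues against a reference structure.

#' 1 - Spearman distance between two expression vectors
#'
#' Spearman's rho on mid-ranks (average ranks for ties); the distance
#' `1 - rho` lies in \[0, 2\]: 0 for identical rank orderings, 2 for
#' perfect anti-correlation. Invariant under strictly monotone transforms
#' of either vector, so raw TPM and log TPM give the same value.
#'
#' @param x,y numeric vectors of equal length (>= 3), typically TPM over
#'   the same ortholog units in the two species.
#' @return the distance, a single number in \[0, 2\].
#' @export
spearman_distance <- function(x, y) {
  if (length(x) != length(y)) stopf("vectors differ in length")
  if (length(x) < 3) stopf("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stopf("missing values not allowed")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stopf("undefined correlation: constant vector")
  1 - stats::cor(x, y, method = "spearman")
}

#' Units expressed in a tissue/AP cell
#'
#' A unit passes if its mean TPM across that cell's replicates is at
#' least `min_mean_tpm` in AT LEAST ONE species — a one-species rule, so
#' genes expressed on one side but silent on the other (candidates for
#' expression divergence) are retained.
#'
#' @param paired a `PairedExpression`.
#' @param metadata sample metadata covering the paired samples.
#' @param tissue,ap_level the cell to evaluate.
#' @param min_mean_tpm threshold, default 1 TPM.
#' @return named integer vector of surviving unit indices into
#'   `paired$unit_ids`.
#' @export
expressed_unit_filter <- function(paired, metadata, tissue, ap_level,
                                  min_mean_tpm = 1) {
  cs <- cell_samples(paired, metadata, tissue, ap_level)
  mean_a <- rowMeans(paired$values_a[, cs$a, drop = FALSE])
  mean_b <- rowMeans(paired$values_b[, cs$b, drop = FALSE])
  keep <- which(mean_a >= min_mean_tpm | mean_b >= min_mean_tpm)
  if (!length(keep))
    stopf("no units pass the expression filter in %s/%s", tissue, ap_level)
  names(keep) <- paired$unit_ids[keep]
  keep
}

# Resolve the replicate-ordered sample columns of both species for one
# tissue/AP cell; errors if the cell is absent from the metadata.
cell_samples <- function(paired, metadata, tissue, ap_level) {
  md <- metadata[metadata$tissue == tissue & metadata$ap_level == ap_level, ]
  if (!nrow(md)) stopf("tissue/ap_level '%s/%s' absent from metadata", tissue, ap_level)
  a <- md[md$sample_id %in% colnames(paired$values_a), ]
  b <- md[md$sample_id %in% colnames(paired$values_b), ]
  if (!nrow(a) || !nrow(b))
    stopf("no samples of both species for %s/%s", tissue, ap_level)
  a <- a[order(a$replicate), ]
  b <- b[order(b$replicate), ]
  list(a = a$sample_id, b = b$sample_id,
       rep_a = a$replicate, rep_b = b$replicate)
}

#' Per-tissue cross-species distances over replicate pairs
#'
#' For every tissue/AP cell, computes the 1 - Spearman distance between
#' species over the expressed units, across replicate pairs. `matched`
#' pairing compares replicate i of species A with replicate i of species
#' B (n records per cell = number of replicates); `all_pairs` takes every
#' cross-species replicate combination (n_A x n_B records).
#'
#' @param paired a `PairedExpression`.
#' @param metadata sample metadata.
#' @param pairing_mode `"matched"` or `"all_pairs"`.
#' @param tissues,ap_levels subset of cells to process; default every
#'   tissue/AP combination present for both species.
#' @param min_mean_tpm expression filter threshold (see
#'   [expressed_unit_filter()]).
#' @return data.frame of class `DistanceResult`: tissue, ap_level,
#'   pair_id, n_units, rho, distance.
#' @export
tissue_distances <- function(paired, metadata,
                             pairing_mode = c("matched", "all_pairs"),
                             tissues = NULL, ap_levels = NULL,
                             min_mean_tpm = 1) {
  pairing_mode <- match.arg(pairing_mode)
  md <- metadata[metadata$sample_id %in%
                   c(colnames(paired$values_a), colnames(paired$values_b)), ]
  cells <- unique(md[, c("tissue", "ap_level")])
  if (!is.null(tissues)) cells <- cells[cells$tissue %in% tissues, ]
  if (!is.null(ap_levels)) cells <- cells[cells$ap_level %in% ap_levels, ]
  if (!nrow(cells)) stopf("no tissue/AP cells to process")

  out <- list()
  for (i in seq_len(nrow(cells))) {
    tissue <- cells$tissue[i]; ap <- cells$ap_level[i]
    idx <- expressed_unit_filter(paired, metadata, tissue, ap, min_mean_tpm)
    cs <- cell_samples(paired, metadata, tissue, ap)
    if (pairing_mode == "matched") {
      if (length(cs$a) != length(cs$b))
        stopf("unequal replicate counts in %s/%s (%d vs %d): use pairing_mode = 'all_pairs'",
              tissue, ap, length(cs$a), length(cs$b))
      combos <- cbind(seq_along(cs$a), seq_along(cs$b))
    } else {
      combos <- as.matrix(expand.grid(seq_along(cs$a), seq_along(cs$b)))
    }
    d <- apply(combos, 1, function(ij)
      spearman_distance(paired$values_a[idx, cs$a[ij[1]]],
                        paired$values_b[idx, cs$b[ij[2]]]))
    out[[i]] <- data.frame(
      tissue = tissue, ap_level = ap,
      pair_id = sprintf("%d|%d", cs$rep_a[combos[, 1]], cs$rep_b[combos[, 2]]),
      n_units = length(idx), rho = 1 - d, distance = d,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("DistanceResult", "data.frame"),
            pairing_mode = pairing_mode)
}

#' Mean and SD of distance per tissue/AP cell
#' @param distances a [tissue_distances()] result.
#' @return data.frame: tissue, ap_level, n, mean_distance, sd_distance.
#' @export
distance_summary <- function(distances) {
  agg <- aggregate(distance ~ tissue + ap_level, data = distances,
                   FUN = function(d) c(n = length(d), mean = mean(d), sd = sd(d)))
  data.frame(tissue = agg$tissue, ap_level = agg$ap_level,
             n = agg$distance[, "n"],
             mean_distance = agg$distance[, "mean"],
             sd_distance = agg$distance[, "sd"],
             stringsAsFactors = FALSE)
}

#' Dunnett many-to-one comparison
#'
#' Compares each group's mean against a designated reference group using
#' the pooled error variance and adjusts the two-tailed p-values for the
#' family of comparisons via the Dunnett multivariate-t distribution
#' (exact t for a single comparison; `mvtnorm` quadrature otherwise,
#' seed-controlled and deterministic for a given input).
#'
#' @param values numeric observations (e.g. per-replicate-pair distances).
#' @param groups group label per observation.
#' @param reference the reference group label.
#' @return data.frame of class `DunnettResult`: comparison, mean_diff
#'   (group minus reference), t, df, p_unadjusted, p_adjusted.
#' @export
dunnett_test <- function(values, groups, reference) {
  groups <- as.character(groups)
  if (!reference %in% groups) stopf("reference group '%s' absent", reference)
  lev <- unique(groups)
  if (length(lev) < 2) stopf("need at least two groups")
  ns <- table(factor(groups, levels = lev))
  if (any(ns < 2)) stopf("every group needs at least 2 records")
  means <- tapply(values, factor(groups, levels = lev), mean)
  vars <- tapply(values, factor(groups, levels = lev), stats::var)
  N <- length(values); k <- length(lev)
  df <- N - k
  s2 <- sum((ns - 1) * vars) / df
  comp <- setdiff(lev, reference)
  n_ref <- ns[[reference]]
  se <- sqrt(s2 * (1 / ns[comp] + 1 / n_ref))
  diff <- means[comp] - means[[reference]]
  tstat <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, sign(diff) * Inf))
  lambda <- sqrt(ns[comp] / (ns[comp] + n_ref))
  corr <- outer(lambda, lambda); diag(corr) <- 1
  p_un <- 2 * stats::pt(-abs(tstat), df)
  p_adj <- vapply(seq_along(tstat), function(i) {
    ti <- abs(tstat[i])
    if (!is.finite(ti)) return(0)
    if (length(tstat) == 1L) return(2 * stats::pt(-ti, df))
    pr <- with_seed(1L, mvtnorm::pmvt(
      lower = rep(-ti, length(tstat)), upper = rep(ti, length(tstat)),
      df = as.integer(df), corr = corr, sigma = NULL,
      algorithm = mvtnorm::GenzBretz(abseps = 1e-7, maxpts = 100000)))
    min(1, max(0, 1 - as.numeric(pr)))
  }, numeric(1))
  # family-wise adjustment can never fall below the per-comparison p;
  # enforce the bound against quadrature error
  p_adj <- pmin(1, pmax(p_adj, p_un))
  structure(data.frame(comparison = comp, mean_diff = as.numeric(diff),
                       t = as.numeric(tstat), df = df,
                       p_unadjusted = as.numeric(p_un),
                       p_adjusted = p_adj,
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("DunnettResult", "data.frame"), reference = reference)
}

#' Dunnett comparison of tissue distances against a reference tissue
#'
#' Applies [dunnett_test()] to the per-replicate-pair distances within
#' each AP level, comparing every tissue against `reference_tissue`.
#'
#' @param distances a [tissue_distances()] result.
#' @param reference_tissue default `"notochord"`.
#' @return data.frame with an `ap_level` column ahead of the
#'   [dunnett_test()] columns.
#' @export
distance_dunnett <- function(distances, reference_tissue = "notochord") {
  out <- lapply(split(distances, distances$ap_level), function(d) {
    r <- dunnett_test(d$distance, d$tissue, reference_tissue)
    cbind(ap_level = d$ap_level[1], as.data.frame(r),
          stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "reference") <- reference_tissue
  res
}
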
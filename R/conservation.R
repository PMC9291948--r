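# Twofold-ratio conservation classification and conservation tests.
#
# A unit's cross-species log2 ratio r = log2((a + c) / (b + c)) is taken
# either from replicate-mean TPM per species ("species_mean", one r per
# unit) or from every cross-species replicate pair ("replicate_pair",
# n_A x n_B values per unit). A unit is called conserved when |r| does
# not exceed log2 of the fold threshold (default twofold, boundary
# inclusive). The pseudocount c keeps ratios defined at zero expression
# and pulls a (0, 0) unit to r = 0 — conserved by convention.

#' Cross-species log2 expression ratios
#'
#' @param paired a `PairedExpression`.
#' @param metadata sample metadata.
#' @param tissue,ap_level the cell to evaluate.
#' @param basis `"species_mean"` (ratio of replicate-mean TPM) or
#'   `"replicate_pair"` (one ratio per cross-species replicate pair).
#' @param pseudocount c > 0 added to both species' TPM, default 1.
#' @param units optional unit index from [expressed_unit_filter()]; if
#'   `NULL` the filter is applied with `min_mean_tpm`.
#' @param min_mean_tpm expression threshold used when `units` is `NULL`.
#' @return numeric matrix (units x ratio columns) of class `log_ratios`
#'   with attributes `tissue`, `ap_level`, `basis`, `pseudocount`.
#'   `species_mean` yields one column; `replicate_pair` one column per
#'   pair, named `repA|repB`.
#' @export
log_ratios <- function(paired, metadata, tissue, ap_level,
                       basis = c("species_mean", "replicate_pair"),
                       pseudocount = 1, units = NULL, min_mean_tpm = 1) {
  basis <- match.arg(basis)
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stopf("pseudocount must be > 0")
  if (is.null(units))
    units <- expressed_unit_filter(paired, metadata, tissue, ap_level,
                                   min_mean_tpm)
  cs <- cell_samples(paired, metadata, tissue, ap_level)
  va <- paired$values_a[units, cs$a, drop = FALSE]
  vb <- paired$values_b[units, cs$b, drop = FALSE]
  if (basis == "species_mean") {
    r <- matrix(log2((rowMeans(va) + pseudocount) /
                     (rowMeans(vb) + pseudocount)),
                ncol = 1, dimnames = list(rownames(va), "species_mean"))
  } else {
    combos <- expand.grid(i = seq_along(cs$a), j = seq_along(cs$b))
    r <- vapply(seq_len(nrow(combos)), function(k)
      log2((va[, combos$i[k]] + pseudocount) /
           (vb[, combos$j[k]] + pseudocount)),
      numeric(nrow(va)))
    if (nrow(va) == 1L) r <- matrix(r, nrow = 1)
    dimnames(r) <- list(rownames(va),
                        sprintf("%d|%d", cs$rep_a[combos$i], cs$rep_b[combos$j]))
  }
  structure(r, class = c("log_ratios", "matrix"), tissue = tissue,
            ap_level = ap_level, basis = basis, pseudocount = pseudocount)
}

#' Classify units as conserved by the twofold rule
#'
#' @param ratios a [log_ratios()] matrix.
#' @param fold_threshold F > 1; conserved iff |r| <= log2(F), boundary
#'   inclusive. Default 2 (the twofold rule).
#' @return logical matrix of class `ConservationCall`, same shape and
#'   attributes as `ratios`, plus `fold_threshold`.
#' @export
classify_conserved <- function(ratios, fold_threshold = 2) {
  if (!is.numeric(fold_threshold) || fold_threshold <= 1)
    stopf("fold_threshold must be > 1")
  calls <- abs(unclass(ratios)) <= log2(fold_threshold)
  structure(calls, class = c("ConservationCall", "matrix"),
            tissue = attr(ratios, "tissue"),
            ap_level = attr(ratios, "ap_level"),
            basis = attr(ratios, "basis"),
            pseudocount = attr(ratios, "pseudocount"),
            fold_threshold = fold_threshold)
}

#' Unit ids called conserved (species-mean basis)
#' @param calls a [classify_conserved()] result on `species_mean` basis.
#' @export
conserved_units <- function(calls) {
  if (!identical(attr(calls, "basis"), "species_mean"))
    stopf("conserved_units() needs species_mean basis calls")
  rownames(calls)[calls[, 1]]
}

# ---------------------------------------------------------------------------
# Wilcoxon rank-sum with exact tied-data p-values

# Exact permutation distribution of the rank-sum of the first sample,
# computed by dynamic programming over the generating function of the
# mid-ranks (doubled so tied half-ranks become integers). Handles ties
# exactly, unlike the exact path of stats::wilcox.test.
rank_sum_exact_p <- function(w, ranks, n1) {
  r2 <- as.integer(round(2 * ranks))
  maxs <- sum(sort(r2, decreasing = TRUE)[seq_len(n1)])
  # f[j + 1, s + 1] = number of j-subsets of the ranks seen so far summing s
  f <- matrix(0, nrow = n1 + 1, ncol = maxs + 1)
  f[1, 1] <- 1
  for (r in r2) {
    jmax <- n1
    for (j in jmax:1) {
      src <- f[j, seq_len(maxs + 1 - r)]
      f[j + 1, (r + 1):(maxs + 1)] <- f[j + 1, (r + 1):(maxs + 1)] + src
    }
  }
  dist <- f[n1 + 1, ]
  total <- sum(dist)
  w2 <- as.integer(round(2 * w))
  p_le <- sum(dist[seq_len(min(w2, maxs) + 1)]) / total
  p_ge <- sum(dist[(w2 + 1):(maxs + 1)]) / total
  min(1, 2 * min(p_le, p_ge))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Reports the rank-sum W of `x` (mid-ranks over the pooled sample) and a
#' two-sided p-value: exact — by full enumeration of the permutation
#' distribution, ties included — when the sample sizes allow it
#' (`max(n1, n2) <= 10` or `choose(n1 + n2, min)` at most 1e5), otherwise
#' a normal approximation with tie correction and continuity correction.
#' The two-sided exact p is twice the smaller tail (point included),
#' capped at 1.
#'
#' @param x,y numeric samples.
#' @param exact force (`TRUE`/`FALSE`) or auto-select (`NULL`) the exact
#'   path.
#' @return list: `statistic` (rank-sum of `x`), `p.value`, `exact`,
#'   `n1`, `n2`.
#' @export
rank_sum_test <- function(x, y, exact = NULL) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stopf("both samples must be non-empty")
  pooled <- c(x, y)
  ranks <- rank(pooled)
  w <- sum(ranks[seq_len(n1)])
  if (is.null(exact))
    exact <- max(n1, n2) <= 10 || lchoose(n1 + n2, min(n1, n2)) <= log(1e5)
  if (exact) {
    p <- rank_sum_exact_p(w, ranks, n1)
  } else {
    N <- n1 + n2
    mu <- n1 * (N + 1) / 2
    ties <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- w - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
    p <- min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
  }
  list(statistic = w, p.value = p, exact = exact, n1 = n1, n2 = n2)
}

#' Conservation of a single gene against the genomic background
#'
#' Two-sided Wilcoxon rank-sum test of the focal unit's per-replicate-pair
#' |log2 ratio| values against the pooled per-pair |log2 ratio| values of
#' every other expressed unit. Small |r| means conserved expression, so a
#' focal gene whose values sit below the background ranks is more
#' conserved than the genomic background.
#'
#' @param ratios a [log_ratios()] matrix on `replicate_pair` basis.
#' @param unit_id the focal unit.
#' @return list of class `GeneConservationTest`: unit_id, statistic,
#'   p.value, n_focal, n_background, exact, plus the cell attributes.
#' @export
gene_conservation_test <- function(ratios, unit_id) {
  if (!identical(attr(ratios, "basis"), "replicate_pair"))
    stopf("gene_conservation_test() needs replicate_pair basis ratios")
  if (ncol(ratios) < 2) stopf("need at least 2 replicate pairs")
  if (!unit_id %in% rownames(ratios))
    stopf("unit not expressed in this context: %s", unit_id)
  focal <- abs(ratios[unit_id, ])
  bg <- abs(ratios[setdiff(rownames(ratios), unit_id), , drop = FALSE])
  res <- rank_sum_test(as.numeric(focal), as.numeric(bg))
  structure(list(unit_id = unit_id, statistic = res$statistic,
                 p.value = res$p.value, exact = res$exact,
                 n_focal = res$n1, n_background = res$n2,
                 tissue = attr(ratios, "tissue"),
                 ap_level = attr(ratios, "ap_level")),
            class = "GeneConservationTest")
}

#' @export
print.GeneConservationTest <- function(x, ...) {
  cat(sprintf("Gene conservation (%s, %s/%s): W = %g, p = %.4g (%s; %d vs %d |log2 ratio| values)\n",
              x$unit_id, x$tissue, x$ap_level, x$statistic, x$p.value,
              if (x$exact) "exact" else "normal approx.",
              x$n_focal, x$n_background))
  invisible(x)
}

#' Within-twofold fraction of a gene set vs the genomic background
#'
#' For each cross-species replicate pair, computes the fraction of units
#' called conserved inside the set and in the background, then tests the
#' per-pair differences with a two-tailed Student's t test — paired
#' across replicate pairs by default (each pair contributes one set and
#' one background fraction), with an unpaired pooled-variance mode
#' available. The background excludes the set's own members by default.
#'
#' @param set a `GeneSet` (or character vector of unit ids).
#' @param calls a [classify_conserved()] matrix on `replicate_pair`
#'   basis.
#' @param exclude_set drop set members from the background (default
#'   TRUE).
#' @param paired paired (default) or unpaired t test.
#' @return list of class `SetConservationTest` with per-pair fractions,
#'   their means and SDs, t, df, p.value and n_pairs.
#' @export
set_conservation_test <- function(set, calls, exclude_set = TRUE,
                                  paired = TRUE) {
  members <- if (inherits(set, "GeneSet")) set$members else set
  name <- if (inherits(set, "GeneSet")) set$name else "gene set"
  if (!length(members)) stopf("gene set is empty")
  if (ncol(calls) < 2) stopf("need at least 2 replicate pairs")
  set_units <- intersect(members, rownames(calls))
  if (!length(set_units))
    stopf("gene set has no expressed units in this context")
  bg_units <- setdiff(rownames(calls),
                      if (exclude_set) set_units else character())
  frac_set <- colMeans(calls[set_units, , drop = FALSE])
  frac_bg <- colMeans(calls[bg_units, , drop = FALSE])
  n <- ncol(calls)
  if (paired) {
    d <- frac_set - frac_bg
    if (stats::sd(d) == 0) {
      t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      df <- n - 1
      p <- if (mean(d) == 0) 1 else 0
    } else {
      tt <- stats::t.test(d)
      t <- unname(tt$statistic); df <- unname(tt$parameter); p <- tt$p.value
    }
  } else {
    if (stats::sd(frac_set) == 0 && stats::sd(frac_bg) == 0) {
      d0 <- mean(frac_set) - mean(frac_bg)
      t <- if (d0 == 0) 0 else sign(d0) * Inf
      df <- 2 * n - 2
      p <- if (d0 == 0) 1 else 0
    } else {
      tt <- stats::t.test(frac_set, frac_bg, var.equal = TRUE)
      t <- unname(tt$statistic); df <- unname(tt$parameter); p <- tt$p.value
    }
  }
  structure(list(name = name, n_pairs = n,
                 frac_set = frac_set, frac_bg = frac_bg,
                 mean_frac_set = mean(frac_set), sd_set = stats::sd(frac_set),
                 mean_frac_bg = mean(frac_bg), sd_bg = stats::sd(frac_bg),
                 n_set_units = length(set_units),
                 n_bg_units = length(bg_units),
                 t = t, df = df, p.value = p, paired = paired,
                 tissue = attr(calls, "tissue"),
                 ap_level = attr(calls, "ap_level")),
            class = "SetConservationTest")
}

#' @export
print.SetConservationTest <- function(x, ...) {
  cat(sprintf("Set conservation '%s' (%s/%s), n = %d replicate pairs:\n",
              x$name, x$tissue %||% "?", x$ap_level %||% "?", x$n_pairs))
  cat(sprintf("  within-twofold fraction: set %.3f (SD %.3f, %d units) vs background %.3f (SD %.3f, %d units)\n",
              x$mean_frac_set, x$sd_set, x$n_set_units,
              x$mean_frac_bg, x$sd_bg, x$n_bg_units))
  cat(sprintf("  %s t = %.3f, df = %g, p = %.4g\n",
              if (x$paired) "paired" else "unpaired", x$t, x$df, x$p.value))
  invisible(x)
}
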
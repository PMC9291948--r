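# Term enrichment of a gene list against the genomic background:
# two-sided Fisher's exact test per term, Holm family-wise correction,
# fold enrichment over genomic frequency, and anterior/posterior
# consistency filtering.

# Two-sided hypergeometric p for a 2x2 table (k of n list units
# annotated, K of N background units annotated). "point_prob" sums the
# probabilities of all tables no more likely than the observed one (the
# convention of fisher.test); "doubling" doubles the smaller tail.
fisher_p2 <- function(k, n, K, N, method = c("point_prob", "doubling")) {
  method <- match.arg(method)
  support <- max(0, n + K - N):min(n, K)
  d <- stats::dhyper(support, K, N - K, n)
  d_obs <- d[support == k]
  if (method == "point_prob") {
    p <- sum(d[d <= d_obs * (1 + 1e-7)])
  } else {
    p <- 2 * min(sum(d[support <= k]), sum(d[support >= k]))
  }
  min(1, p)
}

#' Map annotation records onto paired units
#'
#' A unit carries a term when its species-A gene (1:1 pairs) or any of
#' its species-A members (ortholog groups) is annotated with it.
#'
#' @param paired a `PairedExpression`.
#' @param annotations annotation data.frame (gene_id, term_id, term_name).
#' @return data.frame: unit_id, term_id, term_name (unique records).
#' @export
unit_annotations <- function(paired, annotations) {
  members <- paired$members_a
  map <- data.frame(unit_id = rep(paired$unit_ids, lengths(members)),
                    gene_id = unlist(members), stringsAsFactors = FALSE)
  m <- merge(map, annotations, by = "gene_id")
  out <- unique(m[, c("unit_id", "term_id", "term_name")])
  rownames(out) <- NULL
  out
}

#' Term enrichment by two-sided Fisher's exact test
#'
#' For each term annotating at least `min_term_size` background units,
#' builds the 2x2 table (in list vs not, annotated vs not), computes the
#' two-sided exact p and the fold enrichment over genomic frequency
#' (k/n) / (K/N), then Holm-adjusts across all tested terms.
#'
#' @param list_units character vector, the gene list (must be a subset of
#'   the background).
#' @param background_units the genomic background: all expressed paired
#'   units of the run.
#' @param annotations either a unit-level annotation table from
#'   [unit_annotations()] or a `PairedExpression`-free gene-level table;
#'   must have columns `unit_id`, `term_id` (and optionally `term_name`).
#' @param min_term_size skip terms with fewer background units (default
#'   3).
#' @param alpha significance level for the Holm-adjusted call.
#' @param p_method two-sided rule, `"point_prob"` (default) or
#'   `"doubling"`.
#' @return data.frame of class `EnrichmentResult`, one row per tested
#'   term, ordered by raw p: term_id, term_name, k, n, K, N,
#'   fold_enrichment, p_raw, p_holm, significant.
#' @export
fisher_enrichment <- function(list_units, background_units, annotations,
                              min_term_size = 3, alpha = 0.05,
                              p_method = c("point_prob", "doubling")) {
  p_method <- match.arg(p_method)
  if (!length(list_units)) stopf("gene list is empty")
  if (!length(background_units)) stopf("background is empty")
  background_units <- unique(background_units)
  list_units <- unique(list_units)
  if (!all(list_units %in% background_units))
    stopf("gene list is not a subset of the background")
  if (!all(c("unit_id", "term_id") %in% names(annotations)))
    stopf("annotations must carry unit_id and term_id columns")
  if (is.null(annotations$term_name))
    annotations$term_name <- annotations$term_id
  ann <- annotations[annotations$unit_id %in% background_units, ]
  N <- length(background_units)
  n <- length(list_units)
  terms <- split(ann$unit_id, ann$term_id)
  term_name <- tapply(ann$term_name, ann$term_id, `[`, 1)
  terms <- terms[lengths(terms) >= min_term_size]
  if (!length(terms)) stopf("no term passes min_term_size = %d", min_term_size)
  K <- lengths(terms)
  k <- vapply(terms, function(u) sum(u %in% list_units), integer(1))
  fold <- (k / n) / (K / N)
  p_raw <- vapply(seq_along(terms), function(i)
    fisher_p2(k[i], n, K[i], N, p_method), numeric(1))
  p_holm <- holm_adjust(p_raw)
  res <- data.frame(term_id = names(terms),
                    term_name = as.character(term_name[names(terms)]),
                    k = as.integer(k), n = n, K = as.integer(K), N = N,
                    fold_enrichment = as.numeric(fold),
                    p_raw = p_raw, p_holm = p_holm,
                    significant = p_holm <= alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  res <- res[order(res$p_raw, res$term_id), ]
  rownames(res) <- NULL
  structure(res, class = c("EnrichmentResult", "data.frame"),
            alpha = alpha, p_method = p_method)
}

#' Holm step-down adjustment
#'
#' Family-wise error-rate control: sort p ascending, multiply the i-th by
#' (m - i + 1), enforce monotonicity, cap at 1; returned in input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values.
#' @export
holm_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Terms significant in both anterior and posterior analyses
#'
#' @param anterior,posterior [fisher_enrichment()] results for the two AP
#'   levels, computed with the same annotations.
#' @param alpha Holm-adjusted significance level (default 0.05).
#' @return data.frame: term_id, term_name, fold_anterior, fold_posterior,
#'   p_holm_anterior, p_holm_posterior. May have zero rows.
#' @export
consistent_terms <- function(anterior, posterior, alpha = 0.05) {
  m <- merge(as.data.frame(anterior), as.data.frame(posterior),
             by = "term_id", suffixes = c("_anterior", "_posterior"))
  m <- m[m$p_holm_anterior <= alpha & m$p_holm_posterior <= alpha, ]
  out <- data.frame(term_id = m$term_id,
                    term_name = m$term_name_anterior,
                    fold_anterior = m$fold_enrichment_anterior,
                    fold_posterior = m$fold_enrichment_posterior,
                    p_holm_anterior = m$p_holm_anterior,
                    p_holm_posterior = m$p_holm_posterior,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_holm_anterior * out$p_holm_posterior), ]
  rownames(out) <- NULL
  out
}
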
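# Reading, validation and cross-species pairing of expression tables.
#
# All tables are plain TSV. Gene identifiers are matched as exact strings:
# no version-suffix stripping or case folding is ever applied, so that a
# unit present in an output can always be traced to the input rows that
# produced it.

TISSUE_LEVELS <- c("notochord", "neural_tube", "somites", "whole_embryo")
AP_LEVELS <- c("anterior", "posterior", "none")

#' Validate a gene x sample TPM matrix
#'
#' @param mat numeric matrix, genes in rows (rownames), samples in columns
#'   (colnames), values in TPM.
#' @param metadata optional sample metadata; if given, every column of
#'   `mat` must appear in `metadata$sample_id`.
#' @return `mat`, invisibly, after validation.
#' @keywords internal
validate_expression_matrix <- function(mat, metadata = NULL) {
  if (!is.matrix(mat) || !is.numeric(mat))
    stopf("expression data must be a numeric matrix")
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stopf("expression matrix must carry gene and sample names")
  dup <- rownames(mat)[duplicated(rownames(mat))]
  if (length(dup))
    stopf("duplicate gene id(s) in expression matrix: %s",
          paste(unique(dup), collapse = ", "))
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stopf("missing value at gene '%s', sample '%s'",
          rownames(mat)[bad[1]], colnames(mat)[bad[2]])
  }
  if (any(mat < 0)) {
    bad <- which(mat < 0, arr.ind = TRUE)[1, ]
    stopf("negative TPM value (%g) at gene '%s', sample '%s'",
          mat[bad[1], bad[2]], rownames(mat)[bad[1]], colnames(mat)[bad[2]])
  }
  if (!is.null(metadata)) {
    missing <- setdiff(colnames(mat), metadata$sample_id)
    if (length(missing))
      stopf("sample(s) absent from metadata: %s",
            paste(missing, collapse = ", "))
  }
  invisible(mat)
}

#' Read a TPM expression matrix from TSV
#'
#' Expects a header row starting with `gene_id` followed by sample ids,
#' then one gene per row with non-negative decimal TPM values.
#'
#' @param path path to the TSV file.
#' @param metadata optional [read_sample_metadata()] table used to check
#'   that every sample column is described.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_matrix <- function(path, metadata = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2 || names(df)[1] != "gene_id")
    stopf("expression TSV must have a 'gene_id' column followed by samples: %s", path)
  genes <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- genes
  validate_expression_matrix(mat, metadata)
  mat
}

#' @export
write_expression_matrix <- function(mat, path) {
  # %.17g makes the decimal representation round-trip exact
  chr <- matrix(sprintf("%.17g", mat), nrow = nrow(mat),
                dimnames = dimnames(mat))
  df <- data.frame(gene_id = rownames(mat), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read and validate the sample metadata table
#'
#' Tab-separated with header
#' `sample_id  species  tissue  ap_level  replicate  stage`. Replicates
#' must be numbered contiguously from 1 within each
#' (species, tissue, ap_level) cell.
#'
#' @param path TSV path.
#' @return data.frame with one row per sample.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sample_metadata(md)
}

#' Validate a sample metadata table
#' @param md data.frame with columns sample_id, species, tissue,
#'   ap_level, replicate, stage.
#' @return `md` after validation.
#' @export
validate_sample_metadata <- function(md) {
  need <- c("sample_id", "species", "tissue", "ap_level", "replicate", "stage")
  missing <- setdiff(need, names(md))
  if (length(missing))
    stopf("metadata is missing column(s): %s", paste(missing, collapse = ", "))
  if (anyDuplicated(md$sample_id))
    stopf("duplicate sample_id(s): %s",
          paste(unique(md$sample_id[duplicated(md$sample_id)]), collapse = ", "))
  bad_t <- setdiff(unique(md$tissue), TISSUE_LEVELS)
  if (length(bad_t))
    stopf("unknown tissue label(s): %s", paste(bad_t, collapse = ", "))
  bad_a <- setdiff(unique(md$ap_level), AP_LEVELS)
  if (length(bad_a))
    stopf("unknown ap_level label(s): %s", paste(bad_a, collapse = ", "))
  cells <- split(md$replicate, paste(md$species, md$tissue, md$ap_level))
  for (cell in names(cells)) {
    reps <- sort(cells[[cell]])
    if (!identical(as.integer(reps), seq_along(reps)))
      stopf("replicates not numbered contiguously from 1 in cell '%s'", cell)
  }
  md
}

#' @export
write_sample_metadata <- function(md, path) write_tsv(md, path)

#' Read a 1:1 ortholog pair table (2-column headerless TSV)
#' @param path TSV path; column 1 = species-A gene, column 2 = species-B gene.
#' @return data.frame with columns `gene_a`, `gene_b`.
#' @export
read_ortholog_pairs <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != 2) stopf("ortholog pair table must have exactly 2 columns")
  names(df) <- c("gene_a", "gene_b")
  validate_ortholog_pairs(df)
}

#' @keywords internal
validate_ortholog_pairs <- function(pairs) {
  if (anyDuplicated(pairs$gene_a) || anyDuplicated(pairs$gene_b))
    stopf("pair table is not a strict 1:1 bijection: some gene appears twice")
  pairs
}

#' @export
write_ortholog_pairs <- function(pairs, path)
  write_tsv(pairs, path, col.names = FALSE)

#' Read an ortholog group table (3-column headerless TSV)
#'
#' orthoMCL-style long format: `group_id  species  gene_id`, one member
#' per row; a group may have zero, one or many members per species.
#' @export
read_ortholog_groups <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != 3) stopf("ortholog group table must have exactly 3 columns")
  names(df) <- c("group_id", "species", "gene_id")
  validate_ortholog_groups(df)
}

#' @keywords internal
validate_ortholog_groups <- function(groups) {
  key <- paste(groups$species, groups$gene_id)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stopf("gene listed more than once in the group table: %s", d)
  }
  # one group per gene (a gene may not sit in two groups)
  per_gene <- tapply(groups$group_id, key, function(g) length(unique(g)))
  if (any(per_gene > 1))
    stopf("gene assigned to multiple ortholog groups")
  groups
}

#' @export
write_ortholog_groups <- function(groups, path)
  write_tsv(groups, path, col.names = FALSE)

#' Read a gene -> term annotation table (2- or 3-column headerless TSV)
#'
#' Columns: gene_id, term_id and optionally term_name. GAF input is not
#' supported; convert upstream.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (!ncol(df) %in% c(2, 3))
    stopf("annotation table must have 2 or 3 columns")
  names(df) <- c("gene_id", "term_id", "term_name")[seq_len(ncol(df))]
  if (ncol(df) == 2) df$term_name <- df$term_id
  validate_annotations(df)
}

#' @keywords internal
validate_annotations <- function(ann) {
  if (is.null(ann$term_name)) ann$term_name <- ann$term_id
  key <- paste(ann$gene_id, ann$term_id)
  if (anyDuplicated(key))
    stopf("duplicate (gene_id, term_id) annotation record: %s",
          key[duplicated(key)][1])
  ann
}

#' @export
write_annotations <- function(ann, path) write_tsv(ann, path, col.names = FALSE)

# ---------------------------------------------------------------------------
# Cross-species pairing

new_paired_expression <- function(unit_ids, members_a, members_b,
                                  values_a, values_b, provenance,
                                  dropped = NULL) {
  rownames(values_a) <- rownames(values_b) <- unit_ids
  structure(list(unit_ids = unit_ids,
                 members_a = members_a, members_b = members_b,
                 values_a = values_a, values_b = values_b,
                 provenance = provenance, dropped = dropped),
            class = "PairedExpression")
}

#' @export
print.PairedExpression <- function(x, ...) {
  cat(sprintf("PairedExpression (%s): %d units x (%d + %d samples)\n",
              x$provenance, length(x$unit_ids),
              ncol(x$values_a), ncol(x$values_b)))
  if (!is.null(x$dropped) && nrow(x$dropped))
    cat(sprintf("  %d pair(s) dropped (gene absent from a matrix)\n",
                nrow(x$dropped)))
  invisible(x)
}

#' Align two species' expression on 1:1 ortholog pairs
#'
#' One unit per pair whose genes are present in both matrices; pairs with
#' a gene absent from either matrix are dropped and recorded in the
#' `dropped` slot. Unit ids are `geneA|geneB`.
#'
#' @param pairs data.frame `gene_a`, `gene_b` (see [read_ortholog_pairs()]).
#' @param expr_a,expr_b TPM matrices for species A and B.
#' @return a `PairedExpression` object.
#' @export
pair_one_to_one <- function(pairs, expr_a, expr_b) {
  keep <- pairs$gene_a %in% rownames(expr_a) & pairs$gene_b %in% rownames(expr_b)
  if (!any(keep)) stopf("no usable ortholog pairs")
  kept <- pairs[keep, , drop = FALSE]
  dropped <- pairs[!keep, , drop = FALSE]
  unit_ids <- paste0(kept$gene_a, "|", kept$gene_b)
  va <- expr_a[kept$gene_a, , drop = FALSE]
  vb <- expr_b[kept$gene_b, , drop = FALSE]
  new_paired_expression(unit_ids,
                        members_a = as.list(kept$gene_a),
                        members_b = as.list(kept$gene_b),
                        values_a = va, values_b = vb,
                        provenance = "one_to_one", dropped = dropped)
}

#' Aggregate ortholog-group expression across paralogs
#'
#' Collapses each ortholog group to one unit per species by combining its
#' member genes' TPM per sample — by default the SUM, so that a
#' duplicated gene's total expression is compared against its single-copy
#' ortholog. A species with no members in a group contributes 0 for all
#' samples (gene loss); annotated members absent from the matrix are
#' treated as 0 with a warning (a lost annotation and an unexpressed gene
#' are indistinguishable at this point).
#'
#' @param groups long-format group table (see [read_ortholog_groups()]).
#' @param expr_a,expr_b TPM matrices.
#' @param species_a,species_b the species labels used in `groups` that
#'   correspond to `expr_a` / `expr_b`; default the first two labels in
#'   order of appearance.
#' @param fun `"sum"` (default) or `"mean"` over member genes.
#' @return a `PairedExpression` with one unit per group.
#' @export
aggregate_group_expression <- function(groups, expr_a, expr_b,
                                       species_a = NULL, species_b = NULL,
                                       fun = c("sum", "mean")) {
  fun <- match.arg(fun)
  sp <- unique(groups$species)
  species_a <- species_a %||% sp[1]
  species_b <- species_b %||% setdiff(sp, species_a)[1]
  if (is.na(species_b)) stopf("group table lists fewer than two species")

  gids <- sort(unique(groups$group_id))
  side <- function(expr, species) {
    g <- groups[groups$species == species, , drop = FALSE]
    present <- g$gene_id %in% rownames(expr)
    if (any(!present))
      warnf("%d group member(s) of species '%s' absent from its matrix; treated as 0",
            sum(!present), species)
    gp <- g[present, , drop = FALSE]
    agg <- matrix(0, nrow = length(gids), ncol = ncol(expr),
                  dimnames = list(gids, colnames(expr)))
    if (nrow(gp)) {
      s <- rowsum(expr[gp$gene_id, , drop = FALSE], group = gp$group_id)
      if (fun == "mean") s <- s / as.vector(table(gp$group_id)[rownames(s)])
      agg[rownames(s), ] <- s
    }
    # membership (hence the group universe) is defined by the annotation,
    # not by presence in the matrix
    list(values = agg,
         members = unname(split(g$gene_id, factor(g$group_id, levels = gids))))
  }
  a <- side(expr_a, species_a)
  b <- side(expr_b, species_b)
  empty <- lengths(a$members) == 0 & lengths(b$members) == 0
  keep <- !empty
  new_paired_expression(gids[keep],
                        members_a = a$members[keep],
                        members_b = b$members[keep],
                        values_a = a$values[keep, , drop = FALSE],
                        values_b = b$values[keep, , drop = FALSE],
                        provenance = "ortholog_group")
}

#' Extract a gene set from an annotation table
#'
#' Returns the paired units whose species-A gene (for 1:1 pairs) or any
#' species-A member (for ortholog groups) carries `term_id`.
#'
#' @param annotations annotation data.frame (gene_id, term_id[, term_name]).
#' @param term_id the term to extract.
#' @param paired the `PairedExpression` the set will be evaluated against.
#' @return an object of class `GeneSet`: `name` and `members` (unit ids).
#' @export
extract_gene_set <- function(annotations, term_id, paired) {
  if (!term_id %in% annotations$term_id)
    stopf("term '%s' absent from the annotation table", term_id)
  genes <- annotations$gene_id[annotations$term_id == term_id]
  hit <- vapply(paired$members_a, function(m) any(m %in% genes), logical(1))
  if (!any(hit)) stopf("term annotates no paired genes: %s", term_id)
  structure(list(name = term_id, members = paired$unit_ids[hit]),
            class = "GeneSet")
}

#' @export
print.GeneSet <- function(x, ...) {
  cat(sprintf("GeneSet '%s': %d units\n", x$name, length(x$members)))
  invisible(x)
}
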
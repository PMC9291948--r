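# End-to-end orchestration: pairing -> expression filters -> distances +
# Dunnett -> conservation calls and tests -> cross-tissue intersection +
# late-stage subtraction -> enrichment per AP level -> consistency
# report. analyze_dataset() works on in-memory objects; run_pipeline()
# wraps it with file I/O, output tables and a run manifest.

#' Analysis parameters
#'
#' All tunables of the pipeline in one validated object. Defaults follow
#' the reference analysis: twofold conservation threshold, 1 TPM
#' pseudocount, 1 TPM expression filter, alpha 0.05 throughout, matched
#' replicate pairing for the distance bars, per-replicate-pair basis for
#' the set test, notochord as the Dunnett reference structure, sum
#' aggregation for ortholog groups.
#'
#' @param fold_threshold conservation fold threshold F > 1.
#' @param pseudocount TPM pseudocount c > 0.
#' @param min_mean_tpm expression filter threshold.
#' @param alpha global significance level, in (0, 1).
#' @param pairing_mode distance replicate pairing, `"matched"` or
#'   `"all_pairs"`.
#' @param reference_tissue Dunnett reference group.
#' @param unit_mode `"one_to_one"` (1:1 pair table) or `"ortholog_group"`
#'   (group aggregation).
#' @param group_aggregation `"sum"` or `"mean"` over group members.
#' @param background_excludes_set drop set members from the background of
#'   the set-conservation test.
#' @param set_test_paired paired (default) or unpaired t test for the set
#'   test.
#' @param gene_set_term annotation term defining the focal gene set
#'   (`NULL` to skip the set and gene tests).
#' @param focal_unit unit id for the single-gene conservation test;
#'   `NULL` takes the first member of the gene set.
#' @param focal_tissue,focal_ap cell for the single-gene test.
#' @param late_tissue,late_ap cell holding the late-stage comparison.
#' @param min_term_size,fisher_p_method enrichment settings, see
#'   [fisher_enrichment()].
#' @return validated list of class `analysis_params`.
#' @export
analysis_params <- function(fold_threshold = 2, pseudocount = 1,
                            min_mean_tpm = 1, alpha = 0.05,
                            pairing_mode = c("matched", "all_pairs"),
                            reference_tissue = "notochord",
                            unit_mode = c("one_to_one", "ortholog_group"),
                            group_aggregation = c("sum", "mean"),
                            background_excludes_set = TRUE,
                            set_test_paired = TRUE,
                            gene_set_term = "GO:0007224",
                            focal_unit = NULL,
                            focal_tissue = "notochord",
                            focal_ap = "posterior",
                            late_tissue = "whole_embryo",
                            late_ap = "none",
                            min_term_size = 3,
                            fisher_p_method = c("point_prob", "doubling")) {
  if (!is.numeric(fold_threshold) || fold_threshold <= 1)
    stopf("invalid parameter 'fold_threshold' (must be > 1)")
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stopf("invalid parameter 'pseudocount' (must be > 0)")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stopf("invalid parameter 'alpha' (must be in (0, 1))")
  if (!is.numeric(min_mean_tpm) || min_mean_tpm < 0)
    stopf("invalid parameter 'min_mean_tpm'")
  structure(list(fold_threshold = fold_threshold, pseudocount = pseudocount,
                 min_mean_tpm = min_mean_tpm, alpha = alpha,
                 pairing_mode = match.arg(pairing_mode),
                 reference_tissue = reference_tissue,
                 unit_mode = match.arg(unit_mode),
                 group_aggregation = match.arg(group_aggregation),
                 background_excludes_set = isTRUE(background_excludes_set),
                 set_test_paired = isTRUE(set_test_paired),
                 gene_set_term = gene_set_term,
                 focal_unit = focal_unit,
                 focal_tissue = focal_tissue, focal_ap = focal_ap,
                 late_tissue = late_tissue, late_ap = late_ap,
                 min_term_size = min_term_size,
                 fisher_p_method = match.arg(fisher_p_method)),
            class = "analysis_params")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full conservation analysis in memory
#'
#' Executes every stage of the pipeline on a dataset — either a
#' [simulate_dataset()] result or a list with elements `expr_a`,
#' `expr_b`, `metadata`, `pairs`, `groups` (optional), `annotations`.
#'
#' @param data the dataset.
#' @param params an [analysis_params()].
#' @return list of class `ConservationAnalysis`: `paired`, `distances`,
#'   `distance_summary`, `dunnett`, `calls` (per AP/tissue species-mean
#'   and replicate-pair calls), `set_tests` (data.frame over cells),
#'   `gene_test`, `conserved_lists` (per AP, before and after late-stage
#'   subtraction), `enrichment` (per AP), `consistent_terms`, `params`.
#' @export
analyze_dataset <- function(data, params = analysis_params()) {
  md <- data$metadata
  paired <- stage("pairing", {
    if (params$unit_mode == "one_to_one") {
      pair_one_to_one(data$pairs, data$expr_a, data$expr_b)
    } else {
      sp_a <- md$species[match(colnames(data$expr_a)[1], md$sample_id)]
      sp_b <- md$species[match(colnames(data$expr_b)[1], md$sample_id)]
      aggregate_group_expression(data$groups, data$expr_a, data$expr_b,
                                 species_a = sp_a, species_b = sp_b,
                                 fun = params$group_aggregation)
    }
  })

  mid <- md[md$tissue != params$late_tissue, ]
  tissues <- unique(mid$tissue)
  aps <- unique(mid$ap_level)

  distances <- stage("distance", tissue_distances(
    paired, md, pairing_mode = params$pairing_mode, tissues = tissues,
    min_mean_tpm = params$min_mean_tpm))
  dunnett <- stage("dunnett", distance_dunnett(distances, params$reference_tissue))

  calls <- stage("conservation", {
    out <- list()
    for (ap in aps) {
      out[[ap]] <- list()
      for (tissue in tissues) {
        idx <- expressed_unit_filter(paired, md, tissue, ap, params$min_mean_tpm)
        rm_ <- log_ratios(paired, md, tissue, ap, basis = "species_mean",
                          pseudocount = params$pseudocount, units = idx)
        rp_ <- log_ratios(paired, md, tissue, ap, basis = "replicate_pair",
                          pseudocount = params$pseudocount, units = idx)
        out[[ap]][[tissue]] <- list(
          units = idx,
          ratios_mean = rm_, calls_mean = classify_conserved(rm_, params$fold_threshold),
          ratios_pair = rp_, calls_pair = classify_conserved(rp_, params$fold_threshold))
      }
    }
    out
  })

  gene_set <- NULL; set_tests <- NULL; gene_test <- NULL
  if (!is.null(params$gene_set_term) &&
      params$gene_set_term %in% data$annotations$term_id) {
    gene_set <- stage("gene_set",
      extract_gene_set(data$annotations, params$gene_set_term, paired))
    set_tests <- stage("set_test", {
      rows <- list()
      for (ap in aps) for (tissue in tissues) {
        st <- set_conservation_test(gene_set, calls[[ap]][[tissue]]$calls_pair,
                                    exclude_set = params$background_excludes_set,
                                    paired = params$set_test_paired)
        rows[[paste(ap, tissue)]] <- data.frame(
          set = st$name, tissue = tissue, ap_level = ap,
          n_pairs = st$n_pairs, n_set_units = st$n_set_units,
          mean_frac_set = st$mean_frac_set, sd_set = st$sd_set,
          mean_frac_bg = st$mean_frac_bg, sd_bg = st$sd_bg,
          t = st$t, p = st$p.value, stringsAsFactors = FALSE)
      }
      out <- do.call(rbind, rows); rownames(out) <- NULL; out
    })
    gene_test <- stage("gene_test", {
      focal <- params$focal_unit %||% gene_set$members[1]
      rp_ <- calls[[params$focal_ap]][[params$focal_tissue]]$ratios_pair
      if (focal %in% rownames(rp_)) gene_conservation_test(rp_, focal) else NULL
    })
  }

  conserved_lists <- stage("cross_tissue", {
    # the late-stage classification takes every paired unit: a gene off in
    # both species late has conserved (zero) levels — the pseudocount pulls
    # its ratio to 0 — and is exactly the constitutive signal to subtract
    late_idx <- expressed_unit_filter(paired, md, params$late_tissue,
                                      params$late_ap, min_mean_tpm = 0)
    late_calls <- classify_conserved(
      log_ratios(paired, md, params$late_tissue, params$late_ap,
                 basis = "species_mean", pseudocount = params$pseudocount,
                 units = late_idx),
      params$fold_threshold)
    out <- list()
    for (ap in aps) {
      all3 <- intersect_conserved(lapply(tissues, function(t)
        calls[[ap]][[t]]$calls_mean))
      out[[ap]] <- list(unfiltered = all3,
                        filtered = subtract_late_stage(all3, late_calls),
                        late_calls = late_calls)
    }
    out
  })

  enr <- stage("enrichment", {
    uann <- unit_annotations(paired, data$annotations)
    out <- list()
    for (ap in aps) {
      background <- Reduce(intersect, lapply(tissues, function(t)
        names(calls[[ap]][[t]]$units)))
      out[[ap]] <- fisher_enrichment(
        conserved_lists[[ap]]$filtered$units, background, uann,
        min_term_size = params$min_term_size, alpha = params$alpha,
        p_method = params$fisher_p_method)
    }
    out
  })

  consistent <- stage("consistency", {
    if (all(c("anterior", "posterior") %in% names(enr)))
      consistent_terms(enr$anterior, enr$posterior, params$alpha)
    else NULL
  })

  structure(list(paired = paired, distances = distances,
                 distance_summary = distance_summary(distances),
                 dunnett = dunnett, calls = calls,
                 gene_set = gene_set, set_tests = set_tests,
                 gene_test = gene_test,
                 conserved_lists = conserved_lists,
                 enrichment = enr, consistent_terms = consistent,
                 params = params),
            class = "ConservationAnalysis")
}

#' @export
print.ConservationAnalysis <- function(x, ...) {
  cat(sprintf("ConservationAnalysis: %d paired units (%s)\n",
              length(x$paired$unit_ids), x$paired$provenance))
  cat(sprintf("  distances: %d records over %d cells\n",
              nrow(x$distances), nrow(x$distance_summary)))
  for (ap in names(x$conserved_lists))
    cat(sprintf("  %s: %d units conserved in all tissues, %d after late-stage subtraction\n",
                ap, length(x$conserved_lists[[ap]]$unfiltered$units),
                length(x$conserved_lists[[ap]]$filtered$units)))
  if (!is.null(x$consistent_terms))
    cat(sprintf("  consistent enriched terms: %d\n", nrow(x$consistent_terms)))
  invisible(x)
}

#' Run the pipeline from input files and write output tables
#'
#' Reads the input TSVs, runs [analyze_dataset()], and writes every
#' result table plus a manifest (package version, parameters, input MD5
#' checksums, unit counts) into `output_dir`. Outputs are written
#' atomically and contain no timestamps, so a rerun on identical inputs
#' is byte-identical.
#'
#' @param inputs named list of file paths: `expression_a`,
#'   `expression_b`, `metadata`, `pairs`, `annotations`, optionally
#'   `groups`; or a directory written by [write_dataset()] (species
#'   order taken from the metadata).
#' @param params an [analysis_params()].
#' @param output_dir directory for the result tables (created).
#' @return the [analyze_dataset()] result, invisibly.
#' @export
run_pipeline <- function(inputs, params = analysis_params(), output_dir) {
  if (is.character(inputs) && length(inputs) == 1 && dir.exists(inputs)) {
    md0 <- read_sample_metadata(file.path(inputs, "sample_metadata.tsv"))
    sp <- unique(md0$species)
    inputs <- list(
      expression_a = file.path(inputs, sprintf("expression_%s.tsv", sp[1])),
      expression_b = file.path(inputs, sprintf("expression_%s.tsv", sp[2])),
      metadata = file.path(inputs, "sample_metadata.tsv"),
      pairs = file.path(inputs, "ortholog_pairs.tsv"),
      groups = file.path(inputs, "ortholog_groups.tsv"),
      annotations = file.path(inputs, "annotations.tsv"))
  }
  data <- stage("input", {
    metadata <- read_sample_metadata(inputs$metadata)
    list(expr_a = read_expression_matrix(inputs$expression_a, metadata),
         expr_b = read_expression_matrix(inputs$expression_b, metadata),
         metadata = metadata,
         pairs = read_ortholog_pairs(inputs$pairs),
         groups = if (!is.null(inputs$groups) && file.exists(inputs$groups))
           read_ortholog_groups(inputs$groups) else NULL,
         annotations = read_annotations(inputs$annotations))
  })
  res <- analyze_dataset(data, params)

  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(output_dir, f)
  write_tsv(as.data.frame(res$distances), p("distances.tsv"))
  write_tsv(res$distance_summary, p("distance_summary.tsv"))
  write_tsv(as.data.frame(res$dunnett), p("dunnett.tsv"))

  call_rows <- do.call(rbind, lapply(names(res$calls), function(ap)
    do.call(rbind, lapply(names(res$calls[[ap]]), function(t) {
      cm <- res$calls[[ap]][[t]]
      data.frame(unit_id = rownames(cm$ratios_mean), tissue = t,
                 ap_level = ap, basis = "species_mean",
                 r = as.numeric(cm$ratios_mean),
                 conserved = as.logical(cm$calls_mean),
                 stringsAsFactors = FALSE)
    }))))
  write_tsv(call_rows, p("conservation_calls.tsv"))
  if (!is.null(res$set_tests)) write_tsv(res$set_tests, p("set_tests.tsv"))
  if (!is.null(res$gene_test))
    write_tsv(data.frame(unit_id = res$gene_test$unit_id,
                         tissue = res$gene_test$tissue,
                         ap_level = res$gene_test$ap_level,
                         W = res$gene_test$statistic,
                         p = res$gene_test$p.value,
                         n_focal = res$gene_test$n_focal,
                         n_background = res$gene_test$n_background),
              p("gene_test.tsv"))

  cons_rows <- do.call(rbind, lapply(names(res$conserved_lists), function(ap) {
    cl <- res$conserved_lists[[ap]]
    prov <- cl$unfiltered$provenance
    units <- sort(unique(unlist(c(prov[setdiff(names(prov), "late")]))))
    data.frame(ap_level = ap, unit_id = units,
               conserved_notochord = units %in% prov$notochord,
               conserved_neural_tube = units %in% prov$neural_tube,
               conserved_somites = units %in% prov$somites,
               conserved_late = units %in% cl$filtered$provenance$late,
               in_final_list = units %in% cl$filtered$units,
               stringsAsFactors = FALSE)
  }))
  write_tsv(cons_rows, p("conserved_genes.tsv"))
  for (ap in names(res$enrichment))
    write_tsv(as.data.frame(res$enrichment[[ap]]),
              p(sprintf("enrichment_%s.tsv", ap)))
  if (!is.null(res$consistent_terms))
    write_tsv(res$consistent_terms, p("consistent_terms.tsv"))

  checks <- vapply(inputs[!vapply(inputs, is.null, logical(1))],
                   function(f) unname(tools::md5sum(f)), character(1))
  manifest <- c(
    sprintf("package: orthoconserv %s", as.character(utils::packageVersion("orthoconserv"))),
    sprintf("parameter %s: %s", names(res$params),
            vapply(res$params, function(v)
              paste(format(v %||% "NULL"), collapse = ","), character(1))),
    sprintf("input %s: %s md5=%s", names(checks), unlist(inputs[names(checks)]), checks),
    sprintf("units_paired: %d", length(res$paired$unit_ids)),
    sprintf("pairs_dropped: %d", nrow(res$paired$dropped %||% data.frame())))
  write_atomic(function(pth) writeLines(manifest, pth), p("manifest.txt"))
  invisible(res)
}
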
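# Cross-tissue intersection of conserved units and late-stage
# subtraction: genes conserved in the notochord, neural tube and somites
# at one AP level, minus genes that are also within-twofold in the late
# whole-embryo comparison (constitutively conserved, housekeeping-like).

#' Units conserved in every tissue
#'
#' Intersects species-mean conservation calls from several tissues at the
#' same AP level.
#'
#' @param ... two or more [classify_conserved()] results (species-mean
#'   basis), one per tissue, all from the same AP level.
#' @return list of class `ConservedGeneList`: `ap_level`,
#'   `stage_filtered` (FALSE), `units`, and `provenance` holding the
#'   per-tissue conserved sets.
#' @export
intersect_conserved <- function(...) {
  calls <- list(...)
  if (length(calls) == 1L && is.list(calls[[1]]) &&
      !inherits(calls[[1]], "ConservationCall"))
    calls <- calls[[1]]
  if (length(calls) < 2) stopf("need at least two tissues' call sets")
  aps <- unique(vapply(calls, function(x) attr(x, "ap_level") %||% NA_character_,
                       character(1)))
  if (length(aps) != 1) stopf("mismatched AP levels: %s", paste(aps, collapse = ", "))
  bases <- unique(vapply(calls, function(x) attr(x, "basis") %||% NA_character_,
                         character(1)))
  if (!identical(bases, "species_mean"))
    stopf("all call sets must share the species_mean basis")
  sets <- lapply(calls, conserved_units)
  names(sets) <- vapply(calls, function(x) attr(x, "tissue"), character(1))
  structure(list(ap_level = aps, stage_filtered = FALSE,
                 units = Reduce(intersect, sets),
                 provenance = c(sets, list(late = NULL))),
            class = "ConservedGeneList")
}

#' Remove units also conserved at the late stage
#'
#' Subtracts from a [intersect_conserved()] list the units whose late
#' whole-embryo comparison is within-twofold, leaving genes whose
#' conservation is specific to the mid-embryonic structures. Idempotent.
#'
#' @param clist a `ConservedGeneList`.
#' @param late_calls [classify_conserved()] result for the late
#'   whole-embryo cell (species-mean basis, same fold threshold and
#'   pseudocount as the mid-stage calls).
#' @return the filtered `ConservedGeneList` (`stage_filtered = TRUE`).
#' @export
subtract_late_stage <- function(clist, late_calls) {
  if (!inherits(clist, "ConservedGeneList")) stopf("not a ConservedGeneList")
  if (is.null(late_calls) || nrow(late_calls) == 0)
    stopf("late-stage call set is empty")
  late_cons <- conserved_units(late_calls)
  structure(list(ap_level = clist$ap_level, stage_filtered = TRUE,
                 units = setdiff(clist$units, late_cons),
                 provenance = c(clist$provenance[setdiff(names(clist$provenance), "late")],
                                list(late = late_cons))),
            class = "ConservedGeneList")
}

#' @export
print.ConservedGeneList <- function(x, ...) {
  cat(sprintf("ConservedGeneList (%s%s): %d units conserved in %s\n",
              x$ap_level, if (x$stage_filtered) ", late-stage filtered" else "",
              length(x$units),
              paste(setdiff(names(x$provenance), "late"), collapse = " & ")))
  invisible(x)
}
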
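#' In-silico knockout of one taxon's dominated enzymes
#'
#' Removes from the enzyme set every EC specifically dominated by a
#' taxonomic group, re-expands the network from the same seed compounds,
#' and reports the taxa-dependent compounds: members of the reference
#' scope lost in the truncated expansion. A reaction only disappears when
#' all of its ECs present in the enzyme set are removed, so functions
#' with an alternative annotated catalyst survive.
#'
#' @param universe a [reaction_universe].
#' @param ecs full enzyme set (character vector of ECs).
#' @param seeds seed compound ids or a `seed_set` (the treatment's
#'   environmental resources).
#' @param dominated named list taxon -> dominated EC sets (from
#'   [dominated_enzyme_sets()]).
#' @param group taxon to knock out (a group absent from `dominated`
#'   removes nothing).
#' @param reference optional precomputed reference `expansion_result`
#'   for `expand_scope(universe, ecs, seeds)`, to avoid recomputation.
#' @return An object of class `knockout_report`: list with `taxon`,
#'   `removed_ecs`, `reference_scope_size`, `truncated_scope_size`,
#'   `dependent_compounds`, `reduction_fraction`.
#' @export
knockout_group <- function(universe, ecs, seeds, dominated, group,
                           reference = NULL) {
  ecs <- unique(as.character(ecs))
  removed <- intersect(if (group %in% names(dominated))
    dominated[[group]] else character(0), ecs)
  if (is.null(reference)) {
    reference <- expand_scope(universe, ecs, seeds)
  }
  truncated <- expand_scope(universe, setdiff(ecs, removed), reference$seeds)
  dependent <- sort(setdiff(reference$scope, truncated$scope))
  ref_size <- length(reference$scope)
  structure(
    list(taxon = group,
         removed_ecs = sort(removed),
         reference_scope_size = ref_size,
         truncated_scope_size = length(truncated$scope),
         dependent_compounds = dependent,
         reduction_fraction = if (ref_size > 0)
           length(dependent) / ref_size else 0),
    class = "knockout_report")
}

#' @export
print.knockout_report <- function(x, ...) {
  cat("knockout_report [", x$taxon, "]: ", length(x$removed_ecs),
      " ECs removed, ", length(x$dependent_compounds),
      " dependent compounds (", sprintf("%.1f%%", 100 * x$reduction_fraction),
      " of ", x$reference_scope_size, ")\n", sep = "")
  invisible(x)
}

#' Iterative knockouts of every dominating taxon plus the combined removal
#'
#' Runs [knockout_group()] independently for each taxon in `dominated`
#' (each starting from the full enzyme set) and once for the union of all
#' dominated enzymes together.
#'
#' @inheritParams knockout_group
#' @return List with `reports` (named list of per-taxon
#'   `knockout_report`s), `combined` (the all-groups report, taxon
#'   `"_all_"`), `summary` (data.frame, one row per report) and
#'   `dependent` (long data.frame `taxon`, `compound_id`).
#' @export
knockout_all <- function(universe, ecs, seeds, dominated) {
  ecs <- unique(as.character(ecs))
  reference <- expand_scope(universe, ecs, seeds)
  groups <- names(dominated)
  reports <- lapply(groups, function(g) {
    knockout_group(universe, ecs, seeds, dominated, g, reference = reference)
  })
  names(reports) <- groups
  all_dominated <- list("_all_" = sort(unique(unlist(dominated))))
  combined <- knockout_group(universe, ecs, seeds, all_dominated, "_all_",
                             reference = reference)
  everything <- c(reports, list(combined))
  summary <- do.call(rbind, lapply(everything, function(r) {
    data.frame(taxon = r$taxon,
               n_removed_ecs = length(r$removed_ecs),
               reference_size = r$reference_scope_size,
               truncated_size = r$truncated_scope_size,
               n_dependent = length(r$dependent_compounds),
               reduction_fraction = r$reduction_fraction,
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  dependent <- do.call(rbind, lapply(everything, function(r) {
    if (length(r$dependent_compounds) == 0L) return(NULL)
    data.frame(taxon = r$taxon, compound_id = r$dependent_compounds,
               stringsAsFactors = FALSE)
  }))
  if (is.null(dependent)) {
    dependent <- data.frame(taxon = character(0), compound_id = character(0),
                            stringsAsFactors = FALSE)
  }
  list(reports = reports, combined = combined, summary = summary,
       dependent = dependent)
}
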
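#' Run the full community-metabolism pipeline from files
#'
#' Executes the whole chain on a dataset directory laid out as written by
#' [synth_all()] (`universe/`, `annotation.tsv`, `design.tsv`):
#' count binning under the EC key, two-group differential abundance,
#' Simpson-index taxa dominance, meta-network and DA sub-network
#' construction, seed prediction with the sub/meta intersection filter,
#' network expansion for treatment and control environments, per-taxon
#' knockouts against the treatment expansion, and pathway enrichment of
#' scope-unique and taxa-dependent compound sets.
#'
#' @param dir dataset directory.
#' @param treatment,control treatment labels to contrast (defaults
#'   `"SM"` vs `"NTC"`).
#' @param rank taxonomic rank for dominance scoring (default
#'   `"genus"`).
#' @param alpha FDR threshold for differential abundance and enrichment.
#' @param simpson_threshold dominance threshold on the mean Simpson
#'   index (default 0.4).
#' @return List with components `universe`, `design`, `ec_counts`, `da`,
#'   `dominance`, `dominated`, `meta_seeds`, `sub_seeds`, `seeds`
#'   (intersected, per contrast side), `expansion` (per side),
#'   `scope_diff`, `knockouts`, `enrichment` (per-taxon dependent-set
#'   pathway enrichment), `unique_enrichment` (pathway enrichment of the
#'   treatment-unique scope).
#' @export
run_pipeline <- function(dir, treatment = "SM", control = "NTC",
                         rank = "genus", alpha = 0.05,
                         simpson_threshold = 0.4) {
  universe <- load_universe(file.path(dir, "universe"), format = "tsv")
  design <- read_design(file.path(dir, "design.tsv"))
  annotation <- read_annotation(file.path(dir, "annotation.tsv"))

  ec_counts <- bin_counts(annotation, "ec", design)
  da <- exact_nb_test(ec_counts, treatment, control, alpha = alpha)
  da_tr <- setdiff(da_significant(da, "treatment-enriched"), "unassigned")
  da_ctl <- setdiff(da_significant(da, "control-enriched"), "unassigned")

  ectax <- ec_taxon_counts(annotation, design, rank)
  dominance <- dominance_table(ectax, design,
                               treatments = c(treatment, control),
                               rank = rank, threshold = simpson_threshold)
  dominated <- dominated_enzyme_sets(dominance, treatment)

  meta_ecs <- intersect(unique(annotation$ec[nzchar(annotation$ec) &
                                               !is.na(annotation$ec)]),
                        universe_ecs(universe))
  meta_graph <- build_graph(universe, meta_ecs)
  meta_seeds <- condensation_seeds(meta_graph, treatment = "meta")

  sub_seeds <- list()
  seeds <- list()
  for (side in c(treatment, control)) {
    ecs_side <- if (side == treatment) da_tr else da_ctl
    sub_graph <- build_graph(universe, ecs_side)
    sub_seeds[[side]] <- condensation_seeds(sub_graph, treatment = side)
    seeds[[side]] <- intersect_seeds(sub_seeds[[side]], meta_seeds)
  }

  expansion <- lapply(setNames(c(treatment, control), c(treatment, control)),
                      function(side) {
    expand_scope(universe, meta_ecs, seeds[[side]])
  })
  scope_diff <- diff_scopes(expansion[[treatment]], expansion[[control]])

  knockouts <- knockout_all(universe, meta_ecs, seeds[[treatment]], dominated)

  background <- sort(unique(c(expansion[[treatment]]$scope,
                              expansion[[control]]$scope)))
  enrichment <- lapply(knockouts$reports, function(r) {
    if (length(r$dependent_compounds) == 0L) return(NULL)
    enrich_terms(r$dependent_compounds, background, universe$pathway_map,
                 alpha = alpha)
  })
  unique_enrichment <- if (length(scope_diff$unique_to_a) > 0L) {
    enrich_terms(scope_diff$unique_to_a, background, universe$pathway_map,
                 alpha = alpha)
  } else NULL

  list(universe = universe, design = design, ec_counts = ec_counts,
       da = da, dominance = dominance, dominated = dominated,
       meta_ecs = meta_ecs, meta_seeds = meta_seeds, sub_seeds = sub_seeds,
       seeds = seeds, expansion = expansion, scope_diff = scope_diff,
       knockouts = knockouts, enrichment = enrichment,
       unique_enrichment = unique_enrichment)
}
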
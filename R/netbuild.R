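#' Build the directed metabolite graph for an enzyme set
#'
#' Nodes are compounds; a directed edge substrate -> product is added for
#' every substrate/product pair of every reaction catalysed by the enzyme
#' set (any of a reaction's ECs present suffices). Reversible reactions
#' contribute edges in both directions. This is the flattened (pairwise)
#' view of the reaction hyperedges used for topology analysis; the
#' expansion simulation uses the unflattened all-substrates semantics.
#'
#' @param universe a [reaction_universe].
#' @param ecs character vector of EC accessions defining the enzyme set;
#'   `NULL` uses every EC in the universe (the meta-network).
#' @return An object of class `metabolite_graph` with elements `edges`
#'   (data.frame `from`, `to`, `reaction_id`, `ecs`), `nodes`, `graph`
#'   (an igraph object) and `provenance`.
#' @export
build_graph <- function(universe, ecs = NULL) {
  if (is.null(ecs)) ecs <- universe_ecs(universe)
  ecs <- unique(as.character(ecs))
  rx <- universe$reactions
  keep <- vapply(rx$ecs, function(e) any(e %in% ecs), logical(1))
  rx <- rx[keep, , drop = FALSE]

  if (nrow(rx) == 0L) {
    edges <- data.frame(from = character(0), to = character(0),
                        reaction_id = character(0), ecs = character(0),
                        stringsAsFactors = FALSE)
  } else {
    per_rx <- lapply(seq_len(nrow(rx)), function(i) {
      s <- rx$substrates[[i]]
      p <- rx$products[[i]]
      from <- rep(s, each = length(p))
      to <- rep(p, times = length(s))
      if (rx$reversible[i]) {
        tmp <- from
        from <- c(from, to)
        to <- c(to, tmp)
      }
      data.frame(from = from, to = to,
                 reaction_id = rx$reaction_id[i],
                 ecs = paste(intersect(rx$ecs[[i]], ecs), collapse = ";"),
                 stringsAsFactors = FALSE)
    })
    edges <- do.call(rbind, per_rx)
    edges <- unique(edges)
  }
  nodes <- sort(unique(c(edges$from, edges$to)))
  g <- igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  structure(
    list(edges = edges, nodes = nodes, graph = g,
         provenance = list(n_ecs = length(ecs),
                           n_reactions = nrow(rx))),
    class = "metabolite_graph")
}

#' @export
print.metabolite_graph <- function(x, ...) {
  cat("metabolite_graph:", length(x$nodes), "compounds,",
      nrow(x$edges), "directed edges from", x$provenance$n_reactions,
      "reactions\n")
  invisible(x)
}

#' Predict seed compounds (environmental resources) by SCC condensation
#'
#' Strongly connected components of the metabolite graph are contracted
#' to a condensation DAG; components with no incoming edge (source
#' components) cannot be produced from elsewhere in the network, so their
#' member compounds are predicted to be acquired from the environment.
#' Every member of a source component is reported as a seed with
#' confidence 1/|component|.
#'
#' @param graph a `metabolite_graph` from [build_graph()].
#' @param treatment optional label attached to the result.
#' @param min_confidence drop seeds with confidence below this value
#'   (default 0 keeps all, i.e. no component-size cutoff).
#' @return An object of class `seed_set`: list with `treatment`, `stage`
#'   (`"raw"`) and `seeds`, a data.frame of `compound_id`, `confidence`,
#'   `component_id`.
#' @export
condensation_seeds <- function(graph, treatment = NA_character_,
                               min_confidence = 0) {
  if (length(graph$nodes) == 0L) {
    return(new_seed_set(data.frame(compound_id = character(0),
                                   confidence = numeric(0),
                                   component_id = integer(0),
                                   stringsAsFactors = FALSE),
                        treatment, "raw"))
  }
  comp <- igraph::components(graph$graph, mode = "strong")
  membership <- comp$membership
  cond <- igraph::contract(graph$graph, membership, vertex.attr.comb = "ignore")
  cond <- igraph::simplify(cond, remove.loops = TRUE, remove.multiple = TRUE)
  stopifnot(igraph::is_dag(cond))
  indeg <- igraph::degree(cond, mode = "in")
  sources <- which(indeg == 0L)
  member_of <- membership[graph$nodes]
  keep <- member_of %in% sources
  seeds <- data.frame(compound_id = graph$nodes[keep],
                      confidence = 1 / comp$csize[member_of[keep]],
                      component_id = as.integer(member_of[keep]),
                      stringsAsFactors = FALSE)
  seeds <- seeds[seeds$confidence >= min_confidence, , drop = FALSE]
  seeds <- seeds[order(seeds$compound_id), , drop = FALSE]
  rownames(seeds) <- NULL
  new_seed_set(seeds, treatment, "raw")
}

new_seed_set <- function(seeds, treatment, stage) {
  structure(list(treatment = treatment, stage = stage, seeds = seeds),
            class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat("seed_set (", x$stage, "): ", nrow(x$seeds), " compounds",
      if (!is.na(x$treatment)) paste0(" [", x$treatment, "]"), "\n", sep = "")
  invisible(x)
}

#' Compound ids of a seed set
#' @param x a `seed_set`.
#' @return Character vector of seed compound ids.
#' @export
seed_ids <- function(x) {
  x$seeds$compound_id
}

#' Intersect sub-network seeds with meta-network seeds
#'
#' Sub-networks built from differentially abundant enzymes alone are
#' highly fragmented, so their raw seed lists contain artificial source
#' metabolites. Only compounds predicted as seeds in both the sub-network
#' and the full meta-network are kept in the environment proxy list.
#' Confidence values are taken from the sub-network prediction.
#'
#' @param sub raw `seed_set` of the treatment sub-network.
#' @param meta raw `seed_set` of the full meta-network.
#' @return A `seed_set` with `stage = "intersected"`.
#' @export
intersect_seeds <- function(sub, meta) {
  stopifnot(inherits(sub, "seed_set"), inherits(meta, "seed_set"))
  if (sub$stage != "raw" || meta$stage != "raw") {
    stop("intersect_seeds expects two stage='raw' seed sets", call. = FALSE)
  }
  keep <- sub$seeds$compound_id %in% meta$seeds$compound_id
  seeds <- sub$seeds[keep, , drop = FALSE]
  rownames(seeds) <- NULL
  if (nrow(seeds) == 0L) {
    warning("sub-network and meta-network seed sets are disjoint",
            call. = FALSE)
  }
  new_seed_set(seeds, sub$treatment, "intersected")
}

#' Export a metabolite graph as GraphML
#' @param graph a `metabolite_graph`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph$graph, path, format = "graphml")
  invisible(path)
}

#' Export a metabolite graph as a directed edge list TSV
#'
#' Columns: `source_compound`, `target_compound`, `reaction_id`, `ecs`.
#' @param graph a `metabolite_graph`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(graph, path) {
  out <- graph$edges
  names(out)[1:2] <- c("source_compound", "target_compound")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
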
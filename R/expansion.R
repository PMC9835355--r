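#' Network expansion: the producible-compound scope of a seed set
#'
#' Simulates community metabolic activity. Starting from a set of source
#' metabolites (the environmental resources), the algorithm repeatedly
#' scans the reaction bank for feasible reactions — reactions catalysed by
#' the enzyme set whose substrates are all already available — and adds
#' their products to the available set. Reversible reactions are checked
#' independently in both directions. Expansion stops when no feasible
#' reaction remains; the fixed point ("scope") reflects both the reaction
#' repertoire and the primary compound set. Set semantics throughout: no
#' stoichiometry, nothing is consumed.
#'
#' @param universe a [reaction_universe].
#' @param ecs enzyme set (character vector of EC accessions); `NULL` uses
#'   all ECs in the universe.
#' @param seeds character vector of seed compound ids, or a `seed_set`.
#'   Seeds absent from the universe are dropped with a warning.
#' @return An object of class `expansion_result`: list with `scope`
#'   (sorted compound ids, includes seeds), `fired` (reaction ids that
#'   fired in at least one direction), `trace` (data.frame per iteration:
#'   `iteration`, `n_reactions`, `n_compounds`, `reactions`, `compounds`),
#'   `seeds` and `ecs`.
#' @export
expand_scope <- function(universe, ecs = NULL, seeds) {
  if (inherits(seeds, "seed_set")) seeds <- seed_ids(seeds)
  seeds <- unique(as.character(seeds))
  known <- universe_compounds(universe)
  unknown <- setdiff(seeds, known)
  if (length(unknown) > 0L) {
    warning("dropping ", length(unknown),
            " seed(s) absent from the universe: ",
            paste(utils::head(sort(unknown), 10L), collapse = ", "),
            call. = FALSE)
    seeds <- intersect(seeds, known)
  }
  if (is.null(ecs)) ecs <- universe_ecs(universe)
  ecs <- unique(as.character(ecs))

  rx <- universe$reactions
  avail <- vapply(rx$ecs, function(e) any(e %in% ecs), logical(1))
  rx <- rx[avail, , drop = FALSE]

  # one entry per reaction direction
  dir_sub <- c(rx$substrates, rx$products[rx$reversible])
  dir_prod <- c(rx$products, rx$substrates[rx$reversible])
  dir_rid <- c(rx$reaction_id, rx$reaction_id[rx$reversible])

  scope <- seeds
  fired <- logical(length(dir_rid))
  trace <- list()
  iter <- 0L
  repeat {
    feasible <- which(!fired & vapply(dir_sub, function(s) all(s %in% scope),
                                      logical(1)))
    if (length(feasible) == 0L) break
    iter <- iter + 1L
    fired[feasible] <- TRUE
    new_compounds <- setdiff(unique(unlist(dir_prod[feasible])), scope)
    trace[[iter]] <- data.frame(
      iteration = iter,
      n_reactions = length(feasible),
      n_compounds = length(new_compounds),
      reactions = paste(sort(unique(dir_rid[feasible])), collapse = ";"),
      compounds = paste(sort(new_compounds), collapse = ";"),
      stringsAsFactors = FALSE)
    if (length(new_compounds) == 0L) break
    scope <- c(scope, new_compounds)
  }
  trace <- if (length(trace) > 0L) do.call(rbind, trace) else
    data.frame(iteration = integer(0), n_reactions = integer(0),
               n_compounds = integer(0), reactions = character(0),
               compounds = character(0), stringsAsFactors = FALSE)

  structure(
    list(scope = sort(scope),
         fired = sort(unique(dir_rid[fired])),
         trace = trace,
         seeds = sort(seeds),
         ecs = sort(ecs)),
    class = "expansion_result")
}

#' @export
print.expansion_result <- function(x, ...) {
  cat("expansion_result:", length(x$scope), "compounds in scope (",
      length(x$seeds), "seeds ),", length(x$fired), "reactions fired in",
      nrow(x$trace), "iterations\n")
  invisible(x)
}

#' Compare two expansion scopes
#'
#' Partitions the union of two scopes into compounds unique to each and
#' compounds shared by both, e.g. treatment vs control metabolic
#' activity.
#'
#' @param a,b `expansion_result` objects (or plain character vectors of
#'   compound ids).
#' @return List with `unique_to_a`, `unique_to_b`, `shared` (disjoint,
#'   their union is the union of the two scopes).
#' @export
diff_scopes <- function(a, b) {
  sa <- if (inherits(a, "expansion_result")) a$scope else as.character(a)
  sb <- if (inherits(b, "expansion_result")) b$scope else as.character(b)
  list(unique_to_a = sort(setdiff(sa, sb)),
       unique_to_b = sort(setdiff(sb, sa)),
       shared = sort(intersect(sa, sb)))
}

#' Write an expansion scope to TSV
#'
#' One row per scope compound with the iteration at which it appeared
#' (0 for seeds) and the reactions that first produced it.
#' @param result an `expansion_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scope <- function(result, path) {
  iteration_added <- setNames(rep(0L, length(result$seeds)), result$seeds)
  via <- setNames(rep("seed", length(result$seeds)), result$seeds)
  if (nrow(result$trace) > 0L) {
    for (i in seq_len(nrow(result$trace))) {
      cps <- strsplit(result$trace$compounds[i], ";", fixed = TRUE)[[1]]
      cps <- cps[nzchar(cps)]
      iteration_added[cps] <- result$trace$iteration[i]
      via[cps] <- result$trace$reactions[i]
    }
  }
  out <- data.frame(compound_id = result$scope,
                    iteration_added = iteration_added[result$scope],
                    via_reaction = via[result$scope],
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
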
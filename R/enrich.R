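#' Hypergeometric over-representation of pathway or module terms
#'
#' One-sided over-representation test: for each term, the upper-tail
#' hypergeometric probability of drawing at least the observed overlap
#' `k` between the selected set (size `n`) and the term members (size
#' `K`, after intersection with the background universe of size `N`).
#' P-values are BH-adjusted across the tested terms (those with
#' `k >= 1`); terms with adjusted p at or below `alpha` are flagged
#' significant.
#'
#' @param selected character vector of selected ids (compounds or KOs).
#'   Ids outside the universe are dropped with a warning.
#' @param universe background id set.
#' @param term_map named list: term id -> member ids.
#' @param alpha FDR threshold (default 0.05).
#' @return data.frame sorted by `q_value` then `p_value`, columns `term`,
#'   `k`, `K`, `n`, `N`, `p_value`, `q_value`, `significant`.
#' @export
enrich_terms <- function(selected, universe, term_map, alpha = 0.05) {
  universe <- unique(as.character(universe))
  selected <- unique(as.character(selected))
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  if (length(selected) == 0L) stop("empty selected set", call. = FALSE)
  outside <- setdiff(selected, universe)
  if (length(outside) > 0L) {
    warning(length(outside), " selected id(s) outside the universe dropped",
            call. = FALSE)
    selected <- intersect(selected, universe)
    if (length(selected) == 0L) stop("empty selected set", call. = FALSE)
  }
  n <- length(selected)
  N <- length(universe)
  rows <- lapply(names(term_map), function(term) {
    members <- intersect(term_map[[term]], universe)
    K <- length(members)
    k <- length(intersect(selected, members))
    if (k == 0L) return(NULL)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_value = numeric(0),
                      q_value = numeric(0), significant = logical(0),
                      stringsAsFactors = FALSE))
  }
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out$significant <- out$q_value <= alpha
  out <- out[order(out$q_value, out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter enriched terms by treatment dominance of their entities
#'
#' Reporting filter for treatment-vs-control comparisons: keeps terms
#' with at least `min_entities` entities overall and a clear dominance
#' (at least `dominance_fraction` of the entities) of one treatment,
#' labelling each kept term with its dominant treatment.
#'
#' @param results data.frame from [enrich_terms()] (must contain a
#'   `term` column).
#' @param entity_counts long data.frame annotating per-treatment entity
#'   counts: columns `term`, `treatment`, `n_entities`.
#' @param min_entities minimum total entities per term (default 6).
#' @param dominance_fraction minimum fraction of entities from the
#'   dominant treatment (default 0.85).
#' @return The kept rows of `results` with added columns
#'   `total_entities`, `dominant_treatment`, `dominance_fraction`.
#' @export
dominance_filtered_terms <- function(results, entity_counts,
                                     min_entities = 6,
                                     dominance_fraction = 0.85) {
  stats_by_term <- lapply(split(entity_counts, entity_counts$term),
                          function(tc) {
    total <- sum(tc$n_entities)
    i <- which.max(tc$n_entities)
    data.frame(term = tc$term[1],
               total_entities = total,
               dominant_treatment = tc$treatment[i],
               dominance_fraction = if (total > 0)
                 tc$n_entities[i] / total else 0,
               stringsAsFactors = FALSE)
  })
  info <- do.call(rbind, stats_by_term)
  merged <- merge(results, info, by = "term")
  kept <- merged$total_entities >= min_entities &
    merged$dominance_fraction >= dominance_fraction
  out <- merged[kept, , drop = FALSE]
  out <- out[order(out$q_value, out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
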
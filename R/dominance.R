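#' Simpson dominance index
#'
#' The dominance form of the Simpson index, `sum(p_i^2)` with
#' `p_i = count_i / total`: 1 when a single taxon carries all reads,
#' approaching 1/k for an even spread over k taxa. Values above the
#' dominance threshold (default 0.4 in [call_dominance()]) indicate that
#' one taxonomic group concentrates the reads of a function.
#'
#' @param counts nonnegative numeric vector of per-taxon read counts
#'   (names optional).
#' @return Numeric scalar in (0, 1].
#' @export
simpson_index <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  total <- sum(counts)
  if (total <= 0) stop("Simpson index undefined for zero total", call. = FALSE)
  sum((counts / total)^2)
}

#' Call taxonomic dominance of one enzyme in one treatment
#'
#' An enzymatic function is dominated by a taxonomic group within a
#' treatment when (i) the mean Simpson index across the treatment's
#' replicate samples exceeds `threshold`, and (ii) the same taxon is the
#' per-replicate read-count argmax in every replicate. Replicates with no
#' reads for the enzyme are excluded (and counted in `n_excluded`);
#' argmax ties are broken lexicographically.
#'
#' @param dists taxon-by-replicate matrix of read counts (rownames =
#'   taxa), or a list of named count vectors, one per replicate.
#' @param threshold mean-Simpson dominance threshold (default 0.4).
#' @return List with `mean_simpson`, `dominant_taxon` (NA unless
#'   dominated), `is_dominated`, `n_replicates`, `n_excluded`,
#'   `replicate_dominants`.
#' @export
call_dominance <- function(dists, threshold = 0.4) {
  if (is.matrix(dists) || is.data.frame(dists)) {
    m <- as.matrix(dists)
    dists <- lapply(seq_len(ncol(m)), function(j) setNames(m[, j], rownames(m)))
  }
  totals <- vapply(dists, sum, numeric(1))
  excluded <- totals <= 0
  dists <- dists[!excluded]
  if (length(dists) == 0L) {
    return(list(mean_simpson = NA_real_, dominant_taxon = NA_character_,
                is_dominated = FALSE, n_replicates = 0L,
                n_excluded = sum(excluded),
                replicate_dominants = character(0)))
  }
  d <- vapply(dists, simpson_index, numeric(1))
  doms <- vapply(dists, function(x) {
    x <- x[order(names(x))]
    names(x)[which.max(x)]
  }, character(1))
  mean_d <- mean(d)
  dominated <- mean_d > threshold && length(unique(doms)) == 1L
  list(mean_simpson = mean_d,
       dominant_taxon = if (dominated) doms[[1]] else NA_character_,
       is_dominated = dominated,
       n_replicates = length(dists),
       n_excluded = sum(excluded),
       replicate_dominants = unname(doms))
}

#' Treatment-specific dominance records for all enzymes
#'
#' Applies [call_dominance()] to every EC in every requested treatment,
#' using the per-sample EC-by-taxon read distributions from
#' [ec_taxon_counts()].
#'
#' @param ectax long data.frame (`ec`, `taxon`, `sample`, `count`).
#' @param design design data.frame (`sample`, `treatment`, `replicate`).
#' @param treatments treatments to score (default: all in the design).
#' @param rank label recorded in the output (the rank `ectax` was built
#'   at).
#' @param threshold mean-Simpson dominance threshold (default 0.4).
#' @return data.frame with columns `ec`, `treatment`, `rank`,
#'   `mean_simpson`, `dominant_taxon`, `is_dominated`, `n_replicates`,
#'   `n_excluded`.
#' @export
dominance_table <- function(ectax, design, treatments = NULL, rank = NA,
                            threshold = 0.4) {
  if (is.null(treatments)) treatments <- unique(design$treatment)
  rows <- list()
  for (tr in treatments) {
    samples <- design$sample[design$treatment == tr]
    sub <- ectax[ectax$sample %in% samples, , drop = FALSE]
    for (e in sort(unique(sub$ec))) {
      se <- sub[sub$ec == e, , drop = FALSE]
      dists <- lapply(samples, function(s) {
        ss <- se[se$sample == s, , drop = FALSE]
        setNames(ss$count, ss$taxon)
      })
      rec <- call_dominance(dists, threshold)
      rows[[length(rows) + 1L]] <- data.frame(
        ec = e, treatment = tr, rank = rank,
        mean_simpson = rec$mean_simpson,
        dominant_taxon = rec$dominant_taxon,
        is_dominated = rec$is_dominated,
        n_replicates = rec$n_replicates,
        n_excluded = rec$n_excluded,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Invert dominance records into per-taxon enzyme sets
#'
#' Each EC has at most one dominant taxon per treatment, so the inverse
#' map partitions the dominated enzymes of a treatment among taxa.
#'
#' @param records data.frame from [dominance_table()].
#' @param treatment treatment to extract.
#' @return Named list: taxon -> character vector of dominated ECs (empty
#'   list when nothing is dominated).
#' @export
dominated_enzyme_sets <- function(records, treatment) {
  sub <- records[records$treatment == treatment & records$is_dominated, ,
                 drop = FALSE]
  if (nrow(sub) == 0L) return(setNames(list(), character(0)))
  lapply(split(sub$ec, sub$dominant_taxon), function(x) sort(unique(x)))
}
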
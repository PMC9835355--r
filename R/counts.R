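#' Construct a feature-by-sample count table
#'
#' @param mat nonnegative integer matrix, features in rows, samples in
#'   columns (column names are sample ids).
#' @param design data.frame with columns `sample`, `treatment`,
#'   `replicate`; every column of `mat` must appear in `design$sample`.
#' @param key_scheme annotation key the features are binned under, e.g.
#'   `"ec"`, `"ko"`, `"taxon@genus"`.
#' @return An object of class `count_table`.
#' @export
count_table <- function(mat, design, key_scheme) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "integer"
  if (any(is.na(mat)) || any(mat < 0L)) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (is.null(colnames(mat)) || is.null(rownames(mat))) {
    stop("count matrix needs feature rownames and sample colnames",
         call. = FALSE)
  }
  design$sample <- as.character(design$sample)
  missing_samples <- setdiff(colnames(mat), design$sample)
  if (length(missing_samples) > 0L) {
    stop("sample(s) absent from design: ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  }
  design <- design[match(colnames(mat), design$sample), , drop = FALSE]
  rownames(design) <- NULL
  structure(list(matrix = mat, design = design, key_scheme = key_scheme),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table [", x$key_scheme, "]: ", nrow(x$matrix), " features x ",
      ncol(x$matrix), " samples (",
      length(unique(x$design$treatment)), " treatments)\n", sep = "")
  invisible(x)
}

#' Parse a taxonomy lineage string
#'
#' Lineages are stored as `"rank:name;rank:name"` strings (e.g.
#' `"genus:Bacillus;order:Bacillales"`).
#'
#' @param lineage character vector of lineage strings.
#' @param rank rank to extract, e.g. `"genus"`.
#' @return Character vector of taxon names; `NA` where the rank is not
#'   annotated.
#' @export
lineage_at_rank <- function(lineage, rank) {
  vapply(strsplit(ifelse(is.na(lineage), "", lineage), ";", fixed = TRUE),
         function(parts) {
           kv <- strsplit(parts, ":", fixed = TRUE)
           hit <- vapply(kv, function(p) length(p) == 2L && p[1] == rank,
                         logical(1))
           if (any(hit)) kv[[which(hit)[1]]][2] else NA_character_
         }, character(1))
}

#' Assign contig-level taxonomy by the gene majority rule
#'
#' Each contig is assigned the most frequent taxonomic annotation of its
#' genes at the requested rank. Ties are broken toward the
#' lexicographically smaller taxon and logged; contigs with no annotated
#' gene at the rank map to `"unassigned"`.
#'
#' @param annotation annotation data.frame (see [read_annotation()]) with
#'   columns `gene_id`, `contig_id`, `taxonomy`.
#' @param rank taxonomic rank (`"genus"`, `"family"`, `"order"`,
#'   `"phylum"`, ...).
#' @return Named character vector: contig id -> taxon.
#' @export
assign_contig_taxonomy <- function(annotation, rank) {
  taxa <- lineage_at_rank(annotation$taxonomy, rank)
  contigs <- as.character(annotation$contig_id)
  out <- vapply(split(taxa, contigs), function(tx) {
    tx <- tx[!is.na(tx) & nzchar(tx)]
    if (length(tx) == 0L) return("unassigned")
    tab <- table(tx)
    winners <- names(tab)[tab == max(tab)]
    sort(winners)[1]
  }, character(1))
  n_ties <- sum(vapply(split(taxa, contigs), function(tx) {
    tx <- tx[!is.na(tx) & nzchar(tx)]
    if (length(tx) == 0L) return(FALSE)
    tab <- table(tx)
    sum(tab == max(tab)) > 1L
  }, logical(1)))
  if (n_ties > 0L) {
    message(n_ties, " contig(s) had tied modal taxa at rank '", rank,
            "'; ties broken lexicographically")
  }
  out
}

#' Consistency of within-contig taxonomic annotations
#'
#' Fraction of multi-annotated contigs whose genes all agree at a rank.
#' @param annotation annotation data.frame.
#' @param rank taxonomic rank.
#' @return A single numeric fraction (NA when no contig is annotated).
#' @export
contig_consistency <- function(annotation, rank) {
  taxa <- lineage_at_rank(annotation$taxonomy, rank)
  per_contig <- split(taxa, as.character(annotation$contig_id))
  annotated <- Filter(function(tx) sum(!is.na(tx) & nzchar(tx)) > 0L,
                      per_contig)
  if (length(annotated) == 0L) return(NA_real_)
  mean(vapply(annotated, function(tx) {
    tx <- tx[!is.na(tx) & nzchar(tx)]
    length(unique(tx)) == 1L
  }, logical(1)))
}

#' Bin gene-level counts into a feature-by-sample count table
#'
#' Sums read counts over all genes sharing an annotation key. Functional
#' keys (`"ec"`, `"ko"`) bin by the gene's own annotation; `"taxon"` bins
#' by the contig-level majority taxonomy at `rank`. Genes without an
#' annotation under the key fall into the `"unassigned"` feature, so
#' column sums are conserved.
#'
#' @param annotation annotation data.frame: columns `gene_id`,
#'   `contig_id`, `taxonomy`, `ec`, `ko`, then one integer column per
#'   sample.
#' @param key_scheme `"ec"`, `"ko"` or `"taxon"`.
#' @param design design data.frame (`sample`, `treatment`, `replicate`).
#' @param rank taxonomic rank, required for `key_scheme = "taxon"`.
#' @return A [count_table].
#' @export
bin_counts <- function(annotation, key_scheme = c("ec", "ko", "taxon"),
                       design, rank = NULL) {
  key_scheme <- match.arg(key_scheme)
  samples <- as.character(design$sample)
  missing_samples <- setdiff(samples, names(annotation))
  if (length(missing_samples) > 0L) {
    stop("annotation table lacks count column(s) for sample(s): ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  }
  if (key_scheme == "taxon") {
    if (is.null(rank)) stop("rank is required for taxon binning", call. = FALSE)
    contig_tax <- assign_contig_taxonomy(annotation, rank)
    key <- unname(contig_tax[as.character(annotation$contig_id)])
    label <- paste0("taxon@", rank)
  } else {
    key <- as.character(annotation[[key_scheme]])
    key[is.na(key) | !nzchar(key)] <- "unassigned"
    label <- key_scheme
  }
  counts <- as.matrix(annotation[, samples, drop = FALSE])
  storage.mode(counts) <- "integer"
  mat <- rowsum(counts, group = key, reorder = TRUE)
  count_table(mat, design, label)
}

#' Merge count tables with disjoint samples
#'
#' Features are unioned (absent cells filled with 0); sample sets must be
#' disjoint and key schemes identical.
#'
#' @param tables list of [count_table] objects.
#' @return A single merged [count_table].
#' @export
merge_tables <- function(tables) {
  stopifnot(length(tables) >= 1L)
  if (length(tables) == 1L) return(tables[[1]])
  schemes <- unique(vapply(tables, function(t) t$key_scheme, character(1)))
  if (length(schemes) > 1L) {
    stop("cannot merge tables with different key schemes: ",
         paste(schemes, collapse = ", "), call. = FALSE)
  }
  all_samples <- unlist(lapply(tables, function(t) colnames(t$matrix)))
  if (anyDuplicated(all_samples)) {
    stop("duplicate sample id(s): ",
         paste(unique(all_samples[duplicated(all_samples)]), collapse = ", "),
         call. = FALSE)
  }
  features <- sort(unique(unlist(lapply(tables, function(t) rownames(t$matrix)))))
  mat <- matrix(0L, nrow = length(features), ncol = length(all_samples),
                dimnames = list(features, all_samples))
  for (t in tables) {
    mat[rownames(t$matrix), colnames(t$matrix)] <- t$matrix
  }
  design <- do.call(rbind, lapply(tables, function(t) t$design))
  rownames(design) <- NULL
  count_table(mat, design, schemes)
}

#' Drop low-count features
#'
#' Mirrors the pre-ordination filter of keeping features with at least
#' `min_total` summed counts. Not applied before differential abundance
#' testing, which uses raw counts.
#'
#' @param table a [count_table].
#' @param min_total minimum total count per feature (default 50).
#' @return Filtered [count_table].
#' @export
filter_low_counts <- function(table, min_total = 50) {
  keep <- rowSums(table$matrix) >= min_total
  count_table(table$matrix[keep, , drop = FALSE], table$design,
              table$key_scheme)
}

#' Per-sample EC-by-taxon read counts
#'
#' Long-format distribution of the taxonomic affiliations (at gene level)
#' of the reads supporting each enzymatic function; input to the
#' dominance scoring.
#'
#' @param annotation annotation data.frame.
#' @param design design data.frame.
#' @param rank taxonomic rank for the gene-level affiliation.
#' @return data.frame with columns `ec`, `taxon`, `sample`, `count`
#'   (genes without an EC or without taxonomy at `rank` are excluded).
#' @export
ec_taxon_counts <- function(annotation, design, rank) {
  samples <- as.character(design$sample)
  ec <- as.character(annotation$ec)
  taxon <- lineage_at_rank(annotation$taxonomy, rank)
  keep <- !is.na(ec) & nzchar(ec) & !is.na(taxon) & nzchar(taxon)
  ann <- annotation[keep, , drop = FALSE]
  ec <- ec[keep]
  taxon <- taxon[keep]
  counts <- as.matrix(ann[, samples, drop = FALSE])
  key <- paste(ec, taxon, sep = "\r")
  agg <- rowsum(counts, group = key, reorder = TRUE)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  out <- data.frame(
    ec = rep(vapply(parts, `[`, character(1), 1L), times = length(samples)),
    taxon = rep(vapply(parts, `[`, character(1), 2L), times = length(samples)),
    sample = rep(samples, each = nrow(agg)),
    count = as.integer(agg[, samples]),
    stringsAsFactors = FALSE)
  out[out$count > 0L, , drop = FALSE]
}

#' Read an annotation table from TSV
#'
#' Expected columns: `gene_id`, `contig_id`, `taxonomy` (lineage string,
#' see [lineage_at_rank()]), `ec`, `ko`, then one integer column per
#' sample.
#' @param path TSV file.
#' @return data.frame.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("gene_id", "contig_id", "taxonomy", "ec", "ko")
  missing_cols <- setdiff(required, names(ann))
  if (length(missing_cols) > 0L) {
    stop("annotation table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(ann$gene_id)) stop("duplicate gene ids", call. = FALSE)
  ann
}

#' Read a sample design table from TSV
#' @param path TSV file with columns `sample`, `treatment`, `replicate`.
#' @return data.frame.
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("sample", "treatment", "replicate")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols) > 0L) {
    stop("design table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  d$sample <- as.character(d$sample)
  d
}

#' Write a count table to TSV
#' @param table a [count_table].
#' @param path output file (first column `feature`, then sample columns).
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  out <- data.frame(feature = rownames(table$matrix),
                    table$matrix, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count table from TSV
#' @param path TSV written by [write_count_table()].
#' @param design design data.frame (see [read_design()]).
#' @param key_scheme annotation key label.
#' @return A [count_table].
#' @export
read_count_table <- function(path, design, key_scheme) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  mat <- as.matrix(tb[, -1, drop = FALSE])
  rownames(mat) <- tb[[1]]
  count_table(mat, design, key_scheme)
}
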
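#' Construct a reaction universe
#'
#' A reaction universe (the "reaction bank") is the global catalogue of
#' enzymatic reactions against which community networks are built: every
#' reaction carries one or more EC numbers, a substrate compound set, a
#' product compound set and a reversibility flag. Pathway and module maps
#' attach KEGG-style pathway membership to compounds and module membership
#' to KO accessions.
#'
#' @param reactions data.frame with columns `reaction_id` (character),
#'   `ecs`, `substrates`, `products` (list columns of character vectors)
#'   and `reversible` (logical).
#' @param compounds optional data.frame with columns `compound_id` and
#'   `name`. When `NULL`, the compound set is derived from the reactions
#'   and pathway map.
#' @param pathway_map named list: pathway id -> character vector of member
#'   compound ids.
#' @param module_map named list: module id -> character vector of member
#'   KO accessions.
#' @return An object of class `reaction_universe` with elements
#'   `reactions`, `compounds`, `ec_index` (EC -> reaction ids),
#'   `pathway_map` and `module_map`.
#' @export
reaction_universe <- function(reactions, compounds = NULL,
                              pathway_map = list(), module_map = list()) {
  stopifnot(is.data.frame(reactions))
  required <- c("reaction_id", "ecs", "substrates", "products", "reversible")
  missing_cols <- setdiff(required, names(reactions))
  if (length(missing_cols) > 0L) {
    stop("reaction table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  reactions$reaction_id <- as.character(reactions$reaction_id)
  if (anyDuplicated(reactions$reaction_id)) {
    stop("duplicate reaction ids: ",
         paste(unique(reactions$reaction_id[duplicated(reactions$reaction_id)]),
               collapse = ", "), call. = FALSE)
  }
  for (col in c("ecs", "substrates", "products")) {
    reactions[[col]] <- lapply(reactions[[col]], function(x) {
      x <- unique(as.character(x))
      x[nzchar(x)]
    })
  }
  reactions$reversible <- as.logical(reactions$reversible)

  bad <- vapply(seq_len(nrow(reactions)), function(i) {
    length(reactions$substrates[[i]]) == 0L ||
      length(reactions$products[[i]]) == 0L ||
      length(reactions$ecs[[i]]) == 0L
  }, logical(1))
  if (any(bad)) {
    stop("reaction(s) with empty EC, substrate or product set: ",
         paste(reactions$reaction_id[bad], collapse = ", "), call. = FALSE)
  }

  referenced <- unique(c(unlist(reactions$substrates),
                         unlist(reactions$products)))
  if (is.null(compounds)) {
    ids <- sort(unique(c(referenced, unlist(pathway_map))))
    compounds <- data.frame(compound_id = ids,
                            name = ids,
                            stringsAsFactors = FALSE)
  } else {
    compounds$compound_id <- as.character(compounds$compound_id)
    if (is.null(compounds$name)) compounds$name <- compounds$compound_id
    unknown <- setdiff(referenced, compounds$compound_id)
    if (length(unknown) > 0L) {
      stop("reaction(s) reference unknown compound id(s): ",
           paste(sort(unknown), collapse = ", "), call. = FALSE)
    }
  }
  if (anyDuplicated(compounds$compound_id)) {
    stop("duplicate compound ids", call. = FALSE)
  }

  pathway_map <- lapply(pathway_map, function(x) sort(unique(as.character(x))))
  stray <- setdiff(unlist(pathway_map), compounds$compound_id)
  if (length(stray) > 0L) {
    stop("pathway map references unknown compound id(s): ",
         paste(sort(stray), collapse = ", "), call. = FALSE)
  }
  module_map <- lapply(module_map, function(x) sort(unique(as.character(x))))

  structure(
    list(reactions = reactions,
         compounds = compounds,
         ec_index = build_ec_index(reactions),
         pathway_map = pathway_map,
         module_map = module_map),
    class = "reaction_universe")
}

build_ec_index <- function(reactions) {
  if (nrow(reactions) == 0L) return(list())
  pairs <- data.frame(
    ec = unlist(reactions$ecs),
    reaction_id = rep(reactions$reaction_id,
                      lengths(reactions$ecs)),
    stringsAsFactors = FALSE)
  lapply(split(pairs$reaction_id, pairs$ec), function(x) sort(unique(x)))
}

#' @export
print.reaction_universe <- function(x, ...) {
  cat("reaction_universe:", nrow(x$reactions), "reactions,",
      nrow(x$compounds), "compounds,", length(x$ec_index), "ECs,",
      length(x$pathway_map), "pathways,", length(x$module_map), "modules\n")
  invisible(x)
}

#' All EC numbers present in a universe
#' @param universe a `reaction_universe`.
#' @return Character vector of EC accessions.
#' @export
universe_ecs <- function(universe) {
  names(universe$ec_index)
}

#' All compound ids present in a universe
#' @param universe a `reaction_universe`.
#' @return Character vector of compound ids.
#' @export
universe_compounds <- function(universe) {
  universe$compounds$compound_id
}

split_field <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  strsplit(x, ";", fixed = TRUE)
}

join_field <- function(x) {
  vapply(x, paste, character(1), collapse = ";")
}

#' Load a reaction universe from disk
#'
#' The TSV dialect is a directory holding `reactions.tsv` (columns
#' `reaction_id`, `ec_list`, `substrates`, `products`, `reversible`; the
#' list-valued columns are semicolon-separated, `reversible` is 0/1),
#' plus optional `compounds.tsv` (`compound_id`, `name`), `pathways.tsv`
#' (`pathway_id`, `member_id`) and `modules.tsv` (`module_id`,
#' `member_id`). The JSON dialect is a single document with the same
#' fields. Reversible reactions are stored as single records;
#' directionalization happens when the metabolite graph is built.
#'
#' @param path directory (tsv format) or file (json format).
#' @param format `"tsv"` or `"json"`.
#' @param exclude optional character vector of compound ids (e.g. currency
#'   metabolites) to drop from all substrate and product sets at load;
#'   reactions left without substrates or products are removed and logged.
#' @return A [reaction_universe].
#' @export
load_universe <- function(path, format = c("tsv", "json"), exclude = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    rfile <- file.path(path, "reactions.tsv")
    if (!file.exists(rfile)) stop("no reactions.tsv under ", path, call. = FALSE)
    rt <- utils::read.delim(rfile, stringsAsFactors = FALSE,
                            colClasses = "character")
    required <- c("reaction_id", "ec_list", "substrates", "products", "reversible")
    missing_cols <- setdiff(required, names(rt))
    if (length(missing_cols) > 0L) {
      stop("reactions.tsv is missing column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    reactions <- data.frame(reaction_id = rt$reaction_id,
                            reversible = rt$reversible %in% c("1", "TRUE", "true"),
                            stringsAsFactors = FALSE)
    reactions$ecs <- split_field(rt$ec_list)
    reactions$substrates <- split_field(rt$substrates)
    reactions$products <- split_field(rt$products)

    compounds <- NULL
    cfile <- file.path(path, "compounds.tsv")
    if (file.exists(cfile)) {
      compounds <- utils::read.delim(cfile, stringsAsFactors = FALSE,
                                     colClasses = "character")
    }
    pathway_map <- read_membership(file.path(path, "pathways.tsv"),
                                   "pathway_id")
    module_map <- read_membership(file.path(path, "modules.tsv"),
                                  "module_id")
  } else {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                               simplifyDataFrame = FALSE)
    rx <- doc$reactions
    reactions <- data.frame(
      reaction_id = vapply(rx, function(r) as.character(r$reaction_id), character(1)),
      reversible = vapply(rx, function(r) isTRUE(as.logical(r$reversible)) ||
                            identical(r$reversible, 1L) || identical(r$reversible, 1),
                          logical(1)),
      stringsAsFactors = FALSE)
    reactions$ecs <- lapply(rx, function(r) as.character(unlist(r$ecs)))
    reactions$substrates <- lapply(rx, function(r) as.character(unlist(r$substrates)))
    reactions$products <- lapply(rx, function(r) as.character(unlist(r$products)))
    compounds <- NULL
    if (!is.null(doc$compounds)) {
      compounds <- data.frame(
        compound_id = vapply(doc$compounds, function(x) as.character(x$compound_id), character(1)),
        name = vapply(doc$compounds, function(x) {
          if (is.null(x$name)) as.character(x$compound_id) else as.character(x$name)
        }, character(1)),
        stringsAsFactors = FALSE)
    }
    pathway_map <- lapply(doc$pathways, function(x) as.character(unlist(x)))
    module_map <- lapply(doc$modules, function(x) as.character(unlist(x)))
    if (is.null(pathway_map)) pathway_map <- list()
    if (is.null(module_map)) module_map <- list()
  }

  if (!is.null(exclude) && length(exclude) > 0L) {
    exclude <- as.character(exclude)
    reactions$substrates <- lapply(reactions$substrates, setdiff, y = exclude)
    reactions$products <- lapply(reactions$products, setdiff, y = exclude)
    dead <- lengths(reactions$substrates) == 0L | lengths(reactions$products) == 0L
    if (any(dead)) {
      message("excluding currency metabolites removed ", sum(dead),
              " reaction(s): ",
              paste(reactions$reaction_id[dead], collapse = ", "))
      reactions <- reactions[!dead, , drop = FALSE]
    }
    if (!is.null(compounds)) {
      compounds <- compounds[!compounds$compound_id %in% exclude, , drop = FALSE]
    }
    pathway_map <- lapply(pathway_map, setdiff, y = exclude)
  }

  reaction_universe(reactions, compounds, pathway_map, module_map)
}

read_membership <- function(file, id_col) {
  if (!file.exists(file)) return(list())
  tb <- utils::read.delim(file, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c(id_col, "member_id") %in% names(tb))) {
    stop(basename(file), " is missing column(s): ",
         paste(setdiff(c(id_col, "member_id"), names(tb)), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(tb) == 0L) return(list())
  lapply(split(tb$member_id, tb[[id_col]]), function(x) sort(unique(x)))
}

#' Serialize a reaction universe
#'
#' Inverse of [load_universe()]: writes the TSV directory dialect or a
#' single JSON document. A save/load round trip reproduces the universe.
#'
#' @param universe a [reaction_universe].
#' @param path output directory (tsv) or file (json).
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
save_universe <- function(universe, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  rx <- universe$reactions
  if (format == "tsv") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    rt <- data.frame(reaction_id = rx$reaction_id,
                     ec_list = join_field(rx$ecs),
                     substrates = join_field(rx$substrates),
                     products = join_field(rx$products),
                     reversible = as.integer(rx$reversible),
                     stringsAsFactors = FALSE)
    utils::write.table(rt, file.path(path, "reactions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(universe$compounds, file.path(path, "compounds.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_membership(universe$pathway_map, file.path(path, "pathways.tsv"),
                     "pathway_id")
    write_membership(universe$module_map, file.path(path, "modules.tsv"),
                     "module_id")
  } else {
    doc <- list(
      reactions = lapply(seq_len(nrow(rx)), function(i) {
        list(reaction_id = rx$reaction_id[i],
             ecs = rx$ecs[[i]],
             substrates = rx$substrates[[i]],
             products = rx$products[[i]],
             reversible = rx$reversible[i])
      }),
      compounds = lapply(seq_len(nrow(universe$compounds)), function(i) {
        list(compound_id = universe$compounds$compound_id[i],
             name = universe$compounds$name[i])
      }),
      pathways = universe$pathway_map,
      modules = universe$module_map)
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

write_membership <- function(map, file, id_col) {
  if (length(map) == 0L) {
    tb <- data.frame(a = character(0), member_id = character(0))
  } else {
    tb <- data.frame(a = rep(names(map), lengths(map)),
                     member_id = unlist(map, use.names = FALSE),
                     stringsAsFactors = FALSE)
  }
  names(tb)[1] <- id_col
  utils::write.table(tb, file, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Restrict a universe to reactions catalysed by a set of enzymes
#'
#' A reaction is retained when any of its EC numbers is in `ecs` (one
#' annotated catalyst suffices for feasibility). The compound set is
#' pruned to compounds referenced by the surviving reactions; the pathway
#' map is pruned accordingly. ECs absent from the universe are reported.
#'
#' @param universe a [reaction_universe].
#' @param ecs character vector of EC accessions.
#' @return A new [reaction_universe]; empty `ecs` yields an empty
#'   reaction set.
#' @export
restrict_to_ecs <- function(universe, ecs) {
  ecs <- unique(as.character(ecs))
  unknown <- setdiff(ecs, names(universe$ec_index))
  if (length(unknown) > 0L) {
    message(length(unknown), " EC(s) not present in universe: ",
            paste(utils::head(sort(unknown), 10L), collapse = ", "),
            if (length(unknown) > 10L) ", ..." else "")
  }
  keep <- vapply(universe$reactions$ecs,
                 function(e) any(e %in% ecs), logical(1))
  rx <- universe$reactions[keep, , drop = FALSE]
  referenced <- unique(c(unlist(rx$substrates), unlist(rx$products)))
  compounds <- universe$compounds[
    universe$compounds$compound_id %in% referenced, , drop = FALSE]
  pathway_map <- lapply(universe$pathway_map, intersect, y = referenced)
  pathway_map <- pathway_map[lengths(pathway_map) > 0L]
  reaction_universe(rx, compounds, pathway_map, universe$module_map)
}
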
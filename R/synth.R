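#' Specification for the synthetic data generator
#'
#' Defines the conditions a synthetic study is generated under: the size
#' and layering of the reaction universe, the planted seed compounds per
#' treatment, the negative-binomial count model with planted
#' differentially abundant enzymes, the planted taxa-dominated enzymes,
#' and per-taxon private biosynthetic chains that give exact knockout
#' ground truth.
#'
#' @param seed RNG seed (integer).
#' @param n_compounds backbone compounds, including seeds.
#' @param n_seed_compounds planted seed (source) compounds.
#' @param n_reactions backbone reactions; must be at least
#'   `n_compounds - n_seed_compounds` so every non-seed compound is
#'   producible.
#' @param n_taxa taxa (genera) in the community.
#' @param n_ecs backbone EC pool size (chain ECs are extra).
#' @param treatments treatment labels; the first is the "treated" state
#'   whose expansion serves as the knockout reference.
#' @param n_samples replicate samples per treatment.
#' @param n_da_features planted differentially abundant ECs per
#'   treatment.
#' @param fold_change abundance fold change of planted DA ECs in their
#'   treatment.
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mean + dispersion * mean^2).
#' @param base_mean baseline mean reads per EC per sample.
#' @param n_knockout_taxa taxa given a private chain (and hence planted
#'   dominated enzymes).
#' @param chain_length compounds per private chain.
#' @param dominant_fraction read fraction of the dominant taxon for
#'   planted dominated ECs (must exceed 0.5).
#' @param dirichlet_alpha symmetric Dirichlet concentration for
#'   non-dominated EC taxon profiles (values well above 1 keep the
#'   expected Simpson index near 1/n_taxa, below the dominance
#'   threshold).
#' @param plant_cycle also plant a reversible two-compound cycle as an
#'   additional source component.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(seed = 1,
                       n_compounds = 80,
                       n_seed_compounds = 6,
                       n_reactions = 95,
                       n_taxa = 8,
                       n_ecs = 60,
                       treatments = c("SM", "NTC"),
                       n_samples = 5,
                       n_da_features = 12,
                       fold_change = 8,
                       nb_dispersion = 0.1,
                       base_mean = 200,
                       n_knockout_taxa = 3,
                       chain_length = 4,
                       dominant_fraction = 0.9,
                       dirichlet_alpha = 5,
                       plant_cycle = FALSE) {
  spec <- as.list(environment())
  if (spec$n_reactions < spec$n_compounds - spec$n_seed_compounds) {
    stop("infeasible spec: need n_reactions >= n_compounds - ",
         "n_seed_compounds so that every non-seed compound has a ",
         "producing reaction", call. = FALSE)
  }
  if (spec$dominant_fraction <= 0.5 || spec$dominant_fraction > 1) {
    stop("dominant_fraction must be in (0.5, 1]", call. = FALSE)
  }
  if (length(spec$treatments) < 2L) {
    stop("need at least two treatments", call. = FALSE)
  }
  class(spec) <- "synth_spec"
  spec
}

synth_taxa <- function(spec) {
  sprintf("g__Taxon%02d", seq_len(spec$n_taxa))
}

synth_orders <- function(spec) {
  sprintf("o__Order%02d", ceiling(seq_len(spec$n_taxa) / 2))
}

rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha, rate = 1)
  x / sum(x)
}

#' Generate a layered synthetic reaction universe with planted structure
#'
#' Builds a layered DAG universe: the planted seed compounds form layer
#' zero and have no producing reaction; every other backbone compound is
#' the product of at least one reaction whose substrates come strictly
#' earlier, so the full-graph source components are exactly the planted
#' seeds (plus the optional planted cycle). Each treatment is assigned a
#' subset of the seeds (a private block plus a shared block), and the
#' reactions consuming a treatment's seeds carry that treatment's planted
#' differentially abundant ECs — emulating amendment-derived resources
#' being consumed by amendment-enriched functions, and guaranteeing that
#' the DA sub-network contains the seed-consuming reactions. Each
#' knockout taxon gets a terminal private chain of compounds reachable
#' only through its own dedicated (to-be-dominated) ECs, assigned to a
#' synthetic pathway.
#'
#' @param spec a [synth_spec].
#' @return List with `universe` (a [reaction_universe]) and `truth`:
#'   `seeds`, `seeds_by_treatment`, `da_ecs` (treatment -> ECs),
#'   `dominated_ecs` (taxon -> ECs), `chains` (taxon -> compounds),
#'   `chain_pathways` (taxon -> pathway id).
#' @export
generate_universe <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  n <- spec$n_compounds
  ns <- spec$n_seed_compounds
  compounds <- sprintf("C%05d", seq_len(n))
  seeds <- compounds[seq_len(ns)]

  # seed blocks: each treatment gets a private block plus the shared tail
  ntr <- length(spec$treatments)
  n_private <- max(1L, floor(ns / (ntr + 1)))
  seeds_by_treatment <- list()
  shared <- seeds[(ntr * n_private + 1):ns]
  for (i in seq_len(ntr)) {
    priv <- seeds[((i - 1) * n_private + 1):(i * n_private)]
    seeds_by_treatment[[spec$treatments[i]]] <- sort(c(priv, shared))
  }

  ec_pool <- sprintf("%d.%d.%d.%d",
                     sample(1:6, spec$n_ecs, replace = TRUE),
                     sample(1:20, spec$n_ecs, replace = TRUE),
                     sample(1:20, spec$n_ecs, replace = TRUE),
                     seq_len(spec$n_ecs))
  if (spec$n_da_features * length(spec$treatments) >= spec$n_ecs) {
    stop("infeasible spec: n_ecs must exceed n_da_features * n_treatments",
         call. = FALSE)
  }
  da_ecs <- list()
  used <- 0L
  for (t in spec$treatments) {
    da_ecs[[t]] <- ec_pool[(used + 1):(used + spec$n_da_features)]
    used <- used + spec$n_da_features
  }
  other_ecs <- ec_pool[(used + 1):spec$n_ecs]

  rid <- function(i) sprintf("R%05d", i)
  reactions <- list()
  k <- 0L

  # seed-consuming single-substrate reactions, one per (treatment, seed),
  # carrying that treatment's DA ECs
  for (t in spec$treatments) {
    ecs_t <- da_ecs[[t]]
    sds <- seeds_by_treatment[[t]]
    for (j in seq_along(sds)) {
      k <- k + 1L
      target <- compounds[ns + ((k - 1L) %% (2L * ns)) + 1L]
      reactions[[k]] <- list(reaction_id = rid(k),
                             ecs = ecs_t[((j - 1L) %% length(ecs_t)) + 1L],
                             substrates = sds[j],
                             products = target,
                             reversible = FALSE)
    }
  }
  # remaining DA ECs also consume their treatment's seeds so every
  # planted DA EC sits in the sub-network
  for (t in spec$treatments) {
    ecs_t <- da_ecs[[t]]
    sds <- seeds_by_treatment[[t]]
    extra <- setdiff(ecs_t, unlist(lapply(reactions, `[[`, "ecs")))
    for (e in extra) {
      k <- k + 1L
      reactions[[k]] <- list(reaction_id = rid(k),
                             ecs = e,
                             substrates = sds[sample.int(length(sds), 1L)],
                             products = compounds[ns + sample.int(2L * ns, 1L)],
                             reversible = FALSE)
    }
  }

  # producing reaction for every non-seed compound not yet produced
  produced <- unique(unlist(lapply(reactions, `[[`, "products")))
  for (i in (ns + 1L):n) {
    if (compounds[i] %in% produced) next
    k <- k + 1L
    nsub <- sample(1:2, 1L)
    reactions[[k]] <- list(reaction_id = rid(k),
                           ecs = sample(other_ecs, 1L),
                           substrates = sample(compounds[seq_len(i - 1L)],
                                               min(nsub, i - 1L)),
                           products = compounds[i],
                           reversible = FALSE)
  }
  # extra density reactions, substrates strictly earlier than the product
  while (k < spec$n_reactions) {
    k <- k + 1L
    ti <- sample((ns + 1L):n, 1L)
    nsub <- sample(1:2, 1L)
    reactions[[k]] <- list(reaction_id = rid(k),
                           ecs = sample(other_ecs, 1L),
                           substrates = sample(compounds[seq_len(ti - 1L)],
                                               min(nsub, ti - 1L)),
                           products = compounds[ti],
                           reversible = FALSE)
  }

  # per-taxon terminal private chains fed by a treatment-1 seed
  taxa <- synth_taxa(spec)
  ko_taxa <- taxa[seq_len(spec$n_knockout_taxa)]
  t1_seeds <- seeds_by_treatment[[spec$treatments[1]]]
  chains <- list()
  dominated_ecs <- list()
  chain_pathways <- list()
  chain_compounds <- character(0)
  for (g in seq_along(ko_taxa)) {
    taxon <- ko_taxa[g]
    prev <- t1_seeds[((g - 1L) %% length(t1_seeds)) + 1L]
    chain <- sprintf("C9%02d%02d", g, seq_len(spec$chain_length))
    ecs_g <- sprintf("9.9.%d.%d", g, seq_len(spec$chain_length))
    for (j in seq_len(spec$chain_length)) {
      k <- k + 1L
      reactions[[k]] <- list(reaction_id = rid(k),
                             ecs = ecs_g[j],
                             substrates = prev,
                             products = chain[j],
                             reversible = FALSE)
      prev <- chain[j]
    }
    chains[[taxon]] <- chain
    dominated_ecs[[taxon]] <- ecs_g
    chain_pathways[[taxon]] <- sprintf("map_chain_%02d", g)
    chain_compounds <- c(chain_compounds, chain)
  }

  cycle <- character(0)
  if (spec$plant_cycle) {
    cycle <- c("C88801", "C88802")
    k <- k + 1L
    reactions[[k]] <- list(reaction_id = rid(k), ecs = "8.8.8.1",
                           substrates = cycle[1], products = cycle[2],
                           reversible = TRUE)
    k <- k + 1L
    reactions[[k]] <- list(reaction_id = rid(k), ecs = "8.8.8.2",
                           substrates = cycle[2],
                           products = compounds[ns + 1L],
                           reversible = FALSE)
  }

  rx <- data.frame(
    reaction_id = vapply(reactions, `[[`, character(1), "reaction_id"),
    reversible = vapply(reactions, `[[`, logical(1), "reversible"),
    stringsAsFactors = FALSE)
  rx$ecs <- lapply(reactions, `[[`, "ecs")
  rx$substrates <- lapply(reactions, `[[`, "substrates")
  rx$products <- lapply(reactions, `[[`, "products")

  # pathways: chain pathways plus backbone blocks
  pathway_map <- list()
  backbone <- compounds[(ns + 1L):n]
  blocks <- split(backbone, ceiling(seq_along(backbone) / 20))
  for (b in seq_along(blocks)) {
    pathway_map[[sprintf("map_backbone_%02d", b)]] <- blocks[[b]]
  }
  pathway_map[["map_seeds"]] <- seeds
  for (taxon in names(chains)) {
    pathway_map[[chain_pathways[[taxon]]]] <- chains[[taxon]]
  }

  # modules group KOs (one KO per EC, see generate_counts)
  all_ecs <- sort(unique(unlist(rx$ecs)))
  kos <- ko_for_ec(all_ecs)
  module_map <- lapply(split(kos, ceiling(seq_along(kos) / 20)), identity)
  names(module_map) <- sprintf("M%05d", seq_along(module_map))

  universe <- reaction_universe(rx, compounds = NULL,
                                pathway_map = pathway_map,
                                module_map = module_map)
  list(universe = universe,
       truth = list(seeds = sort(c(seeds, cycle)),
                    seeds_by_treatment = seeds_by_treatment,
                    cycle = cycle,
                    da_ecs = da_ecs,
                    dominated_ecs = dominated_ecs,
                    chains = chains,
                    chain_pathways = chain_pathways))
}

# deterministic KO accession for an EC
ko_for_ec <- function(ecs) {
  setNames(sprintf("K%05d", seq_along(ecs)), ecs)
}

#' Generate synthetic annotation counts with planted ground truth
#'
#' One gene (on its own contig) per EC-by-taxon pair. Per-sample EC read
#' totals are negative-binomial (variance = mean + dispersion * mean^2);
#' planted DA ECs have their mean multiplied by the fold change in their
#' treatment's samples; totals are split across taxa multinomially.
#' Non-dominated ECs draw one symmetric-Dirichlet taxon profile shared by
#' all samples; planted dominated ECs give the designated taxon the
#' specified read fraction in the first treatment's samples only.
#'
#' @param spec a [synth_spec].
#' @param gen output of [generate_universe()] for the same spec.
#' @return List with `annotation` (data.frame in the
#'   [read_annotation()] layout), `design` and `truth` (the universe
#'   truth plus `da_features`).
#' @export
generate_counts <- function(spec, gen) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed + 1L)
  taxa <- synth_taxa(spec)
  orders <- synth_orders(spec)
  truth <- gen$truth
  all_ecs <- sort(names(gen$universe$ec_index))
  kos <- ko_for_ec(all_ecs)

  design <- data.frame(
    sample = unlist(lapply(spec$treatments, function(t)
      sprintf("%s_%d", t, seq_len(spec$n_samples)))),
    treatment = rep(spec$treatments, each = spec$n_samples),
    replicate = rep(seq_len(spec$n_samples), times = length(spec$treatments)),
    stringsAsFactors = FALSE)

  ec_of_taxon <- setNames(rep(NA_character_, length(all_ecs)), all_ecs)
  for (taxon in names(truth$dominated_ecs)) {
    ec_of_taxon[truth$dominated_ecs[[taxon]]] <- taxon
  }
  base_profile <- lapply(all_ecs, function(e)
    setNames(rdirichlet1(rep(spec$dirichlet_alpha, spec$n_taxa)), taxa))
  names(base_profile) <- all_ecs

  dom_profile <- function(taxon) {
    p <- rep((1 - spec$dominant_fraction) / (spec$n_taxa - 1), spec$n_taxa)
    p[match(taxon, taxa)] <- spec$dominant_fraction
    setNames(p, taxa)
  }

  treated <- spec$treatments[1]
  counts <- array(0L, dim = c(length(all_ecs), spec$n_taxa, nrow(design)),
                  dimnames = list(all_ecs, taxa, design$sample))
  for (si in seq_len(nrow(design))) {
    tr <- design$treatment[si]
    for (e in all_ecs) {
      mu <- spec$base_mean
      if (tr %in% names(truth$da_ecs) && e %in% truth$da_ecs[[tr]]) {
        mu <- mu * spec$fold_change
      }
      total <- rnbinom(1, size = 1 / spec$nb_dispersion, mu = mu)
      prof <- if (!is.na(ec_of_taxon[e]) && tr == treated) {
        dom_profile(ec_of_taxon[e])
      } else {
        base_profile[[e]]
      }
      counts[e, , si] <- as.integer(rmultinom(1, total, prof))
    }
  }

  rows <- list()
  gi <- 0L
  for (e in all_ecs) {
    for (ti in seq_len(spec$n_taxa)) {
      gi <- gi + 1L
      row <- data.frame(
        gene_id = sprintf("gene%05d", gi),
        contig_id = sprintf("contig%05d", gi),
        taxonomy = sprintf("genus:%s;order:%s", taxa[ti], orders[ti]),
        ec = e,
        ko = unname(kos[e]),
        stringsAsFactors = FALSE)
      for (s in design$sample) row[[s]] <- counts[e, ti, s]
      rows[[gi]] <- row
    }
  }
  annotation <- do.call(rbind, rows)

  truth$da_features <- truth$da_ecs
  list(annotation = annotation, design = design, truth = truth)
}

#' Write a complete synthetic dataset to disk
#'
#' Emits the universe TSV directory, annotation and design tables, and
#' ground-truth tables, in the same dialects the pipeline reads, so the
#' whole chain can run from files alone.
#'
#' @param spec a [synth_spec].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the list from [generate_counts()] plus `universe`.
#' @export
synth_all <- function(spec, out_dir) {
  gen <- generate_universe(spec)
  cnt <- generate_counts(spec, gen)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  save_universe(gen$universe, file.path(out_dir, "universe"), format = "tsv")
  utils::write.table(cnt$annotation, file.path(out_dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cnt$design, file.path(out_dir, "design.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tdir <- file.path(out_dir, "truth")
  dir.create(tdir, showWarnings = FALSE)
  truth <- cnt$truth
  utils::write.table(
    data.frame(compound_id = truth$seeds),
    file.path(tdir, "seeds.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(treatment = rep(names(truth$seeds_by_treatment),
                               lengths(truth$seeds_by_treatment)),
               compound_id = unlist(truth$seeds_by_treatment,
                                    use.names = FALSE)),
    file.path(tdir, "seeds_by_treatment.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(treatment = rep(names(truth$da_features),
                               lengths(truth$da_features)),
               feature = unlist(truth$da_features, use.names = FALSE)),
    file.path(tdir, "da_features.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(taxon = rep(names(truth$dominated_ecs),
                           lengths(truth$dominated_ecs)),
               ec = unlist(truth$dominated_ecs, use.names = FALSE)),
    file.path(tdir, "dominated_ecs.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(taxon = rep(names(truth$chains), lengths(truth$chains)),
               compound_id = unlist(truth$chains, use.names = FALSE),
               pathway = rep(unlist(truth$chain_pathways),
                             lengths(truth$chains))),
    file.path(tdir, "chains.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(c(list(universe = gen$universe), cnt))
}
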
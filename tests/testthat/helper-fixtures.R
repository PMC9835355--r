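# Small hand-built fixtures shared across tests.

# Two-reaction toy: R1 (A+B -> C, EC 1.1.1.1), R2 (C -> D, EC 2.2.2.2,
# reversible when asked).
toy_universe <- function(r2_reversible = FALSE) {
  rx <- data.frame(reaction_id = c("R1", "R2"),
                   reversible = c(FALSE, r2_reversible),
                   stringsAsFactors = FALSE)
  rx$ecs <- list("1.1.1.1", "2.2.2.2")
  rx$substrates <- list(c("A", "B"), "C")
  rx$products <- list("C", "D")
  reaction_universe(rx, pathway_map = list(map1 = c("A", "C"),
                                           map2 = c("B", "D")))
}

# Linear chain A -> B -> C -> D, one EC per step.
chain_universe <- function() {
  rx <- data.frame(reaction_id = c("R1", "R2", "R3"),
                   reversible = FALSE, stringsAsFactors = FALSE)
  rx$ecs <- list("1.1.1.1", "2.2.2.2", "3.3.3.3")
  rx$substrates <- list("A", "B", "C")
  rx$products <- list("B", "C", "D")
  reaction_universe(rx)
}

write_toy_universe_tsv <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(c("reaction_id\tec_list\tsubstrates\tproducts\treversible",
               "R1\t1.1.1.1\tA;B\tC\t0",
               "R2\t2.2.2.2\tC\tD\t0"),
             file.path(dir, "reactions.tsv"))
  writeLines(c("pathway_id\tmember_id", "map1\tA", "map1\tC"),
             file.path(dir, "pathways.tsv"))
  dir
}

# Minimal annotation table: genes g1..g3 on contigs, with per-sample
# counts s1/s2.
toy_annotation <- function() {
  data.frame(
    gene_id = c("g1", "g2", "g3"),
    contig_id = c("k1", "k1", "k2"),
    taxonomy = c("genus:X;order:OX", "genus:X;order:OX", "genus:Y;order:OY"),
    ec = c("e1", "e1", "e2"),
    ko = c(NA, NA, "ko3"),
    s1 = c(2L, 3L, 5L),
    s2 = c(1L, 1L, 1L),
    stringsAsFactors = FALSE)
}

toy_design <- function() {
  data.frame(sample = c("s1", "s2"), treatment = c("T", "C"),
             replicate = c(1L, 1L), stringsAsFactors = FALSE)
}

# Count table from a plain matrix with two groups of nrep replicates.
two_group_table <- function(mat, nrep, groups = c("A", "B")) {
  colnames(mat) <- c(paste0(groups[1], "_", seq_len(nrep)),
                     paste0(groups[2], "_", seq_len(nrep)))
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("f%04d", seq_len(nrow(mat)))
  design <- data.frame(sample = colnames(mat),
                       treatment = rep(groups, each = nrep),
                       replicate = rep(seq_len(nrep), 2),
                       stringsAsFactors = FALSE)
  count_table(mat, design, "ec")
}

# Null / spiked NB count simulation used for calibration and power.
nb_sim_table <- function(seed, n = 1000, mean = 50, phi = 0.1, nrep = 5,
                         spike = integer(0), fold = 8) {
  set.seed(seed)
  mat <- matrix(rnbinom(n * 2 * nrep, size = 1 / phi, mu = mean), nrow = n)
  if (length(spike) > 0L) {
    mat[spike, seq_len(nrep)] <-
      rnbinom(length(spike) * nrep, size = 1 / phi, mu = mean * fold)
  }
  rownames(mat) <- sprintf("f%04d", seq_len(n))
  two_group_table(mat, nrep)
}
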
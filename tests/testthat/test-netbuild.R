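test_that("graph edges expand substrate-product pairs with reversibility", {
  u <- toy_universe()
  g <- build_graph(u, "1.1.1.1")
  expect_setequal(paste(g$edges$from, g$edges$to),
                  c("A C", "B C"))

  g2 <- build_graph(toy_universe(r2_reversible = TRUE))
  expect_true(all(c("C D", "D C") %in% paste(g2$edges$from, g2$edges$to)))

  # a second EC on the same reaction adds no duplicate edges
  rx <- data.frame(reaction_id = "R1", reversible = FALSE)
  rx$ecs <- list(c("1.1.1.1", "5.5.5.5"))
  rx$substrates <- list("A")
  rx$products <- list("B")
  u2 <- reaction_universe(rx)
  expect_equal(nrow(build_graph(u2, c("1.1.1.1", "5.5.5.5"))$edges), 1L)

  expect_equal(length(build_graph(u, character(0))$nodes), 0L)
})

test_that("condensation seeds: chain, cycle and empty graph", {
  u <- chain_universe()
  ss <- condensation_seeds(build_graph(u))
  expect_equal(seed_ids(ss), "A")
  expect_equal(ss$seeds$confidence, 1)
  expect_equal(ss$stage, "raw")

  # cycle A <-> B feeding C: source component {A, B}, confidence 1/2
  rx <- data.frame(reaction_id = c("R1", "R2"), reversible = c(TRUE, FALSE))
  rx$ecs <- list("1.1.1.1", "2.2.2.2")
  rx$substrates <- list("A", "B")
  rx$products <- list("B", "C")
  cyc <- reaction_universe(rx)
  ss <- condensation_seeds(build_graph(cyc))
  expect_setequal(seed_ids(ss), c("A", "B"))
  expect_equal(ss$seeds$confidence, c(0.5, 0.5))

  empty <- condensation_seeds(build_graph(toy_universe(), character(0)))
  expect_equal(nrow(empty$seeds), 0L)

  # self-loop-only node is its own source component
  rx <- data.frame(reaction_id = c("R1", "R2"), reversible = FALSE)
  rx$ecs <- list("1.1.1.1", "2.2.2.2")
  rx$substrates <- list("S", "X")
  rx$products <- list("S", "Y")
  self <- reaction_universe(rx)
  ss <- condensation_seeds(build_graph(self))
  expect_true(all(c("S", "X") %in% seed_ids(ss)))
})

test_that("seed prediction equals the reachability oracle on random digraphs", {
  set.seed(21)
  for (i in 1:30) {
    dg <- random_digraph(sample(5:30, 1), runif(1, 0.05, 0.3))
    u <- universe_from_digraph(dg)
    if (is.null(u)) next
    g <- build_graph(u)
    got <- sort(seed_ids(condensation_seeds(g)))
    want <- oracle_seeds(g$edges, g$nodes)
    expect_equal(got, want)
    # every non-seed compound is reachable from some seed
    reach <- oracle_expandable_nodes(g$edges, want)
    expect_setequal(reach, g$nodes)
  }
})

test_that("seeds are invariant to reaction insertion order", {
  set.seed(31)
  ru <- random_universe(15, 25)
  base <- seed_ids(condensation_seeds(build_graph(ru)))
  for (i in 1:5) {
    perm <- sample(nrow(ru$reactions))
    shuffled <- reaction_universe(ru$reactions[perm, ],
                                  pathway_map = ru$pathway_map)
    expect_equal(seed_ids(condensation_seeds(build_graph(shuffled))), base)
  }
})

test_that("seed intersection keeps only compounds predicted in both networks", {
  mk <- function(ids, stage = "raw") {
    comscope:::new_seed_set(
      data.frame(compound_id = ids, confidence = 1,
                 component_id = seq_along(ids), stringsAsFactors = FALSE),
      "t", stage)
  }
  out <- intersect_seeds(mk(c("A", "X")), mk(c("A", "B")))
  expect_equal(seed_ids(out), "A")
  expect_equal(out$stage, "intersected")

  same <- intersect_seeds(mk(c("A", "B")), mk(c("A", "B")))
  expect_setequal(seed_ids(same), c("A", "B"))

  expect_warning(empty <- intersect_seeds(mk("A"), mk("B")), "disjoint")
  expect_equal(nrow(empty$seeds), 0L)

  expect_error(intersect_seeds(out, mk("A")), "raw")
})

test_that("graph exports are readable back", {
  g <- build_graph(toy_universe())
  gml <- tempfile(fileext = ".graphml")
  write_graphml(g, gml)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(back), length(g$nodes))
  expect_equal(igraph::gsize(back), nrow(g$edges))

  el <- tempfile(fileext = ".tsv")
  write_edgelist(g, el)
  tb <- read.delim(el)
  expect_equal(nrow(tb), nrow(g$edges))
  expect_true(all(c("source_compound", "target_compound", "reaction_id")
                  %in% names(tb)))
})
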
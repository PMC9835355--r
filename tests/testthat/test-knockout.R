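test_that("knocking out a mid-chain enzyme loses all downstream compounds", {
  u <- chain_universe()   # A -> B -> C -> D, ECs 1/2/3
  ecs <- universe_ecs(u)
  dominated <- list(tax1 = "2.2.2.2")
  rep <- knockout_group(u, ecs, "A", dominated, "tax1")
  expect_equal(rep$removed_ecs, "2.2.2.2")
  expect_equal(rep$dependent_compounds, c("C", "D"))
  expect_equal(rep$reference_scope_size, 4L)
  expect_equal(rep$truncated_scope_size, 2L)
  expect_equal(rep$reduction_fraction, 0.5)

  # a group dominating nothing removes nothing
  rep0 <- knockout_group(u, ecs, "A", dominated, "absent_taxon")
  expect_length(rep0$dependent_compounds, 0L)
  expect_equal(rep0$reduction_fraction, 0)
})

test_that("a reaction with a surviving alternative catalyst is redundant", {
  # same conversion B -> C catalysed by two distinct ECs on two reactions
  rx <- data.frame(reaction_id = paste0("R", 1:4), reversible = FALSE)
  rx$ecs <- list("1.1.1.1", "2.2.2.2", "9.9.9.9", "3.3.3.3")
  rx$substrates <- list("A", "B", "B", "C")
  rx$products <- list("B", "C", "C", "D")
  u <- reaction_universe(rx)
  ecs <- universe_ecs(u)
  rep <- knockout_group(u, ecs, "A", list(tax1 = "2.2.2.2"), "tax1")
  expect_length(rep$dependent_compounds, 0L)

  # multi-EC reaction: removed only when all its present ECs go
  rx2 <- data.frame(reaction_id = "R1", reversible = FALSE)
  rx2$ecs <- list(c("1.1.1.1", "2.2.2.2"))
  rx2$substrates <- list("A")
  rx2$products <- list("B")
  u2 <- reaction_universe(rx2)
  partial <- knockout_group(u2, universe_ecs(u2), "A",
                            list(t = "1.1.1.1"), "t")
  expect_length(partial$dependent_compounds, 0L)
  full <- knockout_group(u2, universe_ecs(u2), "A",
                         list(t = c("1.1.1.1", "2.2.2.2")), "t")
  expect_equal(full$dependent_compounds, "B")
})

test_that("removing an enzyme that never fires changes nothing", {
  u <- toy_universe()   # R1 needs A+B; seed only A, so nothing fires
  rep <- knockout_group(u, universe_ecs(u), "A",
                        list(t = "2.2.2.2"), "t")
  expect_length(rep$dependent_compounds, 0L)
  expect_equal(rep$reference_scope_size, 1L)
})

test_that("combined removal dominates per-group removals", {
  # two independent branches from A, dominated by different taxa
  rx <- data.frame(reaction_id = paste0("R", 1:4), reversible = FALSE)
  rx$ecs <- list("1.1.1.1", "2.2.2.2", "3.3.3.3", "4.4.4.4")
  rx$substrates <- list("A", "P1", "A", "Q1")
  rx$products <- list("P1", "P2", "Q1", "Q2")
  u <- reaction_universe(rx)
  dominated <- list(taxP = c("1.1.1.1"), taxQ = c("3.3.3.3"))
  out <- knockout_all(u, universe_ecs(u), "A", dominated)
  expect_setequal(out$reports$taxP$dependent_compounds, c("P1", "P2"))
  expect_setequal(out$reports$taxQ$dependent_compounds, c("Q1", "Q2"))
  for (g in names(dominated)) {
    expect_true(all(out$reports[[g]]$dependent_compounds %in%
                      out$combined$dependent_compounds))
    # truncated scope is always inside the reference scope
    expect_lte(out$reports[[g]]$truncated_scope_size,
               out$reports[[g]]$reference_scope_size)
  }
  expect_equal(out$combined$taxon, "_all_")
  expect_setequal(out$combined$dependent_compounds,
                  c("P1", "P2", "Q1", "Q2"))
  expect_equal(nrow(out$summary), 3L)
  expect_setequal(unique(out$dependent$taxon), c("taxP", "taxQ", "_all_"))

  # single group: combined equals the group's report
  solo <- knockout_all(u, universe_ecs(u), "A", dominated["taxP"])
  expect_equal(solo$combined$dependent_compounds,
               solo$reports$taxP$dependent_compounds)
})

test_that("anti-monotonicity holds on random universes", {
  set.seed(53)
  for (i in 1:10) {
    ru <- random_universe(12, 30)
    ecs <- universe_ecs(ru)
    seeds <- sample(universe_compounds(ru), 3)
    dom <- list(g = sample(ecs, 3))
    rep <- knockout_group(ru, ecs, seeds, dom, "g")
    ref <- expand_scope(ru, ecs, seeds)
    expect_true(all(setdiff(ref$scope, rep$dependent_compounds) %in%
                      ref$scope))
    expect_equal(rep$truncated_scope_size + length(rep$dependent_compounds),
                 rep$reference_scope_size)
  }
})
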
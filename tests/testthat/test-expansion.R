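test_that("expansion obeys the all-substrates rule on hand-built universes", {
  u <- toy_universe()
  # no enzymes: scope is the seed set
  res <- expand_scope(u, character(0), c("A", "B"))
  expect_equal(res$scope, c("A", "B"))
  expect_length(res$fired, 0L)

  # B missing: R1 infeasible
  res <- expand_scope(u, seeds = "A")
  expect_equal(res$scope, "A")

  # full chain fires in two iterations
  res <- expand_scope(u, seeds = c("A", "B"))
  expect_setequal(res$scope, c("A", "B", "C", "D"))
  expect_setequal(res$fired, c("R1", "R2"))
  expect_equal(nrow(res$trace), 2L)

  # reversible reactions fire backwards
  res <- expand_scope(toy_universe(r2_reversible = TRUE), seeds = "D")
  expect_setequal(res$scope, c("C", "D"))

  expect_warning(res <- expand_scope(u, seeds = c("A", "ZZZ")), "ZZZ")
  expect_equal(res$scope, "A")
})

test_that("scope equals the naive shuffled-scan oracle on random universes", {
  set.seed(41)
  for (i in 1:20) {
    ru <- random_universe(sample(8:20, 1), sample(10:50, 1))
    ecs <- sample(universe_ecs(ru), sample(2:6, 1))
    seeds <- sample(universe_compounds(ru), sample(1:4, 1))
    res <- expand_scope(ru, ecs, seeds)
    for (s in 1:10) {
      ord <- sample(200)   # longer than any direction list; extras ignored
      got <- oracle_expand(ru, ecs, seeds,
                           order = ord[ord <= oracle_n_dirs(ru, ecs)])
      expect_equal(res$scope, got)
    }
    # fixed point: no available unfired direction is feasible
    rx <- ru$reactions[vapply(ru$reactions$ecs,
                              function(e) any(e %in% ecs), logical(1)), ]
    for (j in seq_len(nrow(rx))) {
      if (all(rx$substrates[[j]] %in% res$scope)) {
        expect_true(all(rx$products[[j]] %in% res$scope))
      }
      if (rx$reversible[j] && all(rx$products[[j]] %in% res$scope)) {
        expect_true(all(rx$substrates[[j]] %in% res$scope))
      }
    }
  }
})

test_that("expansion is monotone in seeds and enzymes, and idempotent", {
  set.seed(43)
  for (i in 1:10) {
    ru <- random_universe(12, 30)
    all_ecs <- universe_ecs(ru)
    ecs2 <- sample(all_ecs, min(6, length(all_ecs)))
    ecs1 <- sample(ecs2, 3)
    seeds2 <- sample(universe_compounds(ru), 4)
    seeds1 <- sample(seeds2, 2)

    s11 <- expand_scope(ru, ecs1, seeds1)$scope
    s12 <- expand_scope(ru, ecs1, seeds2)$scope
    s22 <- expand_scope(ru, ecs2, seeds2)$scope
    expect_true(all(s11 %in% s12))   # seed monotonicity
    expect_true(all(s12 %in% s22))   # enzyme monotonicity

    again <- expand_scope(ru, ecs2, s22)
    expect_equal(again$scope, s22)   # idempotence
  }
})

test_that("scope is invariant to reaction scan order", {
  set.seed(47)
  ru <- random_universe(15, 40)
  ecs <- universe_ecs(ru)
  seeds <- sample(universe_compounds(ru), 3)
  base <- expand_scope(ru, ecs, seeds)
  for (i in 1:5) {
    perm <- sample(nrow(ru$reactions))
    shuffled <- reaction_universe(ru$reactions[perm, ])
    res <- expand_scope(shuffled, ecs, seeds)
    expect_equal(res$scope, base$scope)
    expect_equal(res$fired, base$fired)
  }
})

test_that("scope differences partition the union into three disjoint sets", {
  u <- chain_universe()
  a <- expand_scope(u, seeds = "A")
  same <- diff_scopes(a, a)
  expect_length(same$unique_to_a, 0L)
  expect_length(same$unique_to_b, 0L)

  b <- expand_scope(u, character(0), "D")
  d <- diff_scopes(a, b)
  expect_setequal(d$unique_to_a, c("A", "B", "C"))
  expect_equal(d$shared, "D")
  expect_length(intersect(d$unique_to_a, d$shared), 0L)

  # one extra seed feeding a private chain of 3 compounds
  rx <- data.frame(reaction_id = paste0("R", 1:4), reversible = FALSE)
  rx$ecs <- list("1.1.1.1", "2.2.2.2", "3.3.3.3", "4.4.4.4")
  rx$substrates <- list("A", "P0", "P1", "P2")
  rx$products <- list("B", "P1", "P2", "P3")
  u2 <- reaction_universe(rx)
  ra <- expand_scope(u2, seeds = c("A", "P0"))
  rb <- expand_scope(u2, seeds = "A")
  d <- diff_scopes(ra, rb)
  expect_setequal(d$unique_to_a, c("P0", "P1", "P2", "P3"))
})

test_that("scope TSV export records iteration of first appearance", {
  u <- chain_universe()
  res <- expand_scope(u, seeds = "A")
  tf <- tempfile(fileext = ".tsv")
  write_scope(res, tf)
  tb <- read.delim(tf, stringsAsFactors = FALSE)
  expect_equal(tb$iteration_added[match(c("A", "B", "C", "D"),
                                        tb$compound_id)],
               c(0L, 1L, 2L, 3L))
})
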
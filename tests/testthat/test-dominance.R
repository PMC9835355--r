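test_that("Simpson dominance index matches closed forms and is scale-free", {
  expect_equal(simpson_index(c(A = 10)), 1.0)
  expect_equal(simpson_index(c(A = 50, B = 50)), 0.5)
  expect_equal(simpson_index(c(A = 70, B = 20, C = 10)), 0.54)
  expect_error(simpson_index(c(0, 0)), "zero total")

  set.seed(13)
  for (i in 1:20) {
    x <- runif(sample(2:6, 1), 1, 100)
    s <- simpson_index(x)
    expect_gt(s, 0)
    expect_lte(s, 1)
    expect_equal(simpson_index(x * 7.3), s)
    # concentrating mass (move from a smaller to the largest entry)
    j <- which.max(x)
    k <- which.min(x)
    y <- x
    delta <- x[k] / 2
    y[j] <- y[j] + delta
    y[k] <- y[k] - delta
    expect_gte(simpson_index(y), s)
  }
})

test_that("dominance calls require both the index threshold and replicate agreement", {
  # 5 replicates each {A: 9, B: 1}: mean D = 0.82, dominant A everywhere
  reps <- replicate(5, c(A = 9, B = 1), simplify = FALSE)
  rec <- call_dominance(reps)
  expect_equal(rec$mean_simpson, 0.82)
  expect_true(rec$is_dominated)
  expect_equal(rec$dominant_taxon, "A")

  # alternating dominants: index high enough but condition (ii) fails
  alt <- list(c(A = 8, B = 2), c(A = 2, B = 8), c(A = 8, B = 2),
              c(A = 2, B = 8))
  rec <- call_dominance(alt)
  expect_gt(rec$mean_simpson, 0.4)
  expect_false(rec$is_dominated)
  expect_true(is.na(rec$dominant_taxon))

  # uniform over 10 taxa: mean D = 0.1 < 0.4
  unif <- replicate(3, setNames(rep(5, 10), paste0("t", 1:10)),
                    simplify = FALSE)
  rec <- call_dominance(unif)
  expect_equal(rec$mean_simpson, 0.1)
  expect_false(rec$is_dominated)

  # zero-total replicates are excluded, not fatal
  rec <- call_dominance(list(c(A = 9, B = 1), c(A = 0, B = 0)))
  expect_equal(rec$n_replicates, 1L)
  expect_equal(rec$n_excluded, 1L)
  expect_true(rec$is_dominated)

  rec <- call_dominance(list(c(A = 0), c(A = 0)))
  expect_false(rec$is_dominated)
  expect_true(is.na(rec$mean_simpson))

  # argmax ties break lexicographically regardless of name order
  tie1 <- call_dominance(list(c(B = 5, A = 5), c(A = 5, B = 5)),
                         threshold = 0.4)
  expect_equal(unique(tie1$replicate_dominants), "A")
})

test_that("dominated enzyme sets invert records with one taxon per EC", {
  records <- data.frame(
    ec = c("e1", "e2", "e3", "e4"),
    treatment = c("SM", "SM", "SM", "NTC"),
    rank = "genus",
    mean_simpson = c(0.8, 0.7, 0.9, 0.8),
    dominant_taxon = c("A", "A", "B", "A"),
    is_dominated = c(TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  sets <- dominated_enzyme_sets(records, "SM")
  expect_equal(sets, list(A = c("e1", "e2"), B = "e3"))
  expect_length(dominated_enzyme_sets(records[0, ], "SM"), 0L)
  # disjointness: no EC appears under two taxa
  expect_equal(anyDuplicated(unlist(sets)), 0L)
})

test_that("dominance_table is treatment-specific on a constructed dataset", {
  design <- data.frame(sample = c("a1", "a2", "b1", "b2"),
                       treatment = c("T", "T", "C", "C"),
                       replicate = c(1, 2, 1, 2), stringsAsFactors = FALSE)
  ectax <- rbind(
    data.frame(ec = "e1", taxon = "X", sample = c("a1", "a2"), count = 90L),
    data.frame(ec = "e1", taxon = "Y", sample = c("a1", "a2"), count = 10L),
    data.frame(ec = "e1", taxon = "X", sample = c("b1", "b2"),
               count = c(60L, 40L)),
    data.frame(ec = "e1", taxon = "Y", sample = c("b1", "b2"),
               count = c(40L, 60L)))
  tab <- dominance_table(ectax, design, rank = "genus")
  t_row <- tab[tab$treatment == "T", ]
  c_row <- tab[tab$treatment == "C", ]
  expect_true(t_row$is_dominated)
  expect_equal(t_row$dominant_taxon, "X")
  expect_equal(t_row$mean_simpson, 0.82)
  # replicate dominants disagree (X then Y), so condition (ii) fails even
  # though the mean index (0.52) clears the threshold
  expect_false(c_row$is_dominated)
  expect_equal(c_row$mean_simpson, 0.52)
})
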
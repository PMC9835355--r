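test_that("hypergeometric enrichment matches hand-derived probabilities", {
  universe <- paste0("c", 1:10)
  term_map <- list(T1 = paste0("c", 1:5), T2 = paste0("c", 6:10))
  res <- enrich_terms(paste0("c", 1:5), universe, term_map)
  # all 5 selected inside a 5-member term of a 10-member universe
  expect_equal(res$p_value[res$term == "T1"], 1 / 252, tolerance = 1e-12)
  # T2 has k = 0 and is excluded
  expect_false("T2" %in% res$term)

  # selected = universe: every overlap is certain, p = 1
  res <- enrich_terms(universe, universe, term_map)
  expect_equal(res$p_value, c(1, 1))
  expect_equal(res$k, res$K)

  expect_error(enrich_terms(character(0), universe, term_map), "selected")
  expect_error(enrich_terms("c1", character(0), term_map), "universe")
  expect_warning(enrich_terms(c("c1", "zz"), universe, term_map), "outside")
})

test_that("p-values agree with the exact combinatorial oracle for N <= 30", {
  set.seed(61)
  for (i in 1:50) {
    N <- sample(5:30, 1)
    universe <- paste0("x", seq_len(N))
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    members <- sample(universe, K)
    selected <- sample(universe, n)
    k <- length(intersect(members, selected))
    if (k == 0L) next
    res <- enrich_terms(selected, universe, list(T = members))
    expect_equal(res$p_value, oracle_hyper_p(k, K, n, N), tolerance = 1e-12)
  }
})

test_that("adding a term member to the selection cannot raise the term p", {
  set.seed(67)
  universe <- paste0("x", 1:40)
  members <- paste0("x", 1:12)
  selected <- sample(universe, 10)
  p0 <- enrich_terms(union(selected, "x1"), universe,
                     list(T = members))$p_value
  p1 <- enrich_terms(union(union(selected, "x1"), "x2"), universe,
                     list(T = members))$p_value
  expect_lte(p1, p0)
})

test_that("BH adjustment reproduces the standard rejection set", {
  set.seed(71)
  universe <- paste0("x", 1:60)
  term_map <- lapply(1:12, function(i) sample(universe, sample(5:15, 1)))
  names(term_map) <- paste0("T", 1:12)
  selected <- sample(universe, 15)
  res <- enrich_terms(selected, universe, term_map, alpha = 0.25)
  expect_equal(res$q_value, p.adjust(res$p_value, "BH"))
  want <- oracle_bh_reject(res$p_value, 0.25)
  expect_equal(which(res$significant), want)
  # q is a monotone step function of the p rank
  o <- order(res$p_value)
  expect_true(all(diff(res$q_value[o]) >= -1e-12))
})

test_that("treatment-dominance filter applies both entity rules", {
  results <- data.frame(term = c("T1", "T2", "T3"),
                        k = 3L, K = 5L, n = 6L, N = 20L,
                        p_value = c(0.01, 0.02, 0.03),
                        q_value = c(0.03, 0.03, 0.03),
                        significant = TRUE, stringsAsFactors = FALSE)
  counts <- rbind(
    data.frame(term = "T1", treatment = c("SM", "NTC"), n_entities = c(9L, 1L)),
    data.frame(term = "T2", treatment = c("SM", "NTC"), n_entities = c(3L, 2L)),
    data.frame(term = "T3", treatment = c("SM", "NTC"), n_entities = c(3L, 3L)))
  out <- dominance_filtered_terms(results, counts)
  # T1: 10 entities, 90% SM -> kept; T2: only 5 entities -> dropped;
  # T3: 6 entities split evenly -> dropped
  expect_equal(out$term, "T1")
  expect_equal(out$dominant_treatment, "SM")
  expect_equal(out$dominance_fraction, 0.9)

  # boundary: exactly 6 entities at exactly 85%
  counts2 <- data.frame(term = "T1", treatment = c("SM", "NTC"),
                        n_entities = c(17L, 3L))
  out2 <- dominance_filtered_terms(results[1, ], counts2)
  expect_equal(out2$dominance_fraction, 0.85)
  expect_equal(nrow(out2), 1L)
})
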
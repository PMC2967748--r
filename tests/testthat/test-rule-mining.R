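test_that("inverted index posts every item with its exact report set", {
  idx <- build_inverted_index(tc4_corpus())
  expect_equal(idx$n_reports, 4)
  expect_equal(idx$postings[["D:D1"]], c(1L, 2L, 3L))
  expect_equal(idx$postings[["E:E1"]], c(1L, 2L, 4L))
  expect_null(idx$postings[["D:ABSENT"]])

  one <- build_inverted_index(srs_corpus("R1", list("A"), list("X")))
  expect_equal(lengths(one$postings), c("D:A" = 1L, "E:X" = 1L))
})

test_that("itemset support equals posting intersection and full scan", {
  idx <- build_inverted_index(tc4_corpus())
  expect_equal(itemset_support(c("D:D1", "E:E1"), idx), 2L)
  expect_equal(itemset_support("D:D2", idx), 3L)
  expect_equal(itemset_support(c("D:D1", "D:UNKNOWN"), idx), 0L)
})

test_that("index-based support matches a full scan on random itemsets", {
  corpus <- random_small_corpus(21, n_reports = 150)
  idx <- build_inverted_index(corpus)
  txns <- Map(function(d, e) c(paste0("D:", d), paste0("E:", e)),
              corpus$reports$drugs, corpus$reports$events)
  universe <- unique(unlist(txns))
  set.seed(22)
  for (i in 1:200) {
    items <- sample(universe, sample(1:4, 1))
    scan <- sum(vapply(txns, function(t) all(items %in% t), logical(1)))
    expect_identical(itemset_support(items, idx), as.integer(scan))
  }
})

test_that("TC4 yields exactly the seven frequent itemsets at support 2", {
  fi <- apriori_frequent_itemsets(tc4_corpus(), min_support = 2)
  expect_equal(nrow(fi), 7)
  got <- setNames(fi$support, itemset_keys(fi))
  expect_equal(got, c("D:D1" = 3L, "D:D2" = 3L, "E:E1" = 3L,
                      "D:D1,D:D2" = 2L, "D:D1,E:E1" = 2L, "D:D2,E:E1" = 3L,
                      "D:D1,D:D2,E:E1" = 2L))
  expect_false("E:E2" %in% itemset_keys(fi))
})

test_that("degenerate mining parameters behave as specified", {
  expect_equal(nrow(apriori_frequent_itemsets(tc4_corpus(), 5)), 0)
  fi1 <- apriori_frequent_itemsets(tc4_corpus(), 1, max_size = 1)
  expect_equal(nrow(fi1), 4)  # one per distinct item
  expect_equal(sum(fi1$size), 4)
  expect_error(apriori_frequent_itemsets(tc4_corpus(), 0), "min_support")
})

test_that("level-wise miner agrees exactly with the brute-force oracle", {
  for (seed in 1:12) {
    corpus <- random_small_corpus(seed, n_reports = 120)
    ms <- sample(2:10, 1)
    ap <- apriori_frequent_itemsets(corpus, ms, max_size = 4)
    bf <- brute_force_mine(corpus, ms, max_size = 4)
    expect_identical(itemset_keys(ap), itemset_keys(bf))
    expect_identical(ap$support, bf$support)
  }
})

test_that("anti-monotonicity holds for every mined itemset", {
  corpus <- random_small_corpus(31, n_reports = 200)
  fi <- apriori_frequent_itemsets(corpus, 3, max_size = 4)
  supp <- setNames(fi$support, itemset_keys(fi))
  idx <- build_inverted_index(corpus)
  for (i in which(fi$size > 1)) {
    items <- fi$items[[i]]
    for (d in seq_along(items)) {
      sub_supp <- itemset_support(items[-d], idx)
      expect_gte(sub_supp, fi$support[i])
    }
  }
})

test_that("rule emission is one constrained rule per mixed itemset", {
  fi <- apriori_frequent_itemsets(tc4_corpus(), 2)
  rules <- emit_candidate_rules(fi)
  expect_equal(nrow(rules), 3)
  expect_setequal(rule_keys(rules),
                  c("D1 -> E1", "D2 -> E1", "D1,D2 -> E1"))
  # constraint soundness: all-drug antecedent, all-event consequent
  expect_true(all(lengths(rules$antecedent) >= 1))
  expect_true(all(lengths(rules$consequent) >= 1))
  # {D1,D2,E1} emits only {D1,D2} -> {E1}, never D1 -> {D2,E1}
  expect_false(any(grepl("D2", vapply(rules$consequent, paste,
                                      character(1), collapse = ","))))
})

test_that("drug-only tables emit nothing; broken closure is an error", {
  drugs_only <- srs_corpus(
    report_id = c("R1", "R2"),
    drugs = list(c("A", "B"), c("A", "B")),
    events = list(character(), character())
  )
  fi <- apriori_frequent_itemsets(drugs_only, 2)
  expect_equal(nrow(emit_candidate_rules(fi)), 0)

  fi_mixed <- apriori_frequent_itemsets(tc4_corpus(), 2)
  broken <- fi_mixed[fi_mixed$size != 1 | !grepl("^E:", itemset_keys(fi_mixed)), ]
  attr(broken, "n_reports") <- attr(fi_mixed, "n_reports")
  class(broken) <- class(fi_mixed)
  expect_error(emit_candidate_rules(broken), "not downward closed")
})

test_that("brute force refuses oversized universes and handles empty input", {
  big <- srs_corpus("R1", list(paste0("D", 1:30)), list("E1"))
  expect_error(brute_force_mine(big, 1), "too large")
  empty <- srs_corpus(character(), list(), list())
  expect_equal(nrow(brute_force_mine(empty, 1)), 0)
  # one report, three items: all 2^3 - 1 subsets at min_support 1
  tri <- srs_corpus("R1", list(c("A", "B")), list("X"))
  expect_equal(nrow(brute_force_mine(tri, 1)), 7)
})

test_that("mining output is deterministic across repeated runs", {
  corpus <- random_small_corpus(77, n_reports = 150)
  a <- apriori_frequent_itemsets(corpus, 4)
  b <- apriori_frequent_itemsets(corpus, 4)
  expect_identical(a, b)
  ra <- rank_rules(emit_candidate_rules(a))
  rb <- rank_rules(emit_candidate_rules(b))
  expect_identical(ra, rb)
})
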
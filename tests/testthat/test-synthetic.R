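test_that("generation is deterministic under the spec seed", {
  spec <- synthetic_spec(n_reports = 400, n_drugs = 40, n_events = 40, seed = 9)
  g1 <- generate_corpus(spec)
  g2 <- generate_corpus(spec)
  expect_identical(g1$corpus$reports, g2$corpus$reports)
  g3 <- generate_corpus(synthetic_spec(n_reports = 400, n_drugs = 40,
                                       n_events = 40, seed = 10))
  expect_false(identical(g1$corpus$reports, g3$corpus$reports))
})

test_that("corpus-level statistics hit the generator's targets", {
  gen <- generate_corpus(synthetic_spec(n_reports = 5000, seed = 3))
  s <- corpus_stats(gen$corpus)
  expect_equal(s$mean_drugs_per_report, 3.3, tolerance = 0.05)
  expect_equal(s$mean_events_per_report, 3.4, tolerance = 0.05)
  expect_equal(s$median_events, 2)
  expect_equal(s$frac_multi_drug, 1.0)  # multi-drug corpus by construction
  expect_gt(s$frac_multi_event, 0.6)
})

test_that("planted case reports guarantee the joint support floor", {
  spec <- synthetic_spec(
    n_reports = 2000, n_drugs = 60, n_events = 60,
    planted = list(planted_rule(c("D030", "D040"), "E035", 100L, 1.0)),
    seed = 4)
  gen <- generate_corpus(spec)
  expect_gte(gen$ground_truth$support_joint, 100)
})

test_that("ground truth equals an independent index-based recomputation", {
  spec <- planted_validation_spec(seed = 5, n_reports = 3000)
  gen <- generate_corpus(spec)
  idx <- build_inverted_index(gen$corpus)
  for (i in seq_len(nrow(gen$ground_truth))) {
    a <- paste0("D:", gen$ground_truth$drug_set[[i]])
    b <- paste0("E:", gen$ground_truth$event_set[[i]])
    expect_identical(gen$ground_truth$support_joint[i],
                     itemset_support(c(a, b), idx))
    expect_identical(gen$ground_truth$support_ante[i], itemset_support(a, idx))
    expect_identical(gen$ground_truth$support_cons[i], itemset_support(b, idx))
  }
})

test_that("infeasible specs are rejected", {
  expect_error(synthetic_spec(
    n_drugs = 2, n_events = 2,
    planted = list(planted_rule(c("D1", "D2", "D3"), "E1", 10L))),
    "larger than vocabulary")
  expect_error(synthetic_spec(n_reports = 5,
    planted = list(planted_rule("D001", "E001", 10L))),
    "exceed n_reports")
  expect_error(synthetic_spec(duplication_rate = 1), "duplication_rate")
})

test_that("duplication appends the requested count and inflates RR", {
  corpus <- generate_corpus(synthetic_spec(n_reports = 300, n_drugs = 30,
                                           n_events = 30, seed = 6))$corpus
  expect_identical(inject_duplicates(corpus, 0), corpus)
  dup <- inject_duplicates(corpus, 0.25, seed = 7)
  expect_equal(n_reports(dup), 300 + 75)
  expect_equal(anyDuplicated(dup$reports$report_id), 0)
  expect_identical(inject_duplicates(corpus, 0.25, seed = 7)$reports,
                   dup$reports)

  # duplicating exactly the k reports carrying a rare combination doubles
  # its joint support and strictly raises RR when k < min(S(A), S(B))
  n <- 20
  drugs <- c(rep(list("A"), 6), rep(list("Z"), 14))
  events <- c(rep(list("X"), 2), rep(list("Y"), 4),
              rep(list("X"), 3), rep(list("Y"), 11))
  base <- srs_corpus(paste0("R", 1:n), drugs, events)
  idx <- build_inverted_index(base)
  s_ab <- itemset_support(c("D:A", "E:X"), idx)
  s_a <- itemset_support("D:A", idx)
  s_b <- itemset_support("E:X", idx)
  expect_true(s_ab < min(s_a, s_b))
  rr_before <- relative_reporting_ratio(s_ab, s_a, s_b, n)
  doubled <- srs_corpus(
    c(base$reports$report_id, paste0("DUP", 1:s_ab)),
    c(base$reports$drugs, rep(list("A"), s_ab)),
    c(base$reports$events, rep(list("X"), s_ab))
  )
  idx2 <- build_inverted_index(doubled)
  rr_after <- relative_reporting_ratio(
    itemset_support(c("D:A", "E:X"), idx2),
    itemset_support("D:A", idx2), itemset_support("E:X", idx2), n + s_ab)
  expect_equal(itemset_support(c("D:A", "E:X"), idx2), 2L * s_ab)
  expect_gt(rr_after, rr_before)
})

test_that("closed-form expectations size planted rules correctly", {
  mk <- function(pen, n_rep = 20000L) synthetic_spec(
    n_reports = n_rep,
    planted = list(planted_rule(c("D200", "D210"), "E200", 100L, pen)),
    seed = 1)
  e1 <- expected_rule_stats(mk(1.0))
  expect_equal(e1$exp_support_joint, 100, tolerance = 0.01)
  e2 <- expected_rule_stats(mk(0.5))
  expect_gte(e2$exp_support_joint, 50)
  # expected RR rises with N for fixed case counts
  expect_gt(expected_rule_stats(mk(1.0, 40000L))$exp_rr, e1$exp_rr)

  # the reference validation spec clears the screening thresholds by design
  ref <- expected_rule_stats(planted_validation_spec(seed = 1))
  expect_true(all(ref$exp_support_joint >= 100))
  expect_true(all(ref$exp_rr >= 5))
})
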
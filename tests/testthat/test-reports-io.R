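test_that("transactions reader collapses items to sets and uppercases", {
  path <- tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"report_id":"R1","drugs":["aspirin","ASPIRIN"],"events":["NAUSEA"]}',
    '{"report_id":"R2","drugs":["warfarin"],"events":["bleeding"],"outcomes":["HO"]}'
  ), path)
  corpus <- read_transactions(path)
  expect_equal(n_reports(corpus), 2)
  expect_equal(corpus$reports$drugs[[1]], "ASPIRIN")
  expect_equal(corpus$reports$events[[2]], "BLEEDING")
  expect_equal(corpus$reports$outcomes[[2]], "HO")
})

test_that("empty input yields an empty corpus and malformed records are skipped", {
  empty <- tempfile(fileext = ".jsonl")
  file.create(empty)
  expect_equal(n_reports(read_transactions(empty)), 0)

  path <- tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"report_id":"R1","drugs":["A"],"events":["X"]}',
    'not json at all',
    '{"drugs":["B"],"events":["Y"]}'
  ), path)
  expect_warning(corpus <- read_transactions(path), "skipped 2 malformed")
  expect_equal(n_reports(corpus), 1)
  expect_equal(attr(corpus, "n_skipped"), 2L)
})

test_that("duplicate report ids keep the first occurrence with a warning", {
  path <- tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"report_id":"R1","drugs":["A"],"events":["X"]}',
    '{"report_id":"R1","drugs":["B"],"events":["Y"]}'
  ), path)
  expect_warning(corpus <- read_transactions(path), "duplicate report id")
  expect_equal(n_reports(corpus), 1)
  expect_equal(corpus$reports$drugs[[1]], "A")
})

test_that("transactions round-trip in both dialects", {
  corpus <- srs_corpus(
    report_id = c("R1", "R2"),
    drugs = list(c("ASPIRIN", "WARFARIN"), "METFORMIN"),
    events = list("BLEEDING", c("NAUSEA", "HEADACHE")),
    outcomes = list("HO", c("DE", "LT")),
    roles = list(c(ASPIRIN = "PS", WARFARIN = "C"), c(METFORMIN = "PS")),
    period = c("2008Q1", NA)
  )
  for (ext in c(".jsonl", ".tsv")) {
    path <- tempfile(fileext = ext)
    write_transactions(corpus, path)
    back <- read_transactions(path)
    expect_equal(back$reports$report_id, corpus$reports$report_id)
    expect_equal(back$reports$drugs, corpus$reports$drugs)
    expect_equal(back$reports$events, corpus$reports$events)
    expect_equal(back$reports$outcomes, corpus$reports$outcomes)
    expect_equal(back$reports$roles, corpus$reports$roles)
  }
})

write_aers_fixture <- function(dir = tempfile()) {
  dir.create(dir)
  writeLines(c("isr$age$sex", "100$61$F", "101$45$M"),
             file.path(dir, "DEMO.TXT"))
  writeLines(c("isr$drugname$role",
               "100$AVANDIA$PS", "100$METFORMIN$C", "999$GHOST$PS"),
             file.path(dir, "DRUG.TXT"))
  writeLines(c("isr$pt", "100$NAUSEA", "999$PHANTOM PAIN"),
             file.path(dir, "REAC.TXT"))
  writeLines(c("isr$outc_cod", "100$HO"), file.path(dir, "OUTC.TXT"))
  dir
}

test_that("AERS-style quarter joins the four tables on the report key", {
  dir <- write_aers_fixture()
  warns <- capture_warnings(
    corpus <- read_aers_ascii_quarter(
      file.path(dir, "DEMO.TXT"), file.path(dir, "DRUG.TXT"),
      file.path(dir, "REAC.TXT"), file.path(dir, "OUTC.TXT")))
  expect_length(warns, 2)  # one orphan DRUG row, one orphan REAC row
  expect_match(warns, "absent from DEMO", all = TRUE)
  expect_equal(n_reports(corpus), 2)
  r100 <- corpus$reports[corpus$reports$report_id == "100", ]
  expect_equal(r100$drugs[[1]], c("AVANDIA", "METFORMIN"))
  expect_equal(r100$events[[1]], "NAUSEA")
  expect_equal(r100$outcomes[[1]], "HO")
  expect_equal(r100$roles[[1]][["AVANDIA"]], "PS")
  # DEMO key with no REAC rows yields an empty event set
  r101 <- corpus$reports[corpus$reports$report_id == "101", ]
  expect_length(r101$events[[1]], 0)
})

test_that("AERS reader errors hard on missing header or short rows", {
  dir <- write_aers_fixture()
  bad <- file.path(dir, "BAD.TXT")
  writeLines(c("isr$pt", "100"), bad)  # one column where two are required
  expect_error(
    suppressWarnings(read_aers_ascii_quarter(
      file.path(dir, "DEMO.TXT"), file.path(dir, "DRUG.TXT"),
      bad, file.path(dir, "OUTC.TXT"))),
    "line 2")
  empty <- file.path(dir, "EMPTY.TXT")
  file.create(empty)
  expect_error(
    suppressWarnings(read_aers_ascii_quarter(
      empty, file.path(dir, "DRUG.TXT"),
      file.path(dir, "REAC.TXT"), file.path(dir, "OUTC.TXT"))),
    "missing header")
})

test_that("serious-outcome filter keeps exactly the intersecting reports", {
  corpus <- srs_corpus(
    report_id = c("R1", "R2", "R3"),
    drugs = list("A", "B", "C"), events = list("X", "Y", "Z"),
    outcomes = list("HO", "OT", character())
  )
  kept <- filter_serious(corpus)
  expect_equal(kept$reports$report_id, "R1")
  expect_error(filter_serious(corpus, character()), "non-empty")
})

test_that("minimum-drug filter respects normalization", {
  corpus <- srs_corpus(
    report_id = c("R1", "R2"),
    drugs = list(c("DRUGA", "DRUGB"), c("AVANDIA", "ROSIGLITAZONE MALEATE")),
    events = list("X", "Y")
  )
  expect_equal(filter_min_drugs(corpus, 2)$reports$report_id, c("R1", "R2"))
  # brand and salt collapse to one generic, so R2 now fails k = 2
  norm <- normalize_reports(corpus, avandia_map())
  expect_equal(filter_min_drugs(norm, 2)$reports$report_id, "R1")
})

test_that("per-report selection filters commute", {
  set.seed(11)
  n <- 60
  corpus <- srs_corpus(
    report_id = paste0("R", 1:n),
    drugs = lapply(1:n, function(i) paste0("D", sample(1:6, sample(1:3, 1)))),
    events = lapply(1:n, function(i) paste0("E", sample(1:4, 1))),
    outcomes = lapply(1:n, function(i) sample(c("HO", "OT", "DE"), 1))
  )
  ab <- filter_min_drugs(filter_serious(corpus), 2)
  ba <- filter_serious(filter_min_drugs(corpus, 2))
  expect_equal(ab$reports$report_id, ba$reports$report_id)
})

test_that("corpus statistics match hand enumeration", {
  corpus <- srs_corpus(
    report_id = c("R1", "R2"),
    drugs = list(c("A", "B"), "C"),
    events = list("X", c("Y", "Z", "W"))
  )
  s <- corpus_stats(corpus)
  expect_equal(s$mean_drugs_per_report, 1.5)
  expect_equal(s$mean_events_per_report, 2.0)
  expect_equal(s$frac_multi_drug, 0.5)
  expect_equal(s$frac_three_plus_items, 1.0)

  one <- srs_corpus("R1", list("A"), list("X"))
  expect_equal(corpus_stats(one)$frac_three_plus_items, 0)
  expect_equal(corpus_stats(one)$median_drugs,
               corpus_stats(one)$mean_drugs_per_report)
  expect_error(corpus_stats(srs_corpus(character(), list(), list())),
               "empty")
})

test_that("corpus statistics agree with brute-force recomputation", {
  corpus <- random_small_corpus(99, n_reports = 80)
  s <- corpus_stats(corpus)
  nd <- vapply(corpus$reports$drugs, length, integer(1))
  ne <- vapply(corpus$reports$events, length, integer(1))
  expect_identical(s$frac_multi_drug, sum(nd > 1) / 80)
  expect_identical(s$frac_multi_event, sum(ne > 1) / 80)
  expect_identical(s$frac_three_plus_items, sum(nd + ne >= 3) / 80)
  expect_identical(s$mean_drugs_per_report, sum(nd) / 80)
})

test_that("rule writer is deterministic and handles the empty list", {
  rules <- rank_rules(emit_candidate_rules(
    apriori_frequent_itemsets(tc4_corpus(), 2)))
  p1 <- tempfile(); p2 <- tempfile()
  write_rules(rules, p1)
  write_rules(rules, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  lines <- readLines(p1)
  expect_length(lines, 4)  # header + 3 rules
  expect_match(lines[1], "^antecedent\tconsequent\tsupport")

  p3 <- tempfile()
  write_rules(rules[0, ], p3)
  expect_length(readLines(p3), 1)
})
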
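# Shared fixtures, all built in code.

# Toy corpus used for worked examples throughout:
#   R1 {D1,D2 | E1}, R2 {D1,D2 | E1}, R3 {D1 | E2}, R4 {D2 | E1}
tc4_corpus <- function() {
  srs_corpus(
    report_id = c("R1", "R2", "R3", "R4"),
    drugs = list(c("D1", "D2"), c("D1", "D2"), "D1", "D2"),
    events = list("E1", "E1", "E2", "E1")
  )
}

tc4_file <- function(dir = tempdir()) {
  path <- file.path(dir, "tc4.tsv")
  write_transactions(tc4_corpus(), path)
  path
}

# The brand-name variant list for the rosiglitazone example.
avandia_variants <- function() {
  c("AVANDIA",
    "AVANDIA (ROSIGLITAZONE MELEATE)",
    "AVANDIA /SCH/ (PIOGLITAZONE HYDROCHLORIDE)",
    "AVANDIA /UNK/ (ROSIGLITAZONE MALEATE)",
    "AVANDIA (CON.)",
    "AVANDIA /01445801/",
    "AVANDIA /SCH/ (ROSIGLITAZONE MALEATE)",
    "AVANDIA (2 MILLIGRAM TABLETS)",
    "ROSIGLITAZONE MALEATE (AVANDIA)",
    "  avandia  ")
}

avandia_map <- function() {
  drug_map(c("AVANDIA", "ROSIGLITAZONE MALEATE"),
           c("ROSIGLITAZONE", "ROSIGLITAZONE"))
}

# Small random corpus for oracle cross-checks: <= 10 drugs, <= 8 events.
random_small_corpus <- function(seed, n_reports = NULL) {
  set.seed(seed)
  n_drugs <- sample(3:10, 1)
  n_events <- sample(2:8, 1)
  if (is.null(n_reports)) n_reports <- sample(20:300, 1)
  drug_vocab <- paste0("DR", seq_len(n_drugs))
  event_vocab <- paste0("EV", seq_len(n_events))
  srs_corpus(
    report_id = paste0("R", seq_len(n_reports)),
    drugs = lapply(seq_len(n_reports), function(i) {
      sample(drug_vocab, sample(1:min(4, n_drugs), 1))
    }),
    events = lapply(seq_len(n_reports), function(i) {
      sample(event_vocab, sample(1:min(3, n_events), 1))
    })
  )
}

# Canonical printable key for a rule, for set comparisons.
rule_keys <- function(rules) {
  if (nrow(rules) == 0) return(character())
  mapply(function(a, b) {
    paste(paste(a, collapse = ","), paste(b, collapse = ","), sep = " -> ")
  }, rules$antecedent, rules$consequent, USE.NAMES = FALSE)
}

itemset_keys <- function(itemsets) {
  vapply(itemsets$items, paste, character(1), collapse = ",")
}

# Random printable strings for normalization property tests.
random_strings <- function(n, seed) {
  set.seed(seed)
  alphabet <- c(LETTERS, letters, 0:9, " ", "(", ")", "/", ".", ",", "-", "%")
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, sample(1:30, 1), replace = TRUE), collapse = "")
  }, character(1))
}
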
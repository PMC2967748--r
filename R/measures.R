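#' Rule strength measures: confidence and relative reporting ratio
#'
#' For a rule A -> B over N reports with joint support S(A∪B) and side
#' supports S(A), S(B):
#'
#' * `confidence(A -> B) = S(A∪B) / S(A)`, an estimate of Pr(B | A);
#' * `relative_reporting_ratio = S(A∪B) * N / (S(A) * S(B))`, the observed
#'   joint reporting frequency over the frequency expected if A and B were
#'   reported independently. RR = 1 indicates independence, RR > 1 a
#'   positive association. RR equals confidence normalized by S(B)/N,
#'   which corrects confidence's bias toward frequent events.
#'
#' Confidence is computed and reported for reference but is not used for
#' screening (see [screen_rules()]): frequent events produce large
#' confidence regardless of the drugs involved, and genuinely interesting
#' multi-item associations are rare and low-confidence by nature.
#'
#' @param support_joint S(A∪B), count of reports containing all of A and B.
#' @param support_ante S(A) > 0.
#' @param support_cons S(B) > 0.
#' @param n Total number of reports N.
#' @return Numeric vector of measure values.
#' @examples
#' confidence(50, 100)
#' relative_reporting_ratio(50, 100, 100, 1000)
#' @export
confidence <- function(support_joint, support_ante) {
  if (any(support_ante <= 0)) {
    stop("confidence undefined: S(A) must be positive", call. = FALSE)
  }
  if (any(support_joint > support_ante)) {
    stop("S(A ∪ B) cannot exceed S(A)", call. = FALSE)
  }
  support_joint / support_ante
}

#' @rdname confidence
#' @export
relative_reporting_ratio <- function(support_joint, support_ante,
                                     support_cons, n) {
  if (any(support_ante <= 0) || any(support_cons <= 0)) {
    stop("relative reporting ratio undefined: S(A) and S(B) must be positive",
         call. = FALSE)
  }
  if (any(n < pmax(support_ante, support_cons))) {
    stop("N must be at least max(S(A), S(B))", call. = FALSE)
  }
  support_joint * n / (support_ante * support_cons)
}

#' Mining configuration
#'
#' Collects the thresholds of the screening step and the corpus selection
#' filters. Defaults follow the screening regime the method was designed
#' around: minimum joint support 50 reports and minimum relative
#' reporting ratio 2, with only multi-item rules (three or more items in
#' antecedent plus consequent, i.e. at least two drugs or two events)
#' retained. The support floor doubles as the reason no low-count
#' variance adjustment (such as a Gamma Poisson shrinker) is applied: at
#' these supports the adjusted and unadjusted RR essentially coincide.
#'
#' @param min_support Minimum joint support, reports (default 50).
#' @param min_rr Minimum relative reporting ratio (default 2).
#' @param max_size Largest itemset size mined (default 8).
#' @param multi_item_only Keep only rules with >= 3 items (default TRUE).
#' @param serious_codes Outcome codes treated as serious.
#' @param min_drugs_per_report Polypharmacy filter (default 2).
#' @param seed Optional integer seed for synthetic runs.
#' @return A list of class `mining_config`.
#' @export
mining_config <- function(min_support = 50L, min_rr = 2, max_size = 8L,
                          multi_item_only = TRUE,
                          serious_codes = default_serious_codes(),
                          min_drugs_per_report = 2L, seed = NULL) {
  if (!is.numeric(min_support) || min_support < 1) {
    stop("min_support must be >= 1", call. = FALSE)
  }
  if (!is.numeric(min_rr) || min_rr <= 0) {
    stop("min_rr must be > 0", call. = FALSE)
  }
  if (!is.numeric(max_size) || max_size < 2) {
    stop("max_size must be >= 2", call. = FALSE)
  }
  structure(list(
    min_support = as.integer(min_support),
    min_rr = as.numeric(min_rr),
    max_size = as.integer(max_size),
    multi_item_only = isTRUE(multi_item_only),
    serious_codes = as.character(serious_codes),
    min_drugs_per_report = as.integer(min_drugs_per_report),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "mining_config")
}

#' Screen candidate rules by support and relative reporting ratio
#'
#' Keeps the rules with `support_joint >= min_support`, `rr >= min_rr`,
#' and -- when `multi_item_only` is set -- at least three items across
#' antecedent and consequent. The counts before and after the multi-item
#' restriction are attached as attributes `n_input`, `n_pass_thresholds`
#' and `n_multi_item`, so a run can report both the full screened set and
#' its multi-item subset.
#'
#' @param rules An `ade_rules` tibble.
#' @param config A [mining_config()].
#' @return The surviving `ade_rules`, in the input order.
#' @export
screen_rules <- function(rules, config = mining_config()) {
  stopifnot(inherits(config, "mining_config"))
  sizes <- lengths(rules$antecedent) + lengths(rules$consequent)
  pass <- rules$support_joint >= config$min_support & rules$rr >= config$min_rr
  multi <- pass & sizes >= 3
  out <- rules[if (config$multi_item_only) multi else pass, , drop = FALSE]
  attr(out, "n_input") <- nrow(rules)
  attr(out, "n_pass_thresholds") <- sum(pass)
  attr(out, "n_multi_item") <- sum(multi)
  out
}

#' Rank rules by association strength
#'
#' Descending relative reporting ratio; ties broken by descending joint
#' support, then lexicographically by antecedent and consequent, giving a
#' total, deterministic order.
#'
#' @param rules An `ade_rules` tibble.
#' @return The same tibble, reordered.
#' @export
rank_rules <- function(rules) {
  if (nrow(rules) == 0) return(rules)
  a <- vapply(rules$antecedent, paste, character(1), collapse = ",")
  b <- vapply(rules$consequent, paste, character(1), collapse = ",")
  rules[order(-rules$rr, -rules$support_joint, a, b, method = "radix"), ,
        drop = FALSE]
}

#' Size of the naive multi-item candidate space
#'
#' The back-of-envelope count that motivates constrained, support-pruned
#' search: with separate drug and event vocabularies, examining every
#' association of `k_drugs` drugs with `k_events` events naively means on
#' the order of `n_drug_vocab^k_drugs * n_event_vocab^k_events`
#' combinations. With vocabularies of 10,000 and a 2-drug/3-event form
#' this is 10^20, far beyond direct enumeration.
#'
#' @param n_drug_vocab,n_event_vocab Vocabulary sizes.
#' @param k_drugs,k_events Items on each side of the association.
#' @return The (approximate, ordered-tuple) candidate count as a double.
#' @examples
#' candidate_space_bound(10000, 10000, 2, 3)
#' @export
candidate_space_bound <- function(n_drug_vocab, n_event_vocab, k_drugs, k_events) {
  stopifnot(n_drug_vocab >= 1, n_event_vocab >= 1, k_drugs >= 0, k_events >= 0)
  n_drug_vocab^k_drugs * n_event_vocab^k_events
}
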
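#' Inverted index over a report corpus
#'
#' Builds the posting lists used for support counting: for every item
#' (drug or event) the set of report positions containing it. Counting the
#' support of an itemset then reduces to intersecting a few posting lists
#' instead of scanning every report, which is what makes database-wide
#' mining tractable.
#'
#' @param corpus A non-empty `srs_corpus`.
#' @return An object of class `ade_index` with elements `postings` (named
#'   list of sorted integer vectors, one per item key), `n_reports`, and
#'   `report_ids`.
#' @export
build_inverted_index <- function(corpus) {
  stopifnot(inherits(corpus, "srs_corpus"))
  n <- n_reports(corpus)
  if (n == 0) stop("corpus is empty: nothing to index", call. = FALSE)
  txns <- corpus_transactions(corpus)
  items <- unlist(txns, use.names = FALSE)
  rows <- rep.int(seq_len(n), lengths(txns))
  postings <- split(rows, items)
  structure(list(postings = postings, n_reports = n,
                 report_ids = corpus$reports$report_id),
            class = "ade_index")
}

# One character vector of typed item keys per report, drugs then events
# (the canonical order). Zero-length sides must stay zero-length (paste0
# would recycle them to a bare prefix).
corpus_transactions <- function(corpus) {
  tag <- function(prefix, x) if (length(x)) paste0(prefix, x) else character()
  Map(function(d, e) c(tag("D:", d), tag("E:", e)),
      corpus$reports$drugs, corpus$reports$events, USE.NAMES = FALSE)
}

#' Support of an itemset via the inverted index
#'
#' Intersects the posting lists of the itemset's items, smallest list
#' first, short-circuiting as soon as the running intersection drops below
#' `at_least` (when given). An item with no posting list has support 0,
#' and so does any itemset containing it.
#'
#' @param items Character vector of typed item keys (see [ade_item()]).
#' @param index An `ade_index`.
#' @param at_least Optional lower bound below which the exact count is not
#'   needed; the returned value is then only guaranteed to be correct when
#'   it is `>= at_least` or `0`.
#' @return Integer support count.
#' @export
itemset_support <- function(items, index, at_least = NULL) {
  stopifnot(inherits(index, "ade_index"), length(items) >= 1)
  posts <- index$postings[items]
  if (any(vapply(posts, is.null, logical(1)))) return(0L)
  posts <- posts[order(lengths(posts))]
  acc <- posts[[1]]
  for (p in posts[-1]) {
    acc <- acc[match(acc, p, nomatch = 0L) > 0L]
    if (length(acc) == 0L) return(0L)
    if (!is.null(at_least) && length(acc) < at_least) return(length(acc))
  }
  length(acc)
}

#' Frequent typed itemsets by level-wise (Apriori) search
#'
#' Finds every itemset of size at most `max_size` -- drug-only,
#' event-only, and mixed -- contained in at least `min_support` reports.
#' The search is level-wise with prefix-join candidate generation and
#' downward-closure pruning: a candidate is counted only if all of its
#' subsets are frequent, since a superset of an infrequent itemset cannot
#' be frequent. Drug-only and event-only itemsets are retained on purpose:
#' they are needed both for pruning and as the S(A) and S(B) denominators
#' of the relative reporting ratio.
#'
#' Support counting uses the inverted index: the report set of each
#' candidate is obtained by intersecting the report sets of its two
#' generating subsets, so no report scan is ever repeated.
#'
#' @param corpus A non-empty `srs_corpus`.
#' @param min_support Minimum number of reports (>= 1).
#' @param max_size Largest itemset size considered (default 8).
#' @return A tibble of class `ade_itemsets` with columns `items` (list of
#'   sorted typed item keys), `size`, and `support`, ordered by size then
#'   item order; attribute `n_reports` carries N.
#' @export
apriori_frequent_itemsets <- function(corpus, min_support, max_size = 8L) {
  stopifnot(inherits(corpus, "srs_corpus"))
  if (!is.numeric(min_support) || length(min_support) != 1 || min_support < 1) {
    stop("min_support must be a count >= 1", call. = FALSE)
  }
  if (max_size < 1) stop("max_size must be >= 1", call. = FALSE)
  index <- build_inverted_index(corpus)

  out_items <- list()
  out_support <- integer()

  # level 1
  singles <- sort(names(index$postings), method = "radix")
  supp1 <- lengths(index$postings)[singles]
  keep1 <- supp1 >= min_support
  level_items <- as.list(singles[keep1])
  level_tids <- index$postings[singles[keep1]]
  names(level_tids) <- vapply(level_items, itemset_key, character(1))
  out_items <- c(out_items, level_items)
  out_support <- c(out_support, unname(supp1[keep1]))

  k <- 2L
  while (k <= max_size && length(level_items) >= 2) {
    prev_keys <- names(level_tids)
    cand <- generate_candidates(level_items, prev_keys)
    if (length(cand$a) == 0) break
    next_items <- vector("list", length(cand$a))
    next_tids <- vector("list", length(cand$a))
    next_supp <- integer(length(cand$a))
    m <- 0L
    for (i in seq_along(cand$a)) {
      ta <- level_tids[[cand$a[i]]]  # positional: parents index into the level
      tb <- level_tids[[cand$b[i]]]
      tids <- ta[match(ta, tb, nomatch = 0L) > 0L]
      if (length(tids) >= min_support) {
        m <- m + 1L
        next_items[[m]] <- cand$items[[i]]
        next_tids[[m]] <- tids
        next_supp[m] <- length(tids)
      }
    }
    if (m == 0L) break
    length(next_items) <- m
    length(next_tids) <- m
    next_supp <- next_supp[seq_len(m)]
    ord <- order(vapply(next_items, itemset_key, character(1)), method = "radix")
    next_items <- next_items[ord]
    next_tids <- next_tids[ord]
    next_supp <- next_supp[ord]
    names(next_tids) <- vapply(next_items, itemset_key, character(1))
    out_items <- c(out_items, next_items)
    out_support <- c(out_support, next_supp)
    level_items <- next_items
    level_tids <- next_tids
    k <- k + 1L
  }

  res <- tibble::tibble(
    items = out_items,
    size = lengths(out_items),
    support = as.integer(out_support)
  )
  attr(res, "n_reports") <- index$n_reports
  class(res) <- c("ade_itemsets", class(res))
  res
}

# Prefix-join candidate generation with downward-closure pruning.
# level_items: sorted list of size-(k-1) itemsets (each a sorted char
# vector); prev_keys: their keys, for the subset check. Returns, for each
# surviving candidate, the keys of its two generating parents.
generate_candidates <- function(level_items, prev_keys) {
  ksub <- length(level_items[[1]])
  prefixes <- vapply(level_items, function(x) {
    itemset_key(x[-ksub])
  }, character(1))
  lasts <- vapply(level_items, function(x) x[ksub], character(1))
  groups <- split(seq_along(level_items), prefixes)
  groups <- groups[lengths(groups) >= 2]
  if (length(groups) == 0) return(list(a = integer(), b = integer(), items = list()))
  have <- new.env(hash = TRUE, size = max(length(prev_keys), 29L))
  for (key in prev_keys) assign(key, TRUE, envir = have)

  # all within-group pairs, preallocated
  pair_mats <- lapply(groups, utils::combn, m = 2L)
  pair_i <- unlist(lapply(pair_mats, function(m) m[1L, ]), use.names = FALSE)
  pair_j <- unlist(lapply(pair_mats, function(m) m[2L, ]), use.names = FALSE)

  np <- length(pair_i)
  keep <- rep(TRUE, np)
  items <- vector("list", np)
  for (p in seq_len(np)) {
    i <- pair_i[p]; j <- pair_j[p]
    # shared prefix and lasts[i] < lasts[j], so the candidate stays sorted
    cand <- c(level_items[[i]], lasts[j])
    if (ksub >= 2) {
      # the two generating parents are frequent by construction; check
      # the remaining (k-1)-subsets
      for (drop in 1:(ksub - 1)) {
        if (!exists(itemset_key(cand[-drop]), envir = have, inherits = FALSE)) {
          keep[p] <- FALSE
          break
        }
      }
    }
    items[[p]] <- cand
  }
  list(
    a = pair_i[keep],
    b = pair_j[keep],
    items = items[keep]
  )
}

#' Brute-force frequent-itemset oracle
#'
#' Enumerates every itemset up to `max_size` over the corpus's distinct
#' items and counts support by a full scan (an incidence-matrix row sum,
#' with no posting lists involved). Exponential in the item universe, so
#' it refuses more than `max_items` distinct items; intended as an
#' independent cross-check for [apriori_frequent_itemsets()] on small
#' corpora, with the same output contract.
#'
#' @inheritParams apriori_frequent_itemsets
#' @param max_items Refuse corpora with more distinct items than this
#'   (default 25).
#' @return Same contract as [apriori_frequent_itemsets()].
#' @export
brute_force_mine <- function(corpus, min_support, max_size = 8L, max_items = 25L) {
  stopifnot(inherits(corpus, "srs_corpus"), min_support >= 1)
  txns <- corpus_transactions(corpus)
  universe <- sort(unique(as.character(unlist(txns))), method = "radix")
  if (length(universe) > max_items) {
    stop(sprintf("item universe too large for brute force (%d > %d)",
                 length(universe), max_items), call. = FALSE)
  }
  n <- length(txns)
  res <- tibble::tibble(items = list(), size = integer(), support = integer())
  if (n == 0 || length(universe) == 0) {
    attr(res, "n_reports") <- n
    class(res) <- c("ade_itemsets", class(res))
    return(res)
  }
  inc <- vapply(txns, function(t) universe %in% t, logical(length(universe)))
  inc <- matrix(inc, nrow = length(universe))  # items x reports

  out_items <- list(); out_support <- integer()
  for (k in seq_len(min(max_size, length(universe)))) {
    combos <- utils::combn(length(universe), k)
    for (ci in seq_len(ncol(combos))) {
      idx <- combos[, ci]
      supp <- sum(colSums(inc[idx, , drop = FALSE]) == k)
      if (supp >= min_support) {
        out_items <- c(out_items, list(universe[idx]))
        out_support <- c(out_support, supp)
      }
    }
  }
  res <- tibble::tibble(items = out_items,
                        size = lengths(out_items),
                        support = as.integer(out_support))
  if (nrow(res)) {
    ord <- order(res$size, vapply(res$items, itemset_key, character(1)),
                 method = "radix")
    res <- res[ord, ]
  }
  attr(res, "n_reports") <- n
  class(res) <- c("ade_itemsets", class(res))
  res
}

#' Emit the constrained candidate rules from a frequent-itemset table
#'
#' The association form of interest is drugs in the antecedent, adverse
#' events in the consequent. Each *mixed* frequent itemset (at least one
#' drug and at least one event) therefore yields exactly one candidate
#' rule -- its drug part implies its event part -- rather than the
#' 2^k - 2 antecedent/consequent partitions of unconstrained rule
#' generation; drug-only and event-only itemsets yield no rule. S(A) and
#' S(B) are looked up in the same table, where downward closure
#' guarantees their presence; a miss indicates an inconsistent table and
#' is an error.
#'
#' @param frequent An `ade_itemsets` table (downward-closed, as produced
#'   by the miners).
#' @param index The `ade_index` of the same corpus (only `n_reports` is
#'   used; optional if the table carries its `n_reports` attribute).
#' @return A tibble of class `ade_rules` with list columns `antecedent`
#'   and `consequent` (plain sorted names) and columns `support_joint`,
#'   `support_ante`, `support_cons`, `n_reports`, `confidence`, `rr`.
#' @export
emit_candidate_rules <- function(frequent, index = NULL) {
  stopifnot(inherits(frequent, "ade_itemsets"))
  n <- if (!is.null(index)) index$n_reports else attr(frequent, "n_reports")
  if (is.null(n)) stop("corpus size N unavailable", call. = FALSE)

  supp_by_key <- stats::setNames(
    frequent$support,
    vapply(frequent$items, itemset_key, character(1))
  )
  is_drug <- lapply(frequent$items, startsWith, prefix = "D:")
  mixed <- vapply(is_drug, function(d) any(d) && !all(d), logical(1))

  rows <- which(mixed)
  ante <- vector("list", length(rows))
  cons <- vector("list", length(rows))
  s_joint <- integer(length(rows)); s_a <- integer(length(rows))
  s_b <- integer(length(rows))
  for (i in seq_along(rows)) {
    it <- frequent$items[[rows[i]]]
    d <- it[startsWith(it, "D:")]
    e <- it[startsWith(it, "E:")]
    ka <- itemset_key(d); kb <- itemset_key(e)
    if (is.na(supp_by_key[ka]) || is.na(supp_by_key[kb])) {
      stop("frequent-itemset table is not downward closed: missing ",
           if (is.na(supp_by_key[ka])) ka else kb, call. = FALSE)
    }
    ante[[i]] <- item_id(d)
    cons[[i]] <- item_id(e)
    s_joint[i] <- frequent$support[rows[i]]
    s_a[i] <- supp_by_key[[ka]]
    s_b[i] <- supp_by_key[[kb]]
  }
  rules <- tibble::tibble(
    antecedent = ante,
    consequent = cons,
    support_joint = s_joint,
    support_ante = s_a,
    support_cons = s_b,
    n_reports = rep(as.integer(n), length(rows)),
    confidence = if (length(rows)) confidence(s_joint, s_a) else numeric(),
    rr = if (length(rows)) {
      relative_reporting_ratio(s_joint, s_a, s_b, n)
    } else numeric()
  )
  class(rules) <- c("ade_rules", class(rules))
  rules
}
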
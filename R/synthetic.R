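#' Specify a synthetic spontaneous-report corpus
#'
#' Describes an SRS-like corpus with known ground truth: background
#' reports whose drugs and events are drawn independently from Zipf-ranked
#' vocabularies (emulating the heavy-tailed item frequencies of real
#' reporting data), plus case reports that carry planted multi-item
#' drug/event associations, plus optional whole-report duplication
#' (emulating the near-identical duplicate reports that inflate
#' disproportionality statistics in real systems).
#'
#' Per-report item counts follow shifted negative-binomial distributions:
#' drugs per report are `2 + NB(size = drug_disp, mu = mean_drugs - 2)`,
#' matching a corpus already restricted to multi-drug reports, and events
#' per report are `1 + NB(size = event_disp, mu = mean_events - 1)`. The
#' overdispersion (size < 1) reproduces the skew of real reporting data,
#' where the mean item count (defaults 3.3 drugs, 3.4 events) sits well
#' above the median (2 of each) and a small share of reports carries very
#' many items; about two thirds of reports get more than one event.
#'
#' @param n_reports Total reports, case reports included.
#' @param n_drugs,n_events Vocabulary sizes (items named `D001`...,
#'   `E001`...; rank 1 is the most frequent).
#' @param drug_zipf_s,event_zipf_s Zipf exponents (weight of rank r is
#'   proportional to r^-s; default 1).
#' @param mean_drugs,mean_events Mean items per report (>= 2 and >= 1).
#' @param drug_disp,event_disp Negative-binomial dispersion (size) of the
#'   extra-item counts; smaller is heavier-tailed.
#' @param planted List of [planted_rule()]s.
#' @param duplication_rate Fraction of reports to append as duplicates,
#'   in \[0, 1).
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_reports = 20000L, n_drugs = 250L, n_events = 250L,
                           drug_zipf_s = 1, event_zipf_s = 1,
                           mean_drugs = 3.3, mean_events = 3.4,
                           drug_disp = 0.5, event_disp = 0.8,
                           planted = list(), duplication_rate = 0,
                           seed = 1L) {
  stopifnot(n_reports >= 1, n_drugs >= 1, n_events >= 1,
            drug_zipf_s >= 0, event_zipf_s >= 0,
            mean_drugs >= 2, mean_events >= 1,
            drug_disp > 0, event_disp > 0,
            duplication_rate >= 0, duplication_rate < 1)
  if (length(planted) > 0) {
    stopifnot(all(vapply(planted, inherits, logical(1), "planted_rule")))
    max_d <- max(vapply(planted, function(p) length(p$drug_set), integer(1)))
    max_e <- max(vapply(planted, function(p) length(p$event_set), integer(1)))
    if (max_d > n_drugs || max_e > n_events) {
      stop("planted itemset larger than vocabulary", call. = FALSE)
    }
    n_cases <- sum(vapply(planted, function(p) p$n_case_reports, integer(1)))
    if (n_cases > n_reports) {
      stop("planted case reports exceed n_reports", call. = FALSE)
    }
  }
  structure(list(
    n_reports = as.integer(n_reports),
    n_drugs = as.integer(n_drugs), n_events = as.integer(n_events),
    drug_zipf_s = drug_zipf_s, event_zipf_s = event_zipf_s,
    mean_drugs = mean_drugs, mean_events = mean_events,
    drug_disp = drug_disp, event_disp = event_disp,
    planted = planted,
    duplication_rate = duplication_rate,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' @rdname synthetic_spec
#' @param drug_set Character vector of drug ids from the vocabulary
#'   (e.g. `c("D040", "D055")`).
#' @param event_set Character vector of event ids.
#' @param n_case_reports Number of case reports carrying the rule.
#' @param penetrance Probability that a case report includes the full
#'   event set (the drug set is always present).
#' @export
planted_rule <- function(drug_set, event_set, n_case_reports,
                         penetrance = 1) {
  stopifnot(length(drug_set) >= 1, length(event_set) >= 1,
            n_case_reports >= 1, penetrance > 0, penetrance <= 1)
  structure(list(drug_set = sort(normalize_token(drug_set)),
                 event_set = sort(normalize_token(event_set)),
                 n_case_reports = as.integer(n_case_reports),
                 penetrance = penetrance),
            class = "planted_rule")
}

zipf_weights <- function(n, s) {
  w <- seq_len(n)^(-s)
  w / sum(w)
}

# Run expr with a local RNG stream so generators are deterministic under
# their spec seed without disturbing the caller's RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic corpus with ground truth
#'
#' Background reports draw their drug and event sets independently from
#' the Zipf marginals. Each planted rule contributes its case reports:
#' the full drug set plus background drug padding, and -- with
#' probability `penetrance` -- the full event set, always plus background
#' events, so case reports are not trivially separable from background.
#' Report order is shuffled and ids reassigned sequentially. Every report
#' gets a serious outcome code and per-drug role codes drawn with
#' frequencies typical of SRS data (27% primary suspect, 15% secondary,
#' 58% concomitant).
#'
#' The returned ground truth restates, per planted rule, the *realized*
#' supports and relative reporting ratio obtained by a full scan of the
#' emitted corpus (padding coincidences included), which is what a miner
#' should recover.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `corpus` (an `srs_corpus`) and
#'   `ground_truth` (a tibble with one row per planted rule).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_local_seed(spec$seed, {
    drug_vocab <- sprintf("D%03d", seq_len(spec$n_drugs))
    event_vocab <- sprintf("E%03d", seq_len(spec$n_events))
    w_d <- zipf_weights(spec$n_drugs, spec$drug_zipf_s)
    w_e <- zipf_weights(spec$n_events, spec$event_zipf_s)
    rextra_d <- function(n) stats::rnbinom(n, size = spec$drug_disp,
                                           mu = spec$mean_drugs - 2)
    rextra_e <- function(n) stats::rnbinom(n, size = spec$event_disp,
                                           mu = spec$mean_events - 1)

    n_cases <- if (length(spec$planted)) {
      sum(vapply(spec$planted, function(p) p$n_case_reports, integer(1)))
    } else 0L
    n_bg <- spec$n_reports - n_cases

    draw_bg <- function(vocab, w, k) {
      vocab[sample.int(length(vocab), min(k, length(vocab)), prob = w)]
    }

    drugs <- vector("list", spec$n_reports)
    events <- vector("list", spec$n_reports)

    kd <- 2L + rextra_d(n_bg)
    ke <- 1L + rextra_e(n_bg)
    for (i in seq_len(n_bg)) {
      drugs[[i]] <- draw_bg(drug_vocab, w_d, kd[i])
      events[[i]] <- draw_bg(event_vocab, w_e, ke[i])
    }

    pos <- n_bg
    for (p in spec$planted) {
      for (j in seq_len(p$n_case_reports)) {
        pos <- pos + 1L
        k <- max(length(p$drug_set), 2L + rextra_d(1))
        pad <- utils::head(setdiff(draw_bg(drug_vocab, w_d, k), p$drug_set),
                           max(0L, k - length(p$drug_set)))
        drugs[[pos]] <- union(p$drug_set, pad)
        hit <- stats::runif(1) < p$penetrance
        ke1 <- max(if (hit) length(p$event_set) else 1L,
                   1L + rextra_e(1))
        base <- if (hit) p$event_set else character()
        pad_e <- utils::head(setdiff(draw_bg(event_vocab, w_e, ke1), base),
                             max(0L, ke1 - length(base)))
        events[[pos]] <- union(base, pad_e)
      }
    }

    ord <- sample.int(spec$n_reports)
    drugs <- drugs[ord]
    events <- events[ord]
    outcomes <- as.list(sample(c("DE", "LT", "HO", "DS"), spec$n_reports,
                               replace = TRUE, prob = c(0.2, 0.1, 0.6, 0.1)))
    roles <- lapply(drugs, function(d) {
      stats::setNames(sample(c("PS", "SS", "C"), length(d), replace = TRUE,
                             prob = c(0.27, 0.15, 0.58)), d)
    })

    corpus <- srs_corpus(
      report_id = sprintf("S%06d", seq_len(spec$n_reports)),
      drugs = drugs, events = events, outcomes = outcomes, roles = roles
    )
    if (spec$duplication_rate > 0) {
      corpus <- inject_duplicates(corpus, spec$duplication_rate,
                                  seed = spec$seed + 1L)
    }
    list(corpus = corpus, ground_truth = realized_rule_stats(corpus, spec$planted))
  })
}

# Full-scan supports and RR of each planted rule in a realized corpus.
realized_rule_stats <- function(corpus, planted) {
  n <- n_reports(corpus)
  rows <- lapply(planted, function(p) {
    in_a <- vapply(corpus$reports$drugs, function(d) all(p$drug_set %in% d),
                   logical(1))
    in_b <- vapply(corpus$reports$events, function(e) all(p$event_set %in% e),
                   logical(1))
    s_a <- sum(in_a); s_b <- sum(in_b); s_ab <- sum(in_a & in_b)
    tibble::tibble(
      drug_set = list(p$drug_set), event_set = list(p$event_set),
      n_case_reports = p$n_case_reports, penetrance = p$penetrance,
      support_joint = s_ab, support_ante = s_a, support_cons = s_b,
      n_reports = n,
      rr = if (s_a > 0 && s_b > 0) s_ab * n / (s_a * s_b) else NA_real_
    )
  })
  if (length(rows) == 0) {
    return(tibble::tibble(drug_set = list(), event_set = list(),
                          n_case_reports = integer(), penetrance = numeric(),
                          support_joint = integer(), support_ante = integer(),
                          support_cons = integer(), n_reports = integer(),
                          rr = numeric()))
  }
  do.call(rbind, rows)
}

#' Append duplicate reports to a corpus
#'
#' Emulates reporting duplicity -- near-identical reports of the same
#' patient/event entering the database several times, e.g. through
#' unlinked follow-ups or multiple reporters. Appends `floor(rate * N)`
#' copies of uniformly chosen reports with fresh report ids and identical
#' item sets. Duplication inflates the joint support and the relative
#' reporting ratio of whatever the duplicated reports contain.
#'
#' @param corpus An `srs_corpus`.
#' @param rate Fraction of the original corpus to append, in \[0, 1).
#' @param seed Integer seed.
#' @return The enlarged `srs_corpus`.
#' @export
inject_duplicates <- function(corpus, rate, seed = 1L) {
  stopifnot(inherits(corpus, "srs_corpus"), rate >= 0, rate < 1)
  n <- n_reports(corpus)
  n_add <- floor(rate * n)
  if (n_add == 0) return(corpus)
  with_local_seed(seed, {
    idx <- sample.int(n, n_add, replace = TRUE)
    extra <- corpus$reports[idx, , drop = FALSE]
    extra$report_id <- sprintf("%s-DUP%04d", extra$report_id, seq_len(n_add))
    corpus$reports <- rbind(corpus$reports, extra)
    corpus
  })
}

#' Expected supports and RR of planted rules (closed form)
#'
#' Approximate expectations used to size a synthetic spec so that planted
#' rules clear the screening thresholds. An item of Zipf weight w appears
#' in a background report with probability about 1 - (1 - w)^k, with k
#' the mean item count. The expected joint support of a planted rule is
#' its case contribution (`n_case_reports * penetrance`) plus the
#' background coincidence term (independent co-occurrence of all its
#' items), and the expected RR follows by plugging the expectations into
#' the RR formula. For fixed case counts the expected RR grows with the
#' corpus size N, since the baseline expected frequency shrinks.
#'
#' @param spec A [synthetic_spec()] with planted rules.
#' @return A tibble with one row per planted rule: `exp_support_joint`,
#'   `exp_support_ante`, `exp_support_cons`, `exp_rr`.
#' @export
expected_rule_stats <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  w_d <- zipf_weights(spec$n_drugs, spec$drug_zipf_s)
  w_e <- zipf_weights(spec$n_events, spec$event_zipf_s)
  drug_vocab <- sprintf("D%03d", seq_len(spec$n_drugs))
  event_vocab <- sprintf("E%03d", seq_len(spec$n_events))
  p_item <- function(w, k) 1 - (1 - w)^k

  n_cases_all <- if (length(spec$planted)) {
    sum(vapply(spec$planted, function(p) p$n_case_reports, integer(1)))
  } else 0L
  n_bg <- spec$n_reports - n_cases_all

  rows <- lapply(spec$planted, function(p) {
    pd <- p_item(w_d[match(p$drug_set, drug_vocab)], spec$mean_drugs)
    pe <- p_item(w_e[match(p$event_set, event_vocab)], spec$mean_events)
    bg_a <- n_bg * prod(pd)
    bg_b <- n_bg * prod(pe)
    bg_ab <- n_bg * prod(pd) * prod(pe)
    cases <- p$n_case_reports
    e_joint <- cases * p$penetrance + bg_ab
    e_a <- cases + bg_a
    e_b <- cases * p$penetrance + bg_b
    tibble::tibble(
      drug_set = list(p$drug_set), event_set = list(p$event_set),
      exp_support_joint = e_joint, exp_support_ante = e_a,
      exp_support_cons = e_b,
      exp_rr = e_joint * spec$n_reports / (e_a * e_b)
    )
  })
  if (length(rows) == 0) {
    return(tibble::tibble(drug_set = list(), event_set = list(),
                          exp_support_joint = numeric(),
                          exp_support_ante = numeric(),
                          exp_support_cons = numeric(), exp_rr = numeric()))
  }
  do.call(rbind, rows)
}

#' Reference validation spec: five planted multi-item associations
#'
#' The study conditions used throughout the package's validation: a
#' 20,000-report corpus over 250-drug and 250-event Zipf vocabularies
#' with five planted multi-item rules of varying shape (2-3 drugs, 1-2
#' events) on mid-rank items, each carried by 150 case reports at
#' penetrance 0.8, so every rule has expected joint support of about 120
#' and expected RR well above 5 -- comfortably clear of the (50, 2)
#' screening thresholds without being trivially separable from
#' background.
#'
#' @param seed Integer seed.
#' @param n_reports Corpus size (default 20,000).
#' @return A [synthetic_spec()].
#' @export
planted_validation_spec <- function(seed = 1L, n_reports = 20000L) {
  synthetic_spec(
    n_reports = n_reports,
    planted = list(
      planted_rule(c("D040", "D055"), "E045", 150L, 0.8),
      planted_rule(c("D060", "D072", "D081"), "E052", 150L, 0.8),
      planted_rule("D048", c("E060", "E070"), 150L, 0.8),
      planted_rule(c("D090", "D100"), c("E080", "E090"), 150L, 0.8),
      planted_rule(c("D110", "D120", "D130"), c("E100", "E110"), 150L, 0.8)
    ),
    seed = seed
  )
}
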
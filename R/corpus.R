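#' Construct a corpus of spontaneous reports
#'
#' An `srs_corpus` holds one row per spontaneous report: a unique report
#' identifier, the set of drug names on the report, the set of
#' adverse-event terms, optional outcome codes (e.g. `DE`, `HO`), optional
#' drug role codes (`PS` primary suspect, `SS` secondary suspect, `C`
#' concomitant, `I` interacting), and an optional period tag. Item
#' multiplicity within a report is discarded: support is defined as the
#' number of *reports* containing an itemset, so drugs and events are kept
#' as sets.
#'
#' @param report_id Character vector of report keys.
#' @param drugs List of character vectors, one per report.
#' @param events List of character vectors, one per report.
#' @param outcomes Optional list of character vectors of outcome codes.
#' @param roles Optional list of named character vectors mapping a drug
#'   name to its role code.
#' @param period Optional character vector (for example `"2008Q1"`).
#' @return An object of class `srs_corpus`; `n_reports()` gives the number
#'   of reports it contains.
#' @examples
#' srs_corpus("R1", list(c("aspirin", "ASPIRIN")), list("NAUSEA"))
#' @export
srs_corpus <- function(report_id, drugs, events, outcomes = NULL,
                       roles = NULL, period = NULL) {
  n <- length(report_id)
  stopifnot(length(drugs) == n, length(events) == n)
  if (is.null(outcomes)) outcomes <- rep(list(character()), n)
  if (is.null(roles)) roles <- rep(list(character()), n)
  if (is.null(period)) period <- rep(NA_character_, n)
  stopifnot(length(outcomes) == n, length(roles) == n, length(period) == n)

  report_id <- as.character(report_id)
  drugs <- lapply(drugs, function(x) sort_items_chr(normalize_token(drop_empty(x))))
  events <- lapply(events, function(x) sort_items_chr(normalize_token(drop_empty(x))))
  outcomes <- lapply(outcomes, function(x) sort_items_chr(normalize_token(drop_empty(x))))
  roles <- lapply(roles, normalize_roles)

  dup <- duplicated(report_id)
  if (any(dup)) {
    warning(sprintf("%d duplicate report id(s) dropped (kept first occurrence): %s",
                    sum(dup), paste(utils::head(unique(report_id[dup]), 5L), collapse = ", ")),
            call. = FALSE)
    keep <- !dup
    report_id <- report_id[keep]
    drugs <- drugs[keep]
    events <- events[keep]
    outcomes <- outcomes[keep]
    roles <- roles[keep]
    period <- period[keep]
  }

  out <- list(reports = tibble::tibble(
    report_id = report_id,
    drugs = drugs,
    events = events,
    outcomes = outcomes,
    roles = roles,
    period = as.character(period)
  ))
  class(out) <- "srs_corpus"
  out
}

drop_empty <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & nzchar(trimws(x))]
}

sort_items_chr <- function(x) sort(unique(x), method = "radix")

normalize_roles <- function(r) {
  if (length(r) == 0) return(character())
  ids <- normalize_token(names(r))
  vals <- toupper(trimws(as.character(r)))
  keep <- !duplicated(ids)
  stats::setNames(vals[keep], ids[keep])
}

#' @rdname srs_corpus
#' @param corpus An `srs_corpus`.
#' @export
n_reports <- function(corpus) {
  stopifnot(inherits(corpus, "srs_corpus"))
  nrow(corpus$reports)
}

#' @export
print.srs_corpus <- function(x, ...) {
  n <- n_reports(x)
  nd <- length(unique(unlist(x$reports$drugs)))
  ne <- length(unique(unlist(x$reports$events)))
  cat(sprintf("<srs_corpus> %d reports, %d distinct drugs, %d distinct events\n",
              n, nd, ne))
  invisible(x)
}

#' Keep reports with a serious patient outcome
#'
#' Retains exactly the reports whose outcome codes intersect the given set
#' of serious codes. The default follows AERS outcome coding: death (`DE`),
#' life-threatening (`LT`), hospitalization (`HO`), disability (`DS`),
#' congenital anomaly (`CA`) and required intervention (`RI`); `OT`
#' ("other") is not considered serious. Reports with no outcome codes are
#' dropped.
#'
#' @param corpus An `srs_corpus`.
#' @param serious_codes Non-empty character vector of outcome codes.
#' @return The filtered `srs_corpus`.
#' @export
filter_serious <- function(corpus, serious_codes = default_serious_codes()) {
  stopifnot(inherits(corpus, "srs_corpus"))
  serious_codes <- normalize_token(drop_empty(serious_codes))
  if (length(serious_codes) == 0) {
    stop("serious_codes must be non-empty", call. = FALSE)
  }
  keep <- vapply(corpus$reports$outcomes,
                 function(o) any(o %in% serious_codes), logical(1))
  subset_corpus(corpus, keep)
}

#' @rdname filter_serious
#' @export
default_serious_codes <- function() c("DE", "LT", "HO", "DS", "CA", "RI")

#' Keep reports carrying at least k distinct drugs
#'
#' Polypharmacy selection: multi-drug reports are the ones in which
#' drug-drug interaction signals can appear. Apply after
#' [normalize_reports()] so that brand/generic collapse is reflected in
#' the drug count.
#'
#' @param corpus An `srs_corpus`.
#' @param k Minimum number of distinct drugs per report (default 2).
#' @return The filtered `srs_corpus`.
#' @export
filter_min_drugs <- function(corpus, k = 2L) {
  stopifnot(inherits(corpus, "srs_corpus"), k >= 1)
  keep <- lengths(corpus$reports$drugs) >= k
  subset_corpus(corpus, keep)
}

subset_corpus <- function(corpus, keep) {
  corpus$reports <- corpus$reports[keep, , drop = FALSE]
  corpus
}

#' Summary statistics of a report corpus
#'
#' Computes the corpus-level descriptives usually quoted for SRS samples:
#' report and vocabulary counts, mean and median items per report, the
#' fraction of multi-drug and multi-event reports, the fraction of reports
#' with at least three items in total (the reports in which a multi-item
#' association can occur at all), and the distribution of drug role codes.
#'
#' @param corpus A non-empty `srs_corpus`.
#' @return A list of class `corpus_stats`.
#' @export
corpus_stats <- function(corpus) {
  stopifnot(inherits(corpus, "srs_corpus"))
  if (n_reports(corpus) == 0) {
    stop("corpus is empty: nothing to summarize", call. = FALSE)
  }
  nd <- lengths(corpus$reports$drugs)
  ne <- lengths(corpus$reports$events)
  all_roles <- unlist(lapply(corpus$reports$roles, unname))
  role_fractions <- if (length(all_roles)) {
    tab <- table(all_roles)
    stats::setNames(as.numeric(tab) / length(all_roles), names(tab))
  } else {
    stats::setNames(numeric(), character())
  }
  out <- list(
    n_reports = n_reports(corpus),
    n_unique_drugs = length(unique(unlist(corpus$reports$drugs))),
    n_unique_events = length(unique(unlist(corpus$reports$events))),
    mean_drugs_per_report = mean(nd),
    mean_events_per_report = mean(ne),
    median_drugs = stats::median(nd),
    median_events = stats::median(ne),
    frac_multi_drug = mean(nd > 1),
    frac_multi_event = mean(ne > 1),
    frac_three_plus_items = mean(nd + ne >= 3),
    role_fractions = role_fractions
  )
  class(out) <- "corpus_stats"
  out
}

#' @export
print.corpus_stats <- function(x, ...) {
  cat(sprintf("reports:                %d\n", x$n_reports))
  cat(sprintf("unique drugs:           %d\n", x$n_unique_drugs))
  cat(sprintf("unique events:          %d\n", x$n_unique_events))
  cat(sprintf("mean drugs/report:      %.2f (median %g)\n",
              x$mean_drugs_per_report, x$median_drugs))
  cat(sprintf("mean events/report:     %.2f (median %g)\n",
              x$mean_events_per_report, x$median_events))
  cat(sprintf("multi-drug reports:     %.1f%%\n", 100 * x$frac_multi_drug))
  cat(sprintf("multi-event reports:    %.1f%%\n", 100 * x$frac_multi_event))
  cat(sprintf(">=3 item reports:       %.1f%%\n", 100 * x$frac_three_plus_items))
  if (length(x$role_fractions)) {
    cat("drug roles:             ",
        paste(sprintf("%s %.1f%%", names(x$role_fractions),
                      100 * x$role_fractions), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
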
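#' Run the end-to-end mining pipeline
#'
#' Executes the full process on a corpus or an input file: (1) drug-name
#' normalization, (2) report selection (serious outcome, minimum drug
#' count), (3) constrained Apriori candidate generation, (4) screening by
#' support and relative reporting ratio, (5) deterministic ranking and
#' TSV output. Returns a `run_summary` with the stage-by-stage counts
#' that reconcile the run: reports kept after each filter, distinct raw
#' vs normalized drug names, frequent itemsets per level, candidate rules
#' (one per mixed frequent itemset), and survivors after screening.
#'
#' The serious-outcome filter is skipped when `config$serious_codes` is
#' empty, and the minimum-drug filter when `config$min_drugs_per_report`
#' is 0; this allows the miner to run on corpora that were already
#' selected upstream (or on toy examples).
#'
#' @param input An `srs_corpus`, or the path to a transactions file (see
#'   [read_transactions()]).
#' @param output_rules Optional path for the ranked rule TSV.
#' @param config A [mining_config()].
#' @param map A [drug_map()] for brand-to-generic normalization.
#' @param summary_path Optional path for the JSON-serialized summary.
#' @param quiet Suppress stage progress messages.
#' @return A list of class `run_summary`; its `rules` element holds the
#'   ranked surviving rules.
#' @export
run_pipeline <- function(input, output_rules = NULL, config = mining_config(),
                         map = drug_map(), summary_path = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "mining_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  tic <- function() proc.time()[["elapsed"]]
  timings <- numeric()

  t0 <- tic()
  corpus <- if (inherits(input, "srs_corpus")) input else read_transactions(input)
  n_read <- n_reports(corpus)
  timings["ingest"] <- tic() - t0
  say("ingest: %d reports", n_read)
  if (n_read == 0) stop("no reports to mine", call. = FALSE)

  t0 <- tic()
  corpus <- normalize_reports(corpus, map)
  red <- attr(corpus, "name_reduction")
  timings["normalize"] <- tic() - t0
  say("normalize: %d raw drug names -> %d", red["n_raw"], red["n_normalized"])

  t0 <- tic()
  n_after_serious <- n_read
  if (length(config$serious_codes) > 0) {
    corpus <- filter_serious(corpus, config$serious_codes)
    n_after_serious <- n_reports(corpus)
    say("serious-outcome filter: %d reports kept", n_after_serious)
  }
  n_after_drugs <- n_after_serious
  if (config$min_drugs_per_report >= 1) {
    corpus <- filter_min_drugs(corpus, config$min_drugs_per_report)
    n_after_drugs <- n_reports(corpus)
    say("min-drugs filter (k=%d): %d reports kept",
        config$min_drugs_per_report, n_after_drugs)
  }
  timings["filter"] <- tic() - t0
  if (n_reports(corpus) == 0) stop("no reports survive the filters", call. = FALSE)

  t0 <- tic()
  frequent <- apriori_frequent_itemsets(corpus, config$min_support,
                                        config$max_size)
  timings["mine"] <- tic() - t0
  by_level <- table(frequent$size)
  say("mining: %d frequent itemsets (min_support=%d, max_size=%d)",
      nrow(frequent), config$min_support, config$max_size)

  t0 <- tic()
  rules <- emit_candidate_rules(frequent)
  screened <- screen_rules(rules, config)
  ranked <- rank_rules(screened)
  timings["screen"] <- tic() - t0
  say("rules: %d candidates, %d pass thresholds, %d multi-item, %d survivors",
      nrow(rules), attr(screened, "n_pass_thresholds"),
      attr(screened, "n_multi_item"), nrow(ranked))
  if (nrow(ranked) == 0) say("notice: no rules survive screening")

  if (!is.null(output_rules)) write_rules(ranked, output_rules)

  summary <- structure(list(
    n_read = n_read,
    n_after_serious = n_after_serious,
    n_after_min_drugs = n_after_drugs,
    drug_names_raw = unname(red["n_raw"]),
    drug_names_normalized = unname(red["n_normalized"]),
    frequent_by_level = stats::setNames(as.integer(by_level), names(by_level)),
    n_frequent = nrow(frequent),
    n_rules_total = nrow(rules),
    n_pass_thresholds = attr(screened, "n_pass_thresholds"),
    n_multi_item = attr(screened, "n_multi_item"),
    n_survivors = nrow(ranked),
    config = config,
    timings = round(timings, 3),
    rules = ranked
  ), class = "run_summary")

  if (!is.null(summary_path)) {
    ser <- summary[setdiff(names(summary), c("rules", "config"))]
    ser$config <- unclass(config)
    jsonlite::write_json(ser, summary_path, auto_unbox = TRUE, null = "null")
  }
  summary
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf("reports read:            %d\n", x$n_read))
  cat(sprintf("after serious filter:    %d\n", x$n_after_serious))
  cat(sprintf("after min-drugs filter:  %d\n", x$n_after_min_drugs))
  cat(sprintf("drug names raw -> norm:  %d -> %d\n",
              x$drug_names_raw, x$drug_names_normalized))
  cat(sprintf("frequent itemsets:       %d (%s)\n", x$n_frequent,
              paste(sprintf("size %s: %d", names(x$frequent_by_level),
                            x$frequent_by_level), collapse = ", ")))
  cat(sprintf("candidate rules:         %d\n", x$n_rules_total))
  cat(sprintf("pass support+RR:         %d\n", x$n_pass_thresholds))
  cat(sprintf("  of which multi-item:   %d\n", x$n_multi_item))
  cat(sprintf("survivors written:       %d\n", x$n_survivors))
  invisible(x)
}

#' Load a mining configuration from a YAML file
#'
#' The file mirrors [mining_config()] (`min_support`, `min_rr`,
#' `max_size`, `multi_item_only`, `serious_codes`, `min_drugs_per_report`,
#' `seed`) and may additionally carry `drug_map`, a path to the
#' brand-to-generic TSV, resolved relative to the config file. Named
#' `overrides` (e.g. from command-line flags) replace file values.
#'
#' @param path Path to the YAML config; `NULL` gives the defaults.
#' @param overrides Named list of values taking precedence.
#' @return A list with elements `config` (a `mining_config`) and `map`
#'   (a `drug_map`).
#' @export
load_config <- function(path = NULL, overrides = list()) {
  vals <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("cannot read config: ", path, call. = FALSE)
    yaml::read_yaml(path)
  }
  vals[names(overrides)] <- overrides
  map <- drug_map()
  if (!is.null(vals$drug_map)) {
    map_path <- vals$drug_map
    if (!is.null(path) && !file.exists(map_path)) {
      map_path <- file.path(dirname(path), vals$drug_map)
    }
    map <- read_drug_map(map_path)
  }
  allowed <- c("min_support", "min_rr", "max_size", "multi_item_only",
               "serious_codes", "min_drugs_per_report", "seed")
  args <- vals[intersect(names(vals), allowed)]
  if (!is.null(args$serious_codes)) {
    args$serious_codes <- as.character(unlist(args$serious_codes))
  }
  config <- do.call(mining_config, args)
  list(config = config, map = map)
}
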
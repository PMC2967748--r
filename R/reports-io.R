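#' Read and write line-delimited report transactions
#'
#' The native interchange format is one report per line. Two dialects are
#' supported and auto-detected from the file extension:
#'
#' * **jsonl** (`.jsonl`, `.ndjson`, `.json`): each line is a JSON object
#'   with fields `report_id`, `drugs`, `events`, and optionally `outcomes`,
#'   `roles` (an object mapping drug name to role code) and `period`.
#' * **tsv** (anything else): a header line then one tab-separated row per
#'   report with columns `report_id`, `drugs`, `events`, `outcomes`,
#'   `roles`, `period`; the list columns are pipe-joined
#'   (`ASPIRIN|WARFARIN`), roles as `ASPIRIN:PS|WARFARIN:C`, empty fields
#'   allowed.
#'
#' Malformed records are skipped with a warning; the number skipped is
#' attached as attribute `n_skipped`. Duplicate report ids keep the first
#' occurrence (with a warning).
#'
#' @param path Path to the transactions file.
#' @param format `"auto"`, `"jsonl"` or `"tsv"`.
#' @return An `srs_corpus`.
#' @seealso [write_transactions()] for the inverse operation.
#' @export
read_transactions <- function(path, format = c("auto", "jsonl", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read transactions file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(jsonl|ndjson|json)$", path, ignore.case = TRUE)) "jsonl" else "tsv"
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (format == "tsv" && length(lines) > 0) lines <- lines[-1L]  # header
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    corpus <- srs_corpus(character(), list(), list())
    attr(corpus, "n_skipped") <- 0L
    return(corpus)
  }

  parse_one <- if (format == "jsonl") parse_jsonl_record else parse_tsv_record
  recs <- lapply(lines, function(l) tryCatch(parse_one(l), error = function(e) NULL))
  bad <- vapply(recs, is.null, logical(1))
  if (any(bad)) {
    warning(sprintf("skipped %d malformed record(s) in %s", sum(bad), path),
            call. = FALSE)
  }
  recs <- recs[!bad]
  if (length(recs) == 0) {
    corpus <- srs_corpus(character(), list(), list())
  } else {
    corpus <- srs_corpus(
      report_id = vapply(recs, `[[`, character(1), "report_id"),
      drugs = lapply(recs, `[[`, "drugs"),
      events = lapply(recs, `[[`, "events"),
      outcomes = lapply(recs, `[[`, "outcomes"),
      roles = lapply(recs, `[[`, "roles"),
      period = vapply(recs, `[[`, character(1), "period")
    )
  }
  attr(corpus, "n_skipped") <- sum(bad)
  corpus
}

parse_jsonl_record <- function(line) {
  x <- jsonlite::fromJSON(line, simplifyVector = TRUE)
  if (is.null(x$report_id) || !nzchar(as.character(x$report_id)[1])) {
    stop("missing report_id")
  }
  roles <- x$roles
  roles <- if (is.null(roles) || length(roles) == 0) character() else unlist(roles)
  list(report_id = as.character(x$report_id)[1],
       drugs = as.character(unlist(x$drugs)),
       events = as.character(unlist(x$events)),
       outcomes = as.character(unlist(x$outcomes)),
       roles = roles,
       period = if (is.null(x$period)) NA_character_ else as.character(x$period)[1])
}

parse_tsv_record <- function(line) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(f) < 3 || !nzchar(trimws(f[1]))) stop("malformed tsv record")
  f <- c(f, rep("", 6L - length(f)))[1:6]
  split_pipe <- function(s) {
    if (!nzchar(s)) character() else strsplit(s, "|", fixed = TRUE)[[1]]
  }
  role_pairs <- split_pipe(f[5])
  roles <- character()
  if (length(role_pairs)) {
    parts <- strsplit(role_pairs, ":", fixed = TRUE)
    ok <- lengths(parts) == 2
    roles <- stats::setNames(vapply(parts[ok], `[`, character(1), 2),
                             vapply(parts[ok], `[`, character(1), 1))
  }
  list(report_id = f[1], drugs = split_pipe(f[2]), events = split_pipe(f[3]),
       outcomes = split_pipe(f[4]), roles = roles,
       period = if (nzchar(f[6])) f[6] else NA_character_)
}

#' @rdname read_transactions
#' @param corpus An `srs_corpus`.
#' @export
write_transactions <- function(corpus, path, format = c("auto", "jsonl", "tsv")) {
  stopifnot(inherits(corpus, "srs_corpus"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(jsonl|ndjson|json)$", path, ignore.case = TRUE)) "jsonl" else "tsv"
  }
  r <- corpus$reports
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(r)), function(i) {
      rec <- list(report_id = r$report_id[i], drugs = r$drugs[[i]],
                  events = r$events[[i]], outcomes = r$outcomes[[i]])
      if (length(r$roles[[i]])) rec$roles <- as.list(r$roles[[i]])
      if (!is.na(r$period[i])) rec$period <- r$period[i]
      jsonlite::toJSON(rec, auto_unbox = TRUE) |> as.character()
    }, character(1))
  } else {
    join_pipe <- function(x) paste(x, collapse = "|")
    body <- vapply(seq_len(nrow(r)), function(i) {
      roles <- r$roles[[i]]
      role_s <- if (length(roles)) {
        paste(paste0(names(roles), ":", roles), collapse = "|")
      } else ""
      paste(r$report_id[i], join_pipe(r$drugs[[i]]), join_pipe(r$events[[i]]),
            join_pipe(r$outcomes[[i]]), role_s,
            ifelse(is.na(r$period[i]), "", r$period[i]), sep = "\t")
    }, character(1))
    lines <- c(paste("report_id", "drugs", "events", "outcomes", "roles",
                     "period", sep = "\t"), body)
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read one AERS-style quarterly extract
#'
#' Joins the four '$'-delimited ASCII tables of an AERS-style quarterly
#' release on the report key (the first column of every file): `DEMO` (one
#' row per report), `DRUG` (report key, verbatim drug name, optional role
#' code), `REAC` (report key, event term) and `OUTC` (report key, outcome
#' code). One `Report` is produced per DEMO key; DRUG/REAC/OUTC rows whose
#' key does not appear in DEMO are dropped with a warning. A DEMO key with
#' no REAC rows yields a report with an empty event set (removable later
#' by filters). Every file must start with a header row; a data row with
#' fewer columns than required is a hard error naming the file and line.
#'
#' @param demo,drug,reac,outc Paths to the four tables.
#' @param period Optional period tag stored on every report.
#' @return An `srs_corpus`.
#' @export
read_aers_ascii_quarter <- function(demo, drug, reac, outc, period = NA_character_) {
  demo_t <- read_dollar_file(demo, min_cols = 1L)
  drug_t <- read_dollar_file(drug, min_cols = 2L)
  reac_t <- read_dollar_file(reac, min_cols = 2L)
  outc_t <- read_dollar_file(outc, min_cols = 2L)

  keys <- unique(vapply(demo_t, `[`, character(1), 1L))
  known <- stats::setNames(rep(TRUE, length(keys)), keys)

  pick <- function(rows, what) {
    k <- vapply(rows, `[`, character(1), 1L)
    orphan <- !(k %in% keys)
    if (any(orphan)) {
      warning(sprintf("%s: dropped %d row(s) with report key(s) absent from DEMO",
                      what, sum(orphan)), call. = FALSE)
    }
    rows[!orphan]
  }
  drug_t <- pick(drug_t, "DRUG")
  reac_t <- pick(reac_t, "REAC")
  outc_t <- pick(outc_t, "OUTC")

  gather <- function(rows, col) {
    k <- vapply(rows, `[`, character(1), 1L)
    v <- vapply(rows, `[`, character(1), col)
    split(v, factor(k, levels = keys))
  }
  drugs_by <- gather(drug_t, 2L)
  events_by <- gather(reac_t, 2L)
  outc_by <- gather(outc_t, 2L)

  roles_by <- {
    k <- vapply(drug_t, `[`, character(1), 1L)
    nm <- vapply(drug_t, `[`, character(1), 2L)
    rl <- vapply(drug_t, function(r) if (length(r) >= 3) r[3] else "", character(1))
    pairs <- split(stats::setNames(rl, nm), factor(k, levels = keys))
    lapply(pairs, function(p) p[nzchar(p)])
  }

  srs_corpus(
    report_id = keys,
    drugs = drugs_by[keys],
    events = events_by[keys],
    outcomes = outc_by[keys],
    roles = roles_by[keys],
    period = rep(period, length(keys))
  )
}

# '$'-delimited reader: one header line, then rows with at least min_cols
# columns. Undecodable bytes are replaced (sub = byte escape) rather than
# erroring, matching the tolerant handling such extracts need.
read_dollar_file <- function(path, min_cols) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  lines <- tryCatch(
    readLines(path, warn = FALSE, encoding = "UTF-8"),
    error = function(e) stop("unreadable file: ", path, call. = FALSE)
  )
  lines <- iconv(lines, from = "UTF-8", to = "UTF-8", sub = "?")
  if (length(lines) == 0 || !nzchar(trimws(lines[1]))) {
    stop(sprintf("%s: missing header row", path), call. = FALSE)
  }
  body <- lines[-1L]
  keep <- nzchar(trimws(body))
  body <- body[keep]
  rows <- strsplit(body, "$", fixed = TRUE)
  short <- lengths(rows) < min_cols
  if (any(short)) {
    first <- which(short)[1]
    stop(sprintf("%s: line %d has %d column(s), expected at least %d",
                 path, first + 1L, lengths(rows)[first], min_cols), call. = FALSE)
  }
  rows
}

#' Write ranked association rules to a TSV file
#'
#' One row per rule with the antecedent drugs and consequent events
#' (sorted, comma-joined), the joint support S(A∪B), the side supports
#' S(A) and S(B), the corpus size N, and the confidence and relative
#' reporting ratio rendered at 4 significant digits. Rows are written in
#' the order given (use [rank_rules()] first); output is byte-identical
#' across runs for the same input.
#'
#' @param rules An `ade_rules` tibble (see [emit_candidate_rules()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_rules <- function(rules, path) {
  header <- paste("antecedent", "consequent", "support", "support_ante",
                  "support_cons", "n_reports", "confidence", "rr", sep = "\t")
  body <- character(0)
  if (nrow(rules) > 0) {
    body <- vapply(seq_len(nrow(rules)), function(i) {
      paste(
        paste(rules$antecedent[[i]], collapse = ","),
        paste(rules$consequent[[i]], collapse = ","),
        rules$support_joint[i], rules$support_ante[i], rules$support_cons[i],
        rules$n_reports[i],
        format(signif(rules$confidence[i], 4), scientific = FALSE),
        format(signif(rules$rr[i], 4), scientific = FALSE),
        sep = "\t")
    }, character(1))
  }
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) stop("cannot write rules to ", path, call. = FALSE))
  on.exit(close(con))
  writeLines(c(header, body), con, useBytes = TRUE)
  invisible(path)
}
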
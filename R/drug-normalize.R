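#' Deterministic drug-string cleanup
#'
#' Verbatim drug strings in spontaneous reports come in many formats:
#' brand names with the salt in parentheses, manufacturer annotations
#' between slashes, trailing dose or dosage-form phrases, inconsistent
#' case and spacing. `clean_drug_string()` reduces such strings to a bare
#' name by a fixed, idempotent sequence of rules:
#'
#' 1. uppercase,
#' 2. remove slash-delimited annotations `/.../`,
#' 3. remove parenthesized qualifiers `(...)` (repeatedly, innermost
#'    first),
#' 4. strip trailing dose/form tokens (numbers and unit words such as
#'    `MG`, `MILLIGRAM`, `TABLETS`; see `dose_form_tokens()`),
#' 5. collapse whitespace and trim.
#'
#' If nothing remains after cleanup the raw string (uppercased,
#' whitespace-collapsed) is kept and a warning is raised, so the result is
#' always a non-empty identifier.
#'
#' @param raw Character vector of verbatim drug strings.
#' @param dose_tokens Character vector of unit/form words stripped from
#'   the tail; defaults to `dose_form_tokens()`.
#' @return Character vector of cleaned names, same length as `raw`.
#' @examples
#' clean_drug_string("AVANDIA /SCH/ (ROSIGLITAZONE MALEATE)")
#' clean_drug_string("  avandia  ")
#' @export
clean_drug_string <- function(raw, dose_tokens = dose_form_tokens()) {
  stopifnot(is.character(raw))
  out <- toupper(raw)
  # slash annotations before parens so "/X (Y)/" goes in one piece
  out <- gsub("/[^/]*/", " ", out)
  # innermost parenthesized groups, repeated to handle nesting
  repeat {
    nxt <- gsub("\\([^()]*\\)", " ", out)
    if (identical(nxt, out)) break
    out <- nxt
  }
  out <- gsub("[[:space:]]+", " ", trimws(out))
  out <- strip_trailing_dose(out, dose_tokens)
  empty <- !nzchar(out)
  if (any(empty)) {
    warning(sprintf("%d drug string(s) empty after cleanup; raw value kept",
                    sum(empty)), call. = FALSE)
    out[empty] <- gsub("[[:space:]]+", " ", trimws(toupper(raw[empty])))
  }
  out
}

# Remove trailing tokens that are numbers (possibly with punctuation) or
# dose/form words, e.g. "DRUG 2 MILLIGRAM TABLETS" -> "DRUG".
strip_trailing_dose <- function(x, dose_tokens) {
  num_re <- "^[0-9]+([.,][0-9]+)?$"
  unit_re <- paste0("^(", paste(dose_tokens, collapse = "|"), ")$")
  vapply(x, function(s) {
    toks <- strsplit(s, " ", fixed = TRUE)[[1]]
    while (length(toks) > 1) {
      last <- toks[length(toks)]
      if (grepl(num_re, last) || grepl(unit_re, last)) {
        toks <- toks[-length(toks)]
      } else break
    }
    # an all-dose string ("5 MG") reduces to its first token only if that
    # token is itself a name; otherwise signal emptiness
    if (length(toks) == 1 &&
        (grepl(num_re, toks) || grepl(unit_re, toks))) return("")
    paste(toks, collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

#' @rdname clean_drug_string
#' @export
dose_form_tokens <- function() {
  c("MG", "MILLIGRAM", "MILLIGRAMS", "MCG", "MICROGRAM", "MICROGRAMS",
    "G", "GRAM", "GRAMS", "KG", "ML", "MILLILITER", "MILLILITERS",
    "TABLET", "TABLETS", "TAB", "TABS", "CAPSULE", "CAPSULES", "CAP",
    "CAPS", "INJECTION", "INJECTABLE", "SOLUTION", "SUSPENSION", "SYRUP",
    "CREAM", "OINTMENT", "PATCH", "ORAL", "IV", "TOPICAL", "DOSE",
    "DOSES", "UNIT", "UNITS", "IU")
}

#' Brand-to-generic drug mapping table
#'
#' A `drug_map` is a lookup from cleaned drug strings to canonical generic
#' identifiers, the table-driven counterpart of mapping coded brand names
#' to their generic ingredient. Keys must already be in cleaned form
#' (applying [clean_drug_string()] to a key is a no-op); the loader
#' enforces this. A generic may map to itself.
#'
#' @param keys Character vector of cleaned drug strings.
#' @param values Character vector of generic identifiers (non-empty).
#' @return A named character vector of class `drug_map`.
#' @export
drug_map <- function(keys = character(), values = character()) {
  stopifnot(length(keys) == length(values))
  keys <- normalize_token(as.character(keys))
  values <- normalize_token(as.character(values))
  recleaned <- suppressWarnings(clean_drug_string(keys))
  if (any(recleaned != keys)) {
    bad <- keys[recleaned != keys]
    stop("drug_map keys must be in cleaned form; offending key(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(values))) stop("drug_map values must be non-empty", call. = FALSE)
  keep <- !duplicated(keys)
  out <- stats::setNames(values[keep], keys[keep])
  class(out) <- "drug_map"
  out
}

#' @rdname drug_map
#' @param path Path to a two-column TSV (cleaned name, generic id), no
#'   header required; a `name<TAB>generic` header line is tolerated.
#' @export
read_drug_map <- function(path) {
  if (!file.exists(path)) stop("cannot read drug map: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && grepl("^name\t", lines[1], ignore.case = TRUE)) {
    lines <- lines[-1L]
  }
  if (length(lines) == 0) return(drug_map())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2)) {
    stop("drug map must have two tab-separated columns on every line",
         call. = FALSE)
  }
  drug_map(vapply(parts, `[`, character(1), 1),
           vapply(parts, `[`, character(1), 2))
}

#' Map a cleaned drug string to its generic identifier
#'
#' Returns the mapped generic when the table has an entry; otherwise
#' returns the cleaned string unchanged (an unmappable name is left as
#' is). Total: never errors on a miss.
#'
#' @param cleaned Character vector of cleaned drug strings.
#' @param map A [drug_map()].
#' @return Character vector of generic identifiers.
#' @export
map_to_generic <- function(cleaned, map) {
  stopifnot(inherits(map, "drug_map"))
  hit <- match(cleaned, names(map))
  out <- cleaned
  out[!is.na(hit)] <- unclass(map)[hit[!is.na(hit)]]
  out
}

#' Normalize every drug name in a corpus
#'
#' Applies [clean_drug_string()] then [map_to_generic()] to every drug
#' item of every report and re-collapses drug sets, so distinct verbatim
#' strings that name the same generic become a single item. Event items
#' are already case/whitespace normalized at ingestion and are not
#' otherwise touched. The reduction in distinct drug names is attached as
#' attribute `name_reduction` (`n_raw`, `n_normalized`) and can be
#' printed from the pipeline summary. Idempotent: normalizing twice gives
#' the corpus of normalizing once.
#'
#' @param corpus An `srs_corpus`.
#' @param map A [drug_map()]; the empty map gives cleanup-only behavior.
#' @return The normalized `srs_corpus`.
#' @export
normalize_reports <- function(corpus, map = drug_map()) {
  stopifnot(inherits(corpus, "srs_corpus"), inherits(map, "drug_map"))
  raw_names <- unique(unlist(corpus$reports$drugs))
  lut <- map_to_generic(suppressWarnings(clean_drug_string(raw_names)), map)
  names(lut) <- raw_names
  roles_old <- corpus$reports$roles
  corpus$reports$drugs <- lapply(corpus$reports$drugs, function(d) {
    sort_items_chr(unname(lut[d]))
  })
  # carry roles over to the normalized names (first role wins on collapse)
  corpus$reports$roles <- lapply(roles_old, function(r) {
    if (length(r) == 0) return(r)
    nm <- unname(lut[names(r)])
    nm[is.na(nm)] <- names(r)[is.na(nm)]
    keep <- !duplicated(nm)
    stats::setNames(unname(r)[keep], nm[keep])
  })
  attr(corpus, "name_reduction") <- c(
    n_raw = length(raw_names),
    n_normalized = length(unique(unlist(corpus$reports$drugs)))
  )
  corpus
}
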
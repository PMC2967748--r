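#' Typed items: drugs and adverse-event terms
#'
#' Reports in a spontaneous reporting system carry two kinds of items:
#' drug names and coded adverse-event (AE) terms. Internally an item is a
#' single string with a one-letter kind tag (`"D:"` for drugs, `"E:"` for
#' events) followed by the canonical identifier, which is uppercased and
#' whitespace-collapsed. The tag gives items a total order -- all drugs
#' before all events, lexicographic within a kind -- which the miner relies
#' on for deterministic candidate generation.
#'
#' @param id Character vector of item identifiers (non-empty after
#'   normalization).
#' @param kind Either `"DRUG"` or `"EVENT"` (recycled along `id`).
#' @return `ade_item()` returns the encoded item key(s); `item_kind()` and
#'   `item_id()` invert the encoding; `sort_items()` sorts a character
#'   vector of item keys in the canonical (kind, id) order.
#' @examples
#' ade_item(c("aspirin", "nausea"), c("DRUG", "EVENT"))
#' item_id(ade_item("ASPIRIN", "DRUG"))
#' @export
ade_item <- function(id, kind = c("DRUG", "EVENT")) {
  kind <- match.arg(kind, several.ok = TRUE)
  id <- normalize_token(id)
  if (any(!nzchar(id) | is.na(id))) {
    stop("item identifiers must be non-empty after normalization", call. = FALSE)
  }
  paste0(ifelse(rep_len(kind, length(id)) == "DRUG", "D:", "E:"), id)
}

#' @rdname ade_item
#' @param item Character vector of encoded item keys.
#' @export
item_kind <- function(item) {
  ifelse(startsWith(item, "D:"), "DRUG", "EVENT")
}

#' @rdname ade_item
#' @export
item_id <- function(item) {
  substr(item, 3L, nchar(item))
}

#' @rdname ade_item
#' @export
sort_items <- function(item) {
  # radix sort is locale-independent, so the (kind, id) order is stable
  # across platforms
  sort(unique(item), method = "radix")
}

# Uppercase and collapse internal whitespace; used for both drug and event
# identifiers at ingestion.
normalize_token <- function(x) {
  x <- toupper(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

# Canonical scalar key for an itemset (sorted item vector) used in the
# support tables of the miner.
itemset_key <- function(items) {
  paste(items, collapse = "\x1f")
}

key_to_items <- function(key) {
  strsplit(key, "\x1f", fixed = TRUE)
}
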
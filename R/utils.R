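#' @importFrom rlang .data .env
#' @importFrom dplyr %>%
NULL

#' Normalize a term string for dictionary matching
#'
#' Lower-cases, strips punctuation at token boundaries and collapses internal
#' whitespace by reducing the string to its alphanumeric tokens joined by a
#' single space. Matching in the tagger is performed on the same token stream,
#' so a normalized term matches text irrespective of case, hyphenation or
#' spacing.
#'
#' @param x Character vector of raw terms.
#' @param keep_case Logical vector (recycled); entries with `TRUE` keep their
#'   original case (used for short all-uppercase gene symbols, which are
#'   matched case-sensitively).
#' @return Character vector of normalized terms. Terms with no alphanumeric
#'   content normalize to `""`.
#' @examples
#' normalize_term(c("Brain  inflammation", "beta-2 microglobulin"))
#' @export
normalize_term <- function(x, keep_case = FALSE) {
  keep_case <- rep_len(keep_case, length(x))
  toks <- stringr::str_extract_all(x, "[A-Za-z0-9]+")
  out <- vapply(toks, paste, character(1), collapse = " ")
  ifelse(keep_case, out, stringr::str_to_lower(out))
}

#' Is a term gene-symbol-like (short, all-uppercase)?
#'
#' Such terms (for example abbreviations like "GCL") are matched
#' case-sensitively to limit false positives from common-word abbreviations.
#'
#' @param x Character vector of raw terms.
#' @param max_len Maximum length (characters) for the case-sensitive rule.
#' @return Logical vector.
#' @keywords internal
is_symbol_like <- function(x, max_len = 5L) {
  stringr::str_detect(x, "^[A-Z][A-Z0-9]*$") & nchar(x) <= max_len
}

# Union-find with path compression over character ids.
# Returns a named character vector: id -> canonical (lexicographically
# smallest member of its group).
uf_merge <- function(ids, pairs) {
  parent <- stats::setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  if (nrow(pairs)) {
    for (i in seq_len(nrow(pairs))) {
      ra <- find(pairs[[1L]][i]); rb <- find(pairs[[2L]][i])
      if (ra != rb) {
        keep <- if (ra < rb) ra else rb
        drop <- if (ra < rb) rb else ra
        parent[[drop]] <- keep
      }
    }
  }
  vapply(ids, find, character(1))
}

utils::globalVariables(".")
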
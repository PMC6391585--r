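#' Dictionary (lexicon) objects
#'
#' A `phenomine_lexicon` maps normalized surface terms to the entity ids they
#' can refer to — gene entities for the gene dictionary, ontology classes for
#' the phenotype dictionary. Dictionaries are refined before use: terms
#' shorter than three characters and terms that collide with common English
#' words are rejected (the rejected terms are retained in the `stoplist`
#' field for audit). Ambiguous terms that survive refinement keep all their
#' entity ids; disambiguation is deferred to the co-occurrence statistics,
#' which a large corpus makes robust to sporadic mis-hits.
#'
#' Matching is case-insensitive, with one exception in the gene dictionary:
#' terms that are all-uppercase and at most five characters long
#' (abbreviation-like symbols such as "GCL") are matched case-sensitively,
#' which removes a class of common-word abbreviation false positives.
#'
#' @section Structure:
#' A list with elements
#' \describe{
#'   \item{entries}{tibble `term`, `entity_id`, `case_sensitive`, `n_tokens`.}
#'   \item{kind}{`"gene"` or `"phenotype"`.}
#'   \item{stoplist}{character vector of terms rejected during refinement.}
#'   \item{members}{tibble `entity_id`, `member_id` (gene lexicons only):
#'     the ortholog-merge partition of original gene ids.}
#' }
#' @name phenomine_lexicon
NULL

new_lexicon <- function(entries, kind, stoplist,
                        members = tibble::tibble(entity_id = character(0),
                                                 member_id = character(0))) {
  entries <- entries %>%
    dplyr::mutate(n_tokens = stringr::str_count(.data$term, stringr::fixed(" ")) + 1L) %>%
    dplyr::distinct(.data$term, .data$entity_id, .keep_all = TRUE) %>%
    dplyr::arrange(.data$term, .data$entity_id)
  structure(list(entries = entries, kind = kind,
                 stoplist = sort(unique(stoplist)), members = members),
            class = "phenomine_lexicon")
}

#' @export
print.phenomine_lexicon <- function(x, ...) {
  cat(sprintf("<phenomine_lexicon: %s> %d terms -> %d entities (%d rejected)\n",
              x$kind, dplyr::n_distinct(x$entries$term),
              dplyr::n_distinct(x$entries$entity_id), length(x$stoplist)))
  invisible(x)
}

#' Default common-English stoplist
#'
#' Terms colliding with everyday English words ("she", "was", "can", ...)
#' would fire on nearly every sentence, so they are removed from the
#' dictionaries. The packaged list holds several hundred high-frequency
#' English words, one per line; pass your own file to extend or replace it.
#'
#' @param path Path to a stoplist file (one lowercase word per line).
#'   Defaults to the packaged list.
#' @return Character vector of stop words.
#' @export
default_stoplist <- function(path = system.file("extdata", "stoplist_en.txt",
                                                package = "phenomine")) {
  readr::read_lines(path, progress = FALSE)
}

# shared refinement: returns list(keep = entries tibble, rejected = chr)
refine_terms <- function(entries, stoplist, min_chars = 3L) {
  entries <- dplyr::filter(entries, nzchar(.data$term))
  bad <- nchar(entries$term) < min_chars |
    stringr::str_to_lower(entries$term) %in% stoplist
  list(keep = entries[!bad, , drop = FALSE],
       rejected = unique(entries$term[bad]))
}

#' Build a refined gene dictionary
#'
#' Collects symbols and synonyms per gene, normalizes them, applies the
#' length and common-word filters, and (optionally) collapses ortholog pairs
#' — e.g. a mouse MGI id and its human Entrez counterpart — into one merged
#' gene entity whose id is the lexicographically smallest member id.
#'
#' @param genes Tibble with columns `gene_id`, `symbol`, `synonyms`
#'   (pipe-separated, may be `NA`/empty); see [read_gene_table()].
#' @param orthologs Optional two-column tibble of gene-id pairs to merge
#'   (e.g. human-mouse orthologs). `NULL` keeps every id separate.
#' @param stoplist Character vector of common-English words to reject.
#' @param min_chars Minimum term length; shorter terms are rejected.
#' @return A [phenomine_lexicon] of kind `"gene"`.
#' @export
build_gene_lexicon <- function(genes, orthologs = NULL,
                               stoplist = default_stoplist(),
                               min_chars = 3L) {
  stopifnot(all(c("gene_id", "symbol") %in% names(genes)))
  if (!"synonyms" %in% names(genes)) genes$synonyms <- NA_character_
  conflicts <- genes %>%
    dplyr::distinct(.data$gene_id, .data$symbol) %>%
    dplyr::count(.data$gene_id) %>%
    dplyr::filter(.data$n > 1L)
  if (nrow(conflicts)) {
    stop("conflicting symbols for gene id(s): ",
         paste(conflicts$gene_id, collapse = ", "), call. = FALSE)
  }

  ids <- unique(genes$gene_id)
  if (!is.null(orthologs) && nrow(orthologs)) {
    pairs <- tibble::tibble(a = as.character(orthologs[[1L]]),
                            b = as.character(orthologs[[2L]]))
    canon <- uf_merge(unique(c(ids, pairs$a, pairs$b)), pairs)
  } else {
    canon <- stats::setNames(ids, ids)
  }
  members <- tibble::tibble(entity_id = unname(canon), member_id = names(canon))

  raw <- genes %>%
    dplyr::mutate(entity_id = unname(canon[.data$gene_id])) %>%
    dplyr::mutate(syn = stringr::str_split(dplyr::coalesce(.data$synonyms, ""),
                                           stringr::fixed("|"))) %>%
    tidyr::unnest("syn") %>%
    tidyr::pivot_longer(c("symbol", "syn"), values_to = "raw") %>%
    dplyr::filter(nzchar(.data$raw)) %>%
    dplyr::transmute(
      .data$entity_id,
      case_sensitive = is_symbol_like(.data$raw),
      term = normalize_term(.data$raw, keep_case = .data$case_sensitive)
    )

  ref <- refine_terms(dplyr::distinct(raw), stoplist, min_chars)
  new_lexicon(ref$keep, "gene", ref$rejected, members = members)
}

#' Read a gene-name table from TSV
#'
#' Expected layout: `gene_id<TAB>symbol<TAB>synonym1|synonym2|...`, no
#' header; the synonym column may be absent or empty.
#'
#' @param path Path to the TSV file.
#' @return Tibble with columns `gene_id`, `symbol`, `synonyms`.
#' @export
read_gene_table <- function(path) {
  tb <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (ncol(tb) < 2L) stop("gene table needs at least gene_id and symbol columns",
                          call. = FALSE)
  if (ncol(tb) == 2L) tb$X3 <- NA_character_
  stats::setNames(tb[, 1:3], c("gene_id", "symbol", "synonyms"))
}

#' Build a refined phenotype dictionary
#'
#' Every class's own labels and synonyms (not the propagated term sets) are
#' normalized and refined; each surviving term maps to the set of
#' most-specific classes whose own labels or synonyms contain it.
#' Propagation to ancestor classes happens at co-occurrence counting time,
#' not in the dictionary, so a term is always normalized to the most
#' specific class it names.
#'
#' @param ontology A [phenomine_ontology].
#' @param stoplist,min_chars As in [build_gene_lexicon()].
#' @return A [phenomine_lexicon] of kind `"phenotype"`.
#' @export
build_phenotype_lexicon <- function(ontology, stoplist = default_stoplist(),
                                    min_chars = 3L) {
  stopifnot(inherits(ontology, "phenomine_ontology"))
  own <- dplyr::bind_rows(
    dplyr::transmute(ontology$classes, entity_id = .data$class_id, raw = .data$label),
    dplyr::transmute(ontology$synonyms, entity_id = .data$class_id, raw = .data$synonym)
  ) %>%
    dplyr::transmute(.data$entity_id, case_sensitive = FALSE,
                     term = normalize_term(.data$raw)) %>%
    dplyr::distinct()
  ref <- refine_terms(own, stoplist, min_chars)
  new_lexicon(ref$keep, "phenotype", ref$rejected)
}

#' Write / read a lexicon dump
#'
#' TSV layout: `term<TAB>kind<TAB>id1,id2,...` — one row per term, entity
#' ids comma-joined and sorted. Reading reconstructs an equivalent lexicon
#' (the rejected-term audit trail is not serialized).
#'
#' @param lexicon A [phenomine_lexicon].
#' @param path File path.
#' @return `write_lexicon()` returns `path` invisibly; `read_lexicon()`
#'   returns a [phenomine_lexicon].
#' @export
write_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "phenomine_lexicon"))
  lexicon$entries %>%
    dplyr::group_by(.data$term) %>%
    dplyr::summarise(ids = paste(sort(.data$entity_id), collapse = ","),
                     .groups = "drop") %>%
    dplyr::mutate(kind = lexicon$kind, .after = "term") %>%
    readr::write_tsv(path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_lexicon
#' @export
read_lexicon <- function(path) {
  tb <- readr::read_tsv(path, col_names = c("term", "kind", "ids"),
                        col_types = "ccc", progress = FALSE)
  entries <- tb %>%
    dplyr::mutate(entity_id = stringr::str_split(.data$ids, stringr::fixed(","))) %>%
    tidyr::unnest("entity_id") %>%
    dplyr::transmute(.data$term, case_sensitive = is_symbol_like(.data$term),
                     .data$entity_id)
  kind <- if (nrow(tb)) tb$kind[[1L]] else "gene"
  new_lexicon(entries, kind, character(0))
}
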
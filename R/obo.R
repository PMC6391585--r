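#' Phenotype ontology objects
#'
#' A `phenomine_ontology` holds the class hierarchy of a phenotype ontology
#' after equivalence merging: every class that was declared equivalent to
#' another (via `equivalent_to` or `xref` lines) is collapsed into one merged
#' node whose id is the lexicographically smallest member id, and the `is_a`
#' graph over merged nodes must be acyclic. Mentions of a subclass count as
#' mentions of every superclass, so the reflexive transitive closure of
#' `is_a` is precomputed once and reused by the term-set builder, the
#' co-occurrence counter and the semantic-similarity code.
#'
#' @section Structure:
#' A list with tibbles
#' \describe{
#'   \item{classes}{`class_id`, `label` — one primary label per merged node.}
#'   \item{synonyms}{`class_id`, `synonym` — may be empty.}
#'   \item{edges}{`class_id`, `parent_id` — direct `is_a` over merged nodes.}
#'   \item{members}{`class_id`, `member_id` — the equivalence partition;
#'     every original id occurs exactly once as a `member_id`.}
#'   \item{ancestors}{`class_id`, `ancestor_id` — reflexive transitive
#'     closure of `is_a`.}
#' }
#'
#' @name phenomine_ontology
NULL

new_ontology <- function(classes, synonyms, edges, members) {
  anc <- compute_ancestors(classes$class_id, edges)
  structure(
    list(classes = classes, synonyms = synonyms, edges = edges,
         members = members, ancestors = anc),
    class = "phenomine_ontology"
  )
}

#' @export
print.phenomine_ontology <- function(x, ...) {
  cat(sprintf(
    "<phenomine_ontology> %d classes (%d original ids), %d is_a edges, %d synonyms\n",
    nrow(x$classes), nrow(x$members), nrow(x$edges), nrow(x$synonyms)))
  invisible(x)
}

# Topological-order ancestor closure. Errors with the offending cycle if the
# merged is_a graph is not a DAG.
compute_ancestors <- function(ids, edges) {
  parents <- split(edges$parent_id, factor(edges$class_id, levels = ids))
  indeg_of <- table(factor(edges$parent_id, levels = ids))
  # Kahn's algorithm from the roots downward: process a class once all of its
  # parents are processed, i.e. traverse edges child -> parent reversed.
  children <- split(edges$class_id, factor(edges$parent_id, levels = ids))
  n_par <- lengths(parents)
  order <- character(0)
  queue <- ids[n_par == 0L]
  remaining <- n_par
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    order <- c(order, v)
    for (ch in children[[v]]) {
      remaining[[ch]] <- remaining[[ch]] - 1L
      if (remaining[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < length(ids)) {
    cyc <- setdiff(ids, order)
    stop("is_a graph is cyclic after equivalence merging; classes on a cycle: ",
         paste(sort(cyc), collapse = ", "), call. = FALSE)
  }
  anc <- vector("list", length(ids))
  names(anc) <- ids
  for (v in order) {
    up <- unlist(anc[parents[[v]]], use.names = FALSE)
    anc[[v]] <- unique(c(v, up))
  }
  tibble::tibble(
    class_id = rep(names(anc), lengths(anc)),
    ancestor_id = unlist(anc, use.names = FALSE)
  )
}

#' Read a phenotype ontology from an OBO flat file
#'
#' Parses the OBO 1.2 subset used by phenotype ontologies: `[Term]` stanzas
#' with `id`, `name`, `synonym`, `is_a`, `xref`, `equivalent_to` and
#' `is_obsolete` tags. Obsolete terms are dropped. Cross-ontology equivalence
#' (`equivalent_to` or `xref` lines pointing at another class) merges both
#' ids into a single node, so that e.g. an MP class and its equivalent HP
#' class contribute one shared pool of labels and one position in the
#' hierarchy. `[Typedef]` stanzas and relationship types other than `is_a`
#' are ignored.
#'
#' @param path Path to an OBO flat file.
#' @return A [phenomine_ontology] object.
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c(
#'   "[Term]", "id: X:1", "name: root", "",
#'   "[Term]", "id: X:2", "name: leaf", "is_a: X:1 ! root"), obo)
#' read_obo(obo)
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) stop("OBO file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s+$", "", lines)

  # stanza boundaries
  starts <- grep("^\\[", lines)
  recs <- list()
  for (k in seq_along(starts)) {
    from <- starts[k]
    to <- if (k < length(starts)) starts[k + 1L] - 1L else length(lines)
    if (lines[from] != "[Term]") next
    body_idx <- (from + 1L):to
    body_idx <- body_idx[nzchar(lines[body_idx]) & !startsWith(lines[body_idx], "!")]
    bad <- body_idx[!grepl("^[A-Za-z_]+\\s*:", lines[body_idx])]
    if (length(bad)) {
      stop(sprintf("malformed OBO stanza line %d: '%s'", bad[1L], lines[bad[1L]]),
           call. = FALSE)
    }
    keys <- sub("^([A-Za-z_]+)\\s*:.*$", "\\1", lines[body_idx])
    vals <- sub("^[A-Za-z_]+\\s*:\\s*", "", lines[body_idx])
    id <- vals[keys == "id"][1L]
    if (is.na(id) || !nzchar(id)) {
      stop(sprintf("malformed OBO stanza at line %d: missing id", from),
           call. = FALSE)
    }
    recs[[length(recs) + 1L]] <- list(
      id = id,
      name = vals[keys == "name"][1L],
      synonyms = parse_synonym(vals[keys == "synonym"]),
      is_a = sub("\\s*!.*$", "", vals[keys == "is_a"]),
      equiv = sub("\\s*!.*$", "", vals[keys %in% c("xref", "equivalent_to")]),
      obsolete = any(keys == "is_obsolete" &
                       stringr::str_detect(vals, stringr::fixed("true")))
    )
  }
  recs <- purrr::discard(recs, "obsolete")
  build_ontology(recs)
}

# synonym: "some text" EXACT [] -> some text; bare values pass through
parse_synonym <- function(x) {
  if (!length(x)) return(character(0))
  quoted <- stringr::str_match(x, '^"(.*?)"')[, 2L]
  ifelse(is.na(quoted), x, quoted)
}

# Assemble the merged graph from parsed stanza records.
build_ontology <- function(recs) {
  if (!length(recs)) {
    return(new_ontology(
      tibble::tibble(class_id = character(0), label = character(0)),
      tibble::tibble(class_id = character(0), synonym = character(0)),
      tibble::tibble(class_id = character(0), parent_id = character(0)),
      tibble::tibble(class_id = character(0), member_id = character(0))))
  }
  ids <- vapply(recs, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate [Term] id: ", ids[duplicated(ids)][1L], call. = FALSE)
  }
  names(recs) <- ids

  equiv_pairs <- purrr::map_dfr(recs, function(r) {
    if (!length(r$equiv)) return(NULL)
    tibble::tibble(a = r$id, b = r$equiv)
  })
  # xref/equivalent_to targets without a stanza of their own still become
  # members (aliases) of the merged node, so either id resolves to it
  alias <- if (nrow(equiv_pairs)) setdiff(unique(equiv_pairs$b), ids) else character(0)
  canon <- uf_merge(c(ids, alias), if (nrow(equiv_pairs)) equiv_pairs else
                           tibble::tibble(a = character(0), b = character(0)))

  members <- tibble::tibble(class_id = unname(canon), member_id = names(canon))

  classes <- members %>%
    dplyr::distinct(.data$class_id) %>%
    dplyr::mutate(label = purrr::map_chr(.data$class_id, function(cid) {
      mem <- sort(members$member_id[members$class_id == cid])
      labs <- purrr::compact(purrr::map(mem, ~ recs[[.x]]$name))
      labs <- purrr::discard(unlist(labs), is.na)
      if (length(labs)) labs[[1L]] else cid
    })) %>%
    dplyr::arrange(.data$class_id)

  # a merged member's own primary label becomes a synonym of the node
  # unless it is the node's label
  synonyms <- purrr::map_dfr(recs, function(r) {
    tibble::tibble(class_id = canon[[r$id]],
                   synonym = c(r$synonyms, if (!is.na(r$name)) r$name else character(0)))
  }) %>%
    dplyr::anti_join(dplyr::rename(classes, synonym = "label"),
                     by = c("class_id", "synonym")) %>%
    dplyr::distinct()

  edges <- purrr::map_dfr(recs, function(r) {
    if (!length(r$is_a)) return(NULL)
    tibble::tibble(class_id = canon[[r$id]],
                   parent_id = unname(canon[r$is_a]))
  })
  if (nrow(edges)) {
    unknown <- edges$parent_id[is.na(edges$parent_id)]
    if (length(unknown)) {
      # is_a pointing outside the file: drop silently (partial extracts)
      edges <- edges[!is.na(edges$parent_id), ]
    }
    edges <- edges %>%
      dplyr::filter(.data$class_id != .data$parent_id) %>%
      dplyr::distinct()
  } else {
    edges <- tibble::tibble(class_id = character(0), parent_id = character(0))
  }

  new_ontology(classes, synonyms, edges, members)
}

#' Map original class ids to their merged node
#'
#' @param ontology A [phenomine_ontology].
#' @param ids Character vector of class ids (original or merged).
#' @return Character vector of merged (canonical) class ids; `NA` for ids the
#'   ontology does not contain.
#' @export
resolve_class <- function(ontology, ids) {
  stopifnot(inherits(ontology, "phenomine_ontology"))
  map <- stats::setNames(ontology$members$class_id, ontology$members$member_id)
  unname(map[ids])
}

#' Descendants and ancestors of an ontology class
#'
#' Both closures are reflexive: a class is its own descendant and ancestor.
#' `descendants()` implements the propagation rule that every mention of a
#' subclass is a mention of its superclasses, read downward: the classes
#' whose labels and synonyms all refer to `class_id`.
#'
#' @param ontology A [phenomine_ontology].
#' @param class_id A single class id (original ids are resolved to their
#'   merged node).
#' @return Character vector of merged class ids.
#' @export
descendants <- function(ontology, class_id) {
  cid <- resolve_one(ontology, class_id)
  sort(ontology$ancestors$class_id[ontology$ancestors$ancestor_id == cid])
}

#' @rdname descendants
#' @export
ancestors <- function(ontology, class_id) {
  cid <- resolve_one(ontology, class_id)
  sort(ontology$ancestors$ancestor_id[ontology$ancestors$class_id == cid])
}

resolve_one <- function(ontology, class_id) {
  stopifnot(length(class_id) == 1L)
  cid <- resolve_class(ontology, class_id)
  if (is.na(cid)) stop("unknown class id: ", class_id, call. = FALSE)
  cid
}

#' Build propagated term sets for every ontology class
#'
#' The term set of a class C collects the normalized labels and synonyms of C
#' and of every subclass of C, so that any term referring to a more specific
#' phenotype also signals the more general one. Term sets grow monotonically
#' up the hierarchy: if S is a subclass of C then `Terms(S)` is a subset of
#' `Terms(C)`.
#'
#' @param ontology A [phenomine_ontology].
#' @return A tibble with columns `class_id`, `term` (normalized, distinct
#'   within class). Terms that normalize to the empty string are dropped.
#' @export
term_sets <- function(ontology) {
  stopifnot(inherits(ontology, "phenomine_ontology"))
  own <- dplyr::bind_rows(
    dplyr::transmute(ontology$classes, class_id = .data$class_id, term = .data$label),
    dplyr::transmute(ontology$synonyms, class_id = .data$class_id, term = .data$synonym)
  ) %>%
    dplyr::mutate(term = normalize_term(.data$term)) %>%
    dplyr::filter(nzchar(.data$term)) %>%
    dplyr::distinct()

  # propagate: Terms(C) = union of own terms over descendants(C)
  ontology$ancestors %>%
    dplyr::inner_join(own, by = "class_id",
                      relationship = "many-to-many") %>%
    dplyr::distinct(class_id = .data$ancestor_id, .data$term) %>%
    dplyr::arrange(.data$class_id, .data$term)
}

#' Write term sets to TSV
#'
#' One row per (class, term): `class_id<TAB>term`.
#'
#' @param sets Tibble as returned by [term_sets()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_term_sets <- function(sets, path) {
  readr::write_tsv(sets, path, col_names = FALSE)
  invisible(path)
}
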
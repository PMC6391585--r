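#' Count ontology-propagated sentence co-occurrences
#'
#' Aggregates tagged mentions into the four counters behind the NPMI score:
#' the total number of sentences `n_tot`, per-gene sentence counts `n_G`,
#' per-phenotype-class sentence counts `n_D`, and per-pair counts `n_GD`.
#' Phenotype mentions are propagated upward before counting: a sentence
#' mentioning a class counts as mentioning every ancestor of that class, so
#' associations can be detected at all levels of the ontology. All counters
#' use sentence-set semantics — a sentence contributes at most 1 to any
#' counter no matter how often an entity is mentioned in it.
#'
#' @param mentions Mention tibble from [tag_sentences()].
#' @param sentences Either the sentence tibble the mentions came from, or a
#'   single integer giving the total number of sentences in the corpus.
#' @param ontology A [phenomine_ontology] used for upward propagation.
#' @return A `phenomine_cooccurrence` object: a list with `n_tot`, tibbles
#'   `genes` (`gene_id`, `n`), `phenotypes` (`class_id`, `n`), `pairs`
#'   (`gene_id`, `class_id`, `n`), and `unknown` (`class_id`, `n`) for
#'   mention classes absent from the ontology (these are reported with a
#'   warning and excluded from propagation, never silently dropped).
#' @export
count_cooccurrences <- function(mentions, sentences, ontology) {
  stopifnot(inherits(ontology, "phenomine_ontology"))
  n_tot <- if (is.data.frame(sentences)) nrow(sentences) else as.integer(sentences)
  stopifnot(n_tot >= 1L)

  mm <- mentions %>%
    dplyr::mutate(sent = paste(.data$doc_id, .data$sentence_index, sep = "\r"))

  g_sent <- mm %>%
    dplyr::filter(.data$kind == "gene") %>%
    dplyr::distinct(.data$sent, gene_id = .data$entity_id)

  p_raw <- mm %>%
    dplyr::filter(.data$kind == "phenotype") %>%
    dplyr::distinct(.data$sent, class_id = .data$entity_id) %>%
    dplyr::mutate(resolved = resolve_class(ontology, .data$class_id))
  unknown <- p_raw %>%
    dplyr::filter(is.na(.data$resolved)) %>%
    dplyr::count(.data$class_id, name = "n")
  if (nrow(unknown)) {
    warning(sprintf("%d phenotype mention class(es) not in ontology: %s",
                    nrow(unknown), paste(utils::head(unknown$class_id, 5L),
                                         collapse = ", ")), call. = FALSE)
  }
  p_sent <- p_raw %>%
    dplyr::filter(!is.na(.data$resolved)) %>%
    dplyr::inner_join(ontology$ancestors, by = c(resolved = "class_id"),
                      relationship = "many-to-many") %>%
    dplyr::distinct(.data$sent, class_id = .data$ancestor_id)

  structure(list(
    n_tot = n_tot,
    genes = dplyr::count(g_sent, .data$gene_id, name = "n"),
    phenotypes = dplyr::count(p_sent, .data$class_id, name = "n"),
    pairs = g_sent %>%
      dplyr::inner_join(p_sent, by = "sent", relationship = "many-to-many") %>%
      dplyr::count(.data$gene_id, .data$class_id, name = "n"),
    unknown = unknown
  ), class = "phenomine_cooccurrence")
}

#' @export
print.phenomine_cooccurrence <- function(x, ...) {
  cat(sprintf(
    "<phenomine_cooccurrence> %d sentences, %d genes, %d classes, %d co-mentioned pairs\n",
    x$n_tot, nrow(x$genes), nrow(x$phenotypes), nrow(x$pairs)))
  invisible(x)
}

#' Normalized pointwise mutual information of a co-mention
#'
#' `npmi_value()` evaluates
#' \deqn{npmi(G,D) = \frac{\log\frac{n_{GD}\, n_{tot}}{n_G\, n_D}}
#'                       {-\log\frac{n_{GD}}{n_{tot}}}}
#' elementwise; `npmi()` looks the counts up in a co-occurrence store.
#' The value lies in \eqn{[-1, 1]}: 1 for perfect co-occurrence
#' (\eqn{n_{GD}=n_G=n_D}), 0 at exact independence. When
#' \eqn{n_{GD}=n_{tot}} the denominator vanishes and the limit value 1 is
#' returned. Pairs that never co-occur (\eqn{n_{GD}=0}) have no defined
#' score and raise an error.
#'
#' @param n_gd,n_g,n_d Sentence counts for the pair and the two marginals.
#' @param n_tot Total number of sentences.
#' @return Numeric vector of NPMI values in `[-1, 1]`.
#' @examples
#' npmi_value(10, 10, 10, 100)  # 1: perfect co-occurrence
#' npmi_value(1, 10, 10, 100)   # 0: exact independence
#' @export
npmi_value <- function(n_gd, n_g, n_d, n_tot) {
  n_gd <- as.numeric(n_gd); n_g <- as.numeric(n_g)
  n_d <- as.numeric(n_d); n_tot <- as.numeric(n_tot)
  if (any(n_gd < 1)) {
    stop("npmi is undefined for pairs with zero co-occurrences", call. = FALSE)
  }
  stopifnot(all(n_gd <= n_g), all(n_gd <= n_d), all(n_g <= n_tot),
            all(n_d <= n_tot))
  # n_GD = n_tot has denominator 0 (limit 1); perfect co-occurrence
  # (n_GD = n_G = n_D) is pinned to exactly 1 rather than trusting two
  # separately-rounded logarithms to cancel
  ifelse(n_gd == n_tot | (n_gd == n_g & n_gd == n_d), 1,
         log(n_gd * n_tot / (n_g * n_d)) / (-log(n_gd / n_tot)))
}

#' @rdname npmi_value
#' @param store A `phenomine_cooccurrence` from [count_cooccurrences()].
#' @param gene_id,class_id Entity ids of the pair to score.
#' @export
npmi <- function(store, gene_id, class_id) {
  stopifnot(inherits(store, "phenomine_cooccurrence"))
  pr <- store$pairs[store$pairs$gene_id == gene_id &
                      store$pairs$class_id == class_id, ]
  if (!nrow(pr)) {
    stop(sprintf("no co-occurrences counted for (%s, %s); npmi undefined",
                 gene_id, class_id), call. = FALSE)
  }
  npmi_value(pr$n,
             store$genes$n[store$genes$gene_id == gene_id],
             store$phenotypes$n[store$phenotypes$class_id == class_id],
             store$n_tot)
}

#' Score all co-mentioned gene-phenotype pairs
#'
#' Every pair with at least one sentence-level co-mention gets an NPMI
#' score; pairs that never co-occur are absent (not scored -1).
#'
#' @param store A `phenomine_cooccurrence` from [count_cooccurrences()].
#' @return Tibble `gene_id`, `phenotype_id`, `n_g`, `n_d`, `n_gd`, `npmi`,
#'   with class `phenomine_associations`.
#' @export
score_associations <- function(store) {
  stopifnot(inherits(store, "phenomine_cooccurrence"))
  out <- store$pairs %>%
    dplyr::rename(phenotype_id = "class_id", n_gd = "n") %>%
    dplyr::inner_join(dplyr::rename(store$genes, n_g = "n"), by = "gene_id") %>%
    dplyr::inner_join(dplyr::rename(store$phenotypes, n_d = "n",
                                    phenotype_id = "class_id"),
                      by = "phenotype_id") %>%
    dplyr::mutate(npmi = npmi_value(.data$n_gd, .data$n_g, .data$n_d,
                                    store$n_tot)) %>%
    dplyr::select("gene_id", "phenotype_id", "n_g", "n_d", "n_gd", "npmi") %>%
    dplyr::arrange(.data$gene_id, dplyr::desc(.data$npmi), .data$phenotype_id)
  class(out) <- c("phenomine_associations", class(out))
  out
}

#' Rank phenotypes per gene and keep the top k
#'
#' Within each gene, phenotypes are ordered by NPMI descending; ties broken
#' by higher co-mention count, then lexicographic phenotype id. Only ranks
#' up to `k` are retained. The default `k = 25` keeps a small phenotype set
#' with less room for false positives while remaining close to the
#' similarity optimum of the rank-threshold sweep.
#'
#' @param associations Tibble from [score_associations()].
#' @param k Rank threshold (positive integer); phenotypes ranked below `k`
#'   are dropped.
#' @return The association tibble with a `rank` column, filtered to
#'   `rank <= k`, sorted by gene then rank.
#' @export
rank_associations <- function(associations, k = 25L) {
  if (!is.numeric(k) || length(k) != 1L || k < 1) {
    stop("k must be a positive integer", call. = FALSE)
  }
  out <- associations %>%
    dplyr::arrange(.data$gene_id, dplyr::desc(.data$npmi),
                   dplyr::desc(.data$n_gd), .data$phenotype_id) %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::mutate(rank = dplyr::row_number()) %>%
    dplyr::ungroup() %>%
    dplyr::filter(.data$rank <= k) %>%
    dplyr::relocate("rank", .after = "npmi")
  class(out) <- unique(c("phenomine_associations", class(out)))
  out
}

#' Write / read an association table
#'
#' TSV layout `gene_id<TAB>phenotype_id<TAB>npmi<TAB>rank<TAB>n_g<TAB>n_d<TAB>n_gd`,
#' sorted by gene then rank (unranked tables are written with rank `NA`).
#'
#' @param associations Association tibble.
#' @param path File path.
#' @export
write_associations <- function(associations, path) {
  tb <- associations
  if (!"rank" %in% names(tb)) tb$rank <- NA_integer_
  tb %>%
    dplyr::select("gene_id", "phenotype_id", "npmi", "rank", "n_g", "n_d", "n_gd") %>%
    readr::write_tsv(path)
  invisible(path)
}

#' @rdname write_associations
#' @export
read_associations <- function(path) {
  out <- readr::read_tsv(path, col_types = "ccdiiii", progress = FALSE)
  class(out) <- c("phenomine_associations", class(out))
  out
}

#' Serialize a co-occurrence store for audit
#'
#' Writes the four counters as TSV triplets `kind<TAB>id1<TAB>id2<TAB>n`
#' (`id2` empty except for pairs; `kind` one of `total`, `gene`,
#' `phenotype`, `pair`).
#'
#' @param store A `phenomine_cooccurrence`.
#' @param path File path.
#' @export
write_cooccurrence_store <- function(store, path) {
  rows <- dplyr::bind_rows(
    tibble::tibble(kind = "total", id1 = "", id2 = "", n = store$n_tot),
    dplyr::transmute(store$genes, kind = "gene", id1 = .data$gene_id,
                     id2 = "", n = .data$n),
    dplyr::transmute(store$phenotypes, kind = "phenotype", id1 = .data$class_id,
                     id2 = "", n = .data$n),
    dplyr::transmute(store$pairs, kind = "pair", id1 = .data$gene_id,
                     id2 = .data$class_id, n = .data$n)
  )
  readr::write_tsv(rows, path)
  invisible(path)
}
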